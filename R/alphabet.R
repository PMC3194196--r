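AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V",
  # ambiguous Leu-or-Ile code accepted by the expanded alphabet
  Xle = "J")

# spellings of the termination (nonsense) codon, all mapped to "*"
TERMINATION_SYMBOLS <- c("term", "amber", "opal", "ochre", "Ter", "X", "*",
                         "stop", "Stop")

AA_ONE <- unique(unname(AA_THREE_TO_ONE))

#' Symbol tables and disambiguation lists for mention recognition
#'
#' Bundles the amino-acid alphabets (three-letter including the ambiguous
#' \code{Xle}, termination spellings mapped to a \code{"*"} stop sentinel),
#' the nucleotide alphabet, and the editable disambiguation lists: a
#' stoplist of surfaces that look like variants but denote other concepts
#' (cell lines, transcription factors, ...), a blacklist of known
#' false-positive rs identifiers, and the keyword/exclusion word lists that
#' gate capitalized rs-identifier matches.
#'
#' The default lists ship as plain-text config files under
#' \code{inst/extdata} and can be replaced or extended.
#'
#' @param stoplist,rs_blacklist,rs_keywords,rs_exclusions character
#'   vectors overriding the packaged defaults.
#' @return a list with elements \code{three_letter_to_one},
#'   \code{termination_symbols}, \code{nucleotide_symbols},
#'   \code{stoplist}, \code{rs_blacklist}, \code{rs_keywords},
#'   \code{rs_exclusions}.
#' @examples
#' tab <- alphabetTables()
#' tab$three_letter_to_one[["Glu"]]
#' @export
alphabetTables <- function(stoplist = NULL, rs_blacklist = NULL,
                           rs_keywords = NULL, rs_exclusions = NULL) {
  readList <- function(file) {
    path <- system.file("extdata", file, package = "snpground")
    if (!nzchar(path)) character() else {
      x <- readLines(path, warn = FALSE)
      x <- trimws(x)
      x[nzchar(x) & !startsWith(x, "#")]
    }
  }
  list(
    three_letter_to_one = AA_THREE_TO_ONE,
    termination_symbols = TERMINATION_SYMBOLS,
    nucleotide_symbols  = NUCLEOTIDES,
    stoplist      = if (is.null(stoplist)) readList("stoplist.txt") else stoplist,
    rs_blacklist  = if (is.null(rs_blacklist)) readList("rs_blacklist.txt") else rs_blacklist,
    rs_keywords   = if (is.null(rs_keywords)) readList("rs_keywords.txt") else rs_keywords,
    rs_exclusions = if (is.null(rs_exclusions)) readList("rs_exclusions.txt") else rs_exclusions)
}

#' Watson-Crick complement of an allele set
#'
#' Needed when a record stores its alleles on the strand opposite to the
#' linked gene: a mention \code{A>G} on the gene strand corresponds to
#' \code{T>C} in such a record.
#'
#' @param alleles character vector of nucleotide symbols (A/C/G/T).
#' @return the complemented symbol set, same length and order.
#' @examples
#' complementAlleles(c("A", "G"))  # "T" "C"
#' @export
complementAlleles <- function(alleles) {
  if (!all(alleles %in% NUCLEOTIDES))
    stop("complementAlleles: non-nucleotide symbol in ",
         paste(alleles, collapse = ","))
  unname(c(A = "T", C = "G", G = "C", T = "A")[alleles])
}
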