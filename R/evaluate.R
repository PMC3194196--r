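#' Round half away from zero
#'
#' Printed evaluation percentages use conventional half-up rounding (98.05
#' becomes 98.1), not banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Score predicted mention/identifier pairs against a gold standard
#'
#' A predicted pair is a true positive when a gold pair with the same key
#' and the same rs id exists; predicted pairs absent from the gold
#' standard are false positives and unpredicted gold pairs are false
#' negatives. Mentions are keyed by document and surface (default) or by
#' document and character span. Precision and recall are reported as
#' percentages rounded half-up to one decimal.
#'
#' @param predicted data.frame with columns \code{doc_id}, \code{surface}
#'   (or \code{start}/\code{end} for span keying) and \code{rs_id}.
#' @param gold data.frame with the same columns.
#' @param key \code{"surface"} or \code{"span"}.
#' @return list with counts \code{tp}, \code{fp}, \code{fn} and
#'   percentages \code{precision}, \code{recall} (\code{precision} is
#'   \code{NA} when nothing was predicted).
#' @examples
#' evaluateNormalization(
#'   data.frame(doc_id = "d", surface = "E298D", rs_id = 1799983),
#'   data.frame(doc_id = "d", surface = "E298D", rs_id = 1799983))
#' @export
evaluateNormalization <- function(predicted, gold, key = c("surface",
                                                           "span")) {
  key <- match.arg(key)
  if (is.null(gold) || nrow(gold) == 0L)
    stop("empty gold standard: recall is undefined")
  mkKey <- function(df) {
    if (key == "surface") paste(df$doc_id, df$surface, df$rs_id, sep = "\r")
    else paste(df$doc_id, df$start, df$end, df$rs_id, sep = "\r")
  }
  pk <- unique(mkKey(predicted))
  gk <- unique(mkKey(gold))
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  evalReport(tp, fp, fn)
}

#' Evaluation report from raw counts
#'
#' @param tp,fp,fn true positive, false positive and false negative
#'   counts.
#' @return list with the counts and \code{precision}/\code{recall}
#'   percentages (half-up, one decimal); \code{precision} is \code{NA}
#'   when \code{tp + fp == 0}.
#' @examples
#' evalReport(356, 7, 171)  # precision 98.1, recall 67.5
#' @export
evalReport <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) roundHalfUp(100 * tp / (tp + fp), 1L) else
    NA_real_
  recall <- roundHalfUp(100 * tp / (tp + fn), 1L)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision,
                 recall = recall),
            class = "snpground_eval")
}

#' @export
print.snpground_eval <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  precision=%.1f%% recall=%.1f%%\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}
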