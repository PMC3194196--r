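# shared helpers: a mention-row builder and an independent base-by-base
# renderer used as oracle for the coordinate engine

mkMention <- function(kind, wild = "", mutated = "", position_text = "",
                      scheme_hint = "", rs_number = NA_real_) {
  data.frame(doc_id = "t", start = 0L, end = 0L, surface = "",
             kind = kind, wild = wild, mutated = mutated,
             position_text = position_text, accession = "",
             rs_number = rs_number, scheme_hint = scheme_hint,
             stringsAsFactors = FALSE)
}

# enumeration oracle: number every reference position of a model window by
# explicit base-by-base walking, independently of the package's geometry
# code, and return the expected textual expression
naiveRender <- function(model, gpos, scheme) {
  st <- IRanges::start(exonRanges(model)); en <- IRanges::end(exonRanges(model))
  minus <- geneStrand(model) == "-"
  # reference positions of the transcript in 5'->3' order
  tx <- if (minus) unlist(lapply(rev(seq_along(st)), function(i) en[i]:st[i]))
        else unlist(lapply(seq_along(st), function(i) st[i]:en[i]))
  idx_atg <- match(model@cds_start, tx)
  idx_stop <- match(model@cds_end, tx)
  idx <- match(gpos, tx)
  upstream_dist <- if (minus) gpos - model@tss else model@tss - gpos
  ivsNum <- function(i) if (i >= idx_atg) i - idx_atg + 1L else i - idx_atg
  if (scheme == "GENOMIC") return(as.character(gpos))
  if (!is.na(idx)) {  # exonic
    return(switch(scheme,
      LEGACY1993 = as.character(idx),
      IVS = as.character(ivsNum(idx)),
      HGVS_C = if (idx < idx_atg) paste0("c.", idx - idx_atg)
        else if (idx <= idx_stop) paste0("c.", idx - idx_atg + 1L)
        else paste0("c.*", idx - idx_stop)))
  }
  if (upstream_dist > 0) {  # upstream of the cap
    return(switch(scheme,
      LEGACY1993 = as.character(-upstream_dist),
      IVS = as.character(ivsNum(1L) - upstream_dist),
      HGVS_C = paste0("c.", ivsNum(1L) - upstream_dist)))
  }
  # intronic: distances to nearest transcript base on either side
  u <- if (minus) -gpos else gpos
  utx <- if (minus) -tx else tx
  before <- utx[utx < u]; after <- utx[utx > u]
  if (!length(before) || !length(after)) return(NA_character_)
  b <- max(before); a <- min(after)
  d5 <- u - b; d3 <- a - u
  anchor_idx <- if (d5 <= d3) match(b, utx) else match(a, utx)
  off <- if (d5 <= d3) d5 else -d3
  # intron ordinal: number of transcript gaps at or before the 5' neighbour
  intron_no <- sum(which(diff(utx) > 1) <= match(b, utx))
  fmtOff <- function(x) sprintf("%+d", x)
  switch(scheme,
    LEGACY1993 = paste0(anchor_idx, fmtOff(off)),
    IVS = paste0("IVS", intron_no, fmtOff(off)),
    HGVS_C = {
      ai <- anchor_idx
      a_txt <- if (ai < idx_atg) as.character(ai - idx_atg)
        else if (ai <= idx_stop) as.character(ai - idx_atg + 1L)
        else paste0("*", ai - idx_stop)
      paste0("c.", a_txt, fmtOff(off))
    })
}
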