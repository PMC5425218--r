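#' Call typical enhancers from histone-mark peak sets
#'
#' A typical enhancer (TE) is an H3K27ac peak that overlaps at least
#' one H3K4me1 peak and carries low promoter signal: no overlapping
#' H3K4me3 peak, or only H3K4me3 peaks below `fold_threshold`-fold
#' enrichment over the input control. The TE footprint is the H3K27ac
#' peak interval itself.
#'
#' @param k27ac H3K27ac `peak_set` (footprints and signal of the calls).
#' @param k4me1 H3K4me1 `peak_set`.
#' @param k4me3 H3K4me3 `peak_set` carrying a `fold_enrichment`
#'   column, or `NULL`/empty when no H3K4me3 peaks exist.
#' @param fold_threshold H3K4me3 fold-enrichment disqualification
#'   threshold; strictly-less-than passes (default 5).
#' @return list with `enhancers` (a `peak_set`, subset of `k27ac`) and
#'   `log` (counts at each filter stage).
#' @export
call_typical_enhancers <- function(k27ac, k4me1, k4me3 = NULL,
                                   fold_threshold = 5) {
  n0 <- nrow(k27ac)
  keep_me1 <- rep(FALSE, n0)
  if (n0 && nrow(k4me1)) {
    keep_me1 <- ov_count(peaks_to_gr(k27ac),
                                             peaks_to_gr(k4me1)) > 0L
  }
  disq <- rep(FALSE, n0)
  if (n0 && !is.null(k4me3) && nrow(k4me3)) {
    if (is.null(k4me3$fold_enrichment) || anyNA(k4me3$fold_enrichment))
      stop("H3K4me3 peaks must carry fold_enrichment over input")
    high <- k4me3[k4me3$fold_enrichment >= fold_threshold, , drop = FALSE]
    if (nrow(high))
      disq <- ov_count(peaks_to_gr(k27ac),
                                           peaks_to_gr(high)) > 0L
  }
  keep <- keep_me1 & !disq
  list(enhancers = peak_set(k27ac[keep, , drop = FALSE]),
       log = c(k27ac_peaks = n0,
               with_k4me1 = sum(keep_me1),
               dropped_high_k4me3 = sum(keep_me1 & disq),
               typical_enhancers = sum(keep)))
}
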