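#' Fraction of regions bound by a TF
#'
#' @param tf_peaks TF ChIP `peak_set`.
#' @param regions `peak_set` or stitched-region data.frame.
#' @return fraction of regions with >= 1 overlapping peak.
#' @export
fraction_bound <- function(tf_peaks, regions) {
  if (nrow(regions) == 0L) stop("no regions supplied")
  if (nrow(tf_peaks) == 0L) return(0)
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  mean(ov_count(gr, peaks_to_gr(tf_peaks)) > 0L)
}

#' Per-region TF peak counts
#'
#' @param tf_peaks TF ChIP `peak_set`.
#' @param regions region data.frame.
#' @return list: `counts` per region, `mean_bound` (mean over regions
#'   with >= 1 peak), `histogram` (table of counts),
#'   `fraction_over_5` (regions with > 5 peaks among bound regions).
#' @export
peaks_per_region <- function(tf_peaks, regions) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  counts <- if (nrow(tf_peaks) == 0L) integer(nrow(regions)) else
    ov_count(gr, peaks_to_gr(tf_peaks))
  bound <- counts[counts > 0L]
  list(counts = counts,
       mean_bound = if (length(bound)) mean(bound) else NA_real_,
       histogram = table(counts),
       fraction_over_5 = if (length(bound)) mean(bound > 5) else NA_real_)
}

#' Ratio of mean TF peak signal in SEs vs TEs
#'
#' Peaks overlapping both classes count once, as SE (priority).
#'
#' @param tf_peaks TF `peak_set` with a `signal` column.
#' @param se_regions,te_regions region data.frames.
#' @return `mean(signal | peak in SE) / mean(signal | peak in TE)`.
#' @export
tag_ratio <- function(tf_peaks, se_regions, te_regions) {
  gp <- peaks_to_gr(tf_peaks)
  as_gr <- function(r) GenomicRanges::GRanges(
    r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  in_se <- ov_count(gp, as_gr(se_regions)) > 0L
  in_te <- ov_count(gp, as_gr(te_regions)) > 0L &
    !in_se
  if (!any(in_te)) stop("no TE-overlapping peaks; tag ratio undefined")
  if (!any(in_se)) stop("no SE-overlapping peaks; tag ratio undefined")
  mean(tf_peaks$signal[in_se]) / mean(tf_peaks$signal[in_te])
}

#' Distribution of TF peaks over genomic classes
#'
#' Each peak is assigned exactly one class by priority
#' promoter > SE > TE > H3K4me3-other > other.
#'
#' @param tf_peaks TF `peak_set`.
#' @param promoter_set promoter windows ([promoter_regions()]).
#' @param se_set,te_set SE/TE footprints.
#' @param k4me3_set H3K4me3 peaks (captures promoter-like regions
#'   outside annotated promoters); may be `NULL`.
#' @return named fractions over
#'   `c("promoter","SE","TE","k4me3_other","other")`, summing to 1,
#'   plus attribute `counts`.
#' @export
genomic_distribution <- function(tf_peaks, promoter_set, se_set, te_set,
                                 k4me3_set = NULL) {
  n <- nrow(tf_peaks)
  cls <- c("promoter", "SE", "TE", "k4me3_other", "other")
  if (n == 0L) return(stats::setNames(rep(NA_real_, 5), cls))
  gp <- peaks_to_gr(tf_peaks)
  hit <- function(r) {
    if (is.null(r) || nrow(r) == 0L) return(rep(FALSE, n))
    ov_count(
      gp, GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$start + 1L, r$end))) > 0L
  }
  assign <- rep("other", n)
  assign[hit(k4me3_set)] <- "k4me3_other"
  assign[hit(te_set)] <- "TE"
  assign[hit(se_set)] <- "SE"
  assign[hit(promoter_set)] <- "promoter"
  counts <- table(factor(assign, levels = cls))
  out <- as.numeric(counts) / n
  names(out) <- cls
  attr(out, "counts") <- as.integer(counts)
  out
}

#' Condition-unique and shared TF peaks
#'
#' Overlap-based approximation of differential binding: peaks unique
#' to each condition have no overlap in the other; shared regions are
#' the merged union of the overlapping peaks of both sets.
#'
#' @param peaks_a,peaks_b TF peak sets from two conditions.
#' @return list: `a_unique`, `b_unique` (peak sets), `shared` (merged
#'   `peak_set`), and `method = "overlap"` flagging the approximation.
#' @export
unique_peaks <- function(peaks_a, peaks_b) {
  ga <- peaks_to_gr(peaks_a); gb <- peaks_to_gr(peaks_b)
  ov_a <- if (nrow(peaks_b)) ov_count(ga, gb) > 0L
  else rep(FALSE, nrow(peaks_a))
  ov_b <- if (nrow(peaks_a)) ov_count(gb, ga) > 0L
  else rep(FALSE, nrow(peaks_b))
  shared_src <- rbind(peaks_a[ov_a, c("chrom", "start", "end"), drop = FALSE],
                      peaks_b[ov_b, c("chrom", "start", "end"), drop = FALSE])
  shared <- if (nrow(shared_src)) {
    shared_src$signal <- 0
    merge_peaks(peak_set(shared_src), max_gap = 0)
  } else peak_set(character(), numeric(), numeric())
  list(a_unique = peak_set(peaks_a[!ov_a, , drop = FALSE]),
       b_unique = peak_set(peaks_b[!ov_b, , drop = FALSE]),
       shared = shared, method = "overlap")
}

#' Direct TF targets from promoter binding and knockdown response
#'
#' Targets are genes with >= 1 TF peak in their proximal promoter and
#' a differential-expression p-value strictly below the threshold upon
#' TF knockdown; the up/down split upon knockdown is reported.
#'
#' @param tf_peaks TF `peak_set`.
#' @param promoter_set promoter windows with gene ids in `name`.
#' @param de_table data.frame: `gene_id`, `log2fc` (knockdown vs
#'   control), `pvalue`.
#' @param p_threshold strict DE cutoff (default 0.05).
#' @return list: `targets` data.frame (`gene_id`, `log2fc`, `pvalue`,
#'   `direction`), `fraction_up`, `fraction_down`, `n_bound_genes`.
#' @export
direct_targets <- function(tf_peaks, promoter_set, de_table,
                           p_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% names(de_table)))
  bound_genes <- character(0)
  if (nrow(tf_peaks) && nrow(promoter_set)) {
    gprom <- peaks_to_gr(promoter_set)
    hit <- ov_count(gprom, peaks_to_gr(tf_peaks)) > 0L
    bound_genes <- unique(promoter_set$name[hit])
  }
  tg <- de_table[de_table$gene_id %in% bound_genes &
                   de_table$pvalue < p_threshold, , drop = FALSE]
  tg$direction <- ifelse(tg$log2fc > 0, "up", "down")
  list(targets = tg,
       fraction_up = if (nrow(tg)) mean(tg$direction == "up") else NA_real_,
       fraction_down = if (nrow(tg)) mean(tg$direction == "down") else NA_real_,
       n_bound_genes = length(bound_genes))
}
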