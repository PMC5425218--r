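CHROMATIN_CATEGORIES <- c("active_SE", "active_TE", "poised",
                          "k4me1_only", "unmarked")

#' Classify regions into chromatin-state categories
#'
#' Priority: active_SE > active_TE > poised > k4me1_only > unmarked.
#' Any overlap (>= 1 bp) decides membership. Poised requires H3K4me1
#' plus H3K27me3; without an H3K27me3 track the poised class is
#' unavailable and such regions fall to k4me1_only (warned once).
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param se,te SE/TE footprints (the partition from the SE caller).
#' @param k4me1 H3K4me1 `peak_set`.
#' @param k27me3 H3K27me3 `peak_set`, or `NULL` when unavailable.
#' @return factor of categories, one per region.
#' @export
classify_region <- function(regions, se, te, k4me1, k27me3 = NULL) {
  n <- nrow(regions)
  if (n == 0L)
    return(factor(character(), levels = CHROMATIN_CATEGORIES))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  hit <- function(p) {
    if (is.null(p) || nrow(p) == 0L) return(rep(FALSE, n))
    ov_count(gr, peaks_to_gr(p)) > 0L
  }
  in_se <- hit(se); in_te <- hit(te); in_me1 <- hit(k4me1)
  if (is.null(k27me3)) {
    warning("no H3K27me3 track: poised class unavailable, ",
            "such regions classify as k4me1_only")
    in_me3 <- rep(FALSE, n)
  } else in_me3 <- hit(k27me3)
  cat <- rep("unmarked", n)
  cat[in_me1] <- "k4me1_only"
  cat[in_me1 & in_me3] <- "poised"
  cat[in_te] <- "active_TE"
  cat[in_se] <- "active_SE"
  factor(cat, levels = CHROMATIN_CATEGORIES)
}

#' Cross-state transition table
#'
#' Classifies each origin region in the destination state's chromatin
#' landscape and tabulates counts and per-origin-category fractions.
#'
#' @param origin_regions data.frame with `chrom`, `start`, `end` and a
#'   `category` column (origin-state classification).
#' @param dest_marks list with elements `se`, `te`, `k4me1` and
#'   optionally `k27me3`: the destination state's peak sets.
#' @return list: `counts` (origin x destination matrix), `fractions`
#'   (rows normalized to 1 over non-empty origins), `dest_category`.
#' @export
transition_table <- function(origin_regions, dest_marks) {
  dest <- classify_region(origin_regions,
                          se = dest_marks$se, te = dest_marks$te,
                          k4me1 = dest_marks$k4me1,
                          k27me3 = dest_marks$k27me3)
  origin <- factor(as.character(origin_regions$category),
                   levels = CHROMATIN_CATEGORIES)
  counts <- table(origin = origin, destination = dest)
  counts <- unclass(counts)
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs > 0, rs, NA_real_)
  list(counts = counts, fractions = fractions, dest_category = dest)
}

#' Three-way Venn counts over merged union elements
#'
#' The union of all three peak sets is merged into disjoint union
#' elements; each element is labeled by which of the inputs overlap
#' it, giving one count per membership class.
#'
#' @param a,b,c peak sets.
#' @param labels names for the three sets.
#' @return named integer vector over the 7 classes
#'   (`a`, `b`, `c`, `ab`, `ac`, `bc`, `abc`) plus `union_total`.
#' @export
venn3 <- function(a, b, c, labels = c("a", "b", "c")) {
  all_peaks <- rbind(a[c("chrom", "start", "end")],
                     b[c("chrom", "start", "end")],
                     c[c("chrom", "start", "end")])
  classes <- c(labels, paste0(labels[1], labels[2]),
               paste0(labels[1], labels[3]),
               paste0(labels[2], labels[3]),
               paste0(labels[1], labels[2], labels[3]))
  out <- stats::setNames(integer(8), c(classes, "union_total"))
  if (nrow(all_peaks) == 0L) return(out)
  all_peaks$signal <- 0
  u <- merge_peaks(peak_set(all_peaks), max_gap = 0)
  gu <- peaks_to_gr(u)
  member <- function(p) if (nrow(p) == 0L) rep(FALSE, length(gu)) else
    ov_count(gu, peaks_to_gr(p)) > 0L
  ma <- member(a); mb <- member(b); mc <- member(c)
  key <- paste0(ifelse(ma, labels[1], ""), ifelse(mb, labels[2], ""),
                ifelse(mc, labels[3], ""))
  tab <- table(key)
  out[names(tab)[names(tab) %in% classes]] <-
    tab[names(tab) %in% classes]
  out["union_total"] <- length(gu)
  out
}

#' Union-normalized persistence between two states
#'
#' Fraction of merged union elements of `a` and `b` that are
#' overlapped by both sets.
#'
#' @param a,b peak sets (e.g. SEs in two states).
#' @param normalization `"union"` (default) divides by the number of
#'   union elements; `"sum"` divides by `|a| + |b|` element counts.
#' @return fraction in \[0, 1\].
#' @export
persistence_fraction <- function(a, b, normalization = c("union", "sum")) {
  normalization <- match.arg(normalization)
  if (nrow(a) == 0L && nrow(b) == 0L)
    stop("persistence undefined: both sets empty")
  all_peaks <- rbind(a[c("chrom", "start", "end")],
                     b[c("chrom", "start", "end")])
  all_peaks$signal <- 0
  u <- merge_peaks(peak_set(all_peaks), max_gap = 0)
  gu <- peaks_to_gr(u)
  member <- function(p) if (nrow(p) == 0L) rep(FALSE, length(gu)) else
    ov_count(gu, peaks_to_gr(p)) > 0L
  shared <- sum(member(a) & member(b))
  denom <- switch(normalization, union = length(gu),
                  sum = nrow(a) + nrow(b))
  shared / denom
}
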