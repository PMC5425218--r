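#' Stitch nearby peaks into candidate super-enhancer regions
#'
#' Peaks separated by at most `stitch_distance` bp on the same
#' chromosome are joined transitively; the stitched region spans the
#' first to the last constituent and its `total_signal` is the sum of
#' constituent signals (apply [subtract_input()] upstream when an
#' input-control track is available).
#'
#' @param peaks sorted H3K27ac `peak_set`.
#' @param stitch_distance maximum gap bridged (bp); ROSE default 12500.
#' @return data.frame of stitched regions: `chrom`, `start`, `end`,
#'   `total_signal`, `n_constituents`, plus a list column
#'   `constituents` of row indices into `peaks`.
#' @export
stitch <- function(peaks, stitch_distance = 12500) {
  if (stitch_distance < 0) stop("stitch_distance must be non-negative")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), total_signal = numeric(),
                      n_constituents = integer()))
  gr <- peaks_to_gr(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    total_signal = vapply(revmap, function(i)
                      sum(peaks$signal[i]), 0),
                    n_constituents = lengths(revmap),
                    stringsAsFactors = FALSE)
  out$constituents <- lapply(revmap, as.integer)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Geometric cutoff on the signal-vs-rank curve
#'
#' Regions are ranked ascending by signal; both axes are scaled to
#' \[0, 1\]. The cutoff is the tangency point of a unit-slope line with
#' the scaled curve, i.e. the rank minimising (scaled signal − scaled
#' rank) — past this point the curve rises faster than the diagonal.
#' Exact ties resolve to the highest such rank (conservative). Regions
#' strictly above the cutoff rank are super-enhancer candidates.
#'
#' @param signals numeric vector of stitched-region signals (any
#'   order; ranked internally).
#' @return list: `cutoff_index` (number of sub-cutoff regions, on the
#'   ascending ranking), `cutoff_signal`, and `order` (permutation
#'   sorting `signals` ascending).
#' @export
find_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 2L) stop("need at least 2 regions to place a cutoff")
  ord <- order(signals)
  y <- signals[ord]
  if (y[n] == y[1]) {
    warning("all region signals equal; no super-enhancers called")
    return(list(cutoff_index = n, cutoff_signal = y[n], order = ord))
  }
  ys <- (y - y[1]) / (y[n] - y[1])
  xs <- (seq_len(n) - 1) / (n - 1)
  d <- ys - xs
  cut <- max(which(d == min(d)))     # highest rank at exact ties
  list(cutoff_index = cut, cutoff_signal = y[cut], order = ord)
}

#' Call super-enhancers from stitched regions
#'
#' Super-enhancers (SEs) are stitched regions ranking above the
#' geometric cutoff of the signal-vs-rank curve AND spanning at least
#' `min_length` bp. Everything else is returned as the TE-eligible
#' remainder; SE footprints should be subtracted from called typical
#' enhancers downstream ([subtract_peaks()]).
#'
#' @param stitched output of [stitch()].
#' @param min_length minimum SE span in bp (default 12500).
#' @return list: `se` and `remainder` (both stitched-region
#'   data.frames), `cutoff_index`, `cutoff_signal`.
#' @export
call_super_enhancers <- function(stitched, min_length = 12500) {
  n <- nrow(stitched)
  empty <- stitched[integer(0), , drop = FALSE]
  if (n == 0L)
    return(list(se = empty, remainder = empty,
                cutoff_index = 0L, cutoff_signal = NA_real_))
  if (n == 1L)
    return(list(se = empty, remainder = stitched,
                cutoff_index = 1L, cutoff_signal = stitched$total_signal))
  cut <- find_cutoff(stitched$total_signal)
  above <- logical(n)
  if (cut$cutoff_index < n)
    above[cut$order[(cut$cutoff_index + 1L):n]] <- TRUE
  long_enough <- (stitched$end - stitched$start) >= min_length
  is_se <- above & long_enough
  list(se = stitched[is_se, , drop = FALSE],
       remainder = stitched[!is_se, , drop = FALSE],
       cutoff_index = cut$cutoff_index,
       cutoff_signal = cut$cutoff_signal)
}

#' Input-control subtraction for peak signal
#'
#' @param peak_signal non-negative ChIP tag counts.
#' @param input_signal non-negative input-control tag counts.
#' @param scale library-size ratio applied to the input (default 1).
#' @return `max(0, peak_signal - scale * input_signal)`, vectorized.
#' @export
subtract_input <- function(peak_signal, input_signal, scale = 1) {
  if (any(scale < 0)) stop("library-size scale must be non-negative")
  if (any(peak_signal < 0) || any(input_signal < 0))
    stop("signals must be non-negative")
  pmax(0, peak_signal - scale * input_signal)
}

#' Rank curve table for plotting/export
#' @param stitched output of [stitch()].
#' @return data.frame `rank` (ascending), `total_signal`, `is_above_cutoff`.
#' @export
rank_curve <- function(stitched) {
  cut <- find_cutoff(stitched$total_signal)
  n <- nrow(stitched)
  data.frame(rank = seq_len(n),
             total_signal = stitched$total_signal[cut$order],
             is_above_cutoff = seq_len(n) > cut$cutoff_index)
}
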