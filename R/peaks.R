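#' Construct a validated, sorted peak set
#'
#' A peak set is the package's basic container for scored genomic
#' intervals: a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open, BED convention), `signal` (non-negative tag
#' count or density) and, optionally, `fold_enrichment` (ratio over an
#' input control) and `name`. Rows are sorted by (chrom, start, end).
#'
#' @param chrom character vector of chromosome names, or a data.frame
#'   already carrying `chrom`/`start`/`end` columns.
#' @param start,end integer coordinates; `end` is exclusive and must
#'   exceed `start`.
#' @param signal numeric, recycled; defaults to 0.
#' @param fold_enrichment optional numeric >= 0.
#' @param name optional character labels.
#' @return a sorted data.frame of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, signal = 0, fold_enrichment = NULL,
                     name = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    if (is.null(df$signal)) df$signal <- 0
  } else {
    n <- length(chrom)
    df <- data.frame(chrom = as.character(chrom),
                     start = as.numeric(start),
                     end = as.numeric(end),
                     signal = rep_len(as.numeric(signal), n),
                     stringsAsFactors = FALSE)
    if (!is.null(fold_enrichment)) df$fold_enrichment <- as.numeric(fold_enrichment)
    if (!is.null(name)) df$name <- as.character(name)
  }
  validate_peaks(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("peak_set", class(df)))
  df
}

validate_peaks <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stop("peak set: empty chromosome name")
  if (any(df$start < 0)) stop("peak set: negative start coordinate")
  if (any(df$end <= df$start))
    stop("peak set: end must exceed start (half-open intervals)")
  if (any(df$signal < 0)) stop("peak set: negative signal")
  if (!is.null(df$fold_enrichment) &&
      any(df$fold_enrichment < 0, na.rm = TRUE))
    stop("peak set: negative fold enrichment")
  invisible(df)
}

#' Convert a peak set to GRanges (1-based closed, internal convention)
#' @param p a `peak_set` data.frame.
#' @return a [GenomicRanges::GRanges] with metadata columns preserved.
#' @export
peaks_to_gr <- function(p) {
  gr <- GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end))
  extra <- setdiff(names(p), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(p[extra])
  gr
}

#' Convert GRanges back to the BED-convention peak set
#' @param gr a GRanges object.
#' @return a `peak_set` data.frame (0-based half-open).
#' @export
gr_to_peaks <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  if (is.null(df$signal)) df$signal <- 0
  peak_set(df)
}

#' Read a BED-like tab-separated peak file
#'
#' Expects >= 3 tab-separated columns (chrom, start, end). Signal and
#' fold-enrichment may sit in any extra numeric column, selected by
#' index; absent signal defaults to 0.
#'
#' @param path file path.
#' @param signal_column 1-based column index carrying the signal, or
#'   `NULL` for none.
#' @param fold_column optional column index of fold enrichment over
#'   input control.
#' @param name_column optional column index of the region name.
#' @return a sorted `peak_set`.
#' @export
read_bed <- function(path, signal_column = NULL, fold_column = NULL,
                     name_column = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(peak_set(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d has %d field(s); expected >= 3 tab-separated",
                 path, bad[1], n[bad[1]]))
  pull <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(pull(i)))
    if (anyNA(v))
      stop(sprintf("%s: line %d: non-numeric %s field",
                   path, which(is.na(v))[1], what))
    v
  }
  start <- num(2L, "start"); end <- num(3L, "end")
  if (any(end <= start))
    stop(sprintf("%s: line %d: end <= start", path, which(end <= start)[1]))
  getcol <- function(idx, what) {
    if (is.null(idx)) return(NULL)
    if (any(n < idx))
      stop(sprintf("%s: line %d lacks column %d", path, which(n < idx)[1], idx))
    num(idx, what)
  }
  sig <- getcol(signal_column, "signal")
  fe <- getcol(fold_column, "fold enrichment")
  nm <- if (is.null(name_column)) NULL else pull(name_column)
  peak_set(pull(1L), start, end,
           signal = if (is.null(sig)) 0 else sig,
           fold_enrichment = fe, name = nm)
}

#' Write a peak set as BED with a signal column
#' @param p a `peak_set`.
#' @param path output path.
#' @export
write_bed <- function(p, path) {
  nm <- if (!is.null(p$name)) p$name else sprintf("region_%d", seq_len(nrow(p)))
  out <- data.frame(p$chrom, format(p$start, scientific = FALSE, trim = TRUE),
                    format(p$end, scientific = FALSE, trim = TRUE),
                    nm, p$signal)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairs of overlapping peaks between two sets
#'
#' @param a,b peak sets.
#' @param min_overlap minimum shared base pairs (default 1, i.e. any
#'   overlap, the intersectBed default).
#' @return data.frame with columns `a_idx`, `b_idx` (row indices into
#'   the sorted inputs) and `overlap_bp`.
#' @export
intersect_peaks <- function(a, b, min_overlap = 1) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  ga <- peaks_to_gr(a); gb <- peaks_to_gr(b)
  hits <- ov_hits(ga, gb, minoverlap = min_overlap)
  ov <- IRanges::width(IRanges::pintersect(
    ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)]))
  data.frame(a_idx = S4Vectors::queryHits(hits),
             b_idx = S4Vectors::subjectHits(hits),
             overlap_bp = ov)
}

#' Subtract one peak set's footprint from another
#'
#' Returns the portions of `a` intervals not covered by any `b`
#' interval; fully covered peaks are dropped, partially covered peaks
#' are truncated (possibly split) and retain their original signal.
#'
#' @param a,b peak sets.
#' @return a `peak_set`.
#' @export
subtract_peaks <- function(a, b) {
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(peak_set(a))
  ga <- peaks_to_gr(a); gb <- peaks_to_gr(b)
  pieces <- GenomicRanges::subtract(ga, gb, ignore.strand = TRUE)
  rep_idx <- rep(seq_along(ga), lengths(pieces))
  flat <- unlist(pieces, use.names = FALSE)
  if (!length(flat))
    return(peak_set(character(), numeric(), numeric()))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(flat)),
                    start = GenomicRanges::start(flat) - 1L,
                    end = GenomicRanges::end(flat),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(a), c("chrom", "start", "end"))
  for (col in extra) out[[col]] <- a[[col]][rep_idx]
  peak_set(out)
}

#' Merge overlapping or nearby peaks
#'
#' Peaks on the same chromosome overlapping or separated by at most
#' `max_gap` bp are unioned transitively; merged signal is the sum of
#' constituent signals.
#'
#' @param a a peak set.
#' @param max_gap maximum gap (bp) bridged by the merge; default 0.
#' @return a `peak_set` with columns `signal` and `n_merged`.
#' @export
merge_peaks <- function(a, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be non-negative")
  if (nrow(a) == 0L) return(a)
  ga <- peaks_to_gr(a)
  red <- GenomicRanges::reduce(ga, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    signal = vapply(revmap, function(i) sum(a$signal[i]), 0),
                    n_merged = lengths(revmap),
                    stringsAsFactors = FALSE)
  peak_set(out)
}

#' Nearest gene for a single region
#'
#' Distance is 0 when the region overlaps the gene body; otherwise the
#' gap in bp between region and gene body. Ties go to the gene with
#' the smaller start, then the lexically smaller `gene_id`.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param annotation gene annotation data.frame (see [gene_annotation()]).
#' @return list with `gene_id` and `distance`.
#' @export
closest_gene <- function(region, annotation) {
  res <- nearest_genes(data.frame(chrom = region$chrom[1],
                                  start = region$start[1],
                                  end = region$end[1]), annotation)
  list(gene_id = res$gene_id[1], distance = res$distance[1])
}

#' Nearest gene for every region (vectorized)
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param annotation gene annotation data.frame.
#' @return data.frame with one row per region: `gene_id`, `distance`.
#' @export
nearest_genes <- function(regions, annotation) {
  if (nrow(annotation) == 0L) stop("empty gene annotation")
  # deterministic tie-break: genes pre-ordered by (start, gene_id)
  ann <- annotation[order(annotation$start, annotation$gene_id), , drop = FALSE]
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  gg <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1L, ann$end))
  # candidate nearest genes: overlapping, nearest upstream, nearest
  # downstream (all ties); resolved here so equidistant genes break
  # deterministically by (start, gene_id) = subject order
  hits_list <- list(
    ov_hits(gr, gg, ignore.strand = TRUE),
    GenomicRanges::precede(gr, gg, select = "all", ignore.strand = TRUE),
    GenomicRanges::follow(gr, gg, select = "all", ignore.strand = TRUE))
  q <- unlist(lapply(hits_list, S4Vectors::queryHits))
  s <- unlist(lapply(hits_list, S4Vectors::subjectHits))
  gene_id <- rep(NA_character_, length(gr))
  distance <- rep(NA_real_, length(gr))
  if (length(q)) {
    d <- GenomicRanges::distance(gr[q], gg[s], ignore.strand = TRUE)
    o <- order(q, d, s)
    q <- q[o]; s <- s[o]; d <- d[o]
    first <- !duplicated(q)
    gene_id[q[first]] <- ann$gene_id[s[first]]
    distance[q[first]] <- d[first]
  }
  if (anyNA(gene_id))
    warning("some regions have no gene on their chromosome; NA returned")
  data.frame(gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Replicate-consensus peaks
#'
#' Keeps first-replicate peaks having any overlap with the second
#' replicate (first-replicate coordinates retained), reporting the
#' fraction of each replicate that overlaps the other.
#'
#' @param rep1,rep2 peak sets for the two replicates.
#' @return list with `peaks` (consensus `peak_set`) and
#'   `overlap_fraction` (named numeric, `rep1` and `rep2`).
#' @export
replicate_consensus <- function(rep1, rep2) {
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) {
    return(list(peaks = peak_set(character(), numeric(), numeric()),
                overlap_fraction = c(rep1 = 0, rep2 = 0)))
  }
  g1 <- peaks_to_gr(rep1); g2 <- peaks_to_gr(rep2)
  ov1 <- ov_count(g1, g2) > 0L
  ov2 <- ov_count(g2, g1) > 0L
  list(peaks = peak_set(rep1[ov1, , drop = FALSE]),
       overlap_fraction = c(rep1 = mean(ov1), rep2 = mean(ov2)))
}

# findOverlaps/countOverlaps emit a warning when the two objects share
# no seqlevels (legitimately empty overlap); silence it package-wide
ov_count <- function(a, b, ...)
  suppressWarnings(GenomicRanges::countOverlaps(a, b, ...))
ov_hits <- function(a, b, ...)
  suppressWarnings(GenomicRanges::findOverlaps(a, b, ...))
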