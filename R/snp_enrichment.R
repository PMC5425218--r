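#' Read a SNP association table
#' @param path TSV with header: chrom, pos (1-based), pvalue, disease,
#'   optionally rsid.
#' @return validated data.frame.
#' @export
read_snps <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "pvalue", "disease") %in% names(df)))
  validate_snps(df)
  df
}

validate_snps <- function(snps) {
  if (any(snps$pos < 1)) stop("SNP positions are 1-based; pos must be >= 1")
  if (any(snps$pvalue <= 0 | snps$pvalue > 1))
    stop("SNP p-values must lie in (0, 1]")
  invisible(snps)
}

#' Keep genome-wide significant associations
#'
#' @param snps SNP data.frame.
#' @param threshold inclusive p-value cutoff (default 5e-8).
#' @return filtered data.frame.
#' @export
filter_genomewide <- function(snps, threshold = 5e-8) {
  validate_snps(snps)
  snps[snps$pvalue <= threshold, , drop = FALSE]
}

#' Prune associated loci to their lead SNP
#'
#' Per disease, SNPs are selected greedily in order of ascending
#' p-value (ties broken by position); every other same-disease SNP on
#' the same chromosome within +-`window` bp of a selected lead is
#' removed.
#'
#' @param snps SNP data.frame.
#' @param window locus half-width in bp (default 500000).
#' @return pruned data.frame (original row order restored).
#' @export
prune_loci <- function(snps, window = 500000) {
  if (nrow(snps) == 0L) return(snps)
  keep <- logical(nrow(snps))
  for (dz in unique(snps$disease)) {
    idx <- which(snps$disease == dz)
    ord <- idx[order(snps$pvalue[idx], snps$pos[idx])]
    taken <- integer(0)
    for (i in ord) {
      clash <- any(snps$chrom[taken] == snps$chrom[i] &
                     abs(snps$pos[taken] - snps$pos[i]) <= window)
      if (!clash) taken <- c(taken, i)
    }
    keep[taken] <- TRUE
  }
  snps[keep, , drop = FALSE]
}

# Count SNPs falling in any region (half-open, SNP pos converted to
# 0-based). Regions are merged first so each SNP counts once.
count_snps_in_regions <- function(snps, regions) {
  if (nrow(snps) == 0L || nrow(regions) == 0L) return(0L)
  total <- 0L
  for (ch in unique(regions$chrom)) {
    pos0 <- sort(snps$pos[snps$chrom == ch] - 1)
    if (!length(pos0)) next
    ri <- regions$chrom == ch
    s <- regions$start[ri]; e <- regions$end[ri]
    o <- order(s); s <- s[o]; e <- e[o]
    # merge overlapping intervals
    cmax <- cummax(e)
    new_block <- c(TRUE, s[-1] > cmax[-length(s)])
    blk <- cumsum(new_block)
    ms <- tapply(s, blk, min); me <- tapply(e, blk, max)
    total <- total + sum(findInterval(me - 0.5, pos0) -
                           findInterval(ms - 0.5, pos0))
  }
  as.integer(total)
}

#' Annotate SNPs overlapping a region set
#'
#' Reports each SNP falling inside any region (half-open test after
#' 1-based to 0-based conversion), annotated with its nearest gene and
#' a location class: Promoter (proximal promoter window), Exon (when
#' an exon set is supplied), Intron (gene body outside exons), else
#' Intergenic.
#'
#' @param snps SNP data.frame.
#' @param regions `peak_set` of regions (e.g. SEs).
#' @param annotation gene annotation data.frame.
#' @param promoters promoter `peak_set`; computed from `annotation`
#'   via [promoter_regions()] when `NULL`.
#' @param exons optional exon `peak_set`.
#' @return data.frame of hits with `gene_id`, `distance`, `location`.
#' @export
overlap_snps <- function(snps, regions, annotation, promoters = NULL,
                         exons = NULL) {
  validate_snps(snps)
  empty <- cbind(snps[integer(0), , drop = FALSE],
                 data.frame(gene_id = character(), distance = numeric(),
                            location = character()))
  if (nrow(snps) == 0L || nrow(regions) == 0L) return(empty)
  if (is.null(promoters)) promoters <- promoter_regions(annotation)
  gs <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  inside <- ov_count(gs, peaks_to_gr(regions)) > 0L
  hits <- snps[inside, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  gh <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$pos, hits$pos))
  ng <- nearest_genes(data.frame(chrom = hits$chrom, start = hits$pos - 1,
                                 end = hits$pos), annotation)
  in_prom <- ov_count(gh, peaks_to_gr(promoters)) > 0L
  gg <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start + 1L,
                                                annotation$end))
  in_body <- ov_count(gh, gg) > 0L
  in_exon <- if (!is.null(exons) && nrow(exons))
    ov_count(gh, peaks_to_gr(exons)) > 0L
  else rep(FALSE, nrow(hits))
  location <- rep("Intergenic", nrow(hits))
  location[in_body] <- "Intron"
  location[in_exon] <- "Exon"
  location[in_prom] <- "Promoter"
  hits$gene_id <- ng$gene_id
  hits$distance <- ng$distance
  hits$location <- location
  rownames(hits) <- NULL
  hits
}

#' Null distribution of SNP overlap with size-matched random regions
#'
#' Each draw replaces every region by a uniformly placed interval of
#' the same length on its own chromosome and counts SNPs falling in
#' the replacement set.
#'
#' @param regions `peak_set` (the observed regions being emulated).
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param snps SNP data.frame whose overlap is counted.
#' @param n_draws number of random-region draws (default 1000).
#' @param seed RNG seed.
#' @return list: `counts` (length `n_draws`), `mean`, `n_draws`, `seed`.
#' @export
random_region_null <- function(regions, chrom_sizes, snps,
                               n_draws = 1000, seed = 1) {
  if (nrow(regions) == 0L) stop("no regions supplied")
  if (!all(regions$chrom %in% names(chrom_sizes)))
    stop("chrom_sizes must cover every region chromosome")
  len <- regions$end - regions$start
  maxstart <- chrom_sizes[regions$chrom] - len
  if (any(maxstart < 0))
    stop("region longer than its chromosome")
  set.seed(seed)
  counts <- integer(n_draws)
  tmpl <- data.frame(chrom = regions$chrom, start = 0, end = 0)
  for (d in seq_len(n_draws)) {
    tmpl$start <- floor(stats::runif(nrow(regions)) * (maxstart + 1))
    tmpl$end <- tmpl$start + len
    counts[d] <- count_snps_in_regions(snps, tmpl)
  }
  list(counts = counts, mean = mean(counts), n_draws = n_draws,
       seed = seed)
}

#' Chi-square and empirical enrichment test against a random null
#'
#' Compares the observed count of SNPs inside regions against the null
#' expectation (mean over random-region draws) with a two-cell
#' chi-square statistic on (in-region, out-of-region) counts, df = 1,
#' and reports alongside the empirical permutation p-value
#' `(1 + #{null >= observed}) / (1 + n_draws)`.
#'
#' @param observed observed in-region SNP count.
#' @param null either the list from [random_region_null()] or a
#'   numeric vector of null counts.
#' @param total_snps total SNPs tested.
#' @return list: `observed`, `expected`, `chisq`, `p.value`
#'   (chi-square upper tail), `empirical_p`, `n_null_draws`, `seed`.
#' @export
enrichment_test <- function(observed, null, total_snps) {
  counts <- if (is.list(null)) null$counts else null
  seed <- if (is.list(null)) null$seed else NA
  expected <- mean(counts)
  if (observed > total_snps) stop("observed exceeds total_snps")
  if (expected <= 0 || expected >= total_snps)
    stop("degenerate null expectation; increase draws or add a pseudo-count")
  chisq <- (observed - expected)^2 / expected +
    ((total_snps - observed) - (total_snps - expected))^2 /
    (total_snps - expected)
  list(observed = observed, expected = expected, chisq = chisq,
       p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       empirical_p = (1 + sum(counts >= observed)) / (1 + length(counts)),
       n_null_draws = length(counts), seed = seed)
}
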