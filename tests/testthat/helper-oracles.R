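# Brute-force oracles used across the suite. Each deliberately avoids
# the package's implementation path (bitmaps, all-pairs scans, direct
# enumeration) so agreement is an independent check.

# per-base occupancy bitmap of a peak set on a toy chromosome
oracle_bitmap <- function(peaks, chrom, len) {
  v <- logical(len)
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != chrom) next
    s <- peaks$start[i] + 1L; e <- peaks$end[i]
    if (e >= s) v[s:e] <- TRUE
  }
  v
}

# all-pairs interval overlap scan
oracle_intersect <- function(a, b, min_overlap = 1) {
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap)
      pairs[[length(pairs) + 1L]] <- c(i, j, ov)
  }
  if (!length(pairs))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  m <- do.call(rbind, pairs)
  data.frame(a_idx = m[, 1], b_idx = m[, 2], overlap_bp = m[, 3])
}

# all-pairs nearest gene with the smaller-start / lexical tie-break
oracle_closest <- function(region, genes) {
  d <- rep(Inf, nrow(genes))
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != region$chrom) next
    if (region$start < genes$end[j] && genes$start[j] < region$end) d[j] <- 0
    else d[j] <- max(genes$start[j] - region$end, region$start - genes$end[j])
  }
  best <- which(d == min(d))
  best <- best[order(genes$start[best], genes$gene_id[best])][1]
  list(gene_id = genes$gene_id[best], distance = min(d))
}

# stepwise weighted running-sum ES, written as an explicit loop
oracle_es <- function(statistics, signature, p = 1) {
  ord <- order(statistics, names(statistics), decreasing = TRUE,
               method = "radix")
  stat <- statistics[ord]
  hits <- names(stat) %in% signature
  n <- length(stat); nh <- sum(hits)
  nr <- sum(abs(stat[hits])^p)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hits[i]) abs(stat[[i]])^p / nr else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# one-sided Fisher p by direct enumeration of more-extreme tables
oracle_fisher_p <- function(a, b, n1, n2) {
  k <- a + b
  num <- vapply(a:min(k, n1), function(x)
    choose(n1, x) * choose(n2, k - x), 0)
  den <- sum(vapply(max(0, k - n2):min(k, n1), function(x)
    choose(n1, x) * choose(n2, k - x), 0))
  sum(num) / den
}

# per-window PWM log-odds sum, scalar loop
oracle_scan_score <- function(p, sequence, offset, strand,
                              background = rep(0.25, 4), pseudo = 1e-3) {
  m <- p$matrix + pseudo
  m <- sweep(m, 2, colSums(m), "/")
  lo <- log2(m / background)
  L <- ncol(lo)
  if (strand == "-") lo <- lo[4:1, L:1, drop = FALSE]
  chars <- strsplit(sequence, "")[[1]][(offset + 1):(offset + L)]
  total <- 0
  for (j in seq_len(L)) {
    k <- match(chars[j], c("A", "C", "G", "T"))
    if (!is.na(k)) total <- total + lo[k, j]
  }
  unname(total)
}

# random peak set on one toy chromosome
random_toy_peaks <- function(n, len = 10000, max_w = 800) {
  if (n == 0) return(peak_set(character(), numeric(), numeric()))
  s <- sort(sample.int(len - max_w, n))
  w <- sample.int(max_w, n, replace = TRUE)
  peak_set(rep("chrT", n), s, pmin(s + w, len), signal = 1)
}

sharp_pwm <- function(id, owner, word, sharp = 0.97) {
  bases <- strsplit(word, "")[[1]]
  m <- matrix((1 - sharp) / 3, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- sharp
  pwm(id, owner, m)
}

dinuc_counts <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  table(paste0(s[-length(s)], s[-1]))
}
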