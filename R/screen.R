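#' Read a knockdown screen matrix
#' @param path TSV: gene rows, factor columns, header, first column
#'   gene ids.
#' @return numeric matrix (genes x factors).
#' @export
read_knockdown_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Project knockdown experiments onto the first two principal components
#'
#' Each factor (column) is one experiment; the matrix is gene-wise
#' centered and decomposed by SVD. Component signs follow a
#' deterministic convention: the largest-magnitude gene loading of
#' each component is made positive.
#'
#' @param matrix numeric genes x factors matrix of expression
#'   statistics.
#' @return list: `coordinates` (factors x 2), `variance_explained`
#'   (fractions for PC1/PC2), `loadings` (genes x 2).
#' @export
pca_project <- function(matrix) {
  if (ncol(matrix) < 2L || nrow(matrix) < 2L)
    stop("need >= 2 factors and >= 2 genes")
  centered <- matrix - rowMeans(matrix)
  if (all(abs(centered) < 1e-12))
    stop("constant matrix: no variance to decompose")
  sv <- svd(centered)
  flip <- vapply(1:2, function(k) {
    u <- sv$u[, k]
    sign(u[which.max(abs(u))])
  }, 0)
  coords <- sweep(sv$v[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2), 2,
                  flip, "*")
  loadings <- sweep(sv$u[, 1:2, drop = FALSE], 2, flip, "*")
  rownames(coords) <- colnames(matrix)
  colnames(coords) <- colnames(loadings) <- c("PC1", "PC2")
  rownames(loadings) <- rownames(matrix)
  list(coordinates = coords,
       variance_explained = sv$d[1:2]^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Weighted running-sum enrichment score (GSEA-style)
#'
#' Genes are ranked by the knockdown statistic (most up-regulated
#' first). Walking down the ranking, signature hits increment the
#' running sum by `|statistic|^p` normalized over signature hits;
#' misses decrement by `1/(N - |S|)`. The enrichment score is the
#' extremum (largest absolute excursion) of the running sum.
#'
#' @param statistics named numeric vector (gene ids as names); ranked
#'   internally in decreasing order, ties broken by gene id for
#'   determinism.
#' @param signature character vector of gene ids.
#' @param weight_exponent `p`; 1 = classic weighted ES, 0 = rank-only.
#' @return list: `es`, `running_sum`, `hit_indices`, `order`.
#' @export
enrichment_score <- function(statistics, signature, weight_exponent = 1) {
  ord <- order(statistics, names(statistics), decreasing = TRUE,
               method = "radix")
  stat <- statistics[ord]
  genes <- names(stat)
  hits <- genes %in% signature
  if (!any(hits)) stop("signature does not intersect the gene universe")
  n <- length(stat); nh <- sum(hits)
  if (nh == n) stop("signature covers the whole universe; ES undefined")
  w <- abs(stat)^weight_exponent
  inc <- numeric(n)
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (n - nh)
  rs <- cumsum(inc)
  es <- rs[which.max(abs(rs))]
  list(es = es, running_sum = rs, hit_indices = which(hits), order = ord)
}

#' Inverse (display) enrichment score
#'
#' Negates the ES computed on the up-regulated-first ranking so that
#' signatures concentrated among genes down-regulated upon knockdown
#' display positive scores.
#'
#' @param es enrichment score (numeric, possibly vector).
#' @return `-es`.
#' @export
inverse_score <- function(es) -es

#' Gene-label permutation p-value for an enrichment score
#'
#' @param statistics named numeric vector of knockdown statistics.
#' @param signature gene-id vector.
#' @param n_perm permutations (default 1000, minimum 100).
#' @param seed RNG seed.
#' @param weight_exponent passed to [enrichment_score()].
#' @return list: `p.value` (two-sided empirical,
#'   `(1 + #{|ES_perm| >= |ES|}) / (1 + n_perm)`), `es`, `n_perm`, `seed`.
#' @export
permutation_p <- function(statistics, signature, n_perm = 1000, seed = 1,
                          weight_exponent = 1) {
  if (n_perm < 100) stop("use at least 100 permutations")
  obs <- enrichment_score(statistics, signature, weight_exponent)$es
  genes <- names(statistics)
  k <- sum(genes %in% signature)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    enrichment_score(statistics, sample(genes, k), weight_exponent)$es
  }, 0)
  list(p.value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
       es = obs, n_perm = n_perm, seed = seed)
}

#' Score every factor against every signature
#'
#' @param matrix genes x factors knockdown statistic matrix.
#' @param signatures named list of gene-id vectors.
#' @param weight_exponent passed to [enrichment_score()].
#' @param inverse display the inverse score (default TRUE).
#' @return factors x signatures matrix of (inverse) enrichment scores.
#' @export
score_screen <- function(matrix, signatures, weight_exponent = 1,
                         inverse = TRUE) {
  out <- sapply(signatures, function(sig) {
    vapply(colnames(matrix), function(f) {
      st <- stats::setNames(matrix[, f], rownames(matrix))
      enrichment_score(st, sig, weight_exponent)$es
    }, 0)
  })
  out <- matrix(out, nrow = ncol(matrix),
                dimnames = list(colnames(matrix), names(signatures)))
  if (inverse) inverse_score(out) else out
}

#' Hierarchically cluster factors by signature scores
#'
#' Euclidean distance, average linkage; rows are pre-sorted by label
#' so equal-distance merges resolve deterministically.
#'
#' @param score_matrix factors x signatures numeric matrix.
#' @return list: `hclust` object, `order` (leaf labels in dendrogram
#'   order), `matrix` (input re-ordered to leaves).
#' @export
cluster_factors <- function(score_matrix) {
  m <- score_matrix[order(rownames(score_matrix)), , drop = FALSE]
  if (nrow(m) == 1L)
    return(list(hclust = NULL, order = rownames(m), matrix = m))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = rownames(m)[hc$order],
       matrix = m[hc$order, , drop = FALSE])
}
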