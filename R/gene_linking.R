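#' Link enhancers to their nearest genes
#'
#' @param enhancers data.frame with `chrom`, `start`, `end`.
#' @param annotation gene annotation data.frame.
#' @return list: `links` (one row per enhancer: `gene_id`,
#'   `distance`), `median_distance`, `genes` (deduplicated gene ids).
#' @export
link_nearest <- function(enhancers, annotation) {
  if (nrow(enhancers) == 0L)
    return(list(links = data.frame(gene_id = character(),
                                   distance = numeric()),
                median_distance = NA_real_, genes = character()))
  links <- nearest_genes(enhancers, annotation)
  list(links = links,
       median_distance = stats::median(links$distance, na.rm = TRUE),
       genes = unique(links$gene_id[!is.na(links$gene_id)]))
}

#' Read a gene x condition expression table
#' @param path TSV with a header; first column `gene_id`.
#' @return data.frame with unique `gene_id` rownames preserved as a column.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- "gene_id"
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in expression table")
  df
}

#' Compare expression between two gene classes (Welch t-test)
#'
#' Expression values for the two gene classes (e.g. SE-nearest vs
#' TE-nearest genes) are compared with an unequal-variance two-sample
#' t-test. Genes below `floor` are treated as not expressed and
#' dropped when `floor` is non-NULL (array convention: raw value 200).
#'
#' @param classA_genes,classB_genes character vectors of gene ids.
#' @param expr named numeric vector of expression, names = gene ids.
#' @param floor not-expressed floor applied before testing, or `NULL`
#'   to disable; default 200.
#' @return list: `statistic`, `p.value`, `means` (named, A and B), `n`.
#' @export
compare_expression <- function(classA_genes, classB_genes, expr,
                               floor = 200) {
  pull <- function(g) {
    v <- expr[intersect(unique(g), names(expr))]
    v <- v[is.finite(v)]
    if (!is.null(floor)) v <- v[v >= floor]
    v
  }
  a <- pull(classA_genes); b <- pull(classB_genes)
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 expressed genes per class for a t-test")
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       means = c(A = mean(a), B = mean(b)),
       n = c(A = length(a), B = length(b)))
}

#' Mean nearest-gene fold-change per enhancer-fate group
#'
#' For each fate group (e.g. TEs lost / gained / unchanged upon
#' knockdown) reports the mean log fold-change of the group's genes
#' with a seeded bootstrap percentile confidence interval.
#'
#' @param groups named list of gene-id vectors, one per fate group.
#' @param fold_changes named numeric vector of log fold-changes.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf CI level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: `group`, `n`, `mean_lfc`, `ci_lo`, `ci_hi`,
#'   `degenerate` (TRUE when the group has < 2 genes). Empty groups
#'   are reported absent (dropped).
#' @export
foldchange_by_enhancer_fate <- function(groups, fold_changes,
                                        n_boot = 1000, conf = 0.95,
                                        seed = 1) {
  rows <- lapply(names(groups), function(nm) {
    v <- fold_changes[intersect(unique(groups[[nm]]), names(fold_changes))]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    if (length(v) < 2L) {
      return(data.frame(group = nm, n = 1L, mean_lfc = mean(v),
                        ci_lo = mean(v), ci_hi = mean(v),
                        degenerate = TRUE))
    }
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i)
      mean(sample(v, length(v), replace = TRUE)), 0)
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    data.frame(group = nm, n = length(v), mean_lfc = mean(v),
               ci_lo = qs[1], ci_hi = qs[2], degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), n = integer(),
                      mean_lfc = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), degenerate = logical())
  rownames(out) <- NULL
  out
}

#' Housekeeping-gene overlap of SE-nearest genes
#'
#' @param se_genes_by_state named list of SE-nearest gene-id vectors.
#' @param housekeeping_genes character vector.
#' @param all_genes gene universe (background).
#' @return data.frame per state: `fraction_housekeeping` among SE
#'   genes and the shared `background_fraction`.
#' @export
housekeeping_overlap <- function(se_genes_by_state, housekeeping_genes,
                                 all_genes) {
  bg <- if (length(all_genes))
    mean(unique(all_genes) %in% housekeeping_genes) else NA_real_
  frac <- vapply(se_genes_by_state, function(g) {
    g <- unique(g)
    if (!length(g)) return(0)
    mean(g %in% housekeeping_genes)
  }, 0)
  data.frame(state = names(se_genes_by_state),
             fraction_housekeeping = unname(frac),
             background_fraction = bg)
}
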