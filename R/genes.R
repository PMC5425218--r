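#' Construct a gene annotation table
#'
#' Gene bodies as BED-convention intervals with strand; the TSS is
#' derived from the strand (`start` on `+`, `end - 1` on `-`).
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end gene-body coordinates (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (any(end <= start)) stop("gene body end must exceed start")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
}

#' Read BED6-like gene records
#' @param path tab-separated file: chrom, start, end, gene_id, score, strand.
#' @return gene annotation data.frame.
#' @export
read_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("gene BED needs 6 columns (strand in column 6)")
  gene_annotation(df[[4]], df[[1]], df[[2]], df[[3]], df[[6]])
}

#' Strand-aware proximal promoter windows
#'
#' The proximal promoter is the 3 kb window spanning 2 kb upstream
#' through 1 kb downstream of the TSS. On the `+` strand the window is
#' `[tss - upstream, tss + downstream)`; on the `-` strand it is
#' mirrored about the TSS base: `[tss - downstream, tss + upstream + 1)`.
#' Windows are truncated at coordinate 0.
#'
#' @param annotation gene annotation data.frame.
#' @param upstream bp upstream of the TSS (default 2000).
#' @param downstream bp downstream (default 1000).
#' @return a `peak_set` with a `name` column carrying the gene id.
#' @export
promoter_regions <- function(annotation, upstream = 2000, downstream = 1000) {
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream,
                  annotation$tss - downstream)
  end <- ifelse(plus, annotation$tss + downstream,
                annotation$tss + upstream + 1)
  peak_set(annotation$chrom, pmax(start, 0), end,
           name = annotation$gene_id)
}
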