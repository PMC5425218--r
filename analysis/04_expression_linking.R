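#!/usr/bin/env Rscript
# Link enhancers to nearest genes and test whether SE-linked genes are
# expressed higher than TE-linked genes (Welch t-test), plus the
# housekeeping-gene overlap of SE-nearest genes per state.

suppressMessages(library(enhancerscape))

out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ls <- make_landscape(landscape_config(seed = 1))
genes <- make_genes(ls)
expr <- make_expression(genes, ls)
v <- setNames(expr$expression, expr$gene_id)

se_tr <- truth_in_state(ls$truth, "NHEK-D", "se")
te_tr <- truth_in_state(ls$truth, "NHEK-D", "te")
se_link <- link_nearest(se_tr, genes)
te_link <- link_nearest(te_tr, genes)
cat(sprintf("Median nearest-gene distance: SE %.0f bp, TE %.0f bp\n",
            se_link$median_distance, te_link$median_distance))

cmp <- compare_expression(se_link$genes,
                          setdiff(te_link$genes, se_link$genes), v)
cat(sprintf(paste0("SE-linked mean %.0f vs TE-linked %.0f ",
                   "(Welch t = %.2f, p = %.2e)\n"),
            cmp$means["A"], cmp$means["B"], cmp$statistic, cmp$p.value))

hk <- housekeeping_overlap(
  lapply(setNames(ls$config$states, ls$config$states), function(st)
    link_nearest(truth_in_state(ls$truth, st, "se"), genes)$genes),
  genes$gene_id[genes$is_housekeeping], genes$gene_id)
write.table(hk, file.path(out, "housekeeping_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr, file.path(out, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote expression table and housekeeping overlap to", out, "\n")
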