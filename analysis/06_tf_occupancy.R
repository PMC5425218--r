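#!/usr/bin/env Rscript
# TF ChIP occupancy over the enhancer landscape: fraction of SEs
# bound, peaks per bound SE, SE/TE tag ratio, distribution of peaks
# over genomic classes, and condition-unique peaks between two states.

suppressMessages(library(enhancerscape))

out <- "results/tf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ls <- make_landscape(landscape_config(seed = 1))
genes <- make_genes(ls)

se_tr <- truth_in_state(ls$truth, "NHEK-D", "se")
te_tr <- truth_in_state(ls$truth, "NHEK-D", "te")
tf <- make_tf_peaks(ls, "NHEK-D", se_preference = 25,
                    tag_ratio_target = 1.5, n_peaks = 500)

cat(sprintf("Fraction of SEs bound: %.2f\n",
            fraction_bound(tf$peaks, se_tr)))
ppr <- peaks_per_region(tf$peaks, se_tr)
cat(sprintf("Mean peaks per bound SE: %.1f; fraction with >5 peaks: %.2f\n",
            ppr$mean_bound, ppr$fraction_over_5))
cat(sprintf("SE/TE tag ratio: %.2f (planted 1.5)\n",
            tag_ratio(tf$peaks, se_tr, te_tr)))

dist <- genomic_distribution(tf$peaks, promoter_regions(genes),
                             se_tr, te_tr,
                             ls$marks[["NHEK-D"]]$H3K4me3)
write.table(data.frame(class = names(dist), fraction = as.numeric(dist)),
            file.path(out, "genomic_distribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Peak distribution:",
    paste(names(dist), sprintf("%.2f", dist), collapse = " "), "\n")

tf_m <- make_tf_peaks(ls, "NHEK-M", se_preference = 25, n_peaks = 400,
                      seed = 99)
uq <- unique_peaks(tf$peaks, tf_m$peaks)
cat(sprintf("Condition-unique peaks: %d NHEK-D-only, %d NHEK-M-only, %d shared regions\n",
            nrow(uq$a_unique), nrow(uq$b_unique), nrow(uq$shared)))

# direct targets demo: planted DE table in which 60% of genes respond
# to the knockdown, repressed targets going up
set.seed(21)
de <- data.frame(gene_id = genes$gene_id,
                 log2fc = rnorm(nrow(genes), 0.5, 0.8),
                 pvalue = ifelse(runif(nrow(genes)) < 0.6,
                                 runif(nrow(genes)) * 0.04,
                                 runif(nrow(genes), 0.05, 1)))
dt <- direct_targets(tf$peaks, promoter_regions(genes), de)
cat(sprintf("Direct targets: %d of %d promoter-bound genes DE (%.0f%% up)\n",
            nrow(dt$targets), dt$n_bound_genes,
            100 * ifelse(is.na(dt$fraction_up), 0, dt$fraction_up)))
cat("Wrote occupancy tables to", out, "\n")
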