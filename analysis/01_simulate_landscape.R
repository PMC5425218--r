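#!/usr/bin/env Rscript
# Generate the synthetic keratinocyte enhancer landscape used by all
# downstream analyses: three states (progenitor NHEK-P, differentiating
# NHEK-D, migrating NHEK-M), four histone-mark tracks per state, and a
# ground-truth table of every planted element. Writes BED peak files,
# the gene annotation and the truth table under results/landscape/.

suppressMessages(library(enhancerscape))

out <- "results/landscape"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- landscape_config(seed = 1)
ls <- make_landscape(cfg)
genes <- make_genes(ls)

for (st in cfg$states) {
  for (mark in names(ls$marks[[st]])) {
    p <- ls$marks[[st]][[mark]]
    if (nrow(p))
      write_bed(p, file.path(out, sprintf("%s_%s.bed", st, mark)))
  }
}
write.table(ls$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(genes, file.path(out, "genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

counts <- table(ls$truth$type)
cat("Planted landscape on", paste(names(cfg$chrom_lengths), collapse = "+"),
    sprintf("(%.0f Mb total):\n", sum(cfg$chrom_lengths) / 1e6))
print(counts)
cat("Per state:", cfg$n_se, "SEs,", cfg$n_te, "TEs,",
    cfg$n_decoy, "H3K4me3-high decoys.\n")
cat("Wrote per-state mark BEDs, genes.tsv and ground_truth.tsv to",
    out, "\n")
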