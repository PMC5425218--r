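#!/usr/bin/env Rscript
# Call typical enhancers (overlapping H3K27ac/H3K4me1, low H3K4me3)
# and super-enhancers (stitched H3K27ac regions above the rank-curve
# cutoff, span >= 12.5 kb) in every state, subtract SE footprints from
# the TE track, and compare the calls to the planted truth. Also
# writes the rank curve and the three-state Venn/persistence summary.

suppressMessages(library(enhancerscape))

out <- "results/enhancers"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ls <- make_landscape(landscape_config(seed = 1))

calls <- list()
for (st in ls$config$states) {
  mk <- ls$marks[[st]]
  te0 <- call_typical_enhancers(mk$H3K27ac, mk$H3K4me1, mk$H3K4me3)
  sti <- stitch(mk$H3K27ac)
  sc <- call_super_enhancers(sti)
  se <- peak_set(sc$se$chrom, sc$se$start, sc$se$end,
                 signal = sc$se$total_signal)
  te <- subtract_peaks(te0$enhancers, se)
  calls[[st]] <- list(se = se, te = te)

  write_bed(se, file.path(out, sprintf("%s_SE.bed", st)))
  write_bed(te, file.path(out, sprintf("%s_TE.bed", st)))
  write.table(rank_curve(sti),
              file.path(out, sprintf("%s_rank_curve.tsv", st)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth_se <- truth_in_state(ls$truth, st, "se")
  truth_te <- truth_in_state(ls$truth, st, "te")
  key <- function(ch, s, e) paste(ch, s, e)
  te_ok <- mean(key(te$chrom, te$start, te$end) %in%
                  key(truth_te$chrom, truth_te$start, truth_te$end))
  cat(sprintf("%s: %d TEs (precision %.3f), %d SEs of %d planted; %s\n",
              st, nrow(te), te_ok, nrow(se), nrow(truth_se),
              paste(names(te0$log), te0$log, sep = "=",
                    collapse = ", ")))
}

venn_se <- venn3(calls[[1]]$se, calls[[2]]$se, calls[[3]]$se,
                 labels = c("P", "D", "M"))
venn_te <- venn3(calls[[1]]$te, calls[[2]]$te, calls[[3]]$te,
                 labels = c("P", "D", "M"))
write.table(rbind(SE = venn_se, TE = venn_te),
            file.path(out, "venn_counts.tsv"), sep = "\t", quote = FALSE,
            col.names = NA)
pm <- persistence_fraction(calls[["NHEK-P"]]$se, calls[["NHEK-M"]]$se)
cat(sprintf("SE persistence P<->M (union-normalized): %.3f\n", pm))
cat(sprintf("Three-state SE Venn: %s\n",
            paste(names(venn_se), venn_se, sep = "=", collapse = " ")))
cat("Wrote SE/TE BEDs, rank curves and Venn counts to", out, "\n")
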