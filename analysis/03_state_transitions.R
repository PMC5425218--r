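#!/usr/bin/env Rscript
# Where do the active enhancers of the derived states come from?
# Classify each NHEK-D / NHEK-M active enhancer by its chromatin state
# in the progenitor (active, poised, H3K4me1-only, unmarked) and write
# the transition tables, plus an exactly-planted fate benchmark.

suppressMessages(library(enhancerscape))

out <- "results/transitions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ls <- make_landscape(landscape_config(seed = 1))

state_marks <- function(st) {
  mk <- ls$marks[[st]]
  sc <- call_super_enhancers(stitch(mk$H3K27ac))
  se <- peak_set(sc$se$chrom, sc$se$start, sc$se$end)
  te <- subtract_peaks(
    call_typical_enhancers(mk$H3K27ac, mk$H3K4me1, mk$H3K4me3)$enhancers,
    se)
  list(se = se, te = te, k4me1 = mk$H3K4me1, k27me3 = mk$H3K27me3)
}
p_marks <- state_marks("NHEK-P")

for (dest in c("NHEK-D", "NHEK-M")) {
  dm <- state_marks(dest)
  active <- rbind(dm$se[c("chrom", "start", "end")],
                  dm$te[c("chrom", "start", "end")])
  active$category <- rep(c("active_SE", "active_TE"),
                         c(nrow(dm$se), nrow(dm$te)))
  tt <- transition_table(active, p_marks)
  write.table(tt$counts,
              file.path(out, sprintf("P_origin_of_%s.tsv", dest)),
              sep = "\t", quote = FALSE, col.names = NA)
  back <- table(tt$dest_category) / nrow(active)
  cat(sprintf("%s active enhancers by NHEK-P state: %s\n", dest,
              paste(names(back), sprintf("%.2f", back),
                    collapse = " ")))
}

fl <- make_fate_landscape(n_per_fate = 25, seed = 7)
tt <- transition_table(
  data.frame(fl$regions[c("chrom", "start", "end")],
             category = "active_TE"), fl$origin_marks)
cat("Planted-fate benchmark (0.25 each):",
    sprintf("%.2f", tt$fractions["active_TE", c("active_TE", "poised",
                                                "k4me1_only",
                                                "unmarked")]), "\n")
cat("Wrote transition tables to", out, "\n")
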