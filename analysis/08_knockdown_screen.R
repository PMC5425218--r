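#!/usr/bin/env Rscript
# Score the 51-factor x 14,000-gene knockdown screen: PCA of the
# experiments, inverse enrichment scores of the four differentiation
# signatures (progenitor / early / mid / late) per factor, permutation
# p-values for a few factors, and hierarchical clustering of factors
# by their signature profile.

suppressMessages(library(enhancerscape))

out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

kd <- make_knockdown_screen(seed = 1)
cat(sprintf("Screen matrix: %d genes x %d factors, 4 signatures of %d genes\n",
            nrow(kd$matrix), ncol(kd$matrix),
            length(kd$signatures[[1]])))

pc <- pca_project(kd$matrix)
write.table(data.frame(factor = rownames(pc$coordinates),
                       pc$coordinates),
            file.path(out, "pca_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PC1/PC2 variance explained: %.3f / %.3f\n",
            pc$variance_explained[1], pc$variance_explained[2]))

scores <- score_screen(kd$matrix, kd$signatures)   # inverse ES
write.table(data.frame(factor = rownames(scores), scores),
            file.path(out, "inverse_es.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
planted <- mapply(function(f, s) scores[f, s],
                  kd$truth$factor, kd$truth$signature)
cat(sprintf("Planted activator pairs with positive inverse ES: %d/%d (mean %.2f)\n",
            sum(planted > 0), nrow(kd$truth), mean(planted)))

# permutation significance for the first three factors' planted pair
for (r in 1:3) {
  f <- kd$truth$factor[r]; sgn <- kd$truth$signature[r]
  st <- setNames(kd$matrix[, f], rownames(kd$matrix))
  pp <- permutation_p(st, kd$signatures[[sgn]], n_perm = 200,
                      seed = 40 + r)
  cat(sprintf("  %s ~ %s: inverse ES %.2f, permutation p = %.4f\n",
              f, sgn, inverse_score(pp$es), pp$p.value))
}

cl <- cluster_factors(scores)
writeLines(cl$order, file.path(out, "factor_cluster_order.txt"))
cat("Wrote PCA, inverse-ES table and cluster order to", out, "\n")
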