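small_cfg <- function(...) landscape_config(
  n_te = 60, n_se = 8, n_decoy = 10, n_poised = 8, n_k4me1_only = 8, ...)

test_that("landscape generation is a pure function of config and seed", {
  a <- make_landscape(small_cfg(seed = 61))
  b <- make_landscape(small_cfg(seed = 61))
  expect_identical(a$truth, b$truth)
  expect_identical(a$marks, b$marks)
  c2 <- make_landscape(small_cfg(seed = 62))
  expect_false(identical(a$truth, c2$truth))
})

test_that("per-state element counts match the config exactly", {
  ls <- make_landscape(small_cfg(seed = 63))
  for (st in ls$config$states) {
    expect_equal(nrow(truth_in_state(ls$truth, st, "te")), 60L)
    expect_equal(nrow(truth_in_state(ls$truth, st, "se")), 8L)
    expect_equal(nrow(truth_in_state(ls$truth, st, "decoy")), 10L)
  }
})

test_that("planted elements respect spacing and SE span constraints", {
  ls <- make_landscape(small_cfg(seed = 64))
  tr <- ls$truth[order(ls$truth$chrom, ls$truth$start), ]
  for (ch in unique(tr$chrom)) {
    sub <- tr[tr$chrom == ch, ]
    gaps <- sub$start[-1] - sub$end[-nrow(sub)]
    expect_true(all(gaps > 12500))   # nothing stitches across elements
  }
  se <- tr[tr$type == "se", ]
  expect_true(all(se$end - se$start >= 12500))
})

test_that("an impossible configuration raises a genome-size error", {
  expect_error(make_landscape(landscape_config(
    chrom_lengths = c(tiny = 2e5), n_te = 500, seed = 1)),
    "too small")
})

test_that("a zero-SE landscape yields an empty SE call", {
  ls <- make_landscape(small_cfg(n_se = 0, shared_fraction = 0, seed = 65))
  mk <- ls$marks[["NHEK-P"]]
  res <- call_super_enhancers(stitch(mk$H3K27ac))
  expect_equal(nrow(res$se), 0L)
})

test_that("planted gene links are recovered by nearest-gene mapping", {
  ls <- make_landscape(small_cfg(seed = 66))
  genes <- make_genes(ls)
  el <- ls$truth[ls$truth$type %in% c("se", "te"), ]
  got <- nearest_genes(el[c("chrom", "start", "end")], genes)
  want <- sprintf("gene_%s", el$element_id)
  expect_equal(got$gene_id, want)
})

test_that("expression elevates SE-linked genes detectably", {
  ls <- make_landscape(small_cfg(n_te = 100, seed = 67))
  genes <- make_genes(ls)
  expr <- make_expression(genes, ls, se_effect = 2, seed = 68)
  v <- setNames(expr$expression, expr$gene_id)
  se_g <- genes$gene_id[genes$is_tf]
  te_g <- setdiff(genes$gene_id, se_g)
  res <- compare_expression(se_g, te_g, v, floor = NULL)
  expect_gt(res$means["A"], res$means["B"])
  expect_lt(res$p.value, 0.01)
})

test_that("TF peak generator plants the requested tag ratio", {
  ls <- make_landscape(small_cfg(seed = 69))
  tf <- make_tf_peaks(ls, "NHEK-P", se_preference = 5,
                      tag_ratio_target = 1.5, n_peaks = 500, seed = 70)
  se <- truth_in_state(ls$truth, "NHEK-P", "se")
  te <- truth_in_state(ls$truth, "NHEK-P", "te")
  got <- tag_ratio(tf$peaks, se, te)
  expect_lt(abs(got - 1.5) / 1.5, 0.1)
  expect_identical(tf$peaks,
                   make_tf_peaks(ls, "NHEK-P", se_preference = 5,
                                 tag_ratio_target = 1.5, n_peaks = 500,
                                 seed = 70)$peaks)
})

test_that("SNP generator exercises the filter and pruning stages", {
  ls <- make_landscape(small_cfg(seed = 71))
  snps <- make_snps(ls, n_snps = 120, enrichment_factor = 2, seed = 72)
  kept <- filter_genomewide(snps)
  expect_true(all(kept$role != "nonsig"))
  expect_gt(sum(snps$role == "nonsig"), 0)
  pruned <- prune_loci(kept)
  # planted satellites are weaker than their leads and get pruned
  # unless their lead itself fell to a stronger neighbour
  for (dz in unique(pruned$disease)) {
    pos <- sort(pruned$pos[pruned$disease == dz &
                             pruned$chrom == "chrS1"])
    if (length(pos) > 1) expect_true(all(diff(pos) > 500000))
  }
})

test_that("sequence generator registry matches scan recovery", {
  ls <- make_landscape(small_cfg(seed = 73))
  set.seed(74)
  pwms <- lapply(1:4, function(i)
    sharp_pwm(sprintf("M%d", i), sprintf("TF%d", i),
              paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                    collapse = "")))
  sq <- make_sequences(ls, pwms, plant_prob = 0.7, seed = 75)
  expect_gt(nrow(sq$registry), 0)
  found <- mapply(function(se_id, motif_id) {
    p <- pwms[[match(motif_id, vapply(pwms, `[[`, "", "motif_id"))]]
    nrow(scan_pwm(p, sq$sequences[[se_id]])) > 0
  }, sq$registry$se_id, sq$registry$motif_id)
  expect_gte(mean(found), 0.95)
  expect_identical(sq$sequences,
                   make_sequences(ls, pwms, plant_prob = 0.7,
                                  seed = 75)$sequences)
})

test_that("knockdown screen plants recoverable signature effects", {
  kd <- make_knockdown_screen(n_factors = 6, n_genes = 800,
                              signature_size = 30, seed = 76)
  expect_equal(dim(kd$matrix), c(800L, 6L))
  # planted activator: signature genes shifted down under its knockdown
  r <- kd$truth[1, ]
  sig <- kd$signatures[[r$signature]]
  expect_lt(mean(kd$matrix[sig, r$factor]),
            mean(kd$matrix[setdiff(rownames(kd$matrix), sig), r$factor]))
  # DE tables flag shifted genes
  de <- kd$de_tables[[r$factor]]
  expect_gt(mean(de$pvalue[de$gene_id %in% sig] < 0.05), 0.5)
  expect_identical(kd$matrix,
                   make_knockdown_screen(n_factors = 6, n_genes = 800,
                                         signature_size = 30,
                                         seed = 76)$matrix)
})
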