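se4 <- data.frame(chrom = "chr1", start = c(0, 2e4, 4e4, 6e4),
                  end = c(1.5e4, 3.5e4, 5.5e4, 7.5e4))

test_that("fraction_bound counts regions with any peak", {
  none <- peak_set(character(), numeric(), numeric())
  expect_equal(fraction_bound(none, se4), 0)
  all_p <- peak_set(rep("chr1", 4), se4$start + 100, se4$start + 400)
  expect_equal(fraction_bound(all_p, se4), 1)
  three <- peak_set(rep("chr1", 3), se4$start[1:3] + 100,
                    se4$start[1:3] + 400)
  expect_equal(fraction_bound(three, se4), 0.75)
  expect_error(fraction_bound(three, se4[0, ]), "no regions")
})

test_that("peaks_per_region averages over bound regions only", {
  p1 <- peak_set("chr1", 100, 300)
  expect_equal(peaks_per_region(p1, se4)$mean_bound, 1)
  starts <- c(100, 200, 20100, 20200, 20300, 40100, 40200, 40300, 40400)
  p <- peak_set(rep("chr1", 9), starts, starts + 50)
  got <- peaks_per_region(p, se4)
  expect_equal(sort(got$counts), c(0, 2, 3, 4))
  expect_equal(got$mean_bound, 3)   # unbound region excluded
})

test_that("tag_ratio uses SE priority and is scale invariant", {
  te <- data.frame(chrom = "chr1", start = 1e5, end = 1.02e5)
  peaks <- peak_set(rep("chr1", 3), c(100, 20100, 100100),
                    c(400, 20400, 100400), signal = c(10, 20, 10))
  expect_equal(tag_ratio(peaks, se4, te), 1.5)
  peaks$signal <- peaks$signal * 1e3
  expect_equal(tag_ratio(peaks, se4, te), 1.5)

  eq <- peak_set(rep("chr1", 2), c(100, 100100), c(400, 100400),
                 signal = c(10, 10))
  expect_equal(tag_ratio(eq, se4, te), 1)

  # a peak spanning SE and TE counts once, as SE
  both_reg_se <- data.frame(chrom = "chr1", start = 0, end = 1000)
  both_reg_te <- data.frame(chrom = "chr1", start = 500, end = 2000)
  pk <- peak_set(rep("chr1", 2), c(400, 1500), c(600, 1600),
                 signal = c(30, 10))
  expect_equal(tag_ratio(pk, both_reg_se, both_reg_te), 3)
  expect_error(tag_ratio(peak_set("chr1", 100, 200, signal = 1),
                         se4, te), "no TE")
})

test_that("genomic_distribution recovers a planted composition exactly", {
  # 30% promoter, 40% SE, 20% TE, 10% other over 100 peaks
  prom <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  se <- data.frame(chrom = "chr1", start = 2e5, end = 3e5)
  te <- data.frame(chrom = "chr1", start = 4e5, end = 5e5)
  anchor <- c(rep(5e4, 30), rep(2.5e5, 40), rep(4.5e5, 20), rep(7e5, 10))
  pos <- anchor + seq_along(anchor) * 10
  peaks <- peak_set(rep("chr1", 100), pos, pos + 5)
  got <- genomic_distribution(peaks, prom, se, te)
  expect_equal(unname(got[c("promoter", "SE", "TE", "other")]),
               c(0.3, 0.4, 0.2, 0.1))
  expect_equal(sum(got), 1)

  # promoter priority beats SE on an overlapping peak
  ov <- genomic_distribution(peak_set("chr1", 5e4, 5.1e4), prom,
                             data.frame(chrom = "chr1", start = 0,
                                        end = 1e5), te)
  expect_equal(unname(ov["promoter"]), 1)
})

test_that("unique_peaks partitions each input", {
  a <- peak_set(rep("chr1", 3), c(0, 1000, 2000), c(100, 1100, 2100))
  ident <- unique_peaks(a, a)
  expect_equal(nrow(ident$a_unique), 0L)
  expect_equal(nrow(ident$b_unique), 0L)

  b <- peak_set("chr1", 1050, 1080)
  got <- unique_peaks(a, b)
  expect_equal(nrow(got$a_unique), 2L)
  expect_equal(nrow(got$b_unique), 0L)
  expect_equal(nrow(got$a_unique) +
                 length(unique(intersect_peaks(a, b)$a_idx)), nrow(a))
  expect_equal(got$method, "overlap")

  disj <- unique_peaks(a, peak_set("chr2", 0, 50))
  expect_equal(nrow(disj$a_unique), 3L)
  expect_equal(nrow(disj$b_unique), 1L)
})

test_that("direct_targets requires promoter binding and strict DE p", {
  prom <- promoter_regions(gene_annotation(c("g1", "g2", "g3"), "chr1",
                                           c(1e4, 5e4, 9e4),
                                           c(2e4, 6e4, 1e5),
                                           c("+", "+", "+")))
  de <- data.frame(gene_id = c("g1", "g2", "g3"),
                   log2fc = c(1.2, -0.8, 2.0),
                   pvalue = c(0.001, 0.01, 0.05))
  peaks <- peak_set(rep("chr1", 3), c(9000, 49000, 89000),
                    c(9500, 49500, 89500))
  got <- direct_targets(peaks, prom, de)
  expect_setequal(got$targets$gene_id, c("g1", "g2"))  # g3 at p = 0.05 out
  expect_equal(got$fraction_up, 0.5)

  none <- direct_targets(peak_set(character(), numeric(), numeric()),
                         prom, de)
  expect_equal(nrow(none$targets), 0L)

  # planted repressed targets: bound and up on knockdown
  de_up <- transform(de, log2fc = abs(log2fc), pvalue = 1e-4)
  expect_equal(direct_targets(peaks, prom, de_up)$fraction_up, 1)
})

test_that("SE binding preference grows with the planted factor", {
  ls <- make_landscape(landscape_config(n_te = 50, n_se = 10, n_decoy = 5,
                                        n_poised = 5, n_k4me1_only = 5,
                                        seed = 13))
  se <- truth_in_state(ls$truth, "NHEK-P", "se")
  fb <- vapply(c(0, 2, 10), function(f) {
    tf <- make_tf_peaks(ls, "NHEK-P", se_preference = f, n_peaks = 400,
                        seed = 100 + f)
    fraction_bound(tf$peaks, se)
  }, 0)
  expect_true(all(diff(fb) > 0))
  expect_lt(fb[1], 0.05)  # f = 0: SEs carry no planted excess
})
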