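test_that("read_bed parses, sorts and validates BED records", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200"), f)
  p <- read_bed(f)
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 100)
  expect_equal(p$signal, 0)

  writeLines(c("chr2\t50\t80\tx\t7", "chr1\t10\t30\ty\t3"), f)
  p <- read_bed(f, signal_column = 5)
  expect_equal(p$chrom, c("chr1", "chr2"))
  expect_equal(p$signal, c(3, 7))

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "end <= start")
  writeLines(c("chr1\t1\t2", "chr1\tbroken"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("intersect_peaks returns exactly the overlapping pairs", {
  a <- peak_set("chr1", 100, 200)
  expect_equal(nrow(intersect_peaks(a, peak_set(character(), numeric(),
                                                numeric()))), 0L)
  expect_equal(nrow(intersect_peaks(a, a)), 1L)

  a2 <- peak_set(c("chr1", "chr1"), c(100, 300), c(200, 400))
  b <- peak_set("chr1", 150, 350)
  got <- intersect_peaks(a2, b)
  expect_equal(got, oracle_intersect(a2, b))
  expect_equal(got$a_idx, c(1L, 2L))
})

test_that("subtract_peaks matches the per-base bitmap oracle", {
  a <- peak_set("chr1", 0, 100, signal = 5)
  expect_equal(nrow(subtract_peaks(a, peak_set("chr1", 0, 100))), 0L)
  expect_equal(subtract_peaks(a, peak_set(character(), numeric(),
                                          numeric()))$end, 100)
  got <- subtract_peaks(a, peak_set("chr1", 40, 60))
  expect_equal(got$start, c(0, 60))
  expect_equal(got$end, c(40, 100))
  expect_equal(got$signal, c(5, 5))   # truncation keeps original signal
})

test_that("merge_peaks unions within-gap runs and conserves signal", {
  p <- peak_set(c("chr1", "chr1"), c(0, 5), c(10, 20), signal = c(1, 2))
  m <- merge_peaks(p)
  expect_equal(m$end, 20)
  expect_equal(m$signal, 3)
  disj <- peak_set(c("chr1", "chr1"), c(0, 30), c(10, 40))
  expect_equal(nrow(merge_peaks(disj)), 2L)
  gap <- peak_set(c("chr1", "chr1"), c(0, 15), c(10, 20))
  expect_equal(merge_peaks(gap, max_gap = 5)$end, 20)
  expect_equal(nrow(merge_peaks(gap, max_gap = 4)), 2L)
})

test_that("merge is idempotent and intersect symmetric in pair count", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_toy_peaks(sample(0:8, 1))
    b <- random_toy_peaks(sample(0:8, 1))
    g <- sample(0:50, 1)
    m1 <- merge_peaks(a, g)
    expect_equal(merge_peaks(peak_set(m1[c("chrom", "start", "end",
                                           "signal")]), g)[
      c("chrom", "start", "end", "signal")],
      m1[c("chrom", "start", "end", "signal")])
    expect_equal(nrow(intersect_peaks(a, b)), nrow(intersect_peaks(b, a)))
  }
})

test_that("closest_gene honors distance and deterministic tie-breaks", {
  genes <- gene_annotation(c("gA", "gB"), "chr1", c(5000, 10000),
                           c(7000, 12000), c("+", "+"))
  inside <- closest_gene(list(chrom = "chr1", start = 5500, end = 5600),
                         genes)
  expect_equal(inside$gene_id, "gA")
  expect_equal(inside$distance, 0)

  res <- closest_gene(list(chrom = "chr1", start = 1000, end = 2000), genes)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$distance, 3000)

  # both genes exactly 750 bp away; smaller start wins
  tie_genes <- gene_annotation(c("gZ", "gA"), "chr1", c(3001, 1000),
                               c(4000, 1500), c("+", "+"))
  tie <- closest_gene(list(chrom = "chr1", start = 2250, end = 2251),
                      tie_genes)
  expect_equal(tie$distance, 750)
  expect_equal(tie$gene_id, "gA")   # gA starts at 1000 < 3001

  expect_error(closest_gene(list(chrom = "chr1", start = 1, end = 2),
                            genes[0, ]), "empty")
})

test_that("nearest_genes agrees with the all-pairs oracle on random cases", {
  set.seed(7)
  s <- sort(sample.int(9000, 50))
  genes <- gene_annotation(sprintf("g%03d", 1:50), "chrT", s, s + 50,
                           sample(c("+", "-"), 50, TRUE))
  regions <- data.frame(chrom = "chrT",
                        start = rs <- sample.int(9900, 200),
                        end = rs + sample.int(80, 200, TRUE))
  got <- nearest_genes(regions, genes)
  for (i in seq_len(nrow(regions))) {
    want <- oracle_closest(regions[i, ], genes)
    expect_equal(got$gene_id[i], want$gene_id)
    expect_equal(got$distance[i], want$distance)
  }
})

test_that("replicate_consensus keeps rep1 footprints and reports fractions", {
  r1 <- peak_set(rep("chr1", 10), seq(0, 9000, 1000),
                 seq(0, 9000, 1000) + 500)
  ident <- replicate_consensus(r1, r1)
  expect_equal(nrow(ident$peaks), 10L)
  expect_equal(unname(ident$overlap_fraction["rep1"]), 1)

  r2 <- peak_set(rep("chr1", 10), seq(0, 9000, 1000) + 600,
                 seq(0, 9000, 1000) + 900)
  disj <- replicate_consensus(r1, r2)
  expect_equal(nrow(disj$peaks), 0L)
  expect_equal(unname(disj$overlap_fraction["rep1"]), 0)

  r3 <- peak_set(rep("chr1", 8), seq(0, 7000, 1000) + 400,
                 seq(0, 7000, 1000) + 700)
  part <- replicate_consensus(r1, r3)
  expect_equal(nrow(part$peaks), 8L)
  expect_equal(unname(part$overlap_fraction["rep1"]), 0.8)
  # rep1 coordinates retained
  expect_true(all(part$peaks$start %in% r1$start))
})
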