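delta_pwm <- function(word) sharp_pwm("delta", "TFX", word, sharp = 1 - 3e-7)

test_that("scan_pwm finds exact-word motifs on both strands", {
  p <- delta_pwm("ACGT")
  hits <- scan_pwm(p, "TTACGTTT")
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 2L)
  # reverse complement of ACGT is ACGT; a true minus test needs an
  # asymmetric word
  p2 <- delta_pwm("AACG")
  rc_seq <- "TTCGTTTT"   # contains CGTT = revcomp(AACG)
  hits2 <- scan_pwm(p2, rc_seq)
  expect_true(any(hits2$strand == "-"))
  expect_equal(hits2$offset[hits2$strand == "-"], 2L)  # CGTT at offset 2
})

test_that("scan scores equal the log-odds sum and honour N scoring", {
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.6, 0.2, 0.1,
                0.25, 0.25, 0.25, 0.25,
                0.05, 0.05, 0.05, 0.85), 4, 4)
  p <- pwm("m1", "TF1", m)
  hits <- scan_pwm(p, "ACGT", threshold_fraction = -10)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$score, oracle_scan_score(p, "ACGT", 0, "+"),
               tolerance = 1e-12)
  # N contributes zero bits
  hn <- scan_pwm(p, "ANGT", threshold_fraction = -10)
  expect_equal(hn$score[hn$strand == "+"],
               oracle_scan_score(p, "ANGT", 0, "+"), tolerance = 1e-12)
})

test_that("window scores agree with the per-window oracle on random pairs", {
  set.seed(41)
  for (i in 1:25) {
    L <- sample(4:10, 1)
    m <- matrix(rgamma(4 * L, 1), 4, L)
    m <- sweep(m, 2, colSums(m), "/")
    p <- pwm("r", "TFR", m)
    s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    hits <- scan_pwm(p, s, threshold_fraction = -100)
    for (k in sample(nrow(hits), min(4, nrow(hits))))
      expect_equal(hits$score[k],
                   oracle_scan_score(p, s, hits$offset[k], hits$strand[k]),
                   tolerance = 1e-10)
  }
})

test_that("reverse-complementing PWM and sequence preserves the hit set", {
  set.seed(42)
  for (i in 1:10) {
    p <- sharp_pwm("s", "TFS",
                   paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                         collapse = ""), sharp = 0.9)
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    rc_p <- pwm("rc", "TFS", p$matrix[4:1, ncol(p$matrix):1])
    h1 <- scan_pwm(p, s, threshold_fraction = 0.7)
    h2 <- scan_pwm(rc_p, reverse_complement(s), threshold_fraction = 0.7)
    expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-10)
  }
})

test_that("motif enrichment p equals the hypergeometric enumeration", {
  # construct sets where 8/10 targets and 2/10 backgrounds carry a hit
  word <- "ACGTACGTAC"
  p <- sharp_pwm("e", "TFE", word)
  set.seed(43)
  bg <- replicate(20, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                            collapse = ""))
  plant <- function(s) paste0(substr(s, 1, 20), word,
                              substr(s, 31, 60))
  targets <- c(vapply(bg[1:8], plant, ""), bg[9:10])
  backgr <- c(vapply(bg[11:12], plant, ""), bg[13:20])
  got <- motif_enrichment(p, targets, backgr)
  expect_equal(got$target_hits, 8L)
  expect_equal(got$background_hits, 2L)
  expect_equal(got$p.value, oracle_fisher_p(8, 2, 10, 10),
               tolerance = 1e-12)
  expect_equal(got$p.value,
               fisher.test(matrix(c(8, 2, 2, 8), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)

  eq <- motif_enrichment(p, targets[1:4], targets[1:4])
  expect_gte(eq$p.value, 0.5)
  none <- motif_enrichment(p, bg[9:10], bg[13:14])
  expect_equal(none$odds_ratio, 1)
  expect_equal(none$p.value, 1)
})

test_that("hypergeometric tail matches enumeration for all margins <= 20", {
  for (n1 in c(1, 3, 5, 10)) for (n2 in c(1, 4, 10)) {
    for (a in 0:n1) for (b in 0:n2) {
      if (a + b == 0) next
      got <- phyper(a - 1, a + b, n1 + n2 - a - b, n1, lower.tail = FALSE)
      expect_equal(got, oracle_fisher_p(a, b, n1, n2), tolerance = 1e-12)
    }
  }
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  set.seed(44)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), 200L)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
  expect_equal(dinuc_shuffle("ACG"), "ACG")
})

test_that("build_network emits source->target edges per motif hit", {
  p <- sharp_pwm("M1", "PRDM1", "ACGTACGTACGT")
  links <- data.frame(se_id = c("se1", "se2"),
                      tf_gene = c("GRHL3", "KLF4"))
  seqs <- c(se1 = paste0(strrep("T", 20), "ACGTACGTACGT", strrep("T", 20)),
            se2 = strrep("TG", 30))
  net <- build_network(list(p), links, seqs)
  expect_equal(nrow(net), 1L)
  expect_equal(net$source_tf, "PRDM1")
  expect_equal(net$target_tf, "GRHL3")
  expect_false(net$self)
  expect_equal(nrow(build_network(list(), links, seqs)), 0L)
})

test_that("validate_edges scores targets against knockdown DE tables", {
  net <- data.frame(source_tf = "PRDM1",
                    target_tf = c("GRHL3", "KLF4"),
                    se_id = c("se1", "se2"), n_hits = 1L)
  de_all <- list(PRDM1 = data.frame(gene_id = c("GRHL3", "KLF4"),
                                    pvalue = c(0.001, 0.002)))
  expect_equal(validate_edges(net, de_all)$validated_fraction, 1)
  de_none <- list(PRDM1 = data.frame(gene_id = c("GRHL3", "KLF4"),
                                     pvalue = c(0.5, 0.9)))
  expect_equal(validate_edges(net, de_none)$validated_fraction, 0)
  expect_message(skip <- validate_edges(net, list()), "skipped")
  expect_equal(nrow(skip), 0L)
})

test_that("planted regulatory edges are recovered on synthetic sequences", {
  ls <- make_landscape(landscape_config(n_te = 30, n_se = 10, n_decoy = 5,
                                        n_poised = 5, n_k4me1_only = 5,
                                        seed = 17))
  genes <- make_genes(ls)
  set.seed(18)
  words <- replicate(5, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                              collapse = ""))
  pwms <- lapply(1:5, function(i)
    sharp_pwm(sprintf("M%d", i), sprintf("TF%d", i), words[i]))
  sq <- make_sequences(ls, pwms, plant_prob = 0.6, seed = 19)
  links <- data.frame(se_id = genes$element_id[genes$is_tf],
                      tf_gene = genes$gene_id[genes$is_tf])
  net <- build_network(pwms, links, sq$sequences)
  planted <- merge(sq$registry, links, by = "se_id")
  key <- function(src, se) paste(src, se)
  owners <- vapply(pwms, `[[`, "", "owner_tf")
  names(owners) <- vapply(pwms, `[[`, "", "motif_id")
  want <- key(owners[planted$motif_id], planted$se_id)
  got <- key(net$source_tf, net$se_id)
  expect_true(all(want %in% got))          # every planted edge recovered
  expect_lte(length(setdiff(got, want)), 1)  # at most one background hit
})

test_that("JASPAR-style matrices parse into normalized PWMs", {
  f <- withr::local_tempfile()
  writeLines(c(">MA0002.1 KLF4",
               "A [ 10  0  5  5 ]",
               "C [  0 20  5  5 ]",
               "G [  5  0  5  5 ]",
               "T [  5  0  5  5 ]"), f)
  ps <- read_jaspar(f)
  expect_equal(ps[["MA0002.1"]]$owner_tf, "KLF4")
  expect_equal(colSums(ps[["MA0002.1"]]$matrix), rep(1, 4))
  expect_equal(unname(ps[["MA0002.1"]]$matrix["C", 2]), 1)
})
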