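#' Configuration for the synthetic enhancer landscape
#'
#' Defaults emulate the study's data shape at desk scale: a toy
#' genome of 2 x 20 Mb chromosomes; three keratinocyte states; per
#' state 20 super-enhancers (clusters of 4-8 H3K27ac constituents
#' within stitching distance, total span >= 24 kb), 500 typical
#' enhancers (isolated ~2 kb dual H3K27ac/H3K4me1 peaks), 50 promoter
#' decoys (dual-marked peaks with H3K4me3 fold enrichment >= 5), and
#' 50 poised plus 50 H3K4me1-only regions for transition analyses.
#' SE constituent signal (mean 500) exceeds TE signal (mean 10) with
#' multiplicative lognormal noise (sigma 0.2; 0 gives a noise-free
#' landscape). Half of each element class is shared across all
#' states; the rest is state-specific.
#'
#' @param ... overrides for any default listed above.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chrS1 = 2e7, chrS2 = 2e7),
    states = c("NHEK-P", "NHEK-D", "NHEK-M"),
    n_se = 20, n_te = 500, n_decoy = 50,
    n_poised = 50, n_k4me1_only = 50,
    shared_fraction = 0.5,
    se_constituents = c(4, 8),
    se_constituent_width = c(1500, 3000),
    se_gap = c(6000, 11000),
    te_width = c(1000, 3000),
    inter_gap = c(14000, 25000),
    se_signal_mean = 500, te_signal_mean = 10, signal_sigma = 0.2,
    decoy_fold_range = c(5, 15), low_k4me3_prob = 0.3,
    me1_premark_prob = 0.8,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$se_signal_mean <= cfg$te_signal_mean)
    stop("SE signal mean must exceed TE signal mean")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  structure(cfg, class = "landscape_config")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])
lnoise <- function(n, sigma) if (sigma > 0) stats::rlnorm(n, 0, sigma) else rep(1, n)

#' Generate a ground-truth enhancer landscape
#'
#' Places SE clusters, TEs, H3K4me3-high decoys, poised and
#' H3K4me1-only elements along the toy genome with inter-element gaps
#' exceeding the stitching distance, then emits per-state, per-mark
#' peak sets consistent with the enhancer-calling rules. Element
#' sharing across states follows `shared_fraction` exactly: per class,
#' `round(shared_fraction * n)` elements are present in every state
#' and the remainder are state-specific, so per-state counts equal the
#' configured n exactly.
#'
#' @param config a [landscape_config()].
#' @return list: `marks` (state -> list of H3K27ac / H3K4me1 /
#'   H3K4me3 / H3K27me3 `peak_set`s), `truth` (per-element table with
#'   type, span and state presence), `config`.
#' @export
make_landscape <- function(config = landscape_config()) {
  set.seed(config$seed)
  states <- config$states
  mk_universe <- function(type, n_per_state) {
    n_sh <- round(config$shared_fraction * n_per_state)
    rows <- list()
    if (n_sh > 0)
      rows[[1]] <- data.frame(type = type,
                              states = paste(states, collapse = ";"),
                              stringsAsFactors = FALSE)[rep(1, n_sh), ]
    n_spec <- n_per_state - n_sh
    for (st in states) {
      if (n_spec > 0)
        rows[[length(rows) + 1L]] <-
          data.frame(type = type, states = st,
                     stringsAsFactors = FALSE)[rep(1, n_spec), ]
    }
    do.call(rbind, rows)
  }
  uni <- rbind(mk_universe("se", config$n_se),
               mk_universe("te", config$n_te),
               mk_universe("decoy", config$n_decoy),
               mk_universe("poised", config$n_poised),
               mk_universe("k4me1_only", config$n_k4me1_only))
  uni <- uni[sample.int(nrow(uni)), , drop = FALSE]   # interleave types
  rownames(uni) <- NULL

  # sequential walk placement; margin keeps room for linked genes
  chroms <- names(config$chrom_lengths)
  margin <- 10000
  ci <- 1L; cur <- 0
  n_el <- nrow(uni)
  el_chrom <- character(n_el); el_start <- el_end <- numeric(n_el)
  constituents <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    repeat {
      gap <- runif1(config$inter_gap)
      start <- cur + gap
      if (uni$type[i] == "se") {
        k <- sample(seq(config$se_constituents[1],
                        config$se_constituents[2]), 1)
        w <- stats::runif(k, config$se_constituent_width[1],
                          config$se_constituent_width[2])
        g <- stats::runif(k - 1, config$se_gap[1], config$se_gap[2])
        cs <- start + c(0, cumsum(w[-k] + g))
        ce <- cs + w
        span_end <- ce[k]
      } else {
        span_end <- start + runif1(config$te_width)
        cs <- start; ce <- span_end
      }
      if (span_end + margin <= config$chrom_lengths[ci]) {
        el_chrom[i] <- chroms[ci]
        el_start[i] <- floor(start); el_end[i] <- ceiling(span_end)
        constituents[[i]] <- cbind(start = floor(cs), end = ceiling(ce))
        cur <- span_end
        break
      }
      ci <- ci + 1L; cur <- 0
      if (ci > length(chroms))
        stop("genome too small for the requested number of elements")
    }
  }
  truth <- data.frame(element_id = sprintf("el_%04d", seq_len(n_el)),
                      type = uni$type, chrom = el_chrom,
                      start = el_start, end = el_end,
                      states = uni$states, stringsAsFactors = FALSE)

  # enhancers inactive in a state are often already H3K4me1-premarked
  # there (regions primed for later activation); decided once per
  # (element, state) so every state's tracks stay reproducible
  premark <- matrix(stats::runif(n_el * length(states)) <
                      config$me1_premark_prob,
                    n_el, length(states),
                    dimnames = list(NULL, states))
  marks <- lapply(stats::setNames(states, states), function(st) {
    present <- vapply(strsplit(truth$states, ";"), function(s)
      st %in% s, TRUE)
    k27 <- k4me1 <- k4me3 <- k27me3 <- list()
    for (i in which(!present)) {
      if (truth$type[i] %in% c("se", "te") && premark[i, st]) {
        cs <- constituents[[i]]
        k4me1[[length(k4me1) + 1L]] <- data.frame(
          chrom = truth$chrom[i], start = pmax(cs[, 1] - 200, 0),
          end = cs[, 2] + 200, signal = config$te_signal_mean / 2,
          name = truth$element_id[i])
      }
    }
    for (i in which(present)) {
      cs <- constituents[[i]]
      type <- truth$type[i]
      if (type %in% c("se", "te", "decoy")) {
        mean_sig <- if (type == "se") config$se_signal_mean else
          config$te_signal_mean
        sig <- mean_sig * lnoise(nrow(cs), config$signal_sigma)
        k27[[length(k27) + 1L]] <- data.frame(
          chrom = truth$chrom[i], start = cs[, 1], end = cs[, 2],
          signal = sig, name = truth$element_id[i])
        k4me1[[length(k4me1) + 1L]] <- data.frame(
          chrom = truth$chrom[i], start = pmax(cs[, 1] - 200, 0),
          end = cs[, 2] + 200, signal = sig / 2,
          name = truth$element_id[i])
        if (type == "decoy") {
          k4me3[[length(k4me3) + 1L]] <- data.frame(
            chrom = truth$chrom[i], start = cs[, 1], end = cs[, 2],
            signal = sig, fold_enrichment = runif1(config$decoy_fold_range),
            name = truth$element_id[i])
        } else if (type == "te" &&
                   stats::runif(1) < config$low_k4me3_prob) {
          k4me3[[length(k4me3) + 1L]] <- data.frame(
            chrom = truth$chrom[i], start = cs[, 1], end = cs[, 2],
            signal = sig / 4, fold_enrichment = stats::runif(1, 1, 4.5),
            name = truth$element_id[i])
        }
      } else {   # poised / k4me1_only carry no H3K27ac
        k4me1[[length(k4me1) + 1L]] <- data.frame(
          chrom = truth$chrom[i], start = cs[, 1], end = cs[, 2],
          signal = config$te_signal_mean *
            lnoise(1, config$signal_sigma) / 2,
          name = truth$element_id[i])
        if (type == "poised")
          k27me3[[length(k27me3) + 1L]] <- data.frame(
            chrom = truth$chrom[i], start = pmax(cs[, 1] - 200, 0),
            end = cs[, 2] + 200, signal = config$te_signal_mean,
            name = truth$element_id[i])
      }
    }
    bind <- function(lst, fe = FALSE) {
      if (!length(lst)) {
        df <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), signal = numeric())
        if (fe) df$fold_enrichment <- numeric(0)
        return(peak_set(df))
      }
      peak_set(do.call(rbind, lst))
    }
    list(H3K27ac = bind(k27), H3K4me1 = bind(k4me1),
         H3K4me3 = bind(k4me3, fe = TRUE), H3K27me3 = bind(k27me3))
  })
  list(marks = marks, truth = truth, config = config)
}

#' Elements of a landscape present in one state
#' @param truth the `truth` table from [make_landscape()].
#' @param state state label.
#' @param type optional element type filter.
#' @return subset of `truth`.
#' @export
truth_in_state <- function(truth, state, type = NULL) {
  present <- vapply(strsplit(truth$states, ";"), function(s)
    state %in% s, TRUE)
  out <- truth[present, , drop = FALSE]
  if (!is.null(type)) out <- out[out$type %in% type, , drop = FALSE]
  out
}

#' Plant genes next to landscape elements
#'
#' One gene per SE/TE element, placed just downstream of the element
#' span; SE-linked genes sit closer (planted offset 200-1000 bp) than
#' TE-linked genes (1500-3000 bp), so nearest-gene distances separate
#' the classes by construction. A random 20% subset is flagged
#' housekeeping; SE-linked genes are flagged as TF genes (the network
#' target universe).
#'
#' @param landscape output of [make_landscape()].
#' @param seed RNG seed (default: config seed + 1).
#' @return gene annotation data.frame with extra columns
#'   `element_id`, `is_housekeeping`, `is_tf`.
#' @export
make_genes <- function(landscape, seed = landscape$config$seed + 1) {
  set.seed(seed)
  el <- landscape$truth[landscape$truth$type %in% c("se", "te"), ,
                        drop = FALSE]
  n <- nrow(el)
  offset <- ifelse(el$type == "se", stats::runif(n, 200, 1000),
                   stats::runif(n, 1500, 3000))
  width <- stats::runif(n, 1000, 2500)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ann <- gene_annotation(sprintf("gene_%s", el$element_id),
                         el$chrom, floor(el$end + offset),
                         floor(el$end + offset + width), strand)
  idx <- match(ann$gene_id, sprintf("gene_%s", el$element_id))
  ann$element_id <- el$element_id[idx]
  ann$is_housekeeping <- stats::runif(n)[idx] < 0.2
  ann$is_tf <- el$type[idx] == "se"
  ann
}

#' Synthetic expression with elevated SE-linked genes
#'
#' SE-linked genes draw at `se_effect` times the TE-linked mean with
#' multiplicative lognormal noise; values are floored at 1.
#'
#' @param genes annotation from [make_genes()].
#' @param landscape the parent landscape (for element types).
#' @param se_effect fold elevation of SE-linked genes (default 2).
#' @param noise_sigma lognormal sdlog (default 0.5).
#' @param base_mean TE-linked mean intensity (default 1000).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `expression`.
#' @export
make_expression <- function(genes, landscape, se_effect = 2,
                            noise_sigma = 0.5, base_mean = 1000,
                            seed = landscape$config$seed + 2) {
  if (se_effect <= 0) stop("se_effect must be positive")
  set.seed(seed)
  type <- landscape$truth$type[match(genes$element_id,
                                     landscape$truth$element_id)]
  mean_val <- base_mean * ifelse(type == "se", se_effect, 1)
  data.frame(gene_id = genes$gene_id,
             expression = pmax(1, mean_val *
                                 lnoise(nrow(genes), noise_sigma)))
}

#' Synthetic TF ChIP peaks with tunable SE preference
#'
#' Per-base peak rate inside SE spans is `se_preference` times the
#' genomic background; peaks landing in SEs draw
#' `tag_ratio_target`-fold higher mean tags. Of the non-SE peaks, a
#' fraction `te_fraction` binds typical enhancers (TFs bind open
#' chromatin preferentially), which keeps the SE/TE tag-ratio
#' estimate well determined.
#'
#' @param landscape output of [make_landscape()].
#' @param state which state's SEs attract the factor.
#' @param se_preference relative per-base rate in SEs (>= 0).
#' @param tag_ratio_target SE/TE mean tag ratio planted (default 1.5).
#' @param n_peaks number of peaks (default 500).
#' @param base_tag_mean background mean tag count (default 50).
#' @param sigma lognormal tag noise (default 0.2).
#' @param peak_width min/max peak width (default 200-400 bp).
#' @param te_fraction fraction of non-SE peaks placed in TEs
#'   (default 0.5).
#' @param seed RNG seed.
#' @return list: `peaks` (`peak_set` with `signal`), `truth`
#'   (per-peak `in_se` flag), `seed`.
#' @export
make_tf_peaks <- function(landscape, state = landscape$config$states[1],
                          se_preference = 5, tag_ratio_target = 1.5,
                          n_peaks = 500, base_tag_mean = 50, sigma = 0.2,
                          peak_width = c(200, 400), te_fraction = 0.5,
                          seed = landscape$config$seed + 3) {
  if (se_preference < 0) stop("se_preference must be >= 0")
  set.seed(seed)
  se <- truth_in_state(landscape$truth, state, "se")
  te <- truth_in_state(landscape$truth, state, "te")
  genome <- sum(landscape$config$chrom_lengths)
  cov <- sum(se$end - se$start) / genome
  p_se <- se_preference * cov / (se_preference * cov + (1 - cov))
  in_se <- stats::runif(n_peaks) < p_se
  in_te <- !in_se & stats::runif(n_peaks) < te_fraction & nrow(te) > 0
  width <- stats::runif(n_peaks, peak_width[1], peak_width[2])
  chrom <- character(n_peaks); start <- numeric(n_peaks)
  cl <- landscape$config$chrom_lengths
  se_w <- se$end - se$start
  te_w <- te$end - te$start
  place_in <- function(el, w, j) {
    floor(stats::runif(1, el$start[j], max(el$start[j] + 1, el$end[j] - w)))
  }
  for (i in seq_len(n_peaks)) {
    if (in_se[i] && nrow(se)) {
      j <- sample.int(nrow(se), 1, prob = se_w)
      chrom[i] <- se$chrom[j]
      start[i] <- place_in(se, width[i], j)
    } else if (in_te[i]) {
      j <- sample.int(nrow(te), 1, prob = te_w)
      chrom[i] <- te$chrom[j]
      start[i] <- place_in(te, width[i], j)
    } else {
      repeat {
        ch <- sample(names(cl), 1, prob = cl)
        st <- floor(stats::runif(1, 0, cl[[ch]] - width[i]))
        hit <- any(se$chrom == ch & st < se$end & (st + width[i]) > se$start)
        if (!hit) { chrom[i] <- ch; start[i] <- st; break }
      }
    }
  }
  tags <- base_tag_mean * ifelse(in_se, tag_ratio_target, 1) *
    lnoise(n_peaks, sigma)
  peaks <- peak_set(chrom, start, start + ceiling(width), signal = tags)
  # re-derive per-peak truth on the sorted order
  key <- paste(chrom, floor(start))
  skey <- paste(peaks$chrom, peaks$start)
  list(peaks = peaks, truth = data.frame(in_se = in_se[match(skey, key)]),
       seed = seed)
}

SKIN_DISEASES <- c("psoriasis", "atopic_dermatitis", "alopecia_areata",
                   "basal_cell_carcinoma", "severe_acne",
                   "androgenic_alopecia", "facial_aging",
                   "stevens_johnson_syndrome")

#' Synthetic disease-SNP table with tunable SE enrichment
#'
#' Lead SNPs are placed uniformly over the genome except for a planted
#' excess inside SE spans (`enrichment_factor` times the per-base
#' background rate) with genome-wide significant p-values. Optional
#' sub-threshold SNPs (p > 5e-8) exercise the significance filter and
#' optional same-disease satellites within +-500 kb of a lead exercise
#' locus pruning.
#'
#' @param landscape output of [make_landscape()].
#' @param state state whose SEs carry the planted excess.
#' @param n_snps number of lead SNPs (default 200).
#' @param enrichment_factor relative SE rate; 1 = uniform null.
#' @param with_satellites,with_nonsig include pruning/filter fodder
#'   (default TRUE).
#' @param seed RNG seed.
#' @return data.frame: `chrom`, `pos`, `pvalue`, `disease`, `rsid`,
#'   plus ground-truth columns `role` (lead/satellite/nonsig) and
#'   `in_se`.
#' @export
make_snps <- function(landscape, state = landscape$config$states[1],
                      n_snps = 200, enrichment_factor = 1,
                      with_satellites = TRUE, with_nonsig = TRUE,
                      seed = landscape$config$seed + 4) {
  if (enrichment_factor < 0) stop("enrichment_factor must be >= 0")
  set.seed(seed)
  se <- truth_in_state(landscape$truth, state, "se")
  cl <- landscape$config$chrom_lengths
  genome <- sum(cl)
  cov <- sum(se$end - se$start) / genome
  p_se <- enrichment_factor * cov /
    (enrichment_factor * cov + (1 - cov))
  in_se <- stats::runif(n_snps) < p_se
  se_w <- se$end - se$start
  chrom <- character(n_snps); pos <- numeric(n_snps)
  for (i in seq_len(n_snps)) {
    if (in_se[i] && nrow(se)) {
      j <- sample.int(nrow(se), 1, prob = se_w)
      chrom[i] <- se$chrom[j]
      pos[i] <- floor(stats::runif(1, se$start[j] + 1, se$end[j]))
    } else {
      repeat {
        ch <- sample(names(cl), 1, prob = cl)
        p <- floor(stats::runif(1, 1, cl[[ch]]))
        if (!any(se$chrom == ch & p > se$start & p <= se$end)) {
          chrom[i] <- ch; pos[i] <- p; break
        }
      }
    }
  }
  leads <- data.frame(chrom = chrom, pos = pos,
                      pvalue = 5e-8 * 10^(-stats::runif(n_snps, 0, 4)),
                      disease = sample(SKIN_DISEASES, n_snps, TRUE),
                      role = "lead", in_se = in_se,
                      stringsAsFactors = FALSE)
  out <- leads
  if (with_satellites) {
    k <- max(1L, round(0.1 * n_snps))
    sat_of <- seq_len(k)
    shift <- sample(c(-1, 1), k, TRUE) *
      floor(stats::runif(k, 1e4, 4.9e5))
    sat <- leads[sat_of, , drop = FALSE]
    sat$pos <- pmax(1, sat$pos + shift)
    # still genome-wide significant, but weaker than the lead
    sat$pvalue <- pmin(sat$pvalue * 10^stats::runif(k, 0.5, 2), 4.9e-8)
    sat$role <- "satellite"; sat$in_se <- NA
    out <- rbind(out, sat)
  }
  if (with_nonsig) {
    k <- max(1L, round(0.25 * n_snps))
    ch <- sample(names(cl), k, TRUE, prob = cl)
    ns <- data.frame(chrom = ch,
                     pos = floor(stats::runif(k, 1, cl[ch])),
                     pvalue = 10^(-stats::runif(k, 3, 6.9)),
                     disease = sample(SKIN_DISEASES, k, TRUE),
                     role = "nonsig", in_se = NA,
                     stringsAsFactors = FALSE)
    out <- rbind(out, ns)
  }
  out$rsid <- sprintf("rsS%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Synthetic SE sequences with planted motif instances
#'
#' One background sequence per SE (i.i.d. bases at the given GC
#' content); each PWM's consensus (or a sampled realization) is
#' inserted with probability `plant_prob` at a random non-overlapping
#' offset and strand. Every insertion is recorded in a registry.
#'
#' @param landscape output of [make_landscape()].
#' @param pwms list of `pwm` objects.
#' @param state state whose SEs are sequenced.
#' @param plant_prob insertion probability per (PWM, SE).
#' @param gc background GC content (default 0.41, human-like).
#' @param seq_len sequence length in bp (default 1000).
#' @param mode `"consensus"` (per-position argmax) or `"sample"`.
#' @param seed RNG seed.
#' @return list: `sequences` (named character, names = SE element
#'   ids), `registry` (data.frame `se_id`, `motif_id`, `offset`,
#'   `strand`), `seed`.
#' @export
make_sequences <- function(landscape, pwms,
                           state = landscape$config$states[1],
                           plant_prob = 0.8, gc = 0.41, seq_len = 1000,
                           mode = c("consensus", "sample"),
                           seed = landscape$config$seed + 5) {
  mode <- match.arg(mode)
  if (plant_prob < 0 || plant_prob > 1) stop("plant_prob must be in [0, 1]")
  set.seed(seed)
  se <- truth_in_state(landscape$truth, state, "se")
  freqs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- stats::setNames(vapply(seq_len(nrow(se)), function(i)
    paste(sample(DNA_BASES, seq_len, TRUE, prob = freqs), collapse = ""),
    ""), se$element_id)
  reg <- list()
  for (si in seq_along(seqs)) {
    occupied <- cbind(start = numeric(0), end = numeric(0))
    for (p in pwms) {
      if (stats::runif(1) >= plant_prob) next
      L <- ncol(p$matrix)
      word <- if (mode == "consensus")
        paste(DNA_BASES[apply(p$matrix, 2, which.max)], collapse = "")
      else paste(apply(p$matrix, 2, function(col)
        sample(DNA_BASES, 1, prob = col)), collapse = "")
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") word else reverse_complement(word)
      off <- NA
      for (try in 1:50) {
        cand <- sample.int(seq_len - L + 1L, 1) - 1L
        if (!nrow(occupied) ||
            all(cand + L <= occupied[, 1] | cand >= occupied[, 2])) {
          off <- cand; break
        }
      }
      if (is.na(off)) next
      substr(seqs[si], off + 1L, off + L) <- ins
      occupied <- rbind(occupied, c(off, off + L))
      reg[[length(reg) + 1L]] <- data.frame(
        se_id = names(seqs)[si], motif_id = p$motif_id,
        offset = off, strand = strand, stringsAsFactors = FALSE)
    }
  }
  registry <- if (length(reg)) do.call(rbind, reg) else
    data.frame(se_id = character(), motif_id = character(),
               offset = integer(), strand = character())
  list(sequences = seqs, registry = registry, seed = seed)
}

#' Toy landscape with planted chromatin-state fates
#'
#' Builds a set of destination-state active enhancers whose
#' origin-state chromatin splits into the four fates active_TE,
#' poised, k4me1_only and unmarked at the given fractions, for
#' transition bookkeeping tests.
#'
#' @param n_per_fate regions per fate (default 25).
#' @param fractions named fractions over the four fates (must sum to
#'   1); overrides `n_per_fate` when given with `n_total`.
#' @param n_total total regions when using `fractions`.
#' @param seed RNG seed.
#' @return list: `regions` (with `category` = "active_TE" in the
#'   destination state and ground-truth `origin_fate`),
#'   `origin_marks` (list of `se`, `te`, `k4me1`, `k27me3` peak sets).
#' @export
make_fate_landscape <- function(n_per_fate = 25, fractions = NULL,
                                n_total = NULL, seed = 1) {
  fates <- c("active_TE", "poised", "k4me1_only", "unmarked")
  counts <- if (is.null(fractions)) stats::setNames(rep(n_per_fate, 4), fates)
  else {
    stopifnot(abs(sum(fractions) - 1) < 1e-9,
              all(names(fractions) %in% fates))
    stats::setNames(round(fractions[fates] * n_total), fates)
  }
  set.seed(seed)
  n <- sum(counts)
  fate <- sample(rep(fates, counts))
  start <- cumsum(stats::runif(n, 20000, 40000))
  width <- stats::runif(n, 1000, 3000)
  regions <- data.frame(chrom = "chrS1", start = floor(start),
                        end = floor(start + width),
                        category = "active_TE", origin_fate = fate,
                        stringsAsFactors = FALSE)
  mk <- function(idx, pad = 0) {
    if (!length(idx)) return(peak_set(character(), numeric(), numeric()))
    peak_set(regions$chrom[idx], pmax(regions$start[idx] - pad, 0),
             regions$end[idx] + pad, signal = 10)
  }
  i_te <- which(fate == "active_TE")
  i_po <- which(fate == "poised")
  i_me1 <- which(fate %in% c("active_TE", "poised", "k4me1_only"))
  list(regions = regions,
       origin_marks = list(se = mk(integer(0)), te = mk(i_te),
                           k4me1 = mk(i_me1, pad = 100),
                           k27me3 = mk(i_po, pad = 100)))
}

#' Synthetic knockdown screen with planted signature effects
#'
#' Emulates the 51-factor x 14,000-gene single-replicate knockdown
#' expression matrix: per-gene log fold-changes vs pooled scramble
#' controls are Gaussian noise, and each planted (factor, signature)
#' edge shifts the signature genes by `-effect_delta` (activator: its
#' targets drop on knockdown) or `+effect_delta` (repressor).
#'
#' @param n_factors number of knocked-down factors (default 51).
#' @param n_genes expression universe size (default 14000).
#' @param signature_size genes per signature (default 100).
#' @param network_truth data.frame `factor`, `signature`, `direction`
#'   ("activator"/"repressor"); `NULL` assigns each factor one
#'   signature round-robin as an activator.
#' @param effect_delta planted shift in log2 units (default 1).
#' @param noise_sigma Gaussian noise sd (default 0.5).
#' @param seed RNG seed.
#' @return list: `matrix` (genes x factors log2 fold-change),
#'   `signatures` (named list over progenitor/early/mid/late),
#'   `truth`, `de_tables` (per factor: `gene_id`, `log2fc`, `pvalue`
#'   from a normal z statistic on the known noise scale), `seed`.
#' @export
make_knockdown_screen <- function(n_factors = 51, n_genes = 14000,
                                  signature_size = 100,
                                  network_truth = NULL,
                                  effect_delta = 1, noise_sigma = 0.5,
                                  seed = 1) {
  stopifnot(is.finite(effect_delta), n_factors >= 2,
            n_genes >= 4 * signature_size)
  set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  factors <- sprintf("siTF%02d", seq_len(n_factors))
  sig_names <- c("progenitor", "early", "mid", "late")
  pool <- sample(genes, 4 * signature_size)
  signatures <- stats::setNames(split(pool, rep(sig_names,
                                                each = signature_size)),
                                NULL)
  names(signatures) <- sig_names
  if (is.null(network_truth))
    network_truth <- data.frame(
      factor = factors,
      signature = sig_names[(seq_len(n_factors) - 1) %% 4 + 1],
      direction = "activator", stringsAsFactors = FALSE)
  m <- matrix(stats::rnorm(n_genes * n_factors, 0, noise_sigma),
              n_genes, n_factors, dimnames = list(genes, factors))
  for (r in seq_len(nrow(network_truth))) {
    f <- network_truth$factor[r]
    sig <- signatures[[network_truth$signature[r]]]
    sgn <- if (network_truth$direction[r] == "activator") -1 else 1
    m[sig, f] <- m[sig, f] + sgn * effect_delta
  }
  de_tables <- lapply(stats::setNames(factors, factors), function(f) {
    z <- m[, f] / noise_sigma
    data.frame(gene_id = genes, log2fc = m[, f],
               pvalue = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  list(matrix = m, signatures = signatures, truth = network_truth,
       de_tables = de_tables, seed = seed)
}
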