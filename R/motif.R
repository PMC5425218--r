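DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param motif_id identifier (e.g. JASPAR accession).
#' @param owner_tf gene symbol of the TF that binds the motif.
#' @param matrix 4 x L numeric matrix of per-position base
#'   probabilities, rows A, C, G, T; columns must sum to 1 (1e-6).
#' @return list of class `pwm`.
#' @export
pwm <- function(motif_id, owner_tf, matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4L) stop("PWM must have length >= 4")
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  rownames(matrix) <- DNA_BASES
  structure(list(motif_id = motif_id, owner_tf = owner_tf,
                 matrix = matrix), class = "pwm")
}

#' Read JASPAR-style plain-text PWMs
#'
#' Parses records of the form `>ID NAME` followed by four lines
#' `A [ 1 2 3 ]` (counts or probabilities; normalized per column).
#'
#' @param path file path.
#' @return named list of `pwm` objects (names = motif ids); the
#'   header's second token becomes `owner_tf`.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records (missing '>' headers)")
  out <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>", "", lines[s]), "\\s+")[[1]]
    rows <- lines[(s + 1):(s + 4)]
    mat <- t(vapply(rows, function(l) {
      v <- sub("^[ACGT]\\s*\\[?", "", l)
      v <- sub("\\]\\s*$", "", v)
      as.numeric(strsplit(trimws(v), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(sub("\\]\\s*$", "",
      sub("^[ACGT]\\s*\\[?", "", rows[1]))), "\\s+")[[1]]))))
    mat <- sweep(mat, 2, colSums(mat), "/")
    id <- hdr[1]
    out[[id]] <- pwm(id, if (length(hdr) > 1) hdr[2] else id, mat)
  }
  out
}

# log2-odds matrix with pseudo-count; N (code NA) scores 0
pwm_logodds <- function(p, background = rep(0.25, 4), pseudo = 1e-3) {
  m <- p$matrix + pseudo
  m <- sweep(m, 2, colSums(m), "/")
  log2(m / background)
}

reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# score every window of `codes` (ints 1..4, NA for N) under log-odds `lo`
window_scores <- function(codes, lo) {
  L <- ncol(lo); n <- length(codes)
  if (n < L) return(numeric(0))
  sc <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    cj <- codes[j:(n - L + j)]
    v <- lo[cbind(cj, j)]
    v[is.na(cj)] <- 0
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset with the log2-odds of the PWM (pseudo-count
#' 1e-3) against the background base frequencies; `N` bases score 0
#' (background). Hits are windows scoring at least
#' `threshold_fraction` of the maximum attainable log-odds score.
#' Minus-strand hits are found by scanning with the
#' reverse-complemented PWM; offsets are always on the given strand's
#' coordinates.
#'
#' @param p a `pwm` object.
#' @param sequence character scalar over A/C/G/T/N.
#' @param background base frequencies (A, C, G, T); default uniform.
#' @param threshold_fraction fraction of the maximum score required
#'   for a hit (default 0.8).
#' @param pseudo pseudo-count added to PWM probabilities.
#' @return data.frame: `offset` (0-based), `strand`, `score` (bits).
#' @export
scan_pwm <- function(p, sequence, background = rep(0.25, 4),
                     threshold_fraction = 0.8, pseudo = 1e-3) {
  lo <- pwm_logodds(p, background, pseudo)
  L <- ncol(lo)
  codes <- match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
  if (length(codes) < L)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  max_score <- sum(apply(lo, 2, max))
  thr <- threshold_fraction * max_score
  fwd <- window_scores(codes, lo)
  rc_lo <- lo[4:1, L:1, drop = FALSE]    # reverse complement of the motif
  rev <- window_scores(codes, rc_lo)
  hit_f <- which(fwd >= thr); hit_r <- which(rev >= thr)
  out <- data.frame(
    offset = c(hit_f, hit_r) - 1L,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]))
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Motif enrichment in target vs background sequences
#'
#' Counts sequences with at least one PWM hit in each set and tests
#' enrichment one-sidedly with the exact hypergeometric (Fisher) tail.
#'
#' @param p a `pwm`.
#' @param target_seqs,background_seqs character vectors of sequences.
#' @param ... passed to [scan_pwm()].
#' @return list: `odds_ratio`, `p.value` (one-sided, enrichment),
#'   `target_hits`, `background_hits`, `n_target`, `n_background`.
#'   Zero hits in both sets reports odds ratio 1 and p 1.
#' @export
motif_enrichment <- function(p, target_seqs, background_seqs, ...) {
  if (!length(target_seqs) || !length(background_seqs))
    stop("both sequence sets must be non-empty")
  has_hit <- function(seqs) vapply(seqs, function(s)
    nrow(scan_pwm(p, s, ...)) > 0L, TRUE)
  a <- sum(has_hit(target_seqs)); n1 <- length(target_seqs)
  b <- sum(has_hit(background_seqs)); n2 <- length(background_seqs)
  if (a + b == 0L)
    return(list(odds_ratio = 1, p.value = 1, target_hits = 0L,
                background_hits = 0L, n_target = n1, n_background = n2))
  pv <- stats::phyper(a - 1, a + b, n1 + n2 - a - b, n1,
                      lower.tail = FALSE)
  or <- (a / max(n1 - a, .Machine$double.eps)) /
    max(b / max(n2 - b, .Machine$double.eps), .Machine$double.eps)
  list(odds_ratio = or, p.value = pv, target_hits = a,
       background_hits = b, n_target = n1, n_background = n2)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul–Erikson shuffle: samples a uniformly random sequence with
#' exactly the original dinucleotide (edge) counts by drawing a random
#' Eulerian path on the base-transition multigraph.
#'
#' @param sequence character scalar.
#' @return shuffled character scalar with identical dinucleotide counts.
#' @export
dinuc_shuffle <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n <= 3L) return(sequence)
  verts <- unique(s)
  edges <- lapply(stats::setNames(verts, verts), function(v)
    s[which(s[-n] == v) + 1L])
  last <- s[n]
  repeat {                              # sample a last-edge arborescence
    final_edge <- vapply(verts, function(v) {
      if (v == last || !length(edges[[v]])) return(NA_character_)
      e <- edges[[v]]
      e[sample.int(length(e), 1L)]
    }, "")
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(final_edge[[v]])) next
      seen <- v; cur <- v
      while (cur != last) {
        cur <- final_edge[[cur]]
        if (is.na(cur) || cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  shuffled <- lapply(stats::setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (!length(e)) return(e)
    if (v != last && !is.na(final_edge[[v]])) {
      i <- match(final_edge[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) rest[sample.int(length(rest))], e[i])
    } else e[sample.int(length(e))]
  })
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n); out[1] <- s[1]; cur <- s[1]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt; cur <- nxt
  }
  paste(out, collapse = "")
}

#' Build the directed SE-to-TF regulatory network
#'
#' For every enriched PWM and every SE sequence containing at least
#' one hit, emits an edge from the motif's owner TF to each TF gene
#' linked to that SE. Self-edges are allowed and flagged.
#'
#' @param enriched_pwms list of `pwm` objects (already filtered for
#'   enrichment).
#' @param se_links data.frame `se_id`, `tf_gene` linking SEs to the TF
#'   genes they overlap or neighbor.
#' @param se_sequences named character vector (names = `se_id`).
#' @param ... passed to [scan_pwm()].
#' @return data.frame of edges: `source_tf`, `target_tf`, `se_id`,
#'   `n_hits`, `self`.
#' @export
build_network <- function(enriched_pwms, se_links, se_sequences, ...) {
  rows <- list()
  for (p in enriched_pwms) {
    for (se_id in names(se_sequences)) {
      targets <- se_links$tf_gene[se_links$se_id == se_id]
      if (!length(targets)) next
      nh <- nrow(scan_pwm(p, se_sequences[[se_id]], ...))
      if (nh == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        source_tf = p$owner_tf, target_tf = targets, se_id = se_id,
        n_hits = nh, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_tf = character(), target_tf = character(),
               se_id = character(), n_hits = integer())
  out$self <- out$source_tf == out$target_tf
  rownames(out) <- NULL
  out
}

#' Validate network edges against knockdown differential expression
#'
#' For each source TF with a knockdown DE table, the fraction of its
#' predicted targets responding (DE p < `p_threshold`) is reported.
#' Sources without a DE table are skipped with a message.
#'
#' @param network edge data.frame from [build_network()].
#' @param knockdown_de named list (source TF -> DE data.frame with
#'   `gene_id`, `pvalue`).
#' @param p_threshold strict DE cutoff (default 0.05).
#' @return data.frame: `source_tf`, `n_targets`, `validated_fraction`,
#'   plus attribute `unvalidated` (named list of unresponsive targets).
#' @export
validate_edges <- function(network, knockdown_de, p_threshold = 0.05) {
  sources <- unique(network$source_tf)
  unvalidated <- list()
  rows <- lapply(sources, function(src) {
    de <- knockdown_de[[src]]
    if (is.null(de)) {
      message("no knockdown DE table for ", src, "; skipped")
      return(NULL)
    }
    targets <- unique(network$target_tf[network$source_tf == src])
    pv <- de$pvalue[match(targets, de$gene_id)]
    responsive <- !is.na(pv) & pv < p_threshold
    unvalidated[[src]] <<- targets[!responsive]
    data.frame(source_tf = src, n_targets = length(targets),
               validated_fraction = mean(responsive))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source_tf = character(), n_targets = integer(),
                      validated_fraction = numeric())
  attr(out, "unvalidated") <- unvalidated
  out
}
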