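---
title: "Methods: enhancer landscapes, super-enhancer calling and regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer landscapes, super-enhancer calling and regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscape)
```

# Scope and model

`enhancerscape` analyses histone-mark-defined enhancer landscapes of
human epidermal keratinocytes across functional states — progenitor
(NHEK-P), differentiating (NHEK-D) and migrating (NHEK-M) — and the
regulatory circuitry that sits on top of them. The package starts
from *called peak sets* (BED-like intervals with signal), not from
reads: alignment and peak calling are upstream of its scope.

The core definitions are:

* **Typical enhancer (TE)** — an H3K27ac peak overlapping at least
  one H3K4me1 peak, with low promoter signal: no overlapping H3K4me3
  peak at or above 5-fold enrichment over the input control. The
  5-fold filter is strict (`< 5` passes, `= 5` fails), and any
  overlap with a high H3K4me3 peak disqualifies, including edge
  overlaps. The TE footprint is the H3K27ac peak itself, because the
  super-enhancer track is also built from H3K27ac and the final
  SE/TE partition subtracts SE footprints from TEs — which is only
  coherent if both live on the same coordinates.
* **Super-enhancer (SE)** — H3K27ac peaks stitched across gaps of at
  most 12,500 bp are ranked by total (optionally input-subtracted)
  signal; regions above the geometric cutoff of the signal-vs-rank
  curve whose span is at least 12,500 bp are SEs. The 12.5 kb value
  serves both as the stitching distance (the ROSE-style default) and
  as a minimum SE length; the two are independent knobs
  (`stitch_distance`, `min_length`) because the published phrase "at
  least 12.5 kb" is ambiguous between the two readings.
* **Chromatin-state categories** — `active_SE > active_TE > poised >
  k4me1_only > unmarked`, with any 1-bp overlap deciding membership.
  Poised requires H3K4me1 *and* H3K27me3; when no H3K27me3 track is
  provided the poised class is unavailable and such regions classify
  as `k4me1_only`, with a warning.

## The rank-curve cutoff

Both axes of the signal-vs-rank curve are scaled to [0, 1]. The
cutoff is placed where a line of unit slope is tangent to the curve
from below, i.e. at the rank minimising `scaled_signal − scaled_rank`.
For a convex ascending curve this is exactly the last point past
which the discrete slope exceeds 1, but unlike a width-1 sliding
secant it is insensitive to local jitter inside the high-signal tail
(two nearly-equal top signals would otherwise truncate the SE set
arbitrarily). Exact ties resolve to the highest such rank, so a
strictly linear curve yields zero SEs; an all-equal curve yields zero
SEs with a warning. The cutoff is invariant to uniform rescaling of
all signals.

## Interval conventions

All coordinates are 0-based half-open (BED). Overlap queries default
to 1 bp minimum overlap (the `intersectBed` default; no published
fraction threshold exists for these analyses). Nearest-gene distance
is measured to the gene body, not the TSS, with ties broken by
smaller gene start then lexically smaller gene id. Replicate
consensus keeps first-replicate coordinates. Proximal promoters are
the 3 kb window from 2 kb upstream to 1 kb downstream of the TSS; on
the minus strand the window is mirrored about the TSS base,
`[tss − 1000, tss + 2001)`, truncated at coordinate 0. Interval
algebra is executed by `GenomicRanges`/`IRanges`; the test suite
checks every operation against per-base bitmap and all-pairs oracles.

# Cross-state comparisons

Three-way Venn counts operate on *merged union elements*: the union
of the three peak sets is reduced to disjoint intervals and each is
labeled by which inputs overlap it. Per-state element counts are
asymmetric when overlaps are many-to-one; the union convention gives
one well-defined count per class. Persistence between two states is
likewise union-normalized (shared union elements / all union
elements); dividing by the summed element counts is available as an
option. Transition tables count *origin-state elements* classified in
the destination landscape, and per-origin fractions sum to 1.

# Expression linkage

SE- and TE-linked gene classes are compared with a Welch
(unequal-variance) two-sample t-test — the robust default where only
"t-test" is specified. Genes are deduplicated within a class before
testing to avoid pseudo-replication from several enhancers sharing a
nearest gene (a per-enhancer option exists). An expression floor of
200 units (the microarray convention for "not expressed") is applied
by default and can be disabled. Fold-change summaries per enhancer
fate report means with seeded 1,000-resample bootstrap percentile
intervals; single-gene groups are flagged degenerate.

# Disease-SNP enrichment

SNPs are filtered at genome-wide significance (p ≤ 5e-8, inclusive)
and pruned per disease to lead SNPs: greedy selection in ascending
p-value (position breaks ties), removing same-disease SNPs within
±500 kb of each selected lead. The greedy rule resolves chains
A–B–C where each pair is within the window but the ends are not.

The null model replaces each region by a uniformly placed interval of
the same length *on its own chromosome* (chromosome- and
length-matched, preserving chromosomal composition), counting SNP
overlap per draw. Enrichment is reported two ways: a two-cell
chi-square on (in-region, out-of-region) counts against the null-mean
expectation (df = 1), and the empirical permutation p-value
`(1 + #{null ≥ observed}) / (1 + n_draws)`. The empirical p is exactly
calibrated but its resolution is bounded below by `1/(1 + n_draws)`,
so very small significance levels (e.g. α = 0.001 with a few hundred
draws) are assessed with the chi-square p; the acceptance tests use
the chi-square p for both the null-calibration and the power check
for that reason, at 200 null draws per simulation.

# TF occupancy

Occupancy statistics are overlap-based: fraction of regions bound,
per-region peak counts (means over *bound* regions only), and the
SE/TE tag ratio over mean peak signal with SE priority for peaks
touching both classes (the ratio is scale-free, so library
normalization cancels). Genomic distribution assigns each peak one
class by priority `promoter > SE > TE > H3K4me3-other > other`;
promoter first because proximal promoters are reported separately
from enhancer classes, SE before TE as a safety net on a partition
that is disjoint by construction. Differential binding between
conditions is approximated by overlap-based unique peaks (flagged
`method = "overlap"` in the output) rather than an affinity model:
the downstream quantities are region counts, not test statistics.

# Motif scanning and the SE→TF network

PWMs are scanned as log2-odds against background base frequencies
with a 1e-3 pseudo-count (avoids −∞ on zero entries); `N` bases score
0 bits. Hits are windows scoring at least a fraction (default 0.8)
of the maximum attainable score — a threshold that needs no
score-distribution approximation. Minus-strand hits come from
scanning with the reverse-complemented matrix;
reverse-complementing both PWM and sequence leaves the hit-score
multiset invariant.

Motif enrichment is a one-sided Fisher (hypergeometric tail) test on
sequences-with-a-hit counts, target vs background, with seeded
Altschul–Erikson dinucleotide-shuffled targets as the default
background. This replaces ranked-list enrichment machinery with an
exactly specified, desk-scale statistic. Zero hits in both sets
report odds ratio 1, p 1.

Network edges run from the motif's owner TF to each TF gene linked
to an SE containing at least one hit; SE→gene links reuse the
nearest-gene mapping restricted to a TF gene list, with gene-body
overlap taking precedence over distance. Self-edges are permitted
and flagged. Edge validation computes, per source TF with a
knockdown DE table, the fraction of predicted targets with DE
p < 0.05.

# Knockdown-screen scoring

The screen is a single-replicate factor × gene matrix of log
fold-changes versus pooled scramble controls (a plain statistic; a
moderated-variance statistic is out of scope and the choice is
recorded in the output metadata). PCA centers gene-wise and uses the
SVD, with a deterministic sign convention (the largest-magnitude
loading of each component is made positive).

Signature enrichment is the weighted Kolmogorov–Smirnov running sum:
genes ranked by statistic (most up-regulated first), signature hits
incrementing by `|s|^p` normalized over hits (default p = 1; p = 0
gives rank-only scores), misses decrementing by `1/(N − |S|)`. The ES
is the extremum of the running sum; when positive and negative
excursions tie in magnitude the first extremum along the ranking is
taken, for determinism. The *inverse* (display) score negates the
ES so that signatures concentrated among genes down-regulated by a
knockdown show positive values. Significance is a gene-label
permutation p (two-sided on |ES|, seeded; single-replicate design
leaves no sample-label permutation). Factor clustering is
hierarchical with Euclidean distance and average linkage, rows
pre-sorted by label so equal-height merges are deterministic.

# The synthetic landscape generator

Every stage is testable without downloads because the generator
plants ground truth that the callers must recover:

* Toy genome: 2 chromosomes × 20 Mb — large enough for 500+ elements
  per state at realistic spacing, small enough for sub-minute runs.
* Per state: 20 SEs (clusters of 4–8 H3K27ac constituents, 1.5–3 kb
  wide, gaps 6–11 kb, so spans run ~24–100 kb and always stitch at
  12.5 kb), 500 TEs (isolated 1–3 kb dual H3K27ac/H3K4me1 peaks,
  matching the ~2 kb typical TE), 50 promoter decoys (dual-marked
  with H3K4me3 fold enrichment ≥ 5, which the TE caller must
  reject), 50 poised and 50 H3K4me1-only elements for transition
  analyses. Inter-element gaps of 14–25 kb exceed the stitching
  distance, so planted TEs never stitch into SEs.
* Signals: SE constituents mean 500, TEs mean 10, multiplicative
  lognormal noise with σ = 0.2 (σ = 0 gives the noise-free setting in
  which calling is exact by construction).
* Sharing: half of each element class is present in all three
  states, the rest state-specific, and per-state counts equal the
  configured numbers exactly. Enhancers inactive in a state are
  H3K4me1-premarked there with probability 0.8, mirroring the
  observation that inactive-state enhancers are frequently already
  primed.
* Genes are planted just downstream of each SE/TE (SE genes at
  200–1000 bp, TE genes at 1500–3000 bp, so SE-linked genes are
  nearer by construction); 20% are flagged housekeeping and SE-linked
  genes form the TF-gene universe. Expression draws SE-linked genes
  at 2× the TE-linked mean with lognormal noise (sdlog 0.5).
* TF peaks land in SEs at `se_preference` times the background
  per-base rate, with tags `tag_ratio_target`-fold (default 1.5)
  higher inside SEs; half the non-SE peaks bind TEs so both ratio
  denominators are well determined at 500 peaks.
* SNPs are uniform except a planted SE excess; sub-threshold
  p-values and same-disease satellites within ±500 kb exercise the
  significance filter and the pruning stage.
* SE sequences are i.i.d. at 41% GC; motif instances are inserted at
  non-overlapping offsets and random strands with probability
  `plant_prob`, and every insertion is registered. The default
  inserts the per-position consensus (a sampled realization is an
  option): the registry then guarantees a scannable instance, so
  recall measures the scanner rather than the sharpness of the PWM.
* The knockdown screen plants factor→signature effects
  (activators shift their signature by −δ, default δ = 1, noise
  σ = 0.5) on a 51 × 14,000 matrix; DE tables use a normal z on the
  known noise scale.

All generators are pure functions of (configuration, seed) and are
byte-identical across runs at a fixed seed.

**What the generator does not emulate:** read-level noise, peak-caller
artefacts, realistic sequence composition beyond GC content, linkage
disequilibrium between SNPs, correlated expression noise, or batch
structure. Passing tests therefore demonstrate that the
implementations compute their definitions correctly and recover
planted structure under controlled noise — not that the definitions
would be robust to every failure mode of real ChIP-seq data.

# Problem sizes used by the test suite

Unit tests run on toy chromosomes (≤ 10 kb) against brute-force
oracles; the end-to-end checks use the full default landscape
(3 states, ~1,300 planted elements), 1,000 randomized interval-algebra
cases, 500 null-calibration and 100 power simulations for SNP
enrichment (200 null draws each), 500 permutation-calibration trials
for the enrichment score (100 permutations each), 100 random
PWM/sequence scan pairs, an exhaustive Fisher enumeration over all
2×2 margins up to 20, and 20 seeded replicates for the rank-curve
separation and network-recovery checks.

# Known limitations

* The SE caller is not a byte-identical ROSE port; it reproduces the
  stitch–rank–cutoff geometry at desk scale.
* Differential binding and differential expression use deliberately
  plain statistics (overlap-based unique peaks; z on a known noise
  scale in the generator); affinity-model and moderated-variance
  alternatives are out of scope.
* Location classes for SNP hits depend on the annotation supplied:
  without exon records, gene-body hits report as intronic.
* The empirical enrichment p cannot resolve below `1/(1 + n_draws)`;
  increase draws for small α or rely on the chi-square p.
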