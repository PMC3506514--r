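---
title: "Assessing CNV call quality from paired blood and buccal array samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing CNV call quality from paired blood and buccal array samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconcord)
library(dplyr)
set.seed(1)
```

## The problem

Cohort studies that collect DNA by subject-mailed buccal (cheek) brushes need
to know whether those samples support genome-wide copy-number variant (CNV)
detection, not just SNP genotyping. CNV inference from SNP arrays leans on the
noisy per-locus log R ratio (LRR) — the base-2 log of observed versus
reference probe intensity — so lower-quality DNA could degrade it badly even
while genotype call rates stay high. The natural study design collects both
whole blood and buccal DNA from the same subjects, including mother–infant
dyads, and asks three questions:

1. Do the two tissues of one person agree (self concordance)?
2. Do mothers and children agree more than unrelated people (heritable CNVs)?
3. Do unrelated people still agree a little (common population CNVs)?

If CNV signal is real, pairwise agreement must be ordered
**self > mother–child > unrelated**, for any reasonable calling method. This
package implements that whole assessment as a reproducible pipeline — two
independent CNV-detection routes, the stratified pairwise correlation
statistic, SNP-identity QC — together with a synthetic cohort generator that
produces data with exactly the statistical structure the assessment assumes.

## The concordance statistic

For a pair of samples $(a, b)$ and a per-locus series $x$ (raw LRR or a
derived segment-mean series), the statistic is plain Pearson correlation on
the genome-wide concatenation of autosomal loci,

$$ r_{ab} = \mathrm{cor}\big(x_a, x_b\big), $$

averaged within pair categories. Categories cross relatedness (self /
mother–child / unrelated) with tissue combination (blood–buccal,
blood–blood, buccal–buccal). Self pairs are by construction cross-tissue.
Cross-tissue pairs of two different subjects are directional (mother-blood
vs child-buccal is a different sample pair than mother-buccal vs
child-blood) and both directions are enumerated; within-tissue pairs are
unordered. Unrelated pairs exclude only a subject's own dyad partner. Every
pair is weighted equally in category averages, and any pair whose
correlation is undefined (zero variance) is dropped with a warning, never
silently.

Raw LRR correlations are heavily diluted by independent per-locus noise, so
the assessment is really about *segment-mean projection*: replace each
locus's LRR by the mean of its enclosing constant-copy segment. Projection
suppresses the independent noise while keeping the (shared) CNV features —
that is what lifts self-pair correlations from roughly 0.3–0.6 on raw data
to 0.9+ after segmentation, and it is why the category ordering becomes
visible.

## Route 1: penalized optimal segmentation

`optimal_segmentation()` partitions one chromosome's LRR series by
minimizing

$$ \sum_{\text{segments } s}\ \sum_{i \in s} (x_i - \bar x_s)^2 \;+\;
   \lambda \cdot \#\{\text{segments}\}, $$

and returns the *global* optimum by dynamic programming, with PELT-style
candidate pruning that only discards strictly dominated change points (so
the optimum and tie-breaking are untouched; pruning is disabled when a
minimum segment length above 1 is requested, where its dominance argument
does not apply). Ties are broken toward fewer segments, then toward the
earliest admissible rightmost breakpoint, applied recursively — and
`brute_force_segmentation()` implements the same objective and tie-break by
exhaustive enumeration, as an independent oracle for series up to length 14.

The default penalty is a BIC-style rule $\lambda = 2\hat\sigma^2\log n$ with
$\hat\sigma = \mathrm{mad}(\Delta x)/\sqrt2$, estimated from first
differences so that genuine copy-number steps do not inflate the noise
estimate. The default minimum segment length is 1, because real deletions
spanning as few as three probes occur and must remain representable.
Chromosomes and samples are always segmented independently. Loci with
missing LRR are dropped for fitting and inherit the enclosing (left)
segment's mean at projection, keeping series aligned across samples.

## Route 2: a distance-dependent copy-number HMM

`call_cnvs()` implements a six-state Bayesian hidden Markov model in the
style of HMM-based array CNV callers: total copy numbers 0, 1, 2, 3, 4 plus
copy-neutral LOH (diploid intensity, homozygous BAF bands only).

* **Emissions.** LRR is Gaussian per state, default means
  $(-3, -0.66, 0, 0, 0.4, 0.75)$ and common sd $0.20$. The B allele
  frequency at SNP probes is an equal-weight mixture of Gaussian bands at
  the allelic ratios each state permits — $\{0, \tfrac12, 1\}$ at two
  copies, $\{0,1\}$ at one copy or LOH, $\{0,\tfrac13,\tfrac23,1\}$ at
  three — plus a 1% uniform outlier mass; at zero copies BAF is uniform.
  Intensity-only probes contribute the LRR term alone. The emission sd of
  0.20 is a deliberate calibration to the noise level of a decent array run
  (and of the generator's defaults): with a wider emission model the
  evidence per locus shrinks enough that a 20-probe deletion hovers at the
  LBF 30 threshold instead of clearing it.
* **Transitions.** Over a gap of $d$ bp the chain leaves its state with
  probability $p(d) = \rho\,(1 - e^{-d/L})$, $\rho = 10^{-3}$,
  $L = 100$ kb, and leave mass is distributed over states in proportion to
  the stationary weights $\pi$ (normal state 0.972). Writing the row as
  $(1-p)\delta_{ij} + p\,\pi_j$ makes $\pi$ *exactly* stationary, so a
  locus with completely uninformative emissions has posterior $\pi$ — a
  property the test suite asserts literally.
* **Decoding and evidence.** Posteriors come from scaled forward–backward
  (no underflow at $10^5$ loci); the state path from Viterbi with ties
  toward the normal state. Each maximal non-normal run becomes a call with
  a log10 Bayes factor: the restricted forward sum over all state paths
  across the run divided by the probability of the same data under the
  all-normal path, both conditioned on the flanking posterior (or the
  stationary prior at a chromosome start). This marginal-likelihood reading
  makes LBF nonnegative and monotone in evidence; thresholds of 10, 30 and
  50 are the conventional filtering levels, and filtered call sets are
  nested by construction. No EM re-estimation is performed — parameters are
  fixed and explicit.

`hmm_segment_mean_series()` turns filtered calls into a per-locus series:
call loci take the call's mean LRR, loci outside calls take the mean of
their maximal normal stretch. How a caller's output is flattened into a
comparable series is genuinely underdetermined; this rule is the package's
explicit contract, chosen because it treats normal stretches and calls
symmetrically.

## SNP-identity QC

Genotype call rate, blood–buccal genotype concordance over co-called loci,
and Mendelian duo consistency (opposite homozygotes AA/BB between mother
and child, flagged above a 1% rate) mirror standard identity checking for
mail-in collections, where mislabeled or miscollected samples are a real
hazard. `detect_sample_swaps()` runs all checks and flags exactly the
affected sample pairs; the flag thresholds (concordance < 0.95, violation
rate > 0.01) sit far from both the true-pair distribution (concordance
$\approx 1$) and the unrelated background (concordance $\approx 0.4$–$0.6$,
violation rate several percent), so the decision is not delicate.

The two-group comparisons (dyad correlations buccal vs blood; per-subject
CNV counts by tissue) use a paired t test on Fisher z-transformed
correlations (or raw counts), with a sign-flip permutation option. The
underlying study-design literature does not pin down a test for these
contrasts; the t test is documented as a pragmatic stand-in and the
permutation route sidesteps its normality assumption.

## What the generator emulates — and what it does not

`simulate_cohort()` produces the cohort structure the assessment assumes:

* a probe manifest of SNP and intensity-only loci spread over the 22
  autosomes in proportion to physical chromosome lengths, exponential
  inter-locus gaps (defaults: 5,479 + 927 loci, mean gap 4.5 kb — a
  1/100-scale model of a 660k-class array);
* common CNV regions (default 40, per-haplotype frequencies uniform on
  [0.05, 0.4], log-normal sizes with 100 kb mean) carried under
  Hardy–Weinberg equilibrium;
* mother–infant dyads with per-chromosome maternal transmission (no
  intra-chromosome recombination — CNV regions are sparse enough that
  recombination would add nothing the analysis tests) plus unrelated
  singletons (defaults 16 + 7, matching a 39-subject, 78-sample study);
* per-subject de novo CNVs and per-sample tissue-private somatic CNVs
  (default rate 0.05 each) so self pairs are high but not perfect;
* per-locus rendering: LRR state means $0.55\log_2(\mathrm{cn}/2)$ (floored
  at $-3$ for cn 0 — a bounded, monotone stand-in for the compressed
  dynamic range of array intensities), Gaussian noise sd 0.18 for blood and
  1.25× that for buccal (near parity, reflecting that swab DNA performed
  comparably in practice), BAF drawn in the band implied by genotype and
  copy number, GenCall-like quality scores from Beta(3.2, 1) with the 0.15
  no-call rule — calibrated so call rates sit near 99.8%;
* optional long-range sinusoidal LRR waves and per-sample batch offsets,
  both off by default.

Not modeled, deliberately: raw two-channel intensities and clustering
internals (quality is just a score with a threshold), sex chromosomes,
recombination maps, population stratification, GC-content waves correlated
across samples, and any DNA-yield-to-noise relationship (reported yields
exist, but no usable yield–noise law does). Passing tests on this generator
therefore demonstrate the *pipeline's* correctness and the *ordering*
structure of the statistic — they do not certify performance on any real
array, where waves, batch effects and cross-hybridization produce
correlated noise this generator intentionally omits.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere except BED export (0-based
  half-open). CNV sizes in kb use the inclusive span; quartiles use linear
  interpolation between order statistics. Both conventions are
  configurable-by-recomputation from the per-call tables.
* The `variant_copy` field of a CNV region is the total copy number of a
  typical aberrant carrier; a variant haplotype carries 0 copies if
  `variant_copy < 2` and `variant_copy - 1` otherwise, with totals clamped
  to [0, 4] — the state space the HMM models.
* One master seed drives the pipeline; each stage reseeds from a
  deterministic sub-seed so stages can be re-run in isolation, and a full
  `run_pipeline()` at a fixed seed is byte-identical across runs (the run
  manifest records versions, seed, and parameters, and no timestamps).
* Degenerate inputs are errors, not guesses: NaN in a segmentation series,
  non-monotone positions in the HMM, zero co-called loci in concordance,
  zero-variance series in correlation all raise typed conditions.

## Evaluation scale

The package's own acceptance checks run at a deliberately reduced scale so
the complete suite executes in minutes on one core: exhaustive-enumeration
cross-checks at series length ≤ 14 and chain length 6 (where enumeration is
exact), and 100 simulated cohorts of 8 dyads + 4 singletons on a
20,000-locus manifest for the ordering, projection-gain, and
threshold-monotonicity properties. The worked pipeline example and the
acceptance script use the 39-subject, 6,406-locus default configuration.
These sizes are the package's documented evaluation conditions; nothing in
the implementation depends on them.

## A worked example

```{r example, eval = FALSE}
library(cnvconcord)
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, "cnvconcord_out")

tidy(res$concordance)      # method x category mean correlations
glance(res$concordance)    # self-minus-unrelated gaps per method
res$cnv_summary            # CNV counts and sizes per tissue and threshold
autoplot(res$concordance)  # category boxplots
plot_lrr(res$samples[[1]], segment_sample(res$samples[[1]]), chrom = 3)
```

## Known limitations

* The segmentation stand-in is a defensible penalized least-squares
  change-point method, not a numerical clone of any commercial
  implementation; likewise the HMM is a transparent re-implementation of
  the HMM-caller *design*, not of a specific released program.
* LBF values depend on the emission calibration; comparisons across
  parameter settings should re-derive thresholds rather than reuse 10/30/50
  unexamined.
* The generator's BAF model uses truncation atoms at 0 and 1 while the HMM
  scores BAF with continuous band densities; the mild mismatch is shared by
  all states and does not bias state choice, but absolute likelihoods
  should not be over-interpreted.
* Correlation-based concordance treats all loci equally; a method that
  called only large CNVs perfectly would still score below one because
  small shared segments contribute too.
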