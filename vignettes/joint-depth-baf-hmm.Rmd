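---
title: "Joint depth and allele-frequency copy-number calling: models and design"
author: "tapcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint depth and allele-frequency copy-number calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models it
fits, the estimators behind them, the design choices that were genuinely
open, and what the simulation-based tests do and do not establish about
real data.

## The data and the problem

Targeted single-cell DNA platforms amplify a fixed panel of genomic
intervals (amplicons) in thousands of cells and genotype variants inside
those intervals. Two signals inform copy number: the read depth of each
amplicon, proportional to local DNA content but noisy and probe-biased,
and the B-allele frequency (BAF) of each variant, which distinguishes
allelic configurations that share the same total depth. Depth-only callers
miss allele-specific events and struggle when states differ by one copy;
BAF is uninformative where no heterozygous variants exist. `tapcnv` calls
integer copy number 1–5 per cell per chromosome by modeling both signals
jointly, with a depth-only baseline caller for comparison.

## Normalization and reference learning

Counts pass three steps. Cells whose total count falls below 10% of the
11th-largest cell total are dropped as debris barcodes (with fewer than
11 cells the anchor falls back to the minimum, keeping everything — the
filter exists to remove empty droplets, which cannot be distinguished at
toy scale). Each cell's counts are divided by its mean count plus a
stabilizer of 1; each amplicon is then scaled so its median over retained
cells maps to the diploid value 2 (a 0.05 stabilizer in the denominator
guards near-zero medians, and amplicons whose median sits below 0.01 are
excluded outright as signal-free).

Reference cells — a user-designated population of known karyotype, with
any non-diploid chromosomes declared in a template (e.g. a trisomy 10
reference is `reference_cn = c("10" = 3)`) — then anchor the absolute
scale: per amplicon, the baseline is the reference median rescaled by
2/CN_ref, so after division a cell at copy number *k* sits near *k*/2
regardless of the reference's own karyotype.

Two further quantities come from reference cells. The pooled depth
variance `sigma_d^2` is the mean squared deviation of reference
normalized depth from its template value. Before computing it the caller
applies probe QC: amplicons whose own reference mean squared residual
exceeds 8× the panel median are excluded. Amplicon capture distributions
in this data type vary enormously; a handful of near-exponential probes
would otherwise dominate the single pooled variance and drown the depth
signal of every well-behaved probe. The multiplier is a control parameter
(`max_dispersion_mult`); 8× separates the heavy-tailed outliers cleanly
from the bulk in this regime without touching ordinary probes.

From the reference BAF (folded to minor allele frequency,
MAF = min(BAF, 1−BAF)) the caller estimates the MAF noise `sigma_b` as
the root mean squared deviation from the nearest diploid genotype mean (0
or 0.5, cut at 0.25), and a per-amplicon heterozygosity rate `h_i` as the
fraction of reference observations with MAF above 0.15. That raw fraction
is biased upward: homozygous observations exceed the threshold by noise
alone. The estimate is debiased by the expected false-heterozygous rate,
computed one-sided because BAF cannot drop below 0 — homozygous noise is
clamped at the boundary, which also halves its apparent second moment, so
the unclamped noise scale is `sigma_b * sqrt(2)`. Without the correction,
panels with little true heterozygosity acquire `h_i` ≈ 0.1 everywhere,
which systematically favors the monosomy state (its genotype set is
purely homozygous and "wastes" no prior mass on heterozygotes).

## The hidden Markov model

Per chromosome, the ordered amplicons form a chain over states 1..K
(K = 5). Transitions use a persistence matrix: probability 1 − ε of
staying, ε/(K−1) to each other state; the initial distribution is uniform
(nothing in the data privileges a state before the first amplicon).

The emission at an amplicon factorizes into a depth term and a BAF term.
Depth is Gaussian, `N(d | mu_k, sigma_d^2)`, with `mu_k = k/2`. For BAF,
each variant's genotype is marginalized **independently**: the term is the
product over variants of `sum_g P(g | k, h_i) TN(b_v | mu_g, sigma_b)`,
where genotypes of state *k* have `mu_g = min(m, k−m)/k` for *m* minor
copies and TN is a normal truncated to [0, 0.5]. Genotype priors put mass
`h_i` on heterozygotes (split uniformly over m = 1..k−1, the
maximum-entropy interpolation that reproduces P(AB) = h at k = 2) and
1 − h_i on the two homozygotes; monosomy has only homozygotes. Variants
are distinct polymorphic sites, so each carries its own latent genotype:
an amplicon can host a heterozygous and a homozygous variant side by
side, and a likelihood that forced one shared genotype per amplicon would
fit neither — in testing, that variant of the model inflated `sigma_b`
to roughly twice its true value on data with mixed genotypes and
collapsed the state posteriors at intermediate heterozygosity, so the
per-variant form is used throughout. A missing depth or an amplicon
without variants simply drops the corresponding factor.

Genotypes sharing an expected MAF are merged analytically (for k = 5,
m = 1 and m = 4 both give 1/5), leaving at most three mixture components
per state; the implementation evaluates the truncated-normal density once
per unique component mean and assembles all amplicons and states with
vectorized log-sum-exp.

### Per-cell EM and its stabilization

Parameters θ = (mu, sigma_d², sigma_b, ε) are re-estimated per cell by
Baum–Welch: forward–backward runs independently per chromosome (scaled
recursions, with per-position stabilization of the emission matrix) and
the M-step pools sufficient statistics across the cell's chromosomes —
individual chromosomes hold only a handful of amplicons, far too few to
estimate noise parameters chain by chain. EM stops when the largest
parameter change falls below 1e-5 or after 50 iterations.

A cell contributes on the order of 100 observations to 8+ free
parameters, and an unpenalized per-cell EM measurably overfits: with weak
allelic signal the five state means drift toward the cell's depth
histogram and collapse onto one another, and the switch rate inflates to
explain emission noise as state flips, destroying the spatial pooling the
chain exists to provide. Two MAP ingredients stabilize the fit, both with
exact or generalized-EM updates so the penalized objective is monotone:

- **Mean ridge.** State means are shrunk toward their prior values *k*/2
  with pseudo-observation weight
  `w = w0 * n_d * max(0.25 − h̄, 0.05) / 0.25` (`w0 = 2`, `n_d` = depth
  observations, `h̄` = mean heterozygosity). The prior means are exact by
  construction of the reference normalization, so the ridge is a
  Gaussian prior on `mu_k`, strongest precisely for states with little
  posterior mass — the ones free to wander. It reaches full strength as
  the allelic anchor disappears (h̄ → 0) and never switches off entirely
  (floor at 1/5 strength): even at full heterozygosity a single variant
  per amplicon is too weak an anchor to license free means.
- **Switch-rate prior.** The ε update is MAP under a Beta prior centered
  at the initial rate (1e-3) with strength 20× the observed transition
  count (`eps_prior`; 0 recovers plain maximum likelihood). Whole
  chromosomes are the event unit here, so within-chromosome breakpoints
  are rare by construction, and ~66 transitions per cell cannot estimate
  a rare rate.

The depth mean/variance updates are the standard Gaussian M-step; the
`sigma_b` update maximizes the expected complete-data log-likelihood over
the truncated-normal scale by one-dimensional optimization with genotype
responsibilities held fixed (the truncation normalizer depends on sigma,
so the naive moment formula is not an M-step and can decrease the
likelihood), with a generalized-EM guard that never accepts a worse value
than the current one.

Final paths come from per-chromosome Viterbi decoding (log space; ties
break to the lowest state) and are aggregated to one call per chromosome
by the mode, ties broken toward the state nearest diploid and then lower
— ambiguous segments are called conservatively. Chromosomes left with no
usable amplicons yield no call, with a warning.

## The depth-only baseline

The baseline caller mirrors the karyotapR approach: per amplicon, a
maximum-likelihood Weibull fit (via `fitdistrplus`) to reference
normalized counts (zeros offset by 1e-3; failed fits flagged and
excluded); 500 synthetic cells per copy-number state drawn with the scale
parameter multiplied by k/CN_ref; per chromosome, each synthetic cell
summarized by its probe median and a Gaussian fitted per state by moment
matching — each component's members are known by construction, so no
mixture EM is needed; real cells classified by posterior probability
under equal priors, ties to the lower state. Segments are whole
chromosomes in this package (arm-level segmentation is out of scope).

## The simulator

The simulator generates the two benchmark designs with known truth.
Amplicon capture heterogeneity is emulated by per-amplicon Weibull
parameters shared across populations: shapes `max(0.3, N(2, 0.8²)+0.3)`,
scales inversely related to the shapes and min–max rescaled to
[0.5, 2.5]. Counts are drawn with the scale multiplied by CN/2, so the
expected count is proportional to copy number. Draws are kept continuous
by default (`round_counts` flag available): at this design's count scale
(about one read per amplicon) integer rounding injects quantization noise
of the same order as the half-copy state spacing, qualitatively changing
the depth-only problem.

Genotypes follow cell-line biology: founder diploid genotypes are drawn
once per population (heterozygous with probability `het_rate`), and
altered chromosomes derive their genotype by sequentially duplicating or
deleting a uniformly chosen allele copy — a trisomic heterozygote thus
has expected MAF 1/3 regardless of which allele was duplicated. A
designated "mixed" diploid population redraws genotypes per cell to mimic
non-clonal heterogeneity. Observed BAF adds Gaussian noise (standard
deviation `baf_sd`/100, i.e. the noise parameter lives on the percent
scale) and clamps to [0, 1].

The balanced design holds six equal populations (CN 1, reference CN 2,
mixed CN 2, CN 3, CN 4, CN 5; 80 cells each) on 22 chromosomes with 4
amplicons each and 3 variants per amplicon, with replicate jitter
(population sizes ×U(0.9, 1.1), BAF sd ×U(0.85, 1.15)). Each aneuploid
population alters a random 11 of 22 chromosomes by default; the
alteration count is a parameter (`n_altered`) because the two natural
choices behave differently — half-altered gives an always-diploid floor
accuracy of 0.667, while 7 of 22 (the load the two-population design
uses) gives 104/132 ≈ 0.788 — and both settings are exercised in the
test suite. The two-population design (diploid
reference plus one gain CN 3 or loss CN 1 line, 100 cells each, 7 of 22
chromosomes altered) is the one-parameter-at-a-time benchmark: BAF sd
{6, 9, 12}, variants per amplicon {0, 1, 3, 5}, amplicons per chromosome
{2, 4, 6}, cells per group {50, 100, 200}, heterozygosity {0, 25, 50,
75, 100}%, baseline values 9 / 3 / 4 / 100 / 100%.

What the simulator does **not** emulate: allelic dropout, doublets,
ambient DNA, subclonal or focal events, arm-level alterations, GC or
mappability trends, or per-cell amplification efficiency beyond the mean
scaling. Tests passing on these simulations therefore demonstrate
correctness of the estimators and the expected qualitative behavior of
the two callers (BAF-driven gains for the joint model, depth-resolution
limits for the baseline), not performance on real Tapestri libraries.

## Evaluation conventions

The evaluation unit is the cell × chromosome pair. The confusion matrix
is 5×5 over states; macro-F1 and balanced accuracy average over classes
present in truth or predictions (a fixed five-class average would cap
macro-F1 at 0.4 in a two-class design however perfect the calls — union
averaging avoids that artifact); all
0/0 ratios are 0, so the always-diploid floor has zero alteration F1.
Alteration metrics collapse states to altered (CN ≠ 2) versus diploid.

## Numerical choices, sizes, defaults

- Forward–backward uses per-position max-stabilized scaled recursions;
  chains of equal length are batched into single matrix operations.
  All-impossible positions raise an error rather than propagate NaN.
- Floors: `sigma_d² ≥ 1e-6`, `sigma_b ≥ 1e-3`, ε clamped to
  [1e-8, 1−1e-6].
- EM: `max_iter = 50`, `tol = 1e-5`, ε₀ = 1e-3, `w0 = 2`,
  `eps_prior = 20`, het threshold 0.15, probe QC multiplier 8 — all
  exposed via `hmm_control()`.
- Test and acceptance problem sizes: the two-population conditions use
  200 cells × 88 amplicons with 3 replicates per condition; the balanced
  design uses 480 cells × 88 amplicons with 10 replicates; oracle
  equivalence uses exhaustive enumeration up to chain length 6 and 4
  states. These match the benchmark designs and keep a full run in the
  minutes range on one CPU.
- Determinism: every stochastic stage derives its seed from a master seed
  and a run label, so adding a stage never perturbs another stage's
  stream.

## Known limitations

High copy-number states (4 and 5) overlap in both signals — their depth
means differ by a quarter of the noise scale and their MAF component sets
interleave — so sensitivity there is intrinsically limited and calls
should be read as "high gain" rather than exact dosage. At zero
heterozygosity the joint model deliberately degrades to depth-only
calling; the depth-only baseline is then the more robust choice. The
per-cell EM assumes the reference noise scales transfer to non-reference
cells up to the per-cell refit; strong per-cell amplification artifacts
would violate that. Copy-neutral LOH is visible to the BAF term but is
not emitted as a distinct state.
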