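---
title: "Cross-paradigm decoding of semantic composition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-paradigm decoding of semantic composition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When listeners hear an adjective–noun phrase ("green glass") rather than a
bare noun ("glass"), left temporal cortex carries a decodable signature of
semantic composition.  A central open question is whether the composition
signature measured under tightly controlled two-word experiments
generalizes to naturalistic listening, where the same nouns arrive inside
running narratives — faster, less predictable, prosodically rich, and
emotionally loaded.  `crossdecode` implements the complete statistical
pipeline for that comparison on source-space MEG epochs: within-paradigm
searchlight decoding, cross-paradigm temporal generalization,
permutation-based group inference, and confound regression against
word-level properties of naturalistic speech.

Because raw MEG recordings are not part of the package, every analysis is
exercised end-to-end on a synthetic source-space generator whose
statistical structure mirrors the paradigm: two paradigms sharing one
latent class-discriminative spatial pattern expressed at different
latencies, plus naturalistic-only confound regressors that correlate with
the phrase/noun class and add a late class-separable signal of their own.

## Source-space geometry

Sources live on an icosahedral mesh: recursive edge-midpoint subdivision
of the regular icosahedron projected to the unit sphere, so a level-$k$
mesh has $10 \cdot 4^k + 2$ vertices.  Level 4 reproduces the conventional
2562 source points of one hemisphere of a cortical source space; desk-scale
analyses default to level 2 (162 sources).  Six contiguous spherical caps
stand in for the anatomical regions of a left-lateralized language mask
(LATL, LMTG, LIFG, LvmPFC, LAG, LSMG); they are synthetic labels chosen so
that result summaries speak the field's vocabulary, not anatomical
parcellations.

A "searchlight radius of 20 sources" is interpreted as a 20-member
nearest-neighbor set (the center plus its 19 nearest masked sources):
the phrase counts sources, not metric distance.  Distances are Euclidean
chord distances on the sphere, which are monotone in geodesic distance and
therefore induce the same neighbor ordering; ties break by ascending
vertex index so neighborhoods are invariant to vertex-order permutations.
Whether the original analysis used geodesic discs, and whether "20"
includes the center, is not stated anywhere we could verify; both choices
are configurable (`k`), and the defaults are recorded here as decisions,
not facts.

## The synthetic data generator

`simulate_epochs()` draws, per subject, independent Gaussian noise per
(epoch, source, timepoint) with SD `noise_sd`, applies
`spatial_smoothing_passes` rounds of neighbor averaging on the masked
mesh, then an AR(1) filter along time with coefficient
`temporal_ar1_phi`.  Class effects are then added: each `effect_spec()`
holds a fixed unit-norm spatial pattern (drawn once from its
`pattern_seed`) which is scaled by `amplitude` and added to phrase-class
epochs inside its time window.  Defaults are `noise_sd = 1`, two smoothing
passes, and `phi = 0.3` — values chosen once to give the smooth, spatially
and temporally correlated background typical of source estimates.  The
noise covariance of real source-space data is not documented in any form
we could reproduce, so the noise model is the package's own choice and
all of its parameters are exposed in `sim_config()`.

The epoch grid is half-open $[0, 875)$ ms at 200 Hz, i.e. 175 samples at
5 ms steps; the stated epoch span ("onset to 875 ms" at 200 Hz) does not
say whether the endpoint is included, and the half-open convention gives
the even sample count.  Class balance is enforced (equal epochs per
class) so that 50% is a valid chance level; per-condition trial counts in
naturalistic designs vary, and 40 epochs per class is used as a
convention, not a reproduction.  Per-subject seeds derive from one master
seed XOR-ed with a hash of (subject, paradigm), so any single subject or
stage can be regenerated in isolation, bit-identically.

`simulate_naturalistic_with_confounds()` additionally draws the seven
word-level regressors per epoch (standard normal), shifts each confound's
mean by `class_shift` SD for phrase epochs, and adds
`loading_gain` × (z-scored regressor) × (fixed unit pattern) inside the
loading window.  This is the mechanism that lets a stimulus property
masquerade as a late composition effect — the structure the confound
regression is designed to remove.

What the generator does *not* emulate: source leakage from an inverse
operator, heteroscedastic sensor noise, cross-subject anatomical
variability, oscillatory structure, and autocorrelated word properties.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated on data with the designed covariance structure — not that
real MEG data meet those assumptions.

## Searchlight decoding

The classifier is a feed-forward network with one hidden layer of two
logistic units (`nnet`), logistic output with cross-entropy loss, trained
by full-batch BFGS with an iteration cap of 500 and relative convergence
tolerance `1e-5`, from fixed seeded initial weights — small, deterministic
given its seed, and robust on the tiny feature sets a searchlight
provides.  The activation, optimizer and iteration budget of the original
two-unit network are unstated; these defaults were chosen for
determinism and stability, and live in `classifier_spec()`.

At every (masked source, timepoint), features are the epoch values at the
searchlight's member sources.  Features are z-scored *within training
folds* (parameters estimated on the training fold, applied to the
held-out fold), which makes accuracy maps invariant to per-source affine
rescaling — accuracy should reflect pattern geometry, not amplitude
scale.  Predicted probabilities exactly at 0.5 resolve to the noun class,
a fixed documented tie-break.

Evaluation defaults to stratified 5-fold cross-validation.  The phrase
"classification accuracies for the training data" is ambiguous between
fit-set and held-out accuracy; fit-set accuracy of a flexible classifier
is biased above chance even under the null, which would invalidate the
group t-test against 50%, so cross-validation is the default and
`eval = "train"` reproduces the literal reading.  Decoding can be
restricted to a decimated time grid (`times_ms`) — standard practice to
keep desk-scale analyses tractable; the searchlight then scans, e.g., 162
sources × 20 timepoints in a few minutes per subject on one CPU.

## Group inference

Per cell, subject accuracies minus 50% enter a one-sample one-tailed t
statistic ($n-1$ SD).  TFCE integrates, over thresholds $h$ in steps of
$dh$, $e(h)^{E} h^{H} dh$ where $e(h)$ is the size of the connected
component supporting the cell at threshold $h$, with the standard
exponents $E = 0.5$, $H = 2$ (the method is named in the source analysis
without parameters; these are its canonical defaults).  $dh$ defaults to
$\max(t)/100$ with a floor of 0.05 t-units, computed once from the
observed map and reused across permutations; halving $dh$ changes scores
by well under 2% on smooth maps.  The family-wise null is the maximum
TFCE statistic over cells under subject sign flips — valid because under
the null hypothesis subject deviations from chance are symmetric — with
$p(v) = (1 + \#\{\max_{perm} \ge \mathrm{TFCE}(v)\})/(n_{perm}+1)$, never
exactly zero.  When $2^{n}$ does not exceed the requested permutation
count the flips are enumerated exhaustively instead.  Clusters are
connected components of $\{p \le \alpha\}$; extent is reported as cells,
sources, and timepoints, since published cluster sizes do not say which
of the three was counted.  Only above-chance accuracy is ever flagged
(one-tailed throughout).

TGM matrices are tested with the cluster-mass variant: cell-level t
against 0.5, cluster-forming threshold at the upper `threshold_p`
t-quantile, 4-connected components, mass = summed t, max-mass sign-flip
null.  Permutation counts default to 10,000 in `tfce_params()` for
full-scale runs; the test suite and examples use 200–1000, which the
calibration suite shows is sufficient for valid (slightly conservative)
p-values.  The degenerate zero-variance cell is reported as a ±Inf
sentinel by `one_sample_t()` and capped at t = 100 inside TFCE so a
single degenerate cell cannot stall the threshold sweep.

## Temporal generalization

Classifiers are trained at each timepoint of one paradigm on the raw
source values of a fixed vertex set — the vertices of the significant
within-paradigm cluster (`restrict_to_cluster()`), matching the logic of
only generalizing the classifiers that carried the within-paradigm effect
— and tested at every timepoint of the other paradigm.  Training uses all
epochs of the training paradigm with no cross-validation, since
evaluation is on the other paradigm; z-scoring parameters come from the
training data only; per-timepoint classifiers are independent, with no
temporal smoothing.  An empty cluster halts TGM with an explicit
"no significant cluster" error rather than silently testing nothing.
After confound regression, the pipeline's default pairing trains on
naturalistic *residuals* and tests on the *raw* two-word data, mirroring
the original analysis order; both pairings are available because the
intended combination is not fully determinate from the source.

## Confound regressors and residualization

The seven regressors are: peak RMS intensity and peak f0 of the target
word (maximum over the 10 ms prosody frames whose start lies in the
half-open word interval), word rate (duration in ms divided by letter
count), log unigram frequency (natural log by default), surprisal
(−log₂ P(word | preceding words of the same sentence), from a pluggable
probability provider; context resets at sentence boundaries), and
sentence-level emotional valence and arousal (across-rater means
broadcast to member words).  Log bases are configurable; since every
column is z-scored before use, base changes only rescale a column and
leave all downstream results unchanged — which is why the package does
not need to know which base the original computation used.  Rating
reliability is summarized by ISC: each rater's Pearson correlation with
the across-rater mean (including that rater, the literal reading), whose
null value is $\sqrt{1/R}$ rather than zero — the Monte-Carlo tests check
the exact attenuation form
$\sqrt{(s^2 + n^2/R)/(s^2 + n^2)}$.

Residualization is per-subject and mass-univariate: per (source,
timepoint), the epoch values are z-scored across epochs and regressed by
OLS on the seven z-scored regressors plus an explicit intercept; the
residuals replace the data.  Residuals are orthogonal to every regressor
column by construction (checked to 1e−6), and the operation is idempotent
because residuals are not re-standardized on a second pass.  Whether the
dependent variable was standardized per cell or globally is not
determinate; per-cell is used and recorded here.  Rank-deficient designs
and misaligned word ids are hard errors, and the pipeline requires
complete regressor tables — there is no missing-data path.

## State space and embeddings

`classical_mds()` is Torgerson's classical scaling (double-centered Gram
eigendecomposition, via `stats::cmdscale`) rather than an iterative
metric MDS: it is deterministic and needs no seed.  Reflections are
canonicalized by making each axis's largest-magnitude coordinate
positive; eigenvalues that are zero at machine precision are truncated
and zero-padded so degenerate configurations embed reproducibly.
Condition trajectories embed the per-timepoint phrase and noun mean
feature vectors over a cluster's sources jointly into 2-D; the
phrase–noun distance timecourse is reported both in the embedded plane
(matching the usual visualization) and in the full feature space, since
2-D truncation can shrink distances.  Embedding per-timepoint condition
means (rather than single trials) is a choice; per-word means are a
straightforward variant of the same code path.

The embedding-side analyses consume pre-extracted per-layer vectors from
a provider interface; the package ships synthetic providers only and
never downloads or runs a transformer.  Word-position residualization
(OLS on the binary position indicator, per layer and dimension) exactly
equalizes position group means; cross-context classification then fits
the same two-unit network on one context and tests on the other, using
the final layer by default.

## Power utility

`power_one_sample_t()` evaluates the noncentral-t power of the one-sample
test: with $n = 31$, $d = 0.6$, $\alpha = 0.05$, power is 0.90 to one
decimal under either one- or two-sided tails (0.947 / 0.898 exactly), so
the conventional 0.8 criterion is exceeded; the tail convention of the
original calculation is unstated and both are exposed, defaulting to
two-sided.

## Orchestration, determinism, and problem sizes

`run_full()` executes the stages in order (simulate both paradigms →
searchlight decode → TFCE inference → cluster-restricted TGMs and the 2-D
cluster test → regressor construction and residualization → re-decode and
re-inference → residual TGM → state-space trajectories), halting with the
stage name on failure and recording content hashes (`rlang::hash`) of
stage outputs, the seeds used, and the pre- vs post-residualization
cluster windows in its report.  Repeated runs with the same config are
hash-identical.  Stage outputs are recomputed rather than cached on disk:
at desk scale every stage is cheap, and the recorded hashes make identity
between runs checkable without a cache's invalidation machinery.

Problem sizes used throughout the examples and tests are desk-scale
choices: level-0 or level-2 meshes (12 / 162 sources), 6–10 subjects,
20–40 epochs per class, decimated decoding grids, and 200–1000
permutations; `tfce_params(n_permutations = 10000)` and a level-4 mesh
reproduce the full-scale settings (2562 sources, 10,000 permutations) when wanted.  The calibration suite runs
the full permutation machinery 200 times on null inputs at the
group-inference boundary (per-subject accuracy maps), confirming
family-wise error ≤ nominal within Monte-Carlo slack for both the TFCE
and the TGM cluster tests.

## Known limitations

- The synthetic generator's Gaussian + smoothing + AR(1) noise is a
  convenience model; no claim is made that its spectra match real source
  estimates.
- Sign-flip inference assumes symmetric subject deviations under the
  null; cross-validated accuracies satisfy this only approximately at
  small epoch counts.
- The two-unit network is trained afresh at every cell; with very small
  feature sets its BFGS path can flip isolated chance-level predictions
  under float-level input perturbations (general affine rescalings are
  equal only up to such flips; power-of-two rescalings are bit-exact).
- Group comparison between cohorts (e.g., adults vs children) is out of
  scope; all group inference pools subjects.
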