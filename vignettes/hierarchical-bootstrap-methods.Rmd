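---
title: "Hierarchical bootstrap analysis of vocal pitch adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical bootstrap analysis of vocal pitch adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songshift)
```

## The problem

Headphones pitch-shift experiments in Bengalese finches measure sensorimotor
adaptation: a bird hears its own song shifted by one semitone in (near) real
time and gradually changes the pitch of its syllables in the opposite
direction. The data are deeply nested — a handful of birds per group, each
singing 4–12 quantifiable syllables, each syllable repeated 40–600 times per
day across a 3-day baseline, a 14-day shift, and a 6–7-day washout. Pooling
all iterations and computing `sd/sqrt(n)` wildly understates the uncertainty
of a group mean, because iterations within a syllable and syllables within a
bird are not independent; collapsing to per-bird means throws most of the
data away. This package implements the middle path: a three-level
hierarchical bootstrap, posterior-probability hypothesis tests on the
bootstrap distributions, a nested linear mixed model as an independent
check, and an optical-density metric for the extent of dopaminergic
(6-OHDA) lesions of Area X — all driven by a synthetic cohort generator so
that every stage is testable with known ground truth.

## Pitch metrics

Every analysis starts from one row per syllable iteration (`bird_id`,
`syllable_id`, `day`, `epoch`, `pitch_hz`). Pitches are kept in Hz and
converted lazily, because the bootstrap must resample Hz and re-derive
baselines per subsample. A syllable's baseline is the arithmetic mean of its
Hz values over the last 3 baseline days (datasets with a longer baseline
use only the final 3 days), and changes are expressed in semitones,

\[ s = 12 \log_2(\mathrm{pitch} / \mathrm{baseline}), \]

so syllables whose base frequencies span 1–6 kHz become comparable. Group
means pool all converted records, which weights each syllable by how often
it was sung — syllables sung more often received more exposures to the
shifted feedback. Whether to pool or to average per-bird means is a genuine
convention choice; pooling is the default and `method = "per_bird"` is
retained as an alternative. Washout dynamics are quantified as
`washout_delta()`: each washout record minus its syllable's mean on the
last shift day with records (a bird occasionally skips a day of singing, so
the reference falls back to the most recent shift day that has data).

A minimal spectral estimator (`extract_pitch()`) accompanies the tabular
pipeline for synthetic waveforms: a single Hann-windowed FFT, the lowest
harmonic taken as the first local maximum above 10% of the global spectral
peak, and a power-weighted mean frequency over ±3 bins around it. It is
exercised only on synthesized harmonic stacks; segmentation of real song is
out of scope.

## The three-level hierarchical bootstrap

Uncertainty is estimated by resampling the hierarchy level by level. For
each of N subsamples (N = 10^4 by default):

1. draw birds with replacement (as many as the dataset has);
2. for each drawn bird, draw syllables with replacement from that bird's
   own syllables (as many as it has);
3. for each drawn syllable, draw a *fixed* number of baseline iterations
   (`m_base`), window iterations (`m_win`), and — for washout — reference-day
   iterations (`m_ref`), all with replacement.

The fixed per-syllable counts implement an explicit assumption: the
bootstrap asks how the group mean would vary across hypothetical new birds,
and in a new bird every syllable is taken as equally likely, so a syllable's
observed frequency must not leak into the subsample. The syllable baseline
is recomputed from the resampled baseline iterations, conversion to
semitones happens only when the subsample mean is taken, and in the washout
variant the reference-day mean is recomputed within the subsample and
subtracted after resampling — so baseline and reference uncertainty
propagate into the estimate. The standard deviation of the N subsample
means estimates the group-mean standard error; the central 67% interval is
reported alongside (comparable to ±1 SEM). The point estimate itself always
comes from the actual data via `weighted_group_mean()`; resampling only
quantifies uncertainty.

Defaults that the data do not pin down: `m_base = m_win = m_ref = 50`
(inside the observed 40–600 iterations/day and cheap at N = 10^4), and
per-bird syllable draws equal to each bird's own syllable count. Both are
configurable. Days within the analysis window (end of shift = shift days
12–14; end of washout = last 2 washout days) are pooled, matching how the
windows are reported. Resamples are drawn sequentially from one seeded RNG
stream; the compiled (Rcpp) engine and the pure-R `hb_resample_once()`
consume the stream draw-for-draw identically, which the tests exploit as an
exact cross-check. The naive pooled `sd/sqrt(n)` is exposed as
`naive_pooled_sem()` purely for comparison — on nested cohorts the
hierarchical SEM is typically an order of magnitude larger.

## Hypothesis tests as posterior probabilities

Instead of p-values, inference reports direct probabilities computed from
bootstrap populations. Against a constant: the proportion of resampled
means greater than or equal to it. Between two groups: the two populations
are treated as independent and the probability is the volume of their joint
distribution on one side of the unity line, including the line itself —
computed exactly as `mean(a_i >= b_j)` over all N^2 pairs by sorting one
population and binary-searching the other, never by subsampling pairs. A
paired index-by-index mode exists for sensitivity analysis; all-pairs is
the default because the two groups are resampled independently, and every
result records which mode produced it. Ties count toward "greater than or
equal", so the probability of a population against itself is above one
half by construction.

All tests are two-way at α = 0.05: a probability is significant below
α/2 = 0.025 or above 1 − α/2 = 0.975, with Bonferroni correction dividing α
across a family of comparisons (the three pairwise lesioned-group tests
share m = 3). A probability of exactly 0 or 1 is stored numerically but
rendered as `p < 1/N` or `p > 1 − 1/N` — 10^4 resamples cannot resolve
smaller tails.

Honest calibration claim: a bootstrap test of this kind is approximate.
Over ≥200 null replicates of the full generate → bootstrap → decide chain
the suite asserts a rejection rate within [0.01, 0.10] at α = 0.05, and
67% CI coverage of the generator's true mean within 67 ± 5 points over 400
replicates — bands that acknowledge the mild anticonservatism of
resampling few birds.

## Mixed-model validation

As an independent check, the same end-of-shift semitone records are fit
with a nested random-intercept linear mixed model
(`st ~ condition + (1 | bird) + (1 | bird : syllable)`, REML via lme4),
with the shift condition coded −1/0/+1 by direction or 0/1 for pooled
shift-vs-no-shift; both codings are reported. The fixed-effect p-value
uses the large-sample normal approximation of the t statistic — with
thousands of iterations per cohort the residual degrees of freedom dwarf
any df correction, and the bird-level effective sample size is what the
bootstrap handles. The response is per-iteration semitones over shift days
12–14 by default (matching the bootstrap window); per-day aggregation is
available. Singular fits — variance components estimated at zero, routine
when a level contributes little — are flagged in the result, never hidden.

## Lesion quantification

Dopaminergic innervation is quantified per histologic section as the
optical-density ratio of Area X to a representative patch of surrounding
striatum (`OD_ratio = OD_AreaX / OD_striatum`); Area X normally stains
darker, so low ratios indicate denervation. The lesion threshold is the
5th percentile of the saline-injected population's section ratios, using
linear interpolation between closest ranks (quantile type 7 — the
convention is recorded in output metadata because it moves the threshold
slightly at small n), and a section counts as lesioned when its ratio is
strictly below the threshold. Reported quantities: the overall fraction of
lesioned-bird sections below threshold, per-bird extents (which average
back to the population fraction exactly, weighted by section counts), a
two-sample Kolmogorov–Smirnov comparison of the populations (asymptotic p,
exact below 50 total sections), and Pearson correlations between per-bird
extent and song metrics (final pitch change, baseline variance, final
variance, percent variance increase). The package consumes per-section OD
tables; image segmentation is out of scope.

## The synthetic cohort generator

No raw recordings are deposited with the study, so the generator emulates
the statistical structure the analysis assumes, with known ground truth.
For each bird: a syllable count uniform on [4, 12], per-syllable base
frequencies log-uniform on [1, 6] kHz, and per-syllable-per-day iteration
counts uniform on [40, 600]. The latent semitone trajectory combines

- a **drift** component `drift_asymptote * (1 − exp(−d_total / 6 d))`
  evolving from the start of the experiment (the lesion-induced pitch drop
  develops over days and is already creeping during baseline);
- an **adaptation** component `adapt_asymptote * (1 − exp(−d_shift / 5 d))`
  from shift onset (opposite in sign to the imposed shift for unlesioned
  groups, zero for lesioned groups);
- bird- and syllable-level response deviations, Normal(0, 0.10 st) and
  Normal(0, 0.15 st), entering *scaled by the adaptation ramp* — they
  describe how strongly an individual responds, so they are absent during
  baseline and survive baseline referencing, which a constant offset would
  not;
- iteration noise Normal(0, 0.50 st), applied in log-frequency:
  `pitch = f0 * 2^((mu + eps)/12)`.

The study reports endpoints, not dynamics, so first-order exponential
approaches with drift τ = 6 d and adaptation τ = 5 d are a modeling choice,
picked once as visually consistent with gradual multi-day change and
exposed as parameters. The variance components were likewise chosen once so
that the naive pooled SEM visibly understates the hierarchical SEM — the
phenomenon the method exists to correct. Iterations are conditionally
independent given the day's latent mean; real song has within-day
autocorrelation the generator does not emulate, so passing calibration
tests here demonstrates correctness of the machinery, not a guarantee
about any real cohort.

During washout the group-level trajectory either **reverts** (the
adaptation decays exponentially, or approaches a calibrated rebound) or
**continues drifting** (the lesioned no-shift default — the pitch drop
deepens after the shift ends); individual response deviations are held at
their end-of-shift values, so the washout change is modeled as a common
group process measured against each syllable's own reference day.

Calibration is exact in expectation: preset asymptotes are solved
numerically so that the *expected measured* plateau — not the bare latent
value — equals the group's reported effect. Two measurement artifacts enter
that expectation: baselines are arithmetic means of Hz, so lognormal
iteration noise inflates them by `sigma_iteration^2 ln 2 / 24` ≈ 0.007 st,
and averaging Hz across baseline days mixing different latent levels adds
a (tiny) Jensen term. `true_plateau()` and `true_washout_delta()` return
these estimands, and the parameter-recovery tests compare pipeline output
against them. Each bird draws from an independently seeded stream derived
from the master seed, so enlarging a cohort never perturbs existing birds.

The six presets encode the study cohorts: 3/3/2 unlesioned birds (+1 / −1 /
no shift) with 6-day washouts, and 4/4/8 lesioned birds (+1 / −1 / no
shift) with 7-day washouts and washout data for 2/2/5 birds. Plateau
targets are −0.40, +0.36, 0, −0.38, −0.46 and −0.19 semitones; the shift
presets carry washout rebounds of +0.17, −0.22, +0.24 and −0.28 semitones
over the last two washout days. The control preset is calibrated to a
measured plateau of exactly 0.

The OD generator draws section ratios from Normal families (saline mean
1.4, sd 0.1 — only the threshold logic matters, the family is a
convenience), and can solve the lesioned mean numerically so that its mass
below the saline population's 5th percentile matches a target fraction
(0.375 for the study-calibrated setting); targets of exactly 0 or 1 are
rejected as infeasible for a continuous family.

## Numerical and design notes

- **Windows.** "End of shift" = shift days 12–14, "end of washout" = last
  2 washout days, both relative to the dataset's own timeline and
  configurable.
- **RNG.** One seed per bootstrap call; the engine consumes R's uniform
  stream via `floor(unif * n)` indexing so compiled and interpreted paths
  match exactly. Sequential draws replace per-resample child streams: a
  sequential engine needs no execution-order independence, and exact
  R-vs-C++ equality is a stronger reproducibility check.
- **Time-of-day structure** (the study samples ~30 song files between
  10 A.M. and noon) is not modeled; records carry only a day index. The
  window choice is reported not to affect results qualitatively.
- **Degenerate inputs.** Silent waveforms, syllables without baselines,
  empty analysis windows, constant condition vectors, non-positive
  frequencies and infeasible OD targets are hard errors naming the
  offending entity; singular LMM fits are flagged, not suppressed.
- **Problem sizes.** The calibration suites run at reduced but realistic
  sizes chosen once: type-I error over 250 null replicates of 8-bird
  cohorts (4–8 syllables, 40–80 iterations/day) at N = 2000 resamples;
  coverage over 400 replicates at the same sizes; recovery checks at the
  full preset cohorts with N = 10^4. The analysis scripts under
  `analysis/` run the full six-cohort experiment at N = 10^4.
- **Serialization.** Pitch and OD tables are plain CSV; truth echoes are
  YAML at 15 significant digits; bootstrap, LMM and lesion summaries are
  JSON. CSV round-trips preserve values to ~15 significant digits, so
  regenerated downstream numbers agree to numerical precision rather than
  bit-for-bit.

## Known limitations

The generator's exponential dynamics, Normal variance components and
conditional independence are stand-ins for unknown real structure; the
bootstrap's calibration bands are asserted under those conditions only.
Lesion extent is consumed from per-section OD values — stain-intensity
normalization across batches and Area X boundary drawing are out of scope.
The spectral estimator assumes a flat, harmonically clean segment and is
not a general pitch tracker.
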