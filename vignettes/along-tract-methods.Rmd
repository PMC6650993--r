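---
title: "Along-tract microstructure analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract microstructure analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alongtract)
```

# The problem

Simple reaction time (RT) — the latency between a visual cue and a
predefined button press — varies substantially between people. Part of that
variability is thought to live outside the decision stage, in stimulus
encoding and motor initiation, and to depend on the microstructure of the
white-matter pathways that carry the motor command, chiefly the
corticospinal tract. Testing that idea requires two reductions:

1. **Behaviour**: decompose each participant's RT distribution into a
   decision component and a *non-decision time* `t_er`, using a
   single-accumulator linear ballistic accumulator (LBA).
2. **Anatomy**: reduce each participant's 3-D tract probability volume to a
   one-dimensional *profile* of microstructural metrics (NDI, ODI, FA, MD)
   at 30 ordered positions along the tract, then test, segment by segment,
   whether the metric covaries with `t_er` across participants, with
   familywise error controlled over all segments and metrics.

This package implements both reductions and the statistics connecting them,
plus synthetic-data generators that give every stage a known ground truth.

# The accumulator model

On each trial, evidence grows linearly from a start point
`k ~ Uniform(0, a)` (with `a = 0.5` fixed as the scaling constant) towards a
threshold `b`, at a drift rate drawn once per trial from
`Normal(mu, sigma)`. The predicted RT is `t_er + (b - k) / v`. Drift rates
are truncated to positive values so every trial terminates; with a 3-second
response window and essentially no omissions in this task, the mass at
negative drifts is negligible and truncation keeps the distribution proper.
`lba_cdf()` provides the closed-form distribution function under this
convention and is the analytic oracle for `simulate_lba()`.

Fitting follows the quantile likelihood-ratio chi-square recipe: the
observed distribution is summarized by its 0.1/0.3/0.5/0.7/0.9 quantiles
(linear-interpolation convention), giving six bins with observed proportions
0.1/0.2/0.2/0.2/0.2/0.1; model bin probabilities come from simulation
(100,000 draws by default; a closed-form route is available via
`method = "cdf"`), floored at `1/(2 n_sim)`; and
`G^2 = 2 sum O_i log(O_i / N pi_i)` is minimized by Nelder-Mead simplex over
log-transformed parameters (positivity by construction), with the best of
100 random initial parameter sets seeding each of 20 repetitions. Within a
repetition the simulation uses common random numbers, so the optimizer sees
a deterministic surface. Internally all times are seconds; interfaces accept
and report milliseconds. Trials outside 150-1500 ms are excluded before
fitting, with the bounds themselves retained.

## What the recovery study shows — an identifiability ridge

The package's recovery experiments expose a structural property of this
estimation procedure that users should know about. Take *exact* model
quantiles as data, displace `t_er` by up to ±80 ms, and re-optimize
`(b, mu, sigma)`: the resulting `G^2` stays below 0.03 — far below the
stochastic noise of quantiles estimated from 50, or even 5000, trials.
Four shape-flexible parameters against five quantile constraints leave a
near-exact ridge along which non-decision time trades against threshold and
drift parameters at negligible cost in fit.

Consequences, measured by the test suite on synthetic cohorts:

- Single-participant `t_er` estimates carry ridge-position noise with a
  standard deviation of roughly 60-80 ms, at 50 *and* at 5000 trials. More
  aggressive optimization does not help; it simply settles elsewhere on the
  ridge.
- With a true between-participant spread of 48 ms, the attainable rank
  correlation between true and fitted `t_er` is bounded near
  `48 / sqrt(48^2 + 65^2) ≈ 0.6`, and is typically 0.4-0.55 in practice.
- Initialization matters precisely because the objective does not: initial
  `t_er` candidates are drawn *uniform* over `[50 ms, min RT]` rather than
  log-uniform, because a log-uniform cloud concentrates at implausibly small
  values and drags the selected ridge point with it (measured bias roughly
  -55 ms vs -35 ms).

This also offers a parsimonious reading of a pattern seen in cohort data
fitted with this procedure: a between-participant SD of fitted `t_er` that
*exceeds* the SD of mean RT while the two are uncorrelated is exactly what
ridge noise produces, since an error in `t_er` is absorbed by an opposite
shift in the fitted decision time. Group-level associations with fitted
`t_er` remain interpretable — the fitted value is a noisy but monotone-ish
carrier of the true one — but per-participant non-decision times should not
be read to better than several tens of milliseconds.

# Tract skeletonization

The group tract volume (thresholded at `5e-5`, the standard tractography
false-positive cutoff) is reduced to a smooth space curve in five steps.

1. **Cleaning** (`clean_volume`): voxels with no second-order neighbour
   (no foreground within Chebyshev distance 2) are removed; the volume is
   dilated with a 2 mm structuring element; internal cavities are filled.
   The "2 mm disk" of the original MATLAB toolbox is implemented as a 3-D
   ball by default (isotropic morphology is the safer reading; a slice-wise
   2-D disk is available via `kernel = "disk"`).
2. **Thinning** (`thin_volume`): iterative removal of *simple* voxels —
   those whose deletion changes neither the number of 26-connected
   foreground components nor the number of 6-connected background
   components in their neighbourhood — in six directional sub-iterations,
   until stable. Deletion is sequential with the criterion re-evaluated on
   the current object, so components, tunnels and cavities are preserved
   exactly (verified against a brute-force cubical-complex Euler
   characteristic counter on small grids). Curve endpoints are retained so
   elongated objects keep their length.
3. **Pruning** (`prune_branches`): the trunk is the longest geodesic path
   between any two endpoints of the skeleton graph (26-adjacency, Euclidean
   edge weights); side branches are discarded.
4. **Smoothing** (`fit_spline`): cubic smoothing splines per coordinate
   against chord length, resampled uniformly in arc length. The smoothing
   level is the heaviest whose mean squared deviation from the voxel
   centres stays within `(0.5 voxel)^2`.
5. **Orientation and clipping** (`orient_skeleton`, `clip_skeleton`): the
   trunk's direction is arbitrary, so analyses anchor the start at a known
   structure; the curve is then clipped to its central portion. Clipping is
   not cosmetic: the curve skeleton of a capped tube necessarily sprouts
   end spurs reaching toward the cap apex (up to about one tube radius past
   the true centreline end), and the central portion is also where tract
   morphology is most consistent across individuals. Clip bounds are
   user-supplied arc-length fractions, since anatomical clip planes require
   atlases outside this package's scope.

On tube phantoms of radius at least 3 voxels, the clipped skeleton lies
within one voxel diagonal of the generating curve (line, arc and helix are
exercised in the tests).

# Segments and profiles

The clipped skeleton of length `S` is divided into `n = 30` segments of
equal length `l` with 20% overlap between neighbours:
`l = S / (1 + (n-1)(1-o))`, segment `i` spanning
`[i(1-o)l, i(1-o)l + l]`. Each foreground voxel projects to its nearest
curve sample (world mm; voxel centres, so anisotropic voxels are handled)
and receives every segment whose interval contains that arc position — one
or two ids under the default overlap. Voxels projecting beyond the clipped
ends belong to the terminal segments.

Two geometric facts about the overlap are worth stating precisely, because
they are easy to conflate. The *share of a segment's voxels that it has in
common with its successor* is `o = 20%` — the direct empirical translation
of "20% overlap between adjacent segments". The *fraction of voxels
carrying two labels*, however, is `(n-1) o l / S ≈ 0.24` in the tract
interior (and a little less overall once end caps dilute it): overlap zones
tile 29 out of 24.2 segment-lengths of arc. The tests check each quantity
against its own value. A practical measurement note: on a tube aligned with
a grid axis, projected arc positions collapse onto voxel-plane positions
and per-pair fractions alias badly (0 to 0.5 per pair); validation phantoms
therefore use generic orientations.

Segment labels live in template space; metrics are never resampled.
Labels are pulled into each participant's native grid by nearest-neighbour
lookup through the participant's affine (label identity must survive
resampling), and a native voxel enters the metric computation only if it is
(1) inside the participant's white-matter mask, (2) has FA strictly above
0.2, and (3) has connection probability at or above `5e-5` — the threshold
value itself survives, mirroring the asymmetry of the two rules' wording.
Per segment and metric the summary is the connection-probability-weighted
mean `sum P(v) m(v) / sum P(v)`, so voxels with uncertain tract membership
contribute less. Segments emptied by the inclusion rules are flagged missing
and excluded pairwise downstream, never imputed or zero-filled.

# Segment-wise statistics

Each segment x metric cell is regressed on the behavioural variable with age
as a nuisance covariate (ordinary least squares; the standardized
coefficient is reported). The segment-wise t map is enhanced with
one-dimensional threshold-free cluster enhancement,

    tfce(s) = sum_{h = dh, 2dh, ...}^{t(s)} e(h, s)^E h^H dh,

with `E = 0.5`, `H = 2` (the standard defaults of the permutation toolbox
this mirrors) and `dh = max |t| / 100` shared across all maps of a call.
Adjacency is segment order; segment overlap does not extend adjacency. Both
signs are enhanced separately.

Familywise error across all segments, four metrics and both signs is
controlled by a Freedman-Lane max-statistic permutation scheme: the outcome
is residualized on the nuisance model, residuals are permuted and the full
model refit; each permutation contributes the maximum enhanced statistic
over the whole family, and
`p_fwe = (1 + #{max_perm >= tfce_obs}) / (n_perm + 1)`, so the smallest
attainable p is `1/(n_perm+1)`. Taking the maximum jointly over metrics and
signs is the more conservative reading of "corrected across metrics". The
default is 10,000 permutations; the calibration suite uses 500-1000 per
replicate, which is ample for error rates near 0.05. Under fully null
synthetic cohorts the realized familywise error is at or below its nominal
level (the add-one estimator and discrete max distribution make it slightly
conservative), and a planted standardized effect of -0.5 in segments 18-30
at n = 46 is detected in over 80% of its segments in the median replicate.

Supporting analyses include frequentist-plus-Bayesian Pearson correlation
reports (two-sided t-test p; Fisher-z 95% CI with the conventional 1.959964
multiplier; the default two-sided Bayes factor under a stretched-beta prior
of width 1, computed by numerical integration of the exact sampling density
of r and cross-checked in the tests against the closed-form hypergeometric
expression) and a fully within-subject two-factor repeated-measures ANOVA
(segments x hemispheres) with Greenhouse-Geisser epsilon per effect from
the covariance of orthonormalized level differences, validated against
`car::Anova` to eight decimals. A two-level factor is automatically
spherical; degenerate (constant) data are flagged rather than tested.

# The synthetic cohort — what it emulates and what it does not

The generators fix the study conditions: 46 participants aged 19-24; true
non-decision times `Normal(250, 48)` ms; 50 simple-RT trials per
participant; thresholds, mean drifts and drift SDs drawn from
`[0.9, 1.3]`, `[5, 8]` and `[1, 2]`, chosen once so that simulated mean RT
lands near 363 ms with realistic trial-level variability; tract phantoms on
a 64^3 grid at 2 mm (the DWI resolution emulated) as tubes of radius 7 mm
around line, arc or helix curves with Gaussian radial probability decay;
smooth along-tract baseline profiles for NDI/ODI/FA/MD with a smooth
participant-level deviation field (SD 0.02 in metric units) plus voxel
noise (SD 0.01); per-participant rigid affine jitter within ±3 degrees and
±2 mm; and a planted *negative* association between the behavioural
z-score and NDI only, restricted to segments 18-30, with amplitude
`beta / sqrt(1 - beta^2) * participant_noise_sd` so the population
correlation in an affected segment equals the standardized beta (-0.5 by
default). Other metrics carry no effect, so specificity is testable; a
no-effect "comparison tract" is just the same generator with
`null_effect = TRUE`.

What the phantoms deliberately do not emulate: crossing fibres, partial
volume at tract borders, nonlinear warps (affine only), spatially
correlated scanner noise, and any q-space signal formation — the generators
start where tensor/NODDI fitting ends. Passing tests therefore demonstrate
the pipeline's internal correctness and statistical calibration, not
robustness to those acquisition-level effects.

# Numerical choices and degenerate inputs

- Quantiles: type-7 linear interpolation throughout.
- `G^2` bins: edges at the *observed* quantiles; model probabilities floored
  at `1/(2 n_sim)`; degenerate samples (non-increasing quantiles) are
  errors.
- Simplex: log-parameterization, `abstol = 1e-4` on `G^2`, at most 2000
  evaluations per repetition; fits with `t_er >= min RT` are rejected by
  penalty.
- Thinning: foreground 26-connectivity, background 6-connectivity;
  raster-order sequential deletion within six directional sub-iterations.
- Cleaning keeps the largest component when stray crumbs (under 1% of the
  largest component or 27 voxels) survive; comparably sized split
  components are an error naming the sizes.
- TFCE `dh` is fixed from the observed maps and reused for all
  permutations, so enhanced statistics are comparable.
- Permutation p-values use the add-one convention; constant cells are
  flagged `NA` and excluded from the family maximum.
- All randomness flows from one master seed through named substreams
  (`lba`, `permutation`, `synthesis`), so stages are independently
  reproducible and reruns are bit-identical.

# Problem sizes used by the test and acceptance suites

The suites are sized for a single CPU: LBA oracle equivalence uses 10^6
draws on a 27-point parameter grid; the cohort recovery study uses 100
participants at 50 trials (10^4 simulations and 5 repetitions per fit) and
20 fits at 5000 trials; FWE calibration uses 500 null cohorts at 1000
permutations; the end-to-end imaging cohort runs all 46 participants on the
default 64^3 phantom with 500 permutations. These are the package's chosen
study sizes; the pipeline defaults remain at the full-scale constants
(10^5 simulations, 20 repetitions, 10^4 permutations).

# Known limitations

- Non-decision time is identified only up to the quantile-objective ridge
  described above; treat per-participant values as ordinal, not metric.
- Only affine template-native transforms are supported.
- The thinning scheme asserts geometric accuracy (one-voxel Hausdorff on
  tubes) and exact topology preservation, but no uniqueness: a different
  sub-iteration order can produce a slightly different, equally valid
  skeleton.
- Segment counts above ~60 on short tracts make overlap zones thinner than
  a voxel; labels remain well-defined but per-segment support becomes
  noisy.
- With overlap above 50% a point can fall inside three or more segment
  intervals; the native-space label carrier keeps the first two ids, so use
  overlaps below 0.5 (the default is 0.2).
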