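---
title: "Models and methods behind mitosleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitosleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosleep)
```

mitosleep packages the quantitative core of a fly sleep–metabolism
study design: sleep architecture from DAM monitors, ratiometric
mitochondrial redox scores, lipid-droplet morphometry, a mitophagy
colocalization index, OCR quality control, and a normality-gated
statistical policy. This vignette explains each model, the defaults and
why they are what they are, the numerical conventions, and what the
synthetic-data validation does and does not establish.

## Sleep architecture

A fly's record is a vector of nonnegative beam-break counts in 1-min
bins on a Zeitgeber grid (ZT0 = lights-on of a 12:12 LD cycle). Sleep
is the standard behavioral definition: a maximal run of zero-count
minutes of length ≥ `min_bout` (default 5). `detect_bouts()` reports
each such run once; shorter quiescent runs contribute no sleep at all,
so shifting every count from 0 to any positive value destroys all
sleep — a property the tests assert.

Day boundaries fall at ZT0. A bout that spans midnight-ZT contributes
its minutes to each day it covers (keeping daily totals additive), but
is *counted* — and its full duration averaged — in the day it starts,
so that `n_bouts × mean_bout_min` recovers total unclipped bout
minutes. Waking activity is total counts divided by awake minutes, the
usual activity index; it is undefined (NA) on a fully sleeping day.
Multi-day summaries drop day 1 by default because the first day in the
monitor confounds acclimation with phenotype.

Death is scored as terminal silence: zero counts from some minute
through the end of the recording, spanning at least `death_window`
(default 1440 min). This is deliberately conservative — a fly that
sleeps its entire final day is indistinguishable from one that died at
its last movement — and the exclusion log records the last-activity
minute so borderline cases can be audited.

Sleep loss is presented per fly as `x_i − mean(control)`. The SEM of
that difference is propagated in quadrature,
`sqrt(SEM_e² + SEM_c²)`, which is exact for independent groups because
`Var(x_i − m̄_c) = Var(x_i)/n_e`-terms and `Var(m̄_c)` add. The raw
groups are retained on the result object: hypothesis tests must use
raw values, since subtracting a common constant only shifts both
groups.

## Ratiometric redox scoring

Two aligned stacks are divided pixel by pixel and the per-brain score
is the arithmetic mean of surviving per-pixel ratios. Two gates run in
a fixed order:

1. **Ratio gate.** Pixels with ratio outside `[ratio_low, ratio_high]`
   are excluded. Zero-denominator pixels have infinite ratio and are
   excluded here by definition. For the glutathione-coupled sensor the
   gate is 0.25–4; the two fluorescent-timer presets
   (`mitotimer_repo`: 1/2.5–2.5, `mitotimer_nsyb`: 0.25–4) encode
   per-instrument constants tuned to different signal/background
   regimes.
2. **Background gate.** Among ratio-gate survivors, pixels dimmer than
   `bg_factor` × that channel's *survivor* mean (in either channel) are
   excluded. Computing the reference mean over survivors rather than
   all pixels makes the cut robust to bright debris that the ratio gate
   already removed; this scope was a genuinely open choice and is
   recorded in the result object via the config.

Mean-of-ratios (not ratio-of-means) is the per-brain statistic because
the gating operates per pixel; the CaLexA index, by contrast, is
defined as a ratio of *total* signal, which under the default sum
projection equals the ratio of whole-stack sums (a maximum projection
is available as an option). Scores are invariant to rescaling both
channels by a common factor — intensity units cancel — and this
invariance is tested exactly.

Percent oxidation interpolates a control-normalized score between the
reductant (DTT, 0%) and oxidant (DA, 100%) calibration means:
`100·(x − DTT)/(DA − DTT)`. Values outside 0–100% are returned
unclamped with a warning flag, since clamping would hide calibration
drift. Within-experiment normalization divides by the control-group
mean, making the control mean exactly 1 before experiments are pooled;
pooling without this step would mix acquisition gains across days.

## Auto-thresholding and droplet morphometry

Histograms use 256 bins over the observed (mask-excluded) range, with
one refinement: integer-valued images whose range fits within 256
levels are binned at unit width. Equal-width binning of, say, a 0–190
integer image interleaves structurally empty bins, and an empty bin
sitting inside the background peak can win the triangle method's
point-to-chord distance outright; unit-width binning reproduces 8-bit
behavior and removes the artifact.

**Triangle.** A chord joins the histogram peak to the farthest nonzero
bin on the longer-tail side; the threshold is the bin maximizing
perpendicular distance from the curve to the chord, ties resolving to
the lowest bin. Foreground is strictly above the threshold bin. The
method assumes a dominant background mode with a minority foreground
tail — exactly the geometry of a sparse lipid stain.

**Rényi entropy.** For a split at bin *t* the background and
foreground class distributions have Rényi entropy
`H_α = (1−α)⁻¹ log Σ pᵢ^α` (Shannon at α→1). The per-order maximizers
at α = 0.5, 1, 2 (lowest bin on ties) are sorted as t1 ≤ t2 ≤ t3 and
combined with the classic three-order weighting: weights (1, 2, 1)
when |t1 − t3| ≤ 5 bins, else (0, 1, 3), via
`t* = t1(P(t1) + ¼ωβ₁) + ¼ t2 ωβ₂ + t3(1 − P(t3) + ¼ωβ₃)` with
`ω = P(t3) − P(t1)`, truncated to a bin index. All arithmetic uses
1-based bin indices; both thresholds are invariant to scaling the
histogram counts, and both are verified bin-exactly against exhaustive
search in the tests.

Particle analysis labels connected components in 2D (8-connectivity by
default, matching common particle-analysis behavior; 4 available) via
a compiled breadth-first search. In per-slice mode counts are summed
across slices with no 3D linking, so a droplet spanning several slices
is counted once per slice — this mirrors slice-wise particle counting
and is flagged in the documentation because it inflates counts
relative to a true 3D census. `mean_size × count = total area` holds
exactly by construction. `min_area_px` defaults to 0 (no size filter).

The end-to-end recovery studies (tests and acceptance script) run the
segmentation with `min_area_px = 5`. The scene generator draws sharp
disks with spatially independent Poisson noise and no optical blur, so
single suprathreshold noise pixels occur at a rate proportional to
image area; they are not droplets under the generator's own geometry
(the smallest modeled droplet, r = 3 px, covers ≈ 28 px), and a 5-px
floor removes them without touching any true droplet. On real,
PSF-blurred micrographs the appropriate floor depends on resolution
and should be set from the optics.

## Mitophagy colocalization

With binarized mitochondrial (M) and autophagosome (A) stacks, each
slice contributes `|M_z ∧ A_z| / |M_z|`, and the index sums these over
a fixed window of `n_slices` (default 30) starting at the slice of
maximal mitochondrial area (ties to the lowest index) — appropriate
when signal concentrates at the tissue surface and stacks start at
variable depths. A `first_slice` mode covers full-stack designs. Slices
with zero mitochondrial area contribute 0 rather than NaN, keeping the
index bounded in [0, n_slices] and windows comparable across brains.
Stacks shorter than the window are clipped with a warning so the
shortfall is visible in logs. When raw stacks are supplied, both
channels are binarized per slice with the Rényi-entropy threshold; the
index is monotone in added autophagosome signal and
slice-permutation-invariant, both asserted in tests.

## OCR quality control

Traces are normalized to the mean of the last `reference_cycles`
(default 3) baseline cycles — "the end of the baseline period"
operationalized as a short window rather than a single noisy cycle.
Instability is a relative consecutive step: a well is excluded iff
`|x_{t+1} − x_t| / x_t > 0.30` for any t, computed on raw values (the
rule commutes with normalization, which the tests verify). The bound
is strict — exactly 30% is kept — and the comparison carries a 1e-9
relative guard so the boundary is decided by the measured value, not
by binary representation of 0.3. The rule is sign-agnostic because
tissue shifting away from or toward the sensor produces steps of
either sign. Injection failure is a manual flag carried in the input:
it is detected by inspecting the cartridge, not inferable from the
trace.

## Group statistics

The gate takes the parametric branch only when every group passes
Shapiro–Wilk *and* a median-centered Levene test shows no variance
difference, both at `alpha_gate = 0.05`. Levene on absolute deviations
from the median is the robust default among homogeneity tests; the
choice is recorded in `gate_details` since the original policy named
no test. Zero-variance groups cannot be assessed by Shapiro–Wilk and
route nonparametric with a warning.

Two-group designs then use an equal-variance t-test (homogeneity was
just established) or a two-sided Mann–Whitney test; multi-group
designs use ANOVA followed by pooled-variance comparisons against the
reference group adjusted by step-down Holm–Šidák
(`p'_(i) = 1 − (1 − p_(i))^(m−i+1)`, monotone-enforced), or
Kruskal–Wallis followed by Dunn's rank z-tests against the reference
with the standard tie correction, Bonferroni-adjusted over those
comparisons (an uncorrected option exists for designs analyzed as
independent experiments — e.g. a sleep-deprivation arm alongside a
circadian panel is a separate two-group comparison, not another level
of the panel's correction).

The dual-control rule for GAL4/UAS designs reports
`max(p_vs_ctrlA, p_vs_ctrlB)` and declares significance only when both
are strictly below α: an effect that beats one genetic background but
not the other is not reported. The rule is commutative and idempotent.

`gated_type1_error()` validates the *composed* procedure: 5,000
simulated null experiments per distribution (n = 20/group) give
empirical rejection rates near 0.05 under both a Gaussian null (branch
almost always parametric) and a lognormal null (branch almost always
nonparametric), showing the data-dependent branch selection does not
inflate size at these settings. This is a calibration at specific
(n, distribution) points, not a uniform guarantee.

ΔΔCt expression is `2^(−(ΔCt − mean ΔCt_control))` with
`ΔCt = Ct_target − Ct_reference`. The control condition's *geometric*
mean expression is 1 by construction; its arithmetic mean is 1 exactly
when control ΔCt values coincide, and exceeds 1 otherwise (Jensen's
inequality) — the identity tests therefore use equal-ΔCt control
fixtures. The statistic is invariant to shifting a sample's target and
reference Ct together, as efficiency-matched primers require.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of (parameters, seed) and emits
ground truth alongside the data; all end-to-end tests consume only
those artifacts.

- **DAM traces** alternate wake and sleep bouts with geometric
  (memoryless, integer-minute) lengths — day/night sleep-bout means 20
  and 60 min, wake-bout mean 15 min, Poisson waking activity with mean
  2 counts/min clipped to ≥ 1 so wake minutes are never misread as
  sleep. Mechanical deprivation is modeled at the 1-min bin: sub-minute
  shaking makes every shaken minute active, so windowed minutes are
  forced to ≥ 1 count. Ground-truth bout lists are computed from the
  emitted counts, making generator/detector closure exact by
  construction. Not emulated: circadian modulation beyond the
  day/night mean split, siesta structure, rebound dynamics.
- **Redox scenes** place signal pixels at a known ratio ρ* over dim
  background constructed to fall below the background gate. At SNR 10
  the mean-of-ratios estimator recovers ρ* within ~1% (the ratio of
  noisy channels is slightly biased upward, O(σ²/μ²)); noise-free
  scenes are exact. Not emulated: spatial structure, bleed-through,
  photobleaching.
- **Droplet scenes** draw non-overlapping sharp disks over Poisson
  (photon-limited) or Gaussian noise, with centers at continuous
  coordinates so disk pixel areas scatter around πr². Not emulated:
  PSF blur, droplet clustering, intensity heterogeneity — hence the
  size-floor discussion above.
- **Colocalization scenes** choose integer pixel budgets so each
  slice's overlap fraction is *exact*, giving an index identity rather
  than an approximation.
- **OCR traces** combine baseline, multiplicative drift/noise and a
  smooth post-injection decline; artifact wells receive one step
  anchored to the previous realized value so the emitted consecutive
  change equals the requested step size exactly, keeping truth labels
  consistent with the exclusion rule at any noise level.

Passing these studies demonstrates correctness of the *computations*
under known generative models — run-length accounting, gating
arithmetic, threshold optimality, component labelling, test-size
calibration. It does not validate biological sensitivity on real
images or behavior, where optics, staining variability and
non-stationary activity dominate.

## Problem sizes and runtime

The shipped studies use the sizes the package is tested at: 1,000
random 2-day traces and 100 simulated flies for sleep closure, 500
random histograms for threshold-oracle agreement, 20 scenes × 50 disks
for morphometry, 200 random mask stacks for colocalization, and
2 × 5,000 simulations for test-size calibration. The full test suite
runs in roughly a minute on one core; `scripts/acceptance.R` in about
one minute.

## Known limitations

- Per-slice droplet counts double-count droplets spanning slices (no
  3D linking); an experimental 3D census is deliberately out of scope.
- The death criterion cannot distinguish death from a terminal
  day-long sleep bout.
- The mitophagy index weights every slice equally; depth-dependent
  signal attenuation is not modeled.
- Dunn and Holm–Šidák adjustments are implemented against their
  published formulas and closed-form checks, not against an external
  reference implementation, since none is available in this
  dependency set.
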