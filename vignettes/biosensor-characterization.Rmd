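---
title: "Characterizing small-molecule biosensors: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing small-molecule biosensors: models, generator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosensr)
```

This vignette is the package's account of its science: the models it
fits, the experiment its generator emulates, the numerical choices that
matter, and what the passing test suite does and does not demonstrate
about real data.

## The measurement model

An inducible system couples an allosteric transcription factor to a
cognate promoter/operator driving a fluorescent reporter. A plate
reader records fluorescence (arbitrary units, AFU) and OD600 for every
well on a common grid (the standard protocol: every 10 minutes for
15 hours, inducer added at time zero). Three derived quantities carry
the characterization:

* **Growth-normalized fluorescence** `F(t)/OD(t)` (AFU/OD), a per-biomass
  expression proxy. Reporter-free control wells measure cellular
  autofluorescence; subtracting their mean AFU/OD at matched timepoints
  isolates reporter signal (`normalize_fluorescence()`). Five control
  wells is the standard layout.
* **Expression velocity**: per-interval raw first differences of AFU/OD
  divided by the interval in seconds; the maximum over post-induction
  intervals is the well's promoter activity
  (`expression_rates()`, units AFU OD^-1 s^-1). Velocities are reported
  per second because the reference parameter set is printed in s^-1.
  No smoothing is applied before the maximum; a rolling-median option
  exists for pathological data but is off everywhere by default.
* **Endpoint response**: AFU/OD at the read nearest 900 min (within half
  a sampling interval — the grid is dense enough that interpolation
  would add nothing), summarized per dose by the replicate mean and a
  95% Student-t interval (`transfer_function()`).

Fluorophore maturation (minutes) and degradation (half-life over a day)
are both negligible on these time scales and are ignored throughout.

## The promoter-activity model

`fit_hill()` fits maximum velocities against inducer concentration with

$$v(I) = V_{min} + V_{max}\,\frac{I^h}{I^h + K_L^h}$$

by plain nonlinear least squares (Levenberg–Marquardt through
`minpack.lm::nlsLM`), all replicate points entering individually so the
covariance reflects replicate scatter. Choices that matter:

* **Initialization and multistart.** Hill fits are multimodal in
  `(h, K_L)`. The default start (`v_max` = range of velocities,
  `v_min` = minimum, `h = 1`, `k_half` = geometric mean of nonzero
  doses) is jittered over `k_half` ×/÷ 10 and `h ∈ {0.7, 1, 2, 4}`; the
  lowest-deviance converged fit wins.
* **Unbounded parameters.** Negative `v_min` estimates are reported,
  not clipped — basal velocities near zero legitimately fit slightly
  negative under noise, and the reference table prints "0 ± 60"-style
  rows. A fit that converges with `h < 0` is a mirrored representation
  of a decreasing curve and is re-expressed canonically
  (`h → -h`, `v_min → v_min + v_max`, `v_max → -v_max`) by refitting
  from the transformed start.
* **Zero doses** enter with the Hill term exactly 0, anchoring
  `v_min`.
* **Uncertainties** are square roots of the least-squares covariance
  diagonal. The tests cross-check them against an independently built
  finite-difference Jacobian covariance.
* **Exclusions.** Doses known to distort growth (the convention in the
  bundled library: 10 mM acrylate) can be excluded by value; exclusions
  are recorded in the fit object and the datasheet.
* **Identifiability guard:** at least four distinct concentrations
  after exclusion, and a degenerate-fit error when all velocities are
  equal.

The half-maximal parameter is fitted as a lumped value;
`compose_half_max()` documents its decomposition `K·K_d·K_p·T`
(promoter binding equilibrium, inducer–TF dissociation, inducer
partition coefficient, TF abundance) and `check_half_max()` flags a
stored value inconsistent with a proposed decomposition, but the
factors are not individually estimable from these data and the package
does not try.

## Fold induction and its error

`fold_induction()` implements the background-subtracted ratio
`F = (Ī − C̄)/(Ū − C̄)` with the propagated standard error

$$\sigma_{\bar F} = \bar F\sqrt{\frac{\sigma_{\bar I}^2 + \sigma_{\bar C}^2}{\bar I_B^2} + \frac{\sigma_{\bar U}^2 + \sigma_{\bar C}^2}{\bar U_B^2}}$$

with all σ values SEMs of the replicate groups. When the uninduced
signal sits within background — formalized as
`Ū_B − 2·sqrt(σ_Ū² + σ_C̄²) ≤ 0`, i.e. the doubled-SE approximation of
the 95% interval touches zero — the ratio is undefined and a flagged
lower bound `(Ī_B − 2σ_IB)/(Ū_B + 2σ_UB)` is returned instead.

Two caveats the tests make explicit. First, the propagated formula
treats the control SEM as an independent contribution to both the
numerator and denominator terms, ignoring the covariance induced by
subtracting the *same* control mean in both; the neglected relative
variance is `2σ_C̄²/(Ī_B Ū_B)`, negligible in the realistic regime
(stable autofluorescence, uninduced signal clear of background) that
the Monte-Carlo agreement tests sample. Second, the formula is a
first-order (delta-method) result; when `σ_UB/Ū_B` approaches ~20% the
true sd of the ratio runs a few percent above it.

`t_interval()` and `bootstrap_sem_ci()` provide the two interval
flavors used for banding: Student-t for endpoint replicates, percentile
bootstrap of the mean for time courses.

## What the generator emulates

`simulate_plate()` is a forward model of the plate experiment, with
per-well parameters assembled by `generator_config()` /
`library_config()`:

* **Growth**: lagged logistic OD, default lag 30 min, rate
  0.023 min^-1 (a 30-min doubling, typical of rich-medium growth in a
  shaking plate reader), carrying capacity 1.0 OD, inoculation at
  0.02 OD (a 1:100-style dilution). Dose-dependent growth effects scale
  the exponential rate only (not the carrying capacity), because
  toxicity is characterized on exponential-phase rates; a saturating
  inhibition curve plus an optional catabolic growth benefit covers
  both toxic inducers (acrylate, naringenin) and metabolizable ones
  (arabinose).
* **Expression**: per-OD reporter signal integrates
  `v(I)·phase(t)·60 dt`, with `v(I)` the Hill model above and
  `phase(t)` gating accumulation: every library sensor stops
  accumulating per-OD fluorescence by stationary onset (defined crisply
  as OD ≥ 95% of carrying capacity), except AcuR, which continues
  accumulating after entry into stationary phase. With shutoff off and
  zero noise the per-OD signal is exactly `v(I)·t` in seconds — the
  closed form the tests assert.
* **Noise**: multiplicative lognormal on each fluorescence read
  (default CV 5% — read noise grows with signal), additive Gaussian on
  each OD read (default sd 0.005 — it does not), and a lognormal
  well-to-well factor on `v_max` (default CV 5%, replicate scatter).
  Autofluorescence background enters as AFU per OD (default 5e4,
  placing control signal in realistic proportion to basal reporter
  signal).
* **Seeds**: a single master seed; each well draws from a substream
  derived from (seed, well index), so adding wells leaves existing
  trajectories unchanged.

Dose series are anchored at the concentrations printed for the
characterization experiments and extended to six levels in the stated
fold steps (2-fold for acrylate and anhydrotetracycline, 3-fold
otherwise); each series brackets its sensor's half-maximal parameter in
both copy-number variants. The cross-reactivity panel concentration for
anhydrotetracycline, which the printed panel list omits, is set to
215 nM (a high sub-toxic dose ~2.7× the high-copy TetR `K_L`).

`simulate_events()` emulates pre-gated cytometry: per channel, "on" and
"off" lognormal single-cell populations (default medians separated
100-fold, geometric CV 0.6) and a non-responder fraction (default
1.5%, cells off in all channels regardless of induction — dead cells or
plasmid dropouts). `simulate_toxicity_series()` and
`simulate_variants()` emulate the dose–growth table and a four-variant
enzyme screen whose latent activities span a ~20-fold fluorescence
range through a saturating sensor transfer.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: mechanistic transcription/translation or
inducer-transport kinetics, plasmid copy-number fluctuation, spectral
spillover between channels, instrument scatter gating, additive
fluorescence noise floors, and any coupling of toxicity to expression
capacity (a dosed well grows slower but expresses per-OD at full
rate, so the real phenomenon of toxic doses depressing apparent
velocity is represented only through the exclusion API, not
reproduced).

## Noise amplification through differencing — a known limitation

The velocity estimator is the maximum of raw first differences. Under
multiplicative read noise the error of a difference scales with the
*accumulated* signal, not the increment: after `n` intervals of
expression the per-interval rate noise is roughly `√2·cv·n` times the
true rate, and after shutoff the plateau contributes pure noise of that
magnitude. Taking a maximum over ~90 intervals then inflates the
velocity estimate several-fold at 5% read CV. Because the inflation
factor is identically distributed across doses (every well's signal is
proportional to its own `v(I)`), the *shape* parameters `h` and `K_L`
recover without systematic bias — the recovery tests demonstrate
exactly this — while `V_max` and `V_min` from noisy single plates are
systematically inflated and should be read qualitatively unless the
read noise is known to be well below 1%. A single fitted `h` still
carries ~25% scatter at 5% read CV, which is why the recovery
benchmarks report medians over many independent simulated experiments:
20 seeds leaves the median with Monte-Carlo error near 0.1·h, and the
acceptance script uses 200 so that its reported medians are limited by
the pipeline, not by seed luck.

## Other analyses

* **Toxicity** (`growth_rate()`, `toxicity_profile()`): exponential-phase
  rate is the slope of ln(OD) over the maximal-slope contiguous window
  of ≥ 4 points with R² ≥ 0.99 (widest on ties) — the threshold pair is
  this package's own, chosen to reject lag and saturation curvature
  crisply. Both normalizations in use (rate ratio and 15-h endpoint OD
  ratio) are implemented; `mode = "rate"` is the default since it
  isolates exponential-phase physiology.
* **Cross-reactivity** (`cross_react()`): a cell activates when its mean
  background-subtracted endpoint response exceeds `k = 3` combined
  standard errors above the sensor's uninduced mean. The rule (and `k`)
  is this package's formalization of "visually flat off-target
  response"; the tests verify it agrees with a direct Welch two-group
  statistic. `orthogonality_report()` passes a sensor iff its sole
  activation is its cognate chemical.
* **Cytometry** (`classify_states()`): deterministic threshold gating at
  midpoints of transformed medians of off/on calibration samples, on an
  asinh scale with cofactor 150 (configurable; the transform is
  order-preserving so gating commutes with it). Mixture modeling is
  deliberately out of scope — the populations of interest are
  well-separated, and the deterministic gate is reproducible.
  `state_count(n, levels)` is `levels^n`: 8 binary states for three
  orthogonal sensors, 16/32 for four/five, 27 and 81 at three induction
  levels. Bimodality in `histogram_summary()` is scored by an exact 1-D
  two-cluster split with a separation threshold of 3.5 pooled sds
  (a unimodal distribution split at its center scores ~2.6).
* **Screening** (`rank_variants()`): variants rank by mean fluorescence
  (ties broken by id for determinism); concordance with titer uses
  Spearman rank correlation, since the sensor transfer links titer to
  fluorescence monotonically but not linearly.

## Decisions on genuinely open points

* Maximum velocities are computed per replicate well, and the fit uses
  all replicate points — rather than fitting replicate-averaged series —
  so parameter uncertainties absorb replicate scatter.
* "Within background" for the fold-induction lower bound is triggered
  by the doubled-SE interval touching zero; the verbal rule gives no
  number, and this is its direct formalization.
* The parameter-error wording in the source material ("square of the
  variance") is internally inconsistent; the only dimensionally
  coherent reading — SE as the square root of the covariance diagonal —
  is used.
* The induced group for fold induction is the replicate set at the
  maximum-response concentration (not the fitted curve top).
* Display normalization divides a graph's series by 1.1× the current
  global maximum (pinning the display maximum at 1/1.1) and rescales
  growth curves by their mid-point value with a zero offset at time
  zero; it is a plotting convention and feeds no analysis.
* Pre-induction reads (negative times) are representable and ignored by
  the maximum-rate search; no analysis requires them.
* The orchestration layer is plain R: `run_pipeline()` takes a YAML or
  list configuration and writes JSON + text datasheets; given the CSV
  readers/writers on every module boundary, a shell wrapper would add
  nothing for the package's intended users (R analysts), so none is
  shipped.

## Problem sizes in the tests

The suite simulates compact but complete experiments: full plates are
~20–30 wells × 91 timepoints; recovery properties use 20–50 independent
simulated experiments per assertion; cytometry panels use 2 000–10 000
events per sample across 8 induction states; Monte-Carlo checks of the
error-propagation formula use 10^5–10^6 draws. The acceptance script
simulates 200 experiments per sensor (~4 minutes on one CPU). These
sizes were chosen so each statistical assertion has comfortable margin
over its own Monte-Carlo error.
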