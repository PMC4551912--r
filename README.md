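# biosensr

Characterization of genetically encoded small-molecule biosensors —
allosteric transcription factors (AraC, TetR, CdaR, MphR, AcuR, TtgR and
friends) driving fluorescent reporters — from plate-reader time courses
and flow-cytometry event data.

Biosensor "datasheets" answer four questions: how strongly does the
output respond to the input (transfer function, fold induction), how
fast (expression kinetics), how uniformly across single cells
(cytometry), and how specifically (cross-reactivity/orthogonality,
inducer toxicity). This package implements the full analysis chain for
those questions, plus a synthetic-data generator that emulates the
underlying experiments so that every stage can be validated end to end
against known ground truth.

## The model at the core

Promoter activity is the time derivative of growth-normalized
fluorescence. For each well, fluorescence is divided by OD600 at the
same read (AFU/OD), background from reporter-free control wells is
subtracted, per-interval rates are formed from raw first differences
(per second), and the maximum post-induction rate is the well's
expression velocity. Velocities are fitted against inducer
concentration `I` with a Hill function extended for basal and maximal
activity:

```
(dGFPn/dt)max = Vmax * I^h / (I^h + K_L^h) + Vmin
```

where `Vmax`/`Vmin` are the maximal/basal expression velocities
(AFU OD^-1 s^-1), `h` is the Hill coefficient (cooperativity), and
`K_L` is the lumped half-maximal parameter — the product
`K * Kd * Kp * T` of promoter binding, inducer-regulator dissociation,
membrane partition, and regulator abundance, fitted as one value (see
`compose_half_max()`).

Fold induction is the background-subtracted induced over uninduced
endpoint signal, `F = (I - C)/(U - C)`, with standard error propagated
from the replicate SEMs:

```
sigma_F = F * sqrt( (sI^2 + sC^2)/IB^2 + (sU^2 + sC^2)/UB^2 )
```

When the uninduced signal sits within the autofluorescence background,
`F` is undefined and a flagged lower bound (lower 95% bound of `IB`
over upper 95% bound of `UB`) is reported instead.

## Worked example

Simulate a high-copy AraC (arabinose) induction experiment from the
bundled parameter library and build its datasheet:

```r
library(biosensr)
out <- run_pipeline(list(seed = 1, sensors = "AraC",
                         output_dir = "demo"))
cat(readLines("demo/datasheet.txt"), sep = "\n")
```

```
=== AraC (high copy) ===
fold induction: 144.3 +/- 8.9 (at 1485 uM)
hill coefficient: 1.26 +/- 0.33
half-maximal parameter: 67.07 +/- 15 uM
max expression velocity: 1.941e+04 +/- 1.9e+03 /s
basal expression velocity: 201 +/- 1e+03 /s
time to signal: 10 min; time to plateau: 280 min
seed: 1
```

Read-out: this single simulated plate (3 replicate wells at six
3-fold-spaced arabinose doses, 10-min reads for 15 h, 5% read noise)
recovers a Hill coefficient of 1.26 ± 0.33 and a half-maximal parameter
of 67 ± 15 μM against generating values of 1.3 and 59 μM; fluorescence
rises above background within 10 min and plateaus by ~4.7 h. The
maximum-velocity estimate from raw first differences is biased upward
under multiplicative read noise (a known property of the estimator —
see the methods vignette), which is why the velocity row exceeds its
generating value while the curve-shape parameters `h` and `K_L` do not.

Averaging the recovery over many independent simulated experiments
pins the shape parameters down:

```r
rec <- recover_hill("AraC", n_seeds = 20, seed = 1)
median(rec$h)
#> [1] 1.273833
```

Lower-level entry points: `simulate_plate()` / `library_config()`
(generator), `plate_velocities()` (kinetics), `transfer_function()` and
`plate_fold_induction()` (dose response), `fit_hill()` (model),
`toxicity_profile()`, `cross_react()` + `orthogonality_report()`,
`simulate_events()` + `classify_states()` + `state_count()`
(cytometry), `rank_variants()` (enzyme screening). All tables are tidy
tibbles; CSV interchange via `read_plate()`/`write_plate()`,
`read_events()`/`write_events()`, `read_variants()`.

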