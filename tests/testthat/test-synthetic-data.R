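# Forward-model correctness: closed forms, limits, determinism.

test_that("zero-noise per-OD fluorescence follows the closed form v(I)*t", {
  expr <- expression_params(v_max = 100, v_min = 5, hill_h = 2,
                            k_half = 10, inducer = "chemX",
                            stationary_shutoff = FALSE)
  cfg <- quiet_config(expr, replicates = 1, n_control_wells = 2)
  exp <- simulate_plate(cfg)
  ctrl <- control_wells(exp)
  for (w in Filter(function(w) !w$condition$is_control, exp$wells)) {
    I <- canonical_concentration(w$condition$concentration,
                                 w$condition$unit)
    v <- hill_velocity(I, 100, 5, 2, 10)
    ns <- normalize_fluorescence(w, controls = ctrl)
    expect_equal(ns$afu_per_od, v * w$times * 60, tolerance = 1e-9)
  }
})

test_that("uninduced zero-basal wells are control-identical (zero noise)", {
  expr <- expression_params(v_max = 100, v_min = 0, hill_h = 2,
                            k_half = 10, inducer = "chemX")
  cfg <- quiet_config(expr, replicates = 1, n_control_wells = 1)
  exp <- simulate_plate(cfg)
  lay <- plate_layout(exp)
  un <- exp$wells[[lay$well[lay$concentration == 0 & !lay$is_control]]]
  ctrl <- control_wells(exp)[[1]]
  expect_equal(un$fluorescence$GFP, ctrl$fluorescence$GFP)
  expect_equal(un$od, ctrl$od)
})

test_that("saturating induction reaches (v_max + v_min) per-interval slope", {
  expr <- expression_params(v_max = 100, v_min = 5, hill_h = 2,
                            k_half = 1e-3, inducer = "chemX")
  cfg <- quiet_config(expr, series = tibble::tibble(
    sensor = "S1", inducer = "chemX", concentration = 1e6, unit = "uM"),
    replicates = 1, n_control_wells = 1)
  exp <- simulate_plate(cfg)
  lay <- plate_layout(exp)
  w <- exp$wells[[lay$well[lay$concentration == 1e6 & !lay$is_control]]]
  ns <- normalize_fluorescence(w, controls = control_wells(exp))
  # during exponential phase (before 95% of carrying capacity)
  expo <- w$od < 0.95 * 1.0
  slopes <- diff(ns$afu_per_od)[expo[-length(expo)]]
  expect_equal(slopes, rep((100 + 5) * 60 * 10, length(slopes)),
               tolerance = 1e-9)
})

test_that("stationary shutoff freezes per-OD accumulation; the
           post-stationary flag overrides it", {
  mk <- function(shutoff, post) {
    expr <- expression_params(v_max = 100, v_min = 0, hill_h = 1,
                              k_half = 1, inducer = "chemX",
                              stationary_shutoff = shutoff,
                              post_stationary_accumulation = post)
    cfg <- quiet_config(expr, series = tibble::tibble(
      sensor = "S1", inducer = "chemX", concentration = 1000,
      unit = "uM"), replicates = 1, n_control_wells = 1,
      include_uninduced = FALSE)
    exp <- simulate_plate(cfg)
    w <- exp$wells[[1]]
    normalize_fluorescence(w, controls = control_wells(exp))
  }
  frozen <- mk(TRUE, FALSE)
  running <- mk(TRUE, TRUE)
  n <- nrow(frozen)
  expect_equal(frozen$afu_per_od[n], frozen$afu_per_od[n - 5])
  expect_gt(running$afu_per_od[n], running$afu_per_od[n - 5])
})

test_that("simulation is reproducible and seed-sensitive", {
  cfg <- library_config(sensors = "TtgR", seed = 11, replicates = 2,
                        n_control_wells = 1)
  expect_equal(plate_data(simulate_plate(cfg)),
               plate_data(simulate_plate(cfg)))
  cfg2 <- library_config(sensors = "TtgR", seed = 12, replicates = 2,
                         n_control_wells = 1)
  expect_false(identical(plate_data(simulate_plate(cfg)),
                         plate_data(simulate_plate(cfg2))))
})

test_that("toxicity scales the exponential growth rate of affected wells", {
  tox <- toxicity_params(ic50 = 10, ic50_unit = "uM", steepness = 1,
                         max_inhibition = 1)
  expr <- expression_params(v_max = 0, v_min = 0, hill_h = 1, k_half = 1,
                            inducer = "chemX")
  cfg <- generator_config(
    sensors = list(S1 = expr), toxicity = list(chemX = tox),
    series = tibble::tibble(sensor = "S1", inducer = "chemX",
                            concentration = 10, unit = "uM"),
    noise = noise_params(0, 0, 0), replicates = 1, n_control_wells = 0,
    seed = 1)
  exp <- simulate_plate(cfg)
  lay <- plate_layout(exp)
  dosed <- exp$wells[[lay$well[lay$concentration == 10]]]
  ctrl0 <- exp$wells[[lay$well[lay$concentration == 0]]]
  r_d <- growth_rate(dosed)$rate
  r_0 <- growth_rate(ctrl0)$rate
  expect_equal(r_d / r_0, 0.5, tolerance = 0.01)
})

test_that("simulate_events honors state, medians and non-responders", {
  cp <- default_channel_params()
  cp$off_gcv <- cp$on_gcv <- 0
  s <- simulate_events(c("glucarate"), cp, n_events = 1,
                       nonresponder_frac = 0, seed = 1)
  expect_equal(unname(s$events[1, ]), c(15000, 150, 150))
  s0 <- simulate_events(character(), cp, n_events = 5,
                        nonresponder_frac = 0, seed = 1)
  expect_true(all(s0$events == 150))
  expect_equal(s0$sample_label, "none")
  # reproducibility
  a <- simulate_events(c("acrylate"), n_events = 100, seed = 9)
  b <- simulate_events(c("acrylate"), n_events = 100, seed = 9)
  expect_equal(a$events, b$events)
  expect_error(simulate_events("unknown_chem"), "no channel parameters")
  expect_error(simulate_events(nonresponder_frac = 0.2), "nonresponder")
})

test_that("toxicity series: control is 1, ic50 halves growth, means are
           monotone without a benefit", {
  tp <- toxicity_params(ic50 = 50, ic50_unit = "uM", steepness = 2,
                        max_inhibition = 1)
  out <- simulate_toxicity_series(tp, c(0, 50), unit = "uM",
                                  replicates = 1, noise_cv = 0, seed = 1)
  expect_equal(out$normalized_rate[out$concentration == 0], 1.0)
  expect_equal(out$normalized_rate[out$concentration == 50], 0.5)
  # monotonicity property over random parameter draws
  set.seed(42)
  for (i in 1:20) {
    tp <- toxicity_params(ic50 = runif(1, 1, 100),
                          steepness = runif(1, 0.5, 4),
                          max_inhibition = runif(1))
    out <- simulate_toxicity_series(tp, sort(runif(8, 0, 200)),
                                    replicates = 1, noise_cv = 0,
                                    seed = i)
    expect_true(all(diff(out$normalized_rate) <= 1e-12))
  }
})

test_that("variant screens are monotone in latent activity", {
  v <- simulate_variants(n_variants = 6, noise_cv = 0, seed = 1)
  summ <- v |> dplyr::group_by(variant_id) |>
    dplyr::summarise(f = mean(fluorescence), t = mean(titer))
  summ <- summ[order(summ$t), ]
  expect_true(all(diff(summ$f) > 0))
  expect_equal(cor(summ$f, summ$t, method = "spearman"), 1)
})

test_that("the pipeline recovers generating h and K_L at standard noise", {
  # 50 experiments keep the Monte-Carlo error of the median well below
  # the 15% recovery band (a single fit has ~25% scatter under 5% read
  # noise; see the vignette on noise amplification through differencing)
  rec <- recover_hill("AraC", n_seeds = 50, seed = 1)
  expect_lt(abs(median(rec$h) - 1.3) / 1.3, 0.15)
  expect_lt(abs(median(rec$k_half_uM) - 59) / 59, 0.15)
})
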