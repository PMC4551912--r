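# Synthetic-data generator: forward model of the plate-reader experiment.
#
# Each well grows along a lagged logistic curve whose exponential rate is
# scaled by a dose-dependent toxicity factor; per-OD reporter fluorescence
# accumulates at the Hill-regulated expression velocity while the culture
# is below stationary phase (and stops there for shutoff sensors);
# reported fluorescence is (per-OD signal + autofluorescence background)
# times OD with multiplicative read noise. Fluorophore maturation delay
# and degradation are both taken as negligible (maturation under two
# minutes, half-life over a day).

#' Growth-curve parameters
#'
#' Lagged logistic growth: OD stays at `initial_od` for `lag_min` minutes,
#' then follows a logistic approach to `carrying_capacity` with
#' exponential rate `rate`. The defaults emulate log-phase E. coli
#' diluted into fresh medium in a shaking plate reader: a short 30-min
#' lag, a 30-min doubling time (rate 0.023 min^-1), a low inoculation
#' density, and a plate-reader saturation OD near 1.
#'
#' @param lag_min Lag before growth resumes (minutes).
#' @param rate Exponential growth rate (per minute).
#' @param carrying_capacity Saturating OD600.
#' @param initial_od OD600 at inoculation; must be below carrying capacity.
#' @return List of class `bs_growth_params`.
#' @export
growth_params <- function(lag_min = 30, rate = 0.023,
                          carrying_capacity = 1.0, initial_od = 0.02) {
  stopifnot(lag_min > 0, rate > 0, carrying_capacity > 0, initial_od > 0,
            initial_od < carrying_capacity)
  structure(list(lag_min = lag_min, rate = rate,
                 carrying_capacity = carrying_capacity,
                 initial_od = initial_od),
            class = "bs_growth_params")
}

#' Expression (promoter-activity) parameters for one sensor
#'
#' The per-OD reporter production velocity at inducer concentration `I` is
#' `v_min + v_max * I^h / (I^h + k_half^h)` (AFU OD^-1 s^-1). Repressor
#' reporters typically stop accumulating at stationary onset
#' (`stationary_shutoff`); set `post_stationary_accumulation` for sensors
#' that keep accumulating after entry into stationary phase.
#'
#' @param v_max Maximum expression velocity (AFU OD^-1 s^-1).
#' @param v_min Basal expression velocity (AFU OD^-1 s^-1).
#' @param hill_h Hill coefficient (> 0).
#' @param k_half Half-maximal inducer concentration, in `k_half_unit`.
#' @param k_half_unit Concentration unit of `k_half`.
#' @param inducer Cognate inducer name; any other chemical applied to this
#'   sensor's wells leaves the Hill input at zero (the sensors are
#'   orthogonal by construction).
#' @param stationary_shutoff Stop accumulation at stationary onset?
#' @param post_stationary_accumulation Continue accumulating after
#'   stationary onset (overrides the shutoff)?
#' @return List of class `bs_expression_params`.
#' @export
expression_params <- function(v_max, v_min = 0, hill_h = 1, k_half,
                              k_half_unit = "uM", inducer,
                              stationary_shutoff = TRUE,
                              post_stationary_accumulation = FALSE) {
  stopifnot(v_max >= 0, v_min >= 0, hill_h > 0, k_half > 0)
  structure(list(v_max = v_max, v_min = v_min, hill_h = hill_h,
                 k_half_uM = canonical_concentration(k_half, k_half_unit),
                 inducer = inducer,
                 stationary_shutoff = isTRUE(stationary_shutoff),
                 post_stationary_accumulation =
                   isTRUE(post_stationary_accumulation)),
            class = "bs_expression_params")
}

#' Measurement-noise parameters
#'
#' Plate-reader fluorescence error grows with signal, so it is modeled as
#' multiplicative lognormal with coefficient of variation `fluor_cv`; OD
#' error does not, so it is additive Gaussian with sd `od_sd`.
#' `well_cv` adds lognormal well-to-well variation on `v_max` (replicate
#' scatter beyond read noise). `background_slope` is the cellular
#' autofluorescence per unit OD, the signal emitted by reporter-free
#' control strains.
#'
#' @param fluor_cv Fractional CV of each fluorescence read.
#' @param od_sd Additive sd of each OD read.
#' @param well_cv Fractional well-to-well CV on `v_max`.
#' @param background_slope Autofluorescence (AFU per OD).
#' @return List of class `bs_noise_params`.
#' @export
noise_params <- function(fluor_cv = 0.05, od_sd = 0.005, well_cv = 0.05,
                         background_slope = 5e4) {
  stopifnot(fluor_cv >= 0, od_sd >= 0, well_cv >= 0, background_slope >= 0)
  structure(list(fluor_cv = fluor_cv, od_sd = od_sd, well_cv = well_cv,
                 background_slope = background_slope),
            class = "bs_noise_params")
}

#' Dose-dependent growth-effect parameters for one chemical
#'
#' The exponential growth rate is multiplied by
#' `(1 - max_inhibition * c^s / (c^s + ic50^s)) *
#'  (1 + growth_benefit * c / (c + ic50))`,
#' a saturating inhibition curve plus an optional growth benefit for
#' chemicals the cells can catabolize (e.g. arabinose).
#'
#' @param ic50 Half-inhibitory concentration, in `ic50_unit`.
#' @param ic50_unit Concentration unit.
#' @param steepness Hill steepness `s` of the inhibition curve.
#' @param max_inhibition Maximal fractional rate reduction, in `[0, 1]`.
#' @param growth_benefit Fractional rate increase at saturating dose.
#' @return List of class `bs_toxicity_params`.
#' @export
toxicity_params <- function(ic50, ic50_unit = "uM", steepness = 2,
                            max_inhibition = 1, growth_benefit = 0) {
  stopifnot(ic50 > 0, steepness > 0, max_inhibition >= 0,
            max_inhibition <= 1, growth_benefit >= 0)
  structure(list(ic50 = ic50, ic50_unit = ic50_unit, steepness = steepness,
                 max_inhibition = max_inhibition,
                 growth_benefit = growth_benefit),
            class = "bs_toxicity_params")
}

# growth-rate multiplier for `concentration` of a chemical; percent and
# molar doses are compared on their own scales
.toxicity_factor <- function(tox, concentration, unit) {
  if (is.null(tox)) return(1)
  pct_c <- unit == "percent"
  pct_i <- tox$ic50_unit == "percent"
  if (pct_c != pct_i) {
    stop("toxicity ic50 unit (", tox$ic50_unit,
         ") not comparable with dose unit (", unit, ")")
  }
  c_ <- canonical_concentration(concentration, unit)
  ic <- canonical_concentration(tox$ic50, tox$ic50_unit)
  inh <- if (c_ == 0) 0 else
    tox$max_inhibition * c_^tox$steepness /
      (c_^tox$steepness + ic^tox$steepness)
  ben <- if (c_ == 0) 0 else tox$growth_benefit * c_ / (c_ + ic)
  (1 - inh) * (1 + ben)
}

#' Full parameterization of a simulated plate experiment
#'
#' @param sensors Named list of [expression_params()], one per sensor.
#' @param growth [growth_params()].
#' @param noise [noise_params()].
#' @param toxicity Named list of [toxicity_params()], keyed by chemical.
#' @param series Tibble with columns `sensor, inducer, concentration,
#'   unit`: the induced wells to simulate (each is replicated
#'   `replicates` times). Rows whose inducer is not the sensor's cognate
#'   chemical produce basal-only responses (cross-reactivity panels).
#' @param replicates Wells per condition (default 3).
#' @param n_control_wells Reporter-free background wells (default 5).
#' @param include_uninduced Add a zero-dose condition per sensor if the
#'   series lacks one (default TRUE).
#' @param sampling_interval_min Read interval (default 10 min).
#' @param duration_min Total observation time (default 900 min = 15 h).
#' @param channel Reporter channel name (default "GFP").
#' @param copy_number Copy-number tag carried into well conditions.
#' @param seed Master seed; per-well substreams are derived from it by
#'   well index, so adding wells does not perturb existing ones.
#' @return List of class `bs_generator_config`.
#' @export
generator_config <- function(sensors, growth = growth_params(),
                             noise = noise_params(), toxicity = list(),
                             series, replicates = 3, n_control_wells = 5,
                             include_uninduced = TRUE,
                             sampling_interval_min = 10,
                             duration_min = 900, channel = "GFP",
                             copy_number = "high", seed = 1L) {
  stopifnot(is.list(sensors), length(sensors) >= 1, !is.null(names(sensors)),
            sampling_interval_min > 0, duration_min > sampling_interval_min,
            replicates >= 1, n_control_wells >= 0, !is.null(seed))
  stopifnot(all(c("sensor", "inducer", "concentration", "unit") %in%
                  names(series)))
  unknown <- setdiff(unique(series$sensor), names(sensors))
  if (length(unknown) > 0) {
    stop("series names sensor(s) with no expression parameters: ",
         paste(unknown, collapse = ", "))
  }
  cognates <- vapply(sensors, function(s) s$inducer, character(1))
  known_chem <- c("none", cognates, names(toxicity))
  bad_chem <- setdiff(unique(series$inducer), known_chem)
  if (length(bad_chem) > 0) {
    stop("series names chemical(s) unknown to the configuration ",
         "(neither a cognate inducer nor in the toxicity list): ",
         paste(bad_chem, collapse = ", "))
  }
  structure(list(sensors = sensors, growth = growth, noise = noise,
                 toxicity = toxicity, series = tibble::as_tibble(series),
                 replicates = as.integer(replicates),
                 n_control_wells = as.integer(n_control_wells),
                 include_uninduced = isTRUE(include_uninduced),
                 sampling_interval_min = sampling_interval_min,
                 duration_min = duration_min, channel = channel,
                 copy_number = copy_number, seed = as.integer(seed)),
            class = "bs_generator_config")
}

#' Build a generator configuration from the bundled sensor library
#'
#' Convenience wrapper: expression parameters from [sensor_library()],
#' dose series from [inducer_series()], growth effects from
#' [toxicity_library()].
#'
#' @param sensors Sensor names (default: all six).
#' @param copy_number `"high"` or `"low"`.
#' @param include_toxicity Attach the library growth-effect parameters?
#' @param ... Passed on to [generator_config()] (e.g. `noise`, `seed`,
#'   `replicates`).
#' @return A `bs_generator_config`.
#' @export
library_config <- function(sensors = unique(sensor_library()$sensor),
                           copy_number = "high", include_toxicity = TRUE,
                           ...) {
  lib <- sensor_library()
  lib <- lib[lib$sensor %in% sensors & lib$copy_number == copy_number, ]
  if (nrow(lib) == 0) stop("no library rows match the requested sensors")
  expr <- lapply(seq_len(nrow(lib)), function(i) {
    r <- lib[i, ]
    # every sensor's reporter stops accumulating by stationary onset
    # (activators reach maximal fluorescence even earlier); AcuR is the
    # documented exception, accumulating well into stationary phase
    expression_params(
      v_max = r$v_max, v_min = r$v_min, hill_h = r$hill_h,
      k_half = r$k_half, k_half_unit = r$k_half_unit, inducer = r$inducer,
      stationary_shutoff = TRUE,
      post_stationary_accumulation = r$sensor == "AcuR")
  })
  names(expr) <- lib$sensor
  ser <- dplyr::bind_rows(lapply(lib$sensor, function(s) {
    dplyr::bind_cols(tibble::tibble(sensor = s),
                     inducer_series(expr[[s]]$inducer))
  }))
  dots <- list(...)
  if (is.null(dots$copy_number)) dots$copy_number <- copy_number
  tox <- list()
  if (include_toxicity) {
    tl <- toxicity_library()
    tox <- lapply(seq_len(nrow(tl)), function(i) {
      r <- tl[i, ]
      toxicity_params(r$ic50, r$ic50_unit, r$steepness, r$max_inhibition,
                      r$growth_benefit)
    })
    names(tox) <- tl$chemical
  }
  do.call(generator_config,
          c(list(sensors = expr, series = ser, toxicity = tox), dots))
}

# deterministic per-well substream seed below 2^31
.derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 69069 + as.numeric(index) * 104729) %%
               2147483647)
}

# logistic OD trajectory with lag
.od_trajectory <- function(times, growth, rate_factor = 1) {
  r <- growth$rate * rate_factor
  N0 <- growth$initial_od
  K <- growth$carrying_capacity
  ifelse(times <= growth$lag_min, N0,
         K * N0 / (N0 + (K - N0) * exp(-r * (times - growth$lag_min))))
}

# one simulated well (deterministic given its substream seed)
.simulate_well <- function(wid, cond, expr, config, seed) {
  set.seed(seed)
  times <- seq(0, config$duration_min, by = config$sampling_interval_min)
  noise <- config$noise
  growth <- config$growth
  tox <- config$toxicity[[cond$inducer]]
  fac <- .toxicity_factor(tox, cond$concentration, cond$unit)
  od_true <- .od_trajectory(times, growth, fac)
  g <- numeric(length(times))
  if (!is.null(expr)) {
    cognate <- identical(cond$inducer, expr$inducer)
    I <- if (cognate) canonical_concentration(cond$concentration, cond$unit) else 0
    v_mult <- if (noise$well_cv > 0) {
      sdl <- sqrt(log(1 + noise$well_cv^2))
      stats::rlnorm(1, -sdl^2 / 2, sdl)
    } else 1
    hill <- if (I == 0) 0 else
      I^expr$hill_h / (I^expr$hill_h + expr$k_half_uM^expr$hill_h)
    v <- expr$v_min + expr$v_max * v_mult * hill
    expressing <- if (!expr$stationary_shutoff ||
                        expr$post_stationary_accumulation) {
      rep(TRUE, length(times))
    } else {
      od_true < 0.95 * growth$carrying_capacity
    }
    inc <- v * 60 * diff(times) * expressing[-length(times)]
    g <- c(0, cumsum(inc))
  }
  f_true <- (g + noise$background_slope) * od_true
  eps <- if (noise$fluor_cv > 0) {
    sdl <- sqrt(log(1 + noise$fluor_cv^2))
    stats::rlnorm(length(times), -sdl^2 / 2, sdl)
  } else 1
  od_meas <- od_true +
    if (noise$od_sd > 0) stats::rnorm(length(times), 0, noise$od_sd) else 0
  fl <- list(f_true * eps)
  names(fl) <- config$channel
  well_time_series(cond, times, pmax(od_meas, 1e-6), fl, well = wid)
}

#' Simulate a plate-reader experiment
#'
#' Runs the forward model for every well implied by the configuration:
#' `replicates` wells per series row, an uninduced condition per sensor
#' (unless disabled), and `n_control_wells` reporter-free background
#' wells. Deterministic given `(config, config$seed)`.
#'
#' @param config A [generator_config()] (or [library_config()]).
#' @return A [plate_experiment()]; generating parameters are retained in
#'   `metadata`.
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "bs_generator_config"))
  ser <- config$series
  if (config$include_uninduced) {
    for (s in unique(ser$sensor)) {
      sub <- ser[ser$sensor == s, ]
      if (!any(sub$concentration == 0)) {
        ser <- dplyr::bind_rows(
          ser, tibble::tibble(sensor = s, inducer = sub$inducer[1],
                              concentration = 0, unit = sub$unit[1]))
      }
    }
  }
  ser <- dplyr::arrange(ser, .data$sensor, .data$inducer,
                        .data$concentration)
  wells <- list()
  idx <- 0L
  for (i in seq_len(nrow(ser))) {
    row <- ser[i, ]
    cn <- if (!is.null(config$copy_number)) config$copy_number else "high"
    for (rep_i in seq_len(config$replicates)) {
      idx <- idx + 1L
      cond <- condition(row$sensor, row$inducer, row$concentration,
                        row$unit, rep_i, is_control = FALSE,
                        copy_number = cn)
      wid <- sprintf("W%03d", idx)
      wells[[wid]] <- .simulate_well(wid, cond, config$sensors[[row$sensor]],
                                     config, .derive_seed(config$seed, idx))
    }
  }
  for (c_i in seq_len(config$n_control_wells)) {
    idx <- idx + 1L
    cond <- condition(NA_character_, "none", 0, "uM", c_i,
                      is_control = TRUE)
    wid <- sprintf("W%03d", idx)
    wells[[wid]] <- .simulate_well(wid, cond, NULL, config,
                                   .derive_seed(config$seed, idx))
  }
  plate_experiment(wells, channels = config$channel, induction_time = 0,
                   metadata = list(seed = config$seed,
                                   generator = "biosensr forward model"))
}

#' Simulate a normalized growth-rate dose series
#'
#' Direct simulation of a toxicity evaluation: per concentration and
#' replicate, the exponential-phase growth rate relative to the
#' no-chemical control, i.e. the dose-dependent rate multiplier plus
#' multiplicative replicate noise.
#'
#' @param params [toxicity_params()] for the chemical.
#' @param concentrations Dose vector (include 0 for the control row).
#' @param unit Concentration unit.
#' @param replicates Replicates per dose (default 3).
#' @param noise_cv Multiplicative replicate CV (default 0.02).
#' @param seed RNG seed.
#' @param chemical Chemical name carried into the output.
#' @return Tibble `chemical, concentration, unit, replicate,
#'   normalized_rate`.
#' @export
simulate_toxicity_series <- function(params, concentrations, unit = "uM",
                                     replicates = 3, noise_cv = 0.02,
                                     seed = 1L, chemical = "chemical") {
  stopifnot(inherits(params, "bs_toxicity_params"))
  set.seed(seed)
  out <- tidyr::expand_grid(concentration = as.numeric(concentrations),
                            replicate = seq_len(replicates))
  fac <- vapply(out$concentration, function(c_)
    .toxicity_factor(params, c_, unit), numeric(1))
  eps <- if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(nrow(out), -sdl^2 / 2, sdl)
  } else 1
  tibble::tibble(chemical = chemical, concentration = out$concentration,
                 unit = unit, replicate = out$replicate,
                 normalized_rate = fac * eps)
}

#' Simulate an enzyme-variant screen read through a biosensor
#'
#' Each variant receives a latent catalytic activity (its titer proxy),
#' log-spaced across `activity_range`; the observed fluorescence is the
#' saturating sensor transfer function applied to that activity, and the
#' observed titer is the activity itself, both with multiplicative
#' replicate noise. The defaults emulate a four-variant screen whose
#' endpoint fluorescence spans roughly 20-fold.
#'
#' @param n_variants Number of variants (default 4).
#' @param activity_range Range of latent activities (titer units; default
#'   `c(20, 5000)`).
#' @param transfer List with `f_max, f_min, hill_h, k_half`: endpoint
#'   fluorescence transfer (AFU/OD vs titer units).
#' @param replicates Replicates per variant (default 3).
#' @param noise_cv Multiplicative replicate CV (default 0.05).
#' @param seed RNG seed.
#' @return Tibble `variant_id, replicate, fluorescence, titer`.
#' @export
simulate_variants <- function(n_variants = 4,
                              activity_range = c(20, 5000),
                              transfer = list(f_max = 5e4, f_min = 250,
                                              hill_h = 1, k_half = 490),
                              replicates = 3, noise_cv = 0.05, seed = 1L) {
  stopifnot(n_variants >= 2, length(activity_range) == 2,
            all(activity_range > 0))
  set.seed(seed)
  act <- exp(seq(log(activity_range[1]), log(activity_range[2]),
                 length.out = n_variants))
  ids <- sprintf("variant_%02d", seq_len(n_variants))
  out <- tidyr::expand_grid(variant_id = ids,
                            replicate = seq_len(replicates))
  a <- act[match(out$variant_id, ids)]
  f <- transfer$f_min + transfer$f_max * a^transfer$hill_h /
    (a^transfer$hill_h + transfer$k_half^transfer$hill_h)
  n <- nrow(out)
  eps <- function() {
    if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, -sdl^2 / 2, sdl)
    } else rep(1, n)
  }
  tibble::tibble(variant_id = out$variant_id, replicate = out$replicate,
                 fluorescence = f * eps(), titer = a * eps())
}
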