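# Small programmatic fixtures shared across test files.

# a bare well with explicit values (single GFP channel)
make_well <- function(times, od, gfp, sensor = "S1", inducer = "chemX",
                      concentration = 0, unit = "uM", replicate = 1L,
                      is_control = FALSE, well = "W1") {
  well_time_series(
    condition(if (is_control) NA_character_ else sensor,
              inducer, concentration, unit, replicate, is_control),
    times, od, list(GFP = gfp), well = well)
}

# a toy plate: n_wells wells with constant OD 0.2 and flat fluorescence
# `levels[i]` * OD (endpoint AFU/OD = levels[i])
make_flat_plate <- function(levels, times = c(0, 450, 900),
                            sensor = "S1", concentration = 1,
                            controls = 0, control_level = 0) {
  wells <- list()
  for (i in seq_along(levels)) {
    wells[[i]] <- make_well(times, rep(0.2, length(times)),
                            rep(levels[i] * 0.2, length(times)),
                            sensor = sensor,
                            concentration = concentration,
                            replicate = i, well = sprintf("A%d", i))
  }
  for (j in seq_len(controls)) {
    wells[[length(wells) + 1]] <-
      make_well(times, rep(0.2, length(times)),
                rep(control_level * 0.2, length(times)),
                is_control = TRUE, replicate = j,
                well = sprintf("C%d", j))
  }
  plate_experiment(wells)
}

# zero-noise single-sensor configuration around given expression params
quiet_config <- function(expr, seed = 1L, series = NULL,
                         noise = noise_params(0, 0, 0,
                                              background_slope = 5e4),
                         ...) {
  if (is.null(series)) {
    series <- tibble::tibble(sensor = "S1", inducer = expr$inducer,
                             concentration = c(1, 3, 10, 30, 100, 300),
                             unit = "uM")
  }
  generator_config(sensors = list(S1 = expr), series = series,
                   noise = noise, seed = seed, ...)
}

# groups engineered to have an exact mean and SEM (n = 3)
group_with <- function(mean, sem) {
  d <- sem * sqrt(3)
  c(mean - d, mean, mean + d)
}
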