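# Orchestration: one call from configuration to per-sensor datasheets.

#' Run the characterization pipeline and build per-sensor datasheets
#'
#' Drives the full analysis from a configuration (a YAML file path or an
#' equivalent named list): obtain a plate experiment (simulated from the
#' bundled sensor library, or read from tidy CSVs), then per sensor
#' compute the endpoint transfer function, fold induction (with the
#' lower-bound rule), the Hill fit of maximum expression velocities, a
#' kinetics summary (time to first above-background signal and time to
#' plateau at the top dose), a toxicity profile of the cognate chemical,
#' and — optionally — a cross-reactivity row. Every stochastic step
#' derives from the single configured seed, so a rerun with the same
#' configuration is byte-identical.
#'
#' Configuration fields: `seed` (required for simulation); either
#' `scenario: library` with optional `sensors`, `copy_number`,
#' `replicates`, or `input: {plate: path, layout: path}`; optional
#' `endpoint_min` (default 900), `exclude` (list of
#' `{sensor, concentration, unit}` dose exclusions for the Hill fit),
#' `crossreact: true/false` (default false), `output_dir` (when given,
#' `datasheet.json` and `datasheet.txt` are written there).
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @return Invisibly, a list of class `bs_datasheets`: per-sensor
#'   datasheet lists plus `validation` notes; written to `output_dir`
#'   when configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0) {
    stop("usage: run_pipeline(config) with a non-empty configuration ",
         "list or YAML path (fields: seed, scenario/input, ...)")
  }
  endpoint_min <- config$endpoint_min %||% 900
  # --- obtain the experiment -------------------------------------------
  if (!is.null(config$input)) {
    if (is.null(config$input$plate) || is.null(config$input$layout)) {
      stop("config$input needs both 'plate' and 'layout' CSV paths")
    }
    exp <- read_plate(config$input$plate, config$input$layout)
    seed <- config$seed %||% 1L
  } else {
    if (is.null(config$seed)) stop("simulation requires config$seed")
    seed <- config$seed
    sensors <- config$sensors %||% unique(sensor_library()$sensor)
    exp <- simulate_plate(library_config(
      sensors = sensors, copy_number = config$copy_number %||% "high",
      replicates = config$replicates %||% 3, seed = seed))
  }
  # --- aggregated validation before computing --------------------------
  problems <- character()
  lay <- plate_layout(exp)
  if (sum(lay$is_control) < 2) {
    problems <- c(problems, "fewer than 2 background control wells")
  }
  for (s in unique(stats::na.omit(lay$sensor[!lay$is_control]))) {
    if (!any(lay$sensor == s & lay$concentration == 0 & !lay$is_control,
             na.rm = TRUE)) {
      problems <- c(problems, paste0("sensor ", s, ": no uninduced wells"))
    }
  }
  if (length(problems) > 0) {
    stop("validation failed:\n  - ", paste(problems, collapse = "\n  - "))
  }
  # --- shared computations ---------------------------------------------
  vel <- plate_velocities(exp)
  tf <- transfer_function(exp, endpoint_min = endpoint_min)
  fi <- plate_fold_induction(exp, endpoint_min = endpoint_min)
  tox <- tryCatch(toxicity_profile(exp, mode = "rate"),
                  error = function(e) NULL)
  xr <- NULL
  if (isTRUE(config$crossreact)) {
    xr_exp <- simulate_crossreact_plate(library_config(
      sensors = unique(stats::na.omit(lay$sensor[!lay$is_control])),
      copy_number = config$copy_number %||% "high",
      replicates = config$replicates %||% 3, seed = seed + 1))
    xr <- cross_react(xr_exp, endpoint_min = endpoint_min)
  }
  excl <- config$exclude %||% list()
  sheets <- lapply(unique(stats::na.omit(lay$sensor[!lay$is_control])),
                   function(s) {
    sv <- vel[vel$sensor == s, ]
    ex_uM <- unlist(lapply(excl, function(e) {
      if (identical(e$sensor, s))
        canonical_concentration(e$concentration, e$unit)
    }))
    fit <- fit_hill(sv, exclude = ex_uM, sensor = s)
    kin <- .kinetics_summary(exp, s)
    list(sensor = s,
         copy_number = sv$copy_number[1],
         seed = seed,
         transfer_function = tf[tf$sensor == s, ],
         fold_induction = as.list(fi[fi$sensor == s, ]),
         hill_fit = list(
           v_max = unname(fit$coef[["v_max"]]),
           v_max_se = unname(fit$se[["v_max"]]),
           v_min = unname(fit$coef[["v_min"]]),
           v_min_se = unname(fit$se[["v_min"]]),
           hill_h = unname(fit$coef[["h"]]),
           hill_h_se = unname(fit$se[["h"]]),
           k_half_uM = unname(fit$coef[["k_half"]]),
           k_half_uM_se = unname(fit$se[["k_half"]]),
           rss = fit$rss, n_points = fit$n_points,
           excluded_uM = fit$excluded),
         kinetics = kin,
         toxicity = if (!is.null(tox)) {
           chem <- sv$inducer[sv$concentration > 0][1]
           tox[tox$chemical == chem, ]
         },
         cross_reactivity = if (!is.null(xr)) xr[xr$sensor == s, ])
  })
  names(sheets) <- vapply(sheets, function(x) x$sensor, character(1))
  out <- structure(list(datasheets = sheets, seed = seed,
                        endpoint_min = endpoint_min),
                   class = "bs_datasheets")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_datasheets(out, config$output_dir)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# time to first above-background signal and time to plateau for the
# top-dose wells of one sensor
.kinetics_summary <- function(exp, sensor) {
  ctrl <- control_wells(exp)
  swells <- Filter(function(w)
    identical(w$condition$sensor, sensor) &&
      !isTRUE(w$condition$is_control), exp$wells)
  concs <- vapply(swells, function(w)
    canonical_concentration(w$condition$concentration, w$condition$unit),
    numeric(1))
  top <- swells[concs == max(concs)]
  norm <- lapply(top, function(w) suppressWarnings(
    normalize_fluorescence(w, controls = ctrl)))
  times <- norm[[1]]$time_min
  m <- rowMeans(vapply(norm, function(n) n$afu_per_od,
                       numeric(length(times))))
  # background spread: sd across control wells' own normalized signal
  cn <- vapply(ctrl, function(w) suppressWarnings(
    normalize_fluorescence(w, controls = NULL))$afu_per_od,
    numeric(length(times)))
  csd <- apply(cn, 1, stats::sd)
  above <- which(!is.na(m) & m > 3 * csd & times > 0)
  final <- m[max(which(!is.na(m)))]
  plateau <- which(!is.na(m) & m >= 0.95 * final)
  list(
    time_to_signal_min = if (length(above)) times[above[1]] else NA_real_,
    time_to_plateau_min = if (length(plateau)) times[plateau[1]]
                          else NA_real_)
}

#' Write datasheets as JSON and a human-readable text document
#'
#' @param sheets A `bs_datasheets` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_datasheets <- function(sheets, dir) {
  stopifnot(inherits(sheets, "bs_datasheets"))
  jsonlite::write_json(
    sheets, file.path(dir, "datasheet.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE,
    na = "null")
  txt <- unlist(lapply(sheets$datasheets, .render_datasheet))
  writeLines(txt, file.path(dir, "datasheet.txt"))
  invisible(dir)
}

.render_datasheet <- function(d) {
  hf <- d$hill_fit
  fi <- d$fold_induction
  fold_str <- if (isTRUE(fi$is_lower_bound)) {
    paste0(">", signif(fi$fold, 3))
  } else {
    paste0(signif(fi$fold, 4), " +/- ", signif(fi$se, 2))
  }
  c(sprintf("=== %s (%s copy) ===", d$sensor, d$copy_number),
    sprintf("fold induction: %s (at %g %s)", fold_str,
            fi$at_concentration, fi$unit),
    sprintf("hill coefficient: %.3g +/- %.2g", hf$hill_h, hf$hill_h_se),
    sprintf("half-maximal parameter: %.4g +/- %.2g uM", hf$k_half_uM,
            hf$k_half_uM_se),
    sprintf("max expression velocity: %.4g +/- %.2g /s", hf$v_max,
            hf$v_max_se),
    sprintf("basal expression velocity: %.3g +/- %.2g /s", hf$v_min,
            hf$v_min_se),
    sprintf("time to signal: %s min; time to plateau: %s min",
            format(d$kinetics$time_to_signal_min),
            format(d$kinetics$time_to_plateau_min)),
    sprintf("seed: %s", d$seed),
    "")
}
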