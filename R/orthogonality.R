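# Cross-reactivity matrix and the orthogonality decision rule.

#' Cross-reactivity matrix of sensors against a chemical panel
#'
#' Each sensor strain is exposed to a panel of chemicals at one fixed
#' concentration each (its cognate inducer plus every off-target
#' chemical, solvents included). A cell's response is the mean endpoint
#' growth-normalized fluorescence minus the sensor's own uninduced mean;
#' the cell is flagged *activated* when the response exceeds `k` times
#' the combined standard error of the two means (default `k = 3`). The
#' threshold rule is this package's formalization of a visually flat
#' off-target response; `k` is configurable.
#'
#' @param exp A `bs_plate` whose non-control wells span sensor x chemical
#'   pairs, including a zero-dose (uninduced) condition per sensor.
#' @param endpoint_min Endpoint in minutes (default 900).
#' @param channel Fluorescence channel (default first).
#' @param k Activation threshold in combined-SE units (default 3).
#' @return Tibble of class `bs_crossreact`: `sensor, chemical,
#'   concentration, unit, response, se_combined, activated`.
#' @export
cross_react <- function(exp, endpoint_min = 900, channel = NULL, k = 3) {
  stopifnot(inherits(exp, "bs_plate"), k > 0)
  if (is.null(channel)) channel <- exp$channels[1]
  wells <- Filter(function(w) !isTRUE(w$condition$is_control), exp$wells)
  vals <- dplyr::bind_rows(lapply(wells, function(w) {
    dplyr::bind_cols(
      tibble::as_tibble(w$condition),
      tibble::tibble(endpoint = .endpoint_afu(w, endpoint_min, channel)))
  }))
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else 0
  rows <- list()
  for (s in unique(vals$sensor)) {
    sub <- vals[vals$sensor == s, ]
    un <- sub$endpoint[sub$concentration == 0]
    if (length(un) == 0) {
      stop("sensor ", s, ": no uninduced reference wells")
    }
    un_m <- mean(un); un_se <- sem(un)
    panel <- sub[sub$concentration > 0, ]
    for (chem in unique(panel$inducer)) {
      cell <- panel[panel$inducer == chem, ]
      m <- mean(cell$endpoint); se <- sem(cell$endpoint)
      se_comb <- sqrt(se^2 + un_se^2)
      resp <- m - un_m
      rows[[length(rows) + 1]] <- tibble::tibble(
        sensor = s, chemical = chem,
        concentration = cell$concentration[1], unit = cell$unit[1],
        response = resp, se_combined = se_comb,
        activated = resp > k * se_comb)
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$sensor,
                        .data$chemical)
  attr(out, "k") <- k
  class(out) <- c("bs_crossreact", class(out))
  out
}

#' Orthogonality verdict per sensor
#'
#' A sensor passes when the only activated cell in its row of the
#' cross-reactivity matrix is its cognate chemical; any off-target
#' activation (or a silent cognate) fails it, and offending pairs are
#' listed.
#'
#' @param matrix A `bs_crossreact` from [cross_react()].
#' @param cognate Named character vector mapping sensor to cognate
#'   chemical; defaults to the [sensor_library()] pairing for known
#'   sensors.
#' @return Tibble `sensor, pass, cognate_activated, off_target` (comma
#'   separated offending chemicals, `""` if none).
#' @export
orthogonality_report <- function(matrix, cognate = NULL) {
  stopifnot(inherits(matrix, "bs_crossreact"))
  if (is.null(cognate)) {
    lib <- sensor_library()
    cognate <- stats::setNames(lib$inducer, lib$sensor)
    cognate <- cognate[!duplicated(names(cognate))]
  }
  rows <- lapply(unique(matrix$sensor), function(s) {
    if (!s %in% names(cognate)) {
      stop("no cognate chemical known for sensor ", s)
    }
    sub <- matrix[matrix$sensor == s, ]
    cog <- cognate[[s]]
    cog_on <- any(sub$activated[sub$chemical == cog])
    off <- sub$chemical[sub$activated & sub$chemical != cog]
    tibble::tibble(sensor = s, pass = cog_on && length(off) == 0,
                   cognate_activated = cog_on,
                   off_target = paste(off, collapse = ","))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a cross-reactivity panel plate
#'
#' Every configured sensor is exposed, in `replicates` wells each, to
#' every chemical of the panel at its single panel concentration (plus
#' the sensor's uninduced condition). Because simulated sensors respond
#' only to their cognate inducer, the expected activation pattern is
#' diagonal.
#'
#' @param config A `bs_generator_config` (e.g. [library_config()]).
#' @param panel Tibble `inducer, concentration, unit`; defaults to the
#'   standard panel: acrylate 5 mM, arabinose 165 uM, glucarate 4.4 mM,
#'   erythromycin 51 uM, aTC 215 nM, naringenin 9 mM, IPTG 1 mM,
#'   rhamnose 10 mM, cumate 20 uM, DMSO 1%, ethanol 1%.
#' @return A `bs_plate`.
#' @export
simulate_crossreact_plate <- function(config, panel = crossreact_panel()) {
  stopifnot(inherits(config, "bs_generator_config"))
  ser <- dplyr::bind_rows(lapply(names(config$sensors), function(s) {
    dplyr::bind_cols(tibble::tibble(sensor = s), panel)
  }))
  cfg <- generator_config(
    sensors = config$sensors, growth = config$growth,
    noise = config$noise, toxicity = config$toxicity, series = ser,
    replicates = config$replicates,
    n_control_wells = config$n_control_wells, include_uninduced = TRUE,
    sampling_interval_min = config$sampling_interval_min,
    duration_min = config$duration_min, channel = config$channel,
    copy_number = config$copy_number, seed = config$seed)
  simulate_plate(cfg)
}

#' The standard cross-reactivity chemical panel
#'
#' Single evaluation concentration per chemical, solvents included.
#'
#' @return Tibble `inducer, concentration, unit`.
#' @export
crossreact_panel <- function() {
  tibble::tribble(
    ~inducer, ~concentration, ~unit,
    "acrylate", 5, "mM",
    "arabinose", 165, "uM",
    "glucarate", 4.4, "mM",
    "erythromycin", 51, "uM",
    "aTC", 215, "nM",
    "naringenin", 9, "mM",
    "IPTG", 1, "mM",
    "rhamnose", 10, "mM",
    "cumate", 20, "uM",
    "DMSO", 1, "percent",
    "ethanol", 1, "percent"
  )
}
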