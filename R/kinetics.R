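# Growth normalization and promoter-activity velocity extraction.

#' Growth-normalize a well's fluorescence, optionally background-subtracted
#'
#' Normalized fluorescence is fluorescence divided by optical density at
#' the same read (AFU/OD), a per-biomass expression proxy. When control
#' wells (reporter-free strains) are supplied, their mean AFU/OD at the
#' matched timepoint is subtracted, removing cellular autofluorescence;
#' the result may then be negative. Samples with OD at or below
#' `od_floor` are excluded (normalization blows up at inoculation
#' densities) and reported via the `excluded` column with a warning.
#'
#' Controls must share the well's time grid; nearest-neighbor matching
#' within half a sampling interval is accepted, anything farther is an
#' error.
#'
#' @param well A `bs_well`.
#' @param controls List of control `bs_well`s (or NULL for no background
#'   subtraction).
#' @param channel Fluorescence channel (default first channel).
#' @param od_floor OD below which samples are excluded (default 0.01).
#' @return Tibble of class `bs_normalized` with columns `time_min,
#'   afu_per_od, excluded`; attribute `background_subtracted`.
#' @export
normalize_fluorescence <- function(well, controls = NULL, channel = NULL,
                                   od_floor = 0.01) {
  stopifnot(inherits(well, "bs_well"))
  if (is.null(channel)) channel <- names(well$fluorescence)[1]
  excluded <- well$od <= od_floor
  if (any(excluded)) {
    warning("well ", well$well, ": ", sum(excluded),
            " sample(s) excluded (OD <= ", od_floor, ")")
  }
  afu <- ifelse(excluded, NA_real_, well$fluorescence[[channel]] / well$od)
  if (!is.null(controls) && length(controls) > 0) {
    half <- stats::median(diff(well$times)) / 2
    ctrl_mat <- vapply(controls, function(cw) {
      idx <- vapply(well$times, function(t) which.min(abs(cw$times - t)),
                    integer(1))
      if (any(abs(cw$times[idx] - well$times) > half)) {
        stop("control well ", cw$well,
             " is on a different time grid (no sample within half an ",
             "interval of some timepoints)")
      }
      ifelse(cw$od[idx] <= od_floor, NA_real_,
             cw$fluorescence[[channel]][idx] / cw$od[idx])
    }, numeric(length(well$times)))
    if (length(well$times) == 1) ctrl_mat <- matrix(ctrl_mat, nrow = 1)
    afu <- afu - rowMeans(ctrl_mat)
  }
  out <- tibble::tibble(time_min = well$times, afu_per_od = afu,
                        excluded = excluded)
  attr(out, "background_subtracted") <- !is.null(controls) &&
    length(controls) > 0
  attr(out, "well") <- well$well
  class(out) <- c("bs_normalized", class(out))
  out
}

#' Per-interval expression rates and the maximum expression velocity
#'
#' The promoter activity over each sampling interval is the first
#' difference of growth-normalized fluorescence divided by the interval
#' length in seconds (AFU OD^-1 s^-1). The maximum observed rate over
#' intervals whose midpoint falls at or after inducer addition is the
#' well's expression velocity, the quantity fitted against inducer
#' concentration by [fit_hill()]. Differences are taken raw; an optional
#' centered rolling-median smoothing of the normalized series
#' (`smooth_window`, default off) is available for noisy data.
#'
#' @param series A `bs_normalized` (from [normalize_fluorescence()]).
#' @param induction_time Minutes; intervals before this are ignored for
#'   the maximum (default 0).
#' @param smooth_window Odd window length for a rolling median applied
#'   before differencing; `NULL` (default) applies none.
#' @return Tibble of class `bs_velocity` with columns `mid_time_min,
#'   rate`; attributes `max_rate` and `max_rate_time` (interval
#'   midpoint, minutes).
#' @export
expression_rates <- function(series, induction_time = 0,
                             smooth_window = NULL) {
  stopifnot(inherits(series, "bs_normalized"))
  ok <- !series$excluded & !is.na(series$afu_per_od)
  t <- series$time_min[ok]
  y <- series$afu_per_od[ok]
  if (length(t) < 2) stop("need at least 2 usable samples to form rates")
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window %% 2 == 1, smooth_window >= 3)
    y <- stats::runmed(y, smooth_window, endrule = "keep")
  }
  rates <- diff(y) / (diff(t) * 60)
  mid <- (t[-1] + t[-length(t)]) / 2
  post <- mid >= induction_time
  if (!any(post)) stop("no intervals at or after induction_time")
  i_max <- which(post)[which.max(rates[post])]
  out <- tibble::tibble(mid_time_min = mid, rate = rates)
  attr(out, "max_rate") <- rates[i_max]
  attr(out, "max_rate_time") <- mid[i_max]
  class(out) <- c("bs_velocity", class(out))
  out
}

#' Maximum expression velocity
#'
#' @param x A `bs_velocity` (from [expression_rates()]).
#' @return Scalar maximum post-induction rate (AFU OD^-1 s^-1).
#' @export
max_rate <- function(x) {
  stopifnot(inherits(x, "bs_velocity"))
  attr(x, "max_rate")
}

#' Per-well maximum expression velocities for a whole plate
#'
#' Applies [normalize_fluorescence()] (with background subtraction against
#' the plate's control wells) and [expression_rates()] to every
#' non-control well.
#'
#' @param exp A `bs_plate`.
#' @param channel Fluorescence channel (default first).
#' @param od_floor Passed to [normalize_fluorescence()].
#' @param smooth_window Passed to [expression_rates()].
#' @return Tibble: layout columns plus `max_rate`, `max_rate_time`, and
#'   `concentration_uM` (canonical molar dose; percent doses are carried
#'   unchanged).
#' @export
plate_velocities <- function(exp, channel = NULL, od_floor = 0.01,
                             smooth_window = NULL) {
  stopifnot(inherits(exp, "bs_plate"))
  ctrl <- control_wells(exp)
  n_excluded <- 0L
  rows <- lapply(Filter(function(w) !isTRUE(w$condition$is_control),
                        exp$wells), function(w) {
    # routine low-OD exclusions at inoculation are tallied, not repeated
    # per well
    ns <- withCallingHandlers(
      normalize_fluorescence(w, controls = ctrl, channel = channel,
                             od_floor = od_floor),
      warning = function(cnd) {
        if (grepl("OD <=", conditionMessage(cnd))) {
          invokeRestart("muffleWarning")
        }
      })
    n_excluded <<- n_excluded + sum(ns$excluded)
    vs <- expression_rates(ns, induction_time = exp$induction_time,
                           smooth_window = smooth_window)
    dplyr::bind_cols(
      tibble::tibble(well = w$well), tibble::as_tibble(w$condition),
      tibble::tibble(max_rate = attr(vs, "max_rate"),
                     max_rate_time = attr(vs, "max_rate_time")))
  })
  out <- dplyr::bind_rows(rows)
  out$concentration_uM <- canonical_concentration(out$concentration,
                                                  out$unit)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Rescale series for co-plotting
#'
#' Fluorescence-style series are divided by 110% of the highest value
#' across the collection, placing every trend on a common 0..0.91 axis.
#' Growth-style series are instead divided by their own mid-point value
#' and offset so each curve starts at zero. The fluorescence scaling
#' always divides by 1.1 times the *current* maximum, so the rescaled
#' maximum is 1/1.1 regardless of how often the transform is applied;
#' it is a fixed display convention, not a unit conversion.
#'
#' @param series List of numeric vectors (or a single vector).
#' @param mode `"fluorescence"` (global 1.1 x max) or `"growth"`
#'   (per-curve midpoint + zero offset).
#' @return List of rescaled vectors (single vector in, single vector
#'   out).
#' @export
normalize_for_display <- function(series, mode = c("fluorescence",
                                                   "growth")) {
  mode <- match.arg(mode)
  single <- is.numeric(series)
  if (single) series <- list(series)
  out <- if (mode == "fluorescence") {
    gmax <- max(unlist(series), na.rm = TRUE)
    lapply(series, function(v) v / (1.1 * gmax))
  } else {
    lapply(series, function(v) {
      mid <- v[ceiling(length(v) / 2)]
      scaled <- v / mid
      scaled - scaled[1]
    })
  }
  if (single) out[[1]] else out
}
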