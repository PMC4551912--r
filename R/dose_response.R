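# Endpoint transfer functions and fold-induction with propagated error.

#' Student-t confidence interval for a sample mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` — the interval used to
#' band replicate endpoint fluorescence (n = 3 in the standard protocol).
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
t_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("t_interval needs at least 2 values")
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  c(low = m - half, high = m + half)
}

#' Percentile bootstrap confidence interval for a sample mean
#'
#' Resamples with replacement and returns the percentile interval of the
#' resampled means; the resampling analogue of [t_interval()] used for
#' banding time-course data.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed (default 1).
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_sem_ci <- function(values, n_boot = 1000, level = 0.95,
                             seed = 1L) {
  n <- length(values)
  if (n < 2) stop("bootstrap_sem_ci needs at least 2 values")
  set.seed(seed)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(sample(values, n, replace = TRUE)),
                  numeric(1))
  qs <- stats::quantile(means, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  c(low = qs[1], high = qs[2])
}

# endpoint AFU/OD per well at the sample nearest `endpoint_min`
# (must fall within half a sampling interval)
.endpoint_afu <- function(well, endpoint_min, channel, od_floor = 0.01) {
  i <- which.min(abs(well$times - endpoint_min))
  half <- stats::median(diff(well$times)) / 2
  if (abs(well$times[i] - endpoint_min) > half) {
    return(NA_real_)
  }
  if (well$od[i] <= od_floor) return(NA_real_)
  well$fluorescence[[channel]][i] / well$od[i]
}

#' Endpoint transfer function of each sensor on a plate
#'
#' For every sensor and inducer concentration, the replicate mean of the
#' endpoint (default 15 h) growth-normalized fluorescence with its 95%
#' Student-t confidence interval. This is the dose-response relationship
#' between inducer concentration and reporter output.
#'
#' @param exp A `bs_plate`.
#' @param endpoint_min Endpoint in minutes (default 900 = 15 h); the
#'   nearest sample within half a sampling interval is used.
#' @param channel Fluorescence channel (default first).
#' @param level Confidence level (default 0.95).
#' @return Tibble `sensor, inducer, concentration, unit,
#'   concentration_uM, mean, ci_low, ci_high, n_replicates`.
#' @export
transfer_function <- function(exp, endpoint_min = 900, channel = NULL,
                              level = 0.95) {
  stopifnot(inherits(exp, "bs_plate"))
  if (is.null(channel)) channel <- exp$channels[1]
  wells <- Filter(function(w) !isTRUE(w$condition$is_control), exp$wells)
  vals <- dplyr::bind_rows(lapply(wells, function(w) {
    dplyr::bind_cols(tibble::as_tibble(w$condition),
                     tibble::tibble(well = w$well,
                                    endpoint = .endpoint_afu(w, endpoint_min,
                                                             channel)))
  }))
  if (anyNA(vals$endpoint)) {
    stop("no endpoint sample within half an interval of ", endpoint_min,
         " min (or OD at floor) for well(s): ",
         paste(vals$well[is.na(vals$endpoint)], collapse = ", "))
  }
  out <- vals |>
    dplyr::group_by(.data$sensor, .data$inducer, .data$concentration,
                    .data$unit) |>
    dplyr::summarise(
      mean = mean(.data$endpoint),
      ci_low = if (dplyr::n() >= 2)
        unname(t_interval(.data$endpoint, level)[1])
      else mean(.data$endpoint),
      ci_high = if (dplyr::n() >= 2)
        unname(t_interval(.data$endpoint, level)[2])
      else mean(.data$endpoint),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$sensor, .data$inducer, .data$concentration)
  out$concentration_uM <- canonical_concentration(out$concentration,
                                                  out$unit)
  out[c("sensor", "inducer", "concentration", "unit", "concentration_uM",
        "mean", "ci_low", "ci_high", "n_replicates")]
}

#' Fold induction with propagated standard error
#'
#' The induction ratio is the background-subtracted induced mean over the
#' background-subtracted uninduced mean,
#' `F = (I - C) / (U - C)`, with standard error propagated from the
#' replicate SEMs by nesting the quadratic sums of the subtraction errors
#' inside the quadratic sum of the fractional division errors:
#'
#' `sigma_F = F * sqrt( (s_I^2 + s_C^2) / I_B^2 + (s_U^2 + s_C^2) / U_B^2 )`
#'
#' When the uninduced mean sits within the background fluorescence — here
#' formalized as the uninduced 95% interval (approximated by doubling the
#' standard error of the background-subtracted value) touching zero — the
#' true ratio is undefined and a lower bound is returned instead:
#' the lower 95% bound of `I_B` divided by the upper 95% bound of `U_B`,
#' flagged via `is_lower_bound`.
#'
#' @param induced,uninduced,control Replicate endpoint AFU/OD values for
#'   induced, uninduced and reporter-free control wells (each length
#'   >= 2 so SEMs are defined).
#' @return List of class `bs_fold` with `value`, `se` (`NA` for lower
#'   bounds), `is_lower_bound`, and the `components` used.
#' @export
fold_induction <- function(induced, uninduced, control) {
  for (v in list(induced, uninduced, control)) {
    if (length(v) < 2) stop("each group needs >= 2 values for an SEM")
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  I_m <- mean(induced); U_m <- mean(uninduced); C_m <- mean(control)
  s_I <- sem(induced); s_U <- sem(uninduced); s_C <- sem(control)
  I_B <- I_m - C_m
  U_B <- U_m - C_m
  s_IB <- sqrt(s_I^2 + s_C^2)
  s_UB <- sqrt(s_U^2 + s_C^2)
  comp <- list(I_mean = I_m, U_mean = U_m, C_mean = C_m,
               se_I = s_I, se_U = s_U, se_C = s_C,
               I_B = I_B, U_B = U_B)
  within_background <- U_B - 2 * s_UB <= 0
  if (within_background) {
    denom <- U_B + 2 * s_UB
    if (denom <= 0) {
      stop("fold induction undefined: uninduced signal within background ",
           "and its upper bound is non-positive")
    }
    value <- (I_B - 2 * s_IB) / denom
    out <- list(value = value, se = NA_real_, is_lower_bound = TRUE,
                components = comp)
  } else {
    if (U_B <= 0) stop("fold induction undefined: U_B <= 0")
    value <- I_B / U_B
    se <- if (s_IB == 0 && s_UB == 0) 0 else
      abs(value) * sqrt((s_I^2 + s_C^2) / I_B^2 +
                          (s_U^2 + s_C^2) / U_B^2)
    out <- list(value = value, se = se, is_lower_bound = FALSE,
                components = comp)
  }
  class(out) <- "bs_fold"
  out
}

#' @export
print.bs_fold <- function(x, ...) {
  if (x$is_lower_bound) {
    cat("fold induction > ", signif(x$value, 3),
        " (lower bound: uninduced within background)\n", sep = "")
  } else {
    cat("fold induction ", signif(x$value, 4), " +/- ", signif(x$se, 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Fold induction of each sensor on a plate
#'
#' Per sensor: induced values are the endpoint replicates at the
#' concentration with the highest mean response (the maximum-response
#' dose), uninduced values come from the sensor's zero-dose wells, and
#' control values from the plate's reporter-free wells.
#'
#' @inheritParams transfer_function
#' @return Tibble `sensor, copy_number, fold, se, is_lower_bound,
#'   at_concentration, unit`.
#' @export
plate_fold_induction <- function(exp, endpoint_min = 900, channel = NULL) {
  stopifnot(inherits(exp, "bs_plate"))
  if (is.null(channel)) channel <- exp$channels[1]
  ctrl <- control_wells(exp)
  if (length(ctrl) < 2) {
    stop("background subtraction requires >= 2 control wells")
  }
  ctrl_vals <- vapply(ctrl, .endpoint_afu, numeric(1),
                      endpoint_min = endpoint_min, channel = channel)
  lay <- plate_layout(exp)
  sensors <- unique(stats::na.omit(lay$sensor[!lay$is_control]))
  rows <- lapply(sensors, function(s) {
    swells <- Filter(function(w)
      identical(w$condition$sensor, s) && !isTRUE(w$condition$is_control),
      exp$wells)
    vals <- tibble::tibble(
      concentration = vapply(swells, function(w) w$condition$concentration,
                             numeric(1)),
      unit = vapply(swells, function(w) w$condition$unit, character(1)),
      endpoint = vapply(swells, .endpoint_afu, numeric(1),
                        endpoint_min = endpoint_min, channel = channel))
    un <- vals$endpoint[vals$concentration == 0]
    if (length(un) < 2) stop("sensor ", s, ": no uninduced replicates")
    by_conc <- vals |>
      dplyr::filter(.data$concentration > 0) |>
      dplyr::group_by(.data$concentration, .data$unit) |>
      dplyr::summarise(m = mean(.data$endpoint), .groups = "drop")
    top <- by_conc[which.max(by_conc$m), ]
    ind <- vals$endpoint[vals$concentration == top$concentration &
                           vals$unit == top$unit]
    fi <- fold_induction(ind, un, ctrl_vals)
    tibble::tibble(sensor = s,
                   copy_number = swells[[1]]$condition$copy_number,
                   fold = fi$value, se = fi$se,
                   is_lower_bound = fi$is_lower_bound,
                   at_concentration = top$concentration, unit = top$unit)
  })
  dplyr::bind_rows(rows)
}
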