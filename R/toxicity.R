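# Dose-dependent growth effects of inducer chemicals.

# Windowed log-linear regression statistics via cumulative sums:
# slope and R^2 of ln(OD) ~ time for every contiguous window of >= minlen
# points, in O(n^2) windows but O(1) per window.
.window_slopes <- function(t, y, minlen) {
  n <- length(t)
  res <- list()
  ct <- cumsum(t); ct2 <- cumsum(t^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(t * y)
  at <- function(cs, i) if (i == 0) 0 else cs[i]
  out <- vector("list", n)
  k <- 0L
  for (i in seq_len(n - minlen + 1)) {
    for (j in (i + minlen - 1):n) {
      m <- j - i + 1
      st <- at(ct, j) - at(ct, i - 1)
      st2 <- at(ct2, j) - at(ct2, i - 1)
      sy <- at(cy, j) - at(cy, i - 1)
      sy2 <- at(cy2, j) - at(cy2, i - 1)
      sty <- at(cty, j) - at(cty, i - 1)
      sxx <- st2 - st^2 / m
      syy <- sy2 - sy^2 / m
      sxy <- sty - st * sy / m
      if (sxx <= 0) next
      slope <- sxy / sxx
      r2 <- if (syy <= 0) 1 else (sxy^2 / (sxx * syy))
      k <- k + 1L
      out[[k]] <- c(i = i, j = j, len = m, slope = slope, r2 = r2)
    }
  }
  if (k == 0) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

#' Exponential-phase growth rate of one well
#'
#' Slope of `ln(OD)` versus time over the detected exponential window:
#' among all contiguous windows of at least `min_points` samples with
#' `R^2 >= r2_min`, the window with the maximal slope is the exponential
#' phase (widest such window on ties). Samples with OD at or below
#' `od_floor` are ignored.
#'
#' @param well A `bs_well`.
#' @param od_floor OD below which samples are ignored (default 0.01).
#' @param min_points Minimum window length (default 4).
#' @param r2_min Minimum window R^2 (default 0.99).
#' @return List of class `bs_growth_rate`: `rate` (per minute),
#'   `window` (start/end times, minutes), `r2`, `n_points`.
#' @export
growth_rate <- function(well, od_floor = 0.01, min_points = 4,
                        r2_min = 0.99) {
  stopifnot(inherits(well, "bs_well"))
  ok <- well$od > od_floor
  t <- well$times[ok]
  y <- log(well$od[ok])
  if (length(t) < min_points) {
    stop("well ", well$well, ": fewer than ", min_points,
         " samples above the OD floor")
  }
  win <- .window_slopes(t, y, min_points)
  if (!is.null(win)) {
    # a flat trace yields numerically-zero slopes; demand real growth
    win <- win[win[, "r2"] >= r2_min & win[, "slope"] > 1e-9, ,
               drop = FALSE]
  }
  if (is.null(win) || nrow(win) == 0) {
    stop("well ", well$well, ": no exponential window of >= ", min_points,
         " points with R^2 >= ", r2_min, " and positive slope")
  }
  smax <- max(win[, "slope"])
  cand <- win[win[, "slope"] >= smax * (1 - 1e-9), , drop = FALSE]
  best <- cand[which.max(cand[, "len"]), ]
  structure(list(rate = unname(best["slope"]),
                 window = c(start = t[best["i"]], end = t[best["j"]]),
                 r2 = unname(best["r2"]),
                 n_points = unname(best["len"])),
            class = "bs_growth_rate")
}

#' Normalized dose-dependent growth effects across a plate
#'
#' Per chemical and concentration, the replicate mean of either the
#' exponential-phase growth rate (`mode = "rate"`) or the endpoint
#' OD600 (`mode = "endpoint"`), normalized to the zero-dose wells of the
#' same chemical. Both normalizations are legitimate summaries of
#' inducer toxicity; rate is the default because it isolates the
#' exponential phase from carrying-capacity effects.
#'
#' @param exp A `bs_plate` whose wells span chemicals x doses (dose 0
#'   rows are the controls and are required).
#' @param mode `"rate"` or `"endpoint"`.
#' @param endpoint_min Endpoint for `mode = "endpoint"` (default 900).
#' @param ... Passed to [growth_rate()].
#' @return Tibble `chemical, concentration, unit, normalized, n_replicates`.
#'   Zero-dose rows equal 1 by construction.
#' @export
toxicity_profile <- function(exp, mode = c("rate", "endpoint"),
                             endpoint_min = 900, ...) {
  stopifnot(inherits(exp, "bs_plate"))
  mode <- match.arg(mode)
  wells <- Filter(function(w) !isTRUE(w$condition$is_control), exp$wells)
  vals <- dplyr::bind_rows(lapply(wells, function(w) {
    v <- if (mode == "rate") {
      growth_rate(w, ...)$rate
    } else {
      i <- which.min(abs(w$times - endpoint_min))
      w$od[i]
    }
    tibble::tibble(chemical = w$condition$inducer,
                   concentration = w$condition$concentration,
                   unit = w$condition$unit, value = v)
  }))
  # wells with no chemical ("none" at dose 0) serve as the shared control
  shared0 <- vals$value[vals$chemical == "none" & vals$concentration == 0]
  out <- vals |>
    dplyr::filter(.data$chemical != "none") |>
    dplyr::group_by(.data$chemical) |>
    dplyr::group_modify(function(g, key) {
      ctrl <- c(g$value[g$concentration == 0], shared0)
      if (length(ctrl) == 0) {
        stop("chemical ", key$chemical, ": no zero-dose control wells")
      }
      g |>
        dplyr::group_by(.data$concentration, .data$unit) |>
        dplyr::summarise(normalized = mean(.data$value) / mean(ctrl),
                         n_replicates = dplyr::n(), .groups = "drop")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chemical, .data$concentration)
  out
}
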