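# Modified Hill model of promoter activity versus inducer concentration.

#' Promoter activity predicted by the modified Hill function
#'
#' `v(I) = v_min + v_max * I^h / (I^h + k_half^h)`: basal activity
#' `v_min` with no inducer, half-maximal induced activity at
#' `I = k_half`, sigmoidicity set by the Hill coefficient `h`. Zero
#' concentration yields exactly `v_min` for any `h`.
#'
#' @param concentration Inducer concentration(s), >= 0, same unit as
#'   `k_half`.
#' @param v_max Maximum induced expression velocity.
#' @param v_min Basal expression velocity.
#' @param h Hill coefficient (> 0).
#' @param k_half Half-maximal (lumped) parameter (> 0).
#' @return Velocity (same units as `v_max`).
#' @export
hill_velocity <- function(concentration, v_max, v_min, h, k_half) {
  stopifnot(all(concentration >= 0), h > 0, k_half > 0)
  term <- ifelse(concentration == 0, 0,
                 concentration^h / (concentration^h + k_half^h))
  v_min + v_max * term
}

#' Fit the modified Hill function to (concentration, velocity) points
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of maximum expression velocity against inducer
#' concentration, fitting all replicate points individually so that the
#' covariance reflects replicate scatter. Multi-start: the default start
#' (`v_max` = max velocity, `v_min` = min velocity, `h = 1`, `k_half` =
#' geometric mean of the nonzero concentrations) is jittered over
#' `k_half` x/÷ 10 and `h` in {0.7, 1, 2, 4} since Hill fits are
#' multimodal in `(h, K)`; the lowest-deviance converged fit wins.
#' Parameters are unbounded, matching a plain least-squares fit: a
#' negative `v_min` estimate is reported, not clipped. Zero-concentration
#' points enter with the Hill term exactly 0.
#'
#' Standard errors are the square roots of the diagonal of the
#' least-squares covariance matrix.
#'
#' @param points Data frame with columns `concentration` and `rate` (one
#'   row per replicate point), or the output of [plate_velocities()]
#'   (whose `concentration_uM` and `max_rate` columns are used).
#' @param exclude Optional concentrations to omit from the fit (e.g. a
#'   dose known to be toxic); recorded in the result.
#' @param sensor Optional sensor name carried into the result.
#' @return Object of class `bs_hill_fit`: `coef` (v_max, v_min, h,
#'   k_half), `se`, `vcov`, `rss`, `df_residual`, `n_points`,
#'   `excluded`, `converged`, `fit` (the underlying nls object).
#' @export
fit_hill <- function(points, exclude = NULL, sensor = NA_character_) {
  if (all(c("concentration_uM", "max_rate") %in% names(points))) {
    dat <- tibble::tibble(concentration = points$concentration_uM,
                          rate = points$max_rate)
  } else {
    stopifnot(all(c("concentration", "rate") %in% names(points)))
    dat <- tibble::tibble(concentration = points$concentration,
                          rate = points$rate)
  }
  dat <- dat[stats::complete.cases(dat), ]
  if (!is.null(exclude)) {
    dat <- dat[!dat$concentration %in% exclude, ]
  }
  if (length(unique(dat$concentration)) < 4) {
    stop("fit_hill needs >= 4 distinct concentrations after exclusion ",
         "(got ", length(unique(dat$concentration)), ")")
  }
  if (diff(range(dat$rate)) == 0) {
    stop("degenerate fit: all velocities are equal")
  }
  conc <- dat$concentration
  rate <- dat$rate
  k0 <- exp(mean(log(conc[conc > 0])))
  base_start <- list(v_max = max(rate) - min(rate), v_min = min(rate),
                     h = 1, k_half = k0)
  hill_rhs <- function(conc, v_max, v_min, h, k_half) {
    term <- ifelse(conc == 0, 0, conc^h / (conc^h + k_half^h))
    v_min + v_max * term
  }
  best <- NULL
  for (h0 in c(0.7, 1, 2, 4)) {
    for (kf in c(0.1, 1, 10)) {
      st <- base_start
      st$h <- h0
      st$k_half <- k0 * kf
      fit <- tryCatch(
        minpack.lm::nlsLM(
          rate ~ hill_rhs(conc, v_max, v_min, h, k_half),
          start = st,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit) &&
            (is.null(best) || stats::deviance(fit) < stats::deviance(best))) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    stop("Hill fit failed to converge from any start")
  }
  cf <- stats::coef(best)
  if (cf[["h"]] < 0) {
    # mirrored optimum: v(I) with h < 0 equals the canonical (h > 0)
    # curve with v_min' = v_min + v_max and v_max' = -v_max; refit from
    # the canonical representation so coefficients and covariance agree
    st <- list(v_max = -cf[["v_max"]],
               v_min = cf[["v_min"]] + cf[["v_max"]],
               h = -cf[["h"]], k_half = cf[["k_half"]])
    refit <- tryCatch(
      minpack.lm::nlsLM(rate ~ hill_rhs(conc, v_max, v_min, h, k_half),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(refit) && stats::deviance(refit) <=
          stats::deviance(best) * (1 + 1e-8)) {
      best <- refit
      cf <- stats::coef(best)
    }
  }
  vc <- tryCatch(stats::vcov(best), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  se <- sqrt(pmax(diag(vc), 0))
  out <- list(sensor = sensor, coef = cf, se = se, vcov = vc,
              rss = stats::deviance(best),
              df_residual = stats::df.residual(best),
              n_points = nrow(dat),
              excluded = if (is.null(exclude)) numeric(0) else exclude,
              converged = isTRUE(best$convInfo$isConv),
              fit = best)
  class(out) <- "bs_hill_fit"
  out
}

#' @export
print.bs_hill_fit <- function(x, ...) {
  cat("<bs_hill_fit>", if (!is.na(x$sensor)) x$sensor else "", "\n")
  tab <- data.frame(estimate = signif(x$coef, 4),
                    se = signif(x$se, 3))
  print(tab)
  cat("n =", x$n_points, " rss =", signif(x$rss, 4),
      if (length(x$excluded)) paste(" excluded:",
                                    paste(x$excluded, collapse = ", ")),
      "\n")
  invisible(x)
}

#' @export
coef.bs_hill_fit <- function(object, ...) object$coef

#' Predicted velocities from a Hill fit
#'
#' @param object A `bs_hill_fit`.
#' @param concentration Concentrations at which to predict (canonical
#'   unit of the fit).
#' @param ... Unused.
#' @return Numeric velocities.
#' @export
predict.bs_hill_fit <- function(object, concentration, ...) {
  cf <- object$coef
  hill_velocity(concentration, cf[["v_max"]], cf[["v_min"]], cf[["h"]],
                cf[["k_half"]])
}

#' Compose the lumped half-maximal parameter from its factors
#'
#' For transcription-factor-regulated systems the half-maximal parameter
#' is the product `K * K_d * K_p * T`: the promoter-binding equilibrium
#' constant, the inducer-regulator dissociation constant, the
#' intracellular/extracellular partition coefficient of the inducer, and
#' the regulator concentration. The factors are rarely individually
#' known, so the model fits the product as one lumped value; this helper
#' documents and checks the decomposition.
#'
#' @param K Promoter-binding equilibrium constant.
#' @param K_d Inducer-regulator dissociation constant.
#' @param K_p Partition coefficient.
#' @param T_conc Regulator concentration.
#' @return The product, i.e. the implied `k_half`.
#' @export
compose_half_max <- function(K, K_d, K_p, T_conc) {
  stopifnot(is.numeric(K), is.numeric(K_d), is.numeric(K_p),
            is.numeric(T_conc))
  K * K_d * K_p * T_conc
}

#' Check a decomposition against a fitted half-maximal value
#'
#' @inheritParams compose_half_max
#' @param k_half Stored lumped value to compare against.
#' @param tol Relative mismatch tolerance (default 1%).
#' @return `TRUE` invisibly if consistent; otherwise an error naming the
#'   relative mismatch.
#' @export
check_half_max <- function(K, K_d, K_p, T_conc, k_half, tol = 0.01) {
  implied <- compose_half_max(K, K_d, K_p, T_conc)
  rel <- abs(implied - k_half) / abs(k_half)
  if (rel > tol) {
    stop("lumped half-maximal mismatch: product ", signif(implied, 6),
         " vs stored ", signif(k_half, 6), " (relative ",
         signif(rel, 3), " > ", tol, ")")
  }
  invisible(TRUE)
}
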