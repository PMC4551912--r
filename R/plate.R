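#' One well's sampled trajectory
#'
#' Bundles a well's time grid (minutes from inducer addition; pre-induction
#' baseline reads carry negative times), OD600 readings, and one or more
#' fluorescence channels, together with the well's [condition()].
#'
#' @param condition One-row condition tibble (see [condition()]).
#' @param times Strictly increasing numeric vector, minutes from induction.
#' @param od Numeric OD600 readings, same length as `times`.
#' @param fluorescence Named list of numeric vectors (one per channel, AFU),
#'   each the same length as `times`.
#' @param well Well identifier (e.g. `"A1"`).
#' @return Object of class `bs_well`.
#' @export
well_time_series <- function(condition, times, od, fluorescence,
                             well = "W1") {
  stopifnot(is.numeric(times), length(times) >= 2, all(diff(times) > 0))
  stopifnot(is.numeric(od), length(od) == length(times))
  stopifnot(is.list(fluorescence), length(fluorescence) >= 1,
            !is.null(names(fluorescence)))
  for (ch in names(fluorescence)) {
    if (length(fluorescence[[ch]]) != length(times)) {
      stop("channel ", ch, ": length differs from time grid")
    }
  }
  structure(
    list(well = well, condition = condition, times = as.numeric(times),
         od = as.numeric(od),
         fluorescence = lapply(fluorescence, as.numeric)),
    class = "bs_well"
  )
}

#' @export
print.bs_well <- function(x, ...) {
  cat("<bs_well> ", x$well, ": ", length(x$times), " samples, channels ",
      paste(names(x$fluorescence), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' A plate-reader experiment
#'
#' A collection of [well_time_series()] sharing a channel set, plus the
#' induction time and free-form metadata. This is the container consumed by
#' the kinetics, dose-response, toxicity and orthogonality modules.
#'
#' @param wells List of `bs_well` objects.
#' @param channels Ordered channel names; defaults to those of the first
#'   well.
#' @param induction_time Minutes; time of inducer addition (default 0).
#' @param metadata Named list of free-form annotations.
#' @return Object of class `bs_plate`.
#' @export
plate_experiment <- function(wells, channels = NULL, induction_time = 0,
                             metadata = list()) {
  stopifnot(is.list(wells), length(wells) >= 1)
  if (is.null(channels)) channels <- names(wells[[1]]$fluorescence)
  for (w in wells) {
    if (!inherits(w, "bs_well")) stop("all wells must be bs_well objects")
    if (!setequal(names(w$fluorescence), channels)) {
      stop("well ", w$well, " does not share the common channel set (",
           paste(channels, collapse = ", "), ")")
    }
  }
  ids <- vapply(wells, function(w) w$well, character(1))
  if (anyDuplicated(ids)) stop("duplicated well ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(wells) <- ids
  structure(list(wells = wells, channels = channels,
                 induction_time = induction_time, metadata = metadata),
            class = "bs_plate")
}

#' @export
print.bs_plate <- function(x, ...) {
  lay <- plate_layout(x)
  cat("<bs_plate> ", length(x$wells), " wells (",
      sum(lay$is_control), " controls), channels: ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  cat("  sensors: ",
      paste(unique(stats::na.omit(lay$sensor[!lay$is_control])), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Layout table of a plate experiment
#'
#' @param exp A `bs_plate`.
#' @return Tibble with one row per well: well id plus all condition fields.
#' @export
plate_layout <- function(exp) {
  stopifnot(inherits(exp, "bs_plate"))
  dplyr::bind_rows(lapply(exp$wells, function(w) {
    dplyr::bind_cols(tibble::tibble(well = w$well),
                     tibble::as_tibble(w$condition))
  }))
}

#' Control wells of a plate experiment
#'
#' @param exp A `bs_plate`.
#' @return List of `bs_well` objects flagged as background controls.
#' @export
control_wells <- function(exp) {
  stopifnot(inherits(exp, "bs_plate"))
  Filter(function(w) isTRUE(w$condition$is_control), exp$wells)
}

#' Tidy long-format view of a plate experiment
#'
#' @param exp A `bs_plate`.
#' @return Tibble with columns well, time_min, od600, channel, value,
#'   sorted by (well, channel, time).
#' @export
plate_data <- function(exp) {
  stopifnot(inherits(exp, "bs_plate"))
  rows <- lapply(exp$wells, function(w) {
    dplyr::bind_rows(lapply(exp$channels, function(ch) {
      tibble::tibble(well = w$well, time_min = w$times, od600 = w$od,
                     channel = ch, value = w$fluorescence[[ch]])
    }))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$well, .data$channel, .data$time_min)
}
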