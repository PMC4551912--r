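# Tidy CSV interchange. Dialect is fixed (UTF-8, comma separator, '.'
# decimal, header required). Writing goes through readr (shortest
# round-trippable float representation); reading goes through base
# read.csv, whose strtod-based parser is correctly rounded, so
# write -> read -> write round-trips are byte-identical after canonical
# sorting.

.read_csv_strict <- function(path, required, col_classes) {
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(required, hdr)
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- utils::read.csv(path, colClasses = col_classes[hdr],
                         na.strings = c("NA", ""),
                         check.names = FALSE)
  tibble::as_tibble(out)
}

#' Read a plate-reader experiment from tidy CSV files
#'
#' @param path Data CSV with columns `well, time_min, od600, channel, value`
#'   (one row per well x time x channel).
#' @param layout Layout CSV mapping wells to conditions, with columns
#'   `well, sensor, inducer, concentration, unit, replicate, is_control,
#'   copy_number`.
#' @param induction_time Minutes at which inducer was added (default 0).
#' @return A [plate_experiment()].
#' @seealso [write_plate()]
#' @export
read_plate <- function(path, layout, induction_time = 0) {
  dat <- .read_csv_strict(
    path, c("well", "time_min", "od600", "channel", "value"),
    c(well = "character", time_min = "numeric", od600 = "numeric",
      channel = "character", value = "numeric"))
  lay <- .read_csv_strict(
    layout, c("well", "sensor", "inducer", "concentration", "unit",
              "replicate", "is_control", "copy_number"),
    c(well = "character", sensor = "character", inducer = "character",
      concentration = "numeric", unit = "character",
      replicate = "integer", is_control = "logical",
      copy_number = "character"))
  unknown <- setdiff(unique(dat$well), lay$well)
  if (length(unknown) > 0) {
    stop("wells present in data but absent from layout: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(lay$well)) stop("layout has duplicated wells")
  channels <- sort(unique(dat$channel))
  wells <- lapply(intersect(lay$well, unique(dat$well)), function(wid) {
    sub <- dplyr::arrange(dat[dat$well == wid, ], .data$channel,
                          .data$time_min)
    times <- sort(unique(sub$time_min))
    if (anyDuplicated(sub[c("channel", "time_min")])) {
      stop("well ", wid, ": duplicated (channel, time) rows")
    }
    fl <- lapply(channels, function(ch) {
      chsub <- sub[sub$channel == ch, ]
      if (!identical(chsub$time_min, times)) {
        stop("well ", wid, ": channels disagree on the time grid")
      }
      chsub$value
    })
    names(fl) <- channels
    od <- sub$od600[sub$channel == channels[1]]
    lrow <- lay[lay$well == wid, ]
    cond <- condition(lrow$sensor, lrow$inducer, lrow$concentration,
                      lrow$unit, lrow$replicate, lrow$is_control,
                      lrow$copy_number)
    well_time_series(cond, times, od, fl, well = wid)
  })
  plate_experiment(wells, channels, induction_time = induction_time)
}

#' Write a plate-reader experiment as tidy CSV files
#'
#' Emits the canonical tidy form: fixed column order, rows sorted by
#' (well, channel, time).
#'
#' @param exp A `bs_plate`.
#' @param path Destination for the data CSV.
#' @param layout Optional destination for the layout CSV.
#' @return `path`, invisibly.
#' @export
write_plate <- function(exp, path, layout = NULL) {
  stopifnot(inherits(exp, "bs_plate"))
  readr::write_csv(plate_data(exp), path)
  if (!is.null(layout)) {
    lay <- dplyr::arrange(plate_layout(exp), .data$well)
    readr::write_csv(lay, layout)
  }
  invisible(path)
}

#' Read cytometry samples from a tidy event CSV
#'
#' @param path CSV with columns `sample_label, event_id, channel, value`.
#' @return Named list of [cytometry_sample()] objects, one per label.
#'   Event order within a sample follows first appearance in the file.
#' @export
read_events <- function(path) {
  dat <- .read_csv_strict(
    path, c("sample_label", "event_id", "channel", "value"),
    c(sample_label = "character", event_id = "integer",
      channel = "character", value = "numeric"))
  if (anyDuplicated(dat[c("sample_label", "event_id", "channel")])) {
    stop("duplicated (sample, event, channel) rows")
  }
  channels <- sort(unique(dat$channel))
  labels <- unique(dat$sample_label)
  out <- lapply(labels, function(lb) {
    sub <- dat[dat$sample_label == lb, ]
    ids <- unique(sub$event_id)
    counts <- table(sub$event_id)
    if (any(counts != length(channels))) {
      stop("sample ", lb, ": ragged channels across events")
    }
    m <- matrix(NA_real_, nrow = length(ids), ncol = length(channels),
                dimnames = list(NULL, channels))
    for (ch in channels) {
      chsub <- sub[sub$channel == ch, ]
      m[match(chsub$event_id, ids), ch] <- chsub$value
    }
    cytometry_sample(lb, m, event_id = ids)
  })
  names(out) <- labels
  out
}

#' Write cytometry samples as a tidy event CSV
#'
#' @param samples List of `bs_cytometry` objects (or a single one).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(samples, path) {
  if (inherits(samples, "bs_cytometry")) samples <- list(samples)
  rows <- dplyr::bind_rows(lapply(samples, function(s) {
    tidyr::pivot_longer(
      dplyr::bind_cols(
        tibble::tibble(sample_label = s$sample_label,
                       event_id = s$event_id),
        tibble::as_tibble(s$events)),
      cols = -c("sample_label", "event_id"),
      names_to = "channel", values_to = "value")
  }))
  # canonical row order: event order preserved, channels alphabetical
  rows <- rows[order(match(rows$sample_label, unique(rows$sample_label)),
                     rows$event_id, rows$channel), ]
  readr::write_csv(rows, path)
  invisible(path)
}

#' Read / write enzyme-variant screen tables
#'
#' Variant tables carry one row per variant x replicate with the endpoint
#' fluorescence readout (AFU/OD) and, when measured, the product titer.
#'
#' @param path CSV with columns `variant_id, replicate, fluorescence,
#'   titer` (titer may be empty).
#' @return Tibble.
#' @export
read_variants <- function(path) {
  .read_csv_strict(
    path, c("variant_id", "replicate", "fluorescence", "titer"),
    c(variant_id = "character", replicate = "integer",
      fluorescence = "numeric", titer = "numeric"))
}

#' @rdname read_variants
#' @param variants Tibble as returned by [simulate_variants()].
#' @export
write_variants <- function(variants, path) {
  stopifnot(all(c("variant_id", "replicate", "fluorescence", "titer") %in%
                  names(variants)))
  readr::write_csv(
    dplyr::arrange(variants[c("variant_id", "replicate", "fluorescence",
                              "titer")],
                   .data$variant_id, .data$replicate),
    path)
  invisible(path)
}
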