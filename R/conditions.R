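#' Concentration units recognised by the package
#'
#' Inducer concentrations are stored as a `(value, unit)` pair. Molar units
#' are convertible to the canonical micromolar scale; volumetric solvent
#' doses ("percent", i.e. % v/v) are kept as percentages and never mixed
#' with molar values in a fit.
#'
#' @format Character vector of allowed unit tags.
#' @export
concentration_units <- c("nM", "uM", "mM", "M", "percent")

# multiplier taking a value in `unit` to micromolar (NA for percent)
.molar_to_uM <- c(nM = 1e-3, uM = 1, mM = 1e3, M = 1e6, percent = NA_real_)

#' Convert a concentration to the canonical micromolar scale
#'
#' @param value Numeric concentration value(s), `>= 0`.
#' @param unit Unit tag(s), one of [concentration_units]. Percent (v/v)
#'   values are returned unchanged since they are not molar quantities.
#' @return Numeric vector: micromolar for molar units, the original value
#'   for `"percent"`.
#' @examples
#' canonical_concentration(2.6, "mM") # 2600
#' @export
canonical_concentration <- function(value, unit) {
  stopifnot(is.numeric(value), all(value >= 0 | is.na(value)))
  unit <- as.character(unit)
  bad <- setdiff(unique(unit), concentration_units)
  if (length(bad) > 0) {
    stop("unknown concentration unit(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(concentration_units, collapse = ", "), ")")
  }
  mult <- unname(.molar_to_uM[unit])
  ifelse(is.na(mult), value, value * mult)
}

#' Describe the experimental condition of one well
#'
#' A condition ties a well to its sensor strain, the applied inducer and
#' dose, the replicate index, and whether the well is a background control
#' (a strain carrying no reporter, used to measure autofluorescence).
#'
#' @param sensor Sensor (regulator) name, e.g. `"AraC"`; `NA` for control
#'   wells.
#' @param inducer Chemical added to the well; `"none"` when uninduced.
#' @param concentration Non-negative dose in `unit`.
#' @param unit One of [concentration_units].
#' @param replicate Positive integer replicate index.
#' @param is_control `TRUE` for background-autofluorescence control wells.
#' @param copy_number `"high"` or `"low"` plasmid copy number.
#' @return A one-row tibble of class `bs_condition`.
#' @export
condition <- function(sensor, inducer = "none", concentration = 0,
                      unit = "uM", replicate = 1L, is_control = FALSE,
                      copy_number = "high") {
  stopifnot(length(concentration) == 1, concentration >= 0,
            length(replicate) == 1, replicate >= 1,
            copy_number %in% c("high", "low"))
  canonical_concentration(concentration, unit) # unit validation
  if (isTRUE(is_control) && !is.na(sensor) && nzchar(sensor) && sensor != "control") {
    stop("control wells carry no sensor; use sensor = NA or \"control\"")
  }
  out <- tibble::tibble(
    sensor = as.character(sensor), inducer = as.character(inducer),
    concentration = as.numeric(concentration), unit = as.character(unit),
    replicate = as.integer(replicate), is_control = isTRUE(is_control),
    copy_number = as.character(copy_number)
  )
  class(out) <- c("bs_condition", class(out))
  out
}
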