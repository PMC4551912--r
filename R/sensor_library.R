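#' Published induction characteristics of six inducible systems
#'
#' Reference parameter set for six allosteric-transcription-factor
#' biosensors (AcuR/acrylate, AraC/arabinose, CdaR/glucarate,
#' MphR/erythromycin, TetR/anhydrotetracycline, TtgR/naringenin), each in
#' a high- and a low-copy plasmid implementation: fold induction, Hill
#' coefficient, lumped half-maximal parameter K_L, and maximum and basal
#' expression velocities (AFU OD^-1 s^-1). These rows parameterize the
#' synthetic-data generator and anchor parameter-recovery tests.
#'
#' Fold-induction entries flagged `fold_is_lower_bound` are minimum values
#' (the uninduced signal sat within the strain's autofluorescence, so only
#' a lower bound is defined). `mechanism` distinguishes transcriptional
#' activators from repressors. All reporters stop accumulating
#' fluorescence by the onset of stationary phase (activators reach their
#' maximum even earlier); the exception is AcuR, which keeps accumulating
#' after entry into stationary phase (`post_stationary_accumulation` in
#' [library_config()]).
#'
#' @return Tibble with one row per sensor x copy number.
#' @export
sensor_library <- function() {
  tibble::tribble(
    ~sensor, ~copy_number, ~inducer, ~mechanism,
    ~fold_induction, ~fold_se, ~fold_is_lower_bound,
    ~hill_h, ~hill_h_se, ~k_half, ~k_half_se, ~k_half_unit,
    ~v_max, ~v_max_se, ~v_min, ~v_min_se,
    "AcuR", "high", "acrylate", "repressor", 90, NA, TRUE,
    3.2, 0.3, 2.6, 0.1, "mM", 910, 40, 5, 7,
    "AcuR", "low", "acrylate", "repressor", 50, NA, TRUE,
    1.3, 0.1, 1.0, 0.1, "mM", 150, 10, 15, 2,
    "AraC", "high", "arabinose", "activator", 210, 9, FALSE,
    1.3, 0.1, 59, 3, "uM", 3150, 60, 20, 50,
    "AraC", "low", "arabinose", "activator", 29, 3, FALSE,
    1.3, 0.2, 250, 30, "uM", 1260, 50, 40, 30,
    "CdaR", "high", "glucarate", "activator", 168, 6, FALSE,
    1.0, 0.1, 490, 60, "uM", 2600, 100, 0, 60,
    "CdaR", "low", "glucarate", "activator", 78, 8, FALSE,
    1.0, 0.2, 8, 2, "mM", 1000, 100, 30, 20,
    "MphR", "high", "erythromycin", "repressor", 108, 9, FALSE,
    1.6, 0, 97, 2, "uM", 2070, 20, 9, 7,
    "MphR", "low", "erythromycin", "repressor", 8, 1, FALSE,
    1.6, 0.1, 22, 1, "uM", 66, 1, 5, 0.4,
    "TetR", "high", "aTC", "repressor", 63, 3, FALSE,
    4.2, 0.1, 81, 1, "nM", 1760, 10, 8, 6,
    "TetR", "low", "aTC", "repressor", 50, NA, TRUE,
    3.1, 0.3, 54, 2, "nM", 116, 2, 2, 1,
    "TtgR", "high", "naringenin", "repressor", 70, 20, FALSE,
    3.8, 0.6, 550, 50, "uM", 180, 6, 4, 3,
    "TtgR", "low", "naringenin", "repressor", 3, 0, FALSE,
    2.3, 0.4, 190, 20, "uM", 25, 1, 6, 1
  )
}

#' Default inducer concentration series for the library sensors
#'
#' Six-level dose series for each inducer, spaced in 2-fold (acrylate,
#' aTC) or 3-fold (others) increments and anchored at the concentrations
#' used in the original characterization experiments. Each series brackets
#' both the high- and low-copy half-maximal parameters of its sensor. The
#' 10 mM acrylate level is included in the series (it was part of the dose
#' panel) but is conventionally excluded from Hill fits because of its
#' growth toxicity; see `exclude` in [fit_hill()].
#'
#' @param inducer Optional inducer name to select one series.
#' @return Tibble with columns `inducer, concentration, unit`.
#' @export
inducer_series <- function(inducer = NULL) {
  ser <- dplyr::bind_rows(
    tibble::tibble(inducer = "acrylate",
                   concentration = 10 / 2^(5:0), unit = "mM"),
    tibble::tibble(inducer = "arabinose",
                   concentration = 1485 / 3^(5:0), unit = "uM"),
    tibble::tibble(inducer = "glucarate",
                   concentration = 40 / 3^(5:0), unit = "mM"),
    tibble::tibble(inducer = "erythromycin",
                   concentration = 1400 / 3^(5:0), unit = "uM"),
    tibble::tibble(inducer = "aTC",
                   concentration = 430 / 2^(5:0), unit = "nM"),
    tibble::tibble(inducer = "naringenin",
                   concentration = 9 / 3^(5:0), unit = "mM")
  )
  if (!is.null(inducer)) {
    ser <- ser[ser$inducer %in% inducer, ]
    if (nrow(ser) == 0) stop("no default series for inducer ", inducer)
  }
  ser
}

#' Default growth-inhibition parameters for the library chemicals
#'
#' Emulation of the observed dose-dependent growth effects: acrylate is
#' substantially toxic at 5-10 mM; naringenin is toxic from roughly
#' 330 uM; erythromycin (with the resistance gene expressed) and aTC show
#' only slight, solvent-attributable growth defects at the top doses;
#' arabinose and (mildly) glucarate increase growth rate because the cells
#' catabolize them.
#'
#' @return Tibble with columns `chemical, ic50, ic50_unit, steepness,
#'   max_inhibition, growth_benefit`.
#' @export
toxicity_library <- function() {
  tibble::tribble(
    ~chemical, ~ic50, ~ic50_unit, ~steepness, ~max_inhibition, ~growth_benefit,
    "acrylate", 6, "mM", 3, 0.9, 0,
    "arabinose", 500, "uM", 1, 0, 0.15,
    "glucarate", 20, "mM", 1, 0, 0.05,
    "erythromycin", 5, "mM", 2, 0.5, 0,
    "aTC", 600, "nM", 2, 0.3, 0,
    "naringenin", 1, "mM", 2, 0.7, 0,
    "IPTG", 100, "mM", 1, 0, 0,
    "rhamnose", 100, "mM", 1, 0, 0.05,
    "cumate", 1, "mM", 1, 0, 0,
    "DMSO", 4, "percent", 2, 0.8, 0,
    "ethanol", 4, "percent", 2, 0.8, 0.02
  )
}
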