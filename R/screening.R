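# Sensor-based ranking of enzyme variants.

#' Rank enzyme variants by sensor readout and check titer concordance
#'
#' Variants are ranked by descending mean endpoint fluorescence (ties
#' broken lexicographically by variant id). When titers are present, the
#' Spearman rank correlation between mean fluorescence and mean titer is
#' reported with its two-sided p-value — rank correlation, because the
#' sensor transfer function links titer to fluorescence monotonically
#' but not linearly. The dynamic range is the ratio of the highest to the
#' lowest mean fluorescence (undefined, `NA`, when the lowest mean is
#' non-positive).
#'
#' @param variants Tibble with columns `variant_id, fluorescence` and
#'   optionally `replicate` and `titer` (per-replicate rows are
#'   summarized to means; the coefficient of variation is reported when
#'   replicates >= 2).
#' @return Object of class `bs_screen`: `ranking` tibble (`rank,
#'   variant_id, mean_fluorescence, cv_fluorescence, mean_titer`),
#'   `top_variant`, `dynamic_range`, `spearman_rho`, `spearman_p`.
#' @export
rank_variants <- function(variants) {
  stopifnot(all(c("variant_id", "fluorescence") %in% names(variants)))
  if (!"titer" %in% names(variants)) variants$titer <- NA_real_
  summ <- variants |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      mean_fluorescence = mean(.data$fluorescence),
      cv_fluorescence = if (dplyr::n() >= 2)
        stats::sd(.data$fluorescence) / mean(.data$fluorescence)
      else NA_real_,
      mean_titer = mean(.data$titer),
      .groups = "drop")
  if (nrow(summ) < 2) stop("need at least 2 variants to rank")
  summ <- dplyr::arrange(summ, dplyr::desc(.data$mean_fluorescence),
                         .data$variant_id)
  summ$rank <- seq_len(nrow(summ))
  dr <- if (min(summ$mean_fluorescence) > 0) {
    max(summ$mean_fluorescence) / min(summ$mean_fluorescence)
  } else NA_real_
  rho <- p <- NA_real_
  if (!anyNA(summ$mean_titer)) {
    ct <- suppressWarnings(
      stats::cor.test(summ$mean_fluorescence, summ$mean_titer,
                      method = "spearman", alternative = "two.sided"))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(ranking = summ[c("rank", "variant_id", "mean_fluorescence",
                          "cv_fluorescence", "mean_titer")],
         top_variant = summ$variant_id[1], dynamic_range = dr,
         spearman_rho = rho, spearman_p = p),
    class = "bs_screen")
}

#' @export
print.bs_screen <- function(x, ...) {
  cat("<bs_screen> top variant:", x$top_variant, "\n")
  if (!is.na(x$dynamic_range)) {
    cat("  dynamic range:", signif(x$dynamic_range, 3), "\n")
  }
  if (!is.na(x$spearman_rho)) {
    cat("  fluorescence~titer Spearman rho:", signif(x$spearman_rho, 3),
        "(p =", signif(x$spearman_p, 3), ")\n")
  }
  print(x$ranking)
  invisible(x)
}
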