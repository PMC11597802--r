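#' Relative (treatment/control) indicator values
#'
#' Converts an indicator panel with paired control and treatment arms into
#' relative indicator values, the treatment-to-control ratio of each
#' measurement. Dividing out the control removes per-variety (or per-time)
#' baselines, so varieties with very different constitutive levels of, say,
#' proline or fresh weight become comparable before any ranking.
#'
#' @param panel A long data frame with columns `entity`, `indicator`,
#'   `arm` (`"control"` or `"treatment"`) and `value`. Replicate rows for
#'   the same (entity, indicator, arm) cell are averaged before the ratio
#'   is taken (mean-then-ratio).
#' @param orientation Named character vector mapping each indicator to
#'   `"larger_better"` or `"smaller_better"`; carried through unchanged as
#'   the `orientation` attribute of the result.
#'
#' @return A wide tibble with one row per entity, one column per indicator,
#'   holding treatment/control ratios; attribute `orientation` as supplied.
#'   Entities with a missing value in any arm are dropped with a warning.
#'
#' @examples
#' panel <- tibble::tibble(
#'   entity = rep(c("A", "B"), each = 4),
#'   indicator = rep(rep(c("height", "mda"), each = 2), 2),
#'   arm = rep(c("control", "treatment"), 4),
#'   value = c(10, 9, 2, 3, 12, 6, 2, 5)
#' )
#' relative_values(panel,
#'   orientation = c(height = "larger_better", mda = "smaller_better"))
#' @export
relative_values <- function(panel, orientation = NULL) {
  req <- c("entity", "indicator", "arm", "value")
  if (!all(req %in% names(panel))) {
    stop_input("`panel` needs columns %s.", paste(req, collapse = ", "))
  }
  bad_arm <- setdiff(unique(panel$arm), c("control", "treatment"))
  if (length(bad_arm)) {
    stop_input("Unknown arm label(s): %s.", paste(bad_arm, collapse = ", "))
  }

  agg <- panel |>
    dplyr::group_by(.data$entity, .data$indicator, .data$arm) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "value")
  if (!all(c("control", "treatment") %in% names(agg))) {
    stop_input("Both arms must be present in `panel`.")
  }

  bad <- agg |>
    dplyr::filter(!is.na(.data$control) & .data$control <= 0)
  if (nrow(bad) > 0) {
    stop_input(
      "Non-positive control value(s); cannot form ratios for: %s.",
      paste(sprintf("%s/%s", bad$entity, bad$indicator), collapse = ", ")
    )
  }

  rel <- agg |>
    dplyr::mutate(value = .data$treatment / .data$control) |>
    dplyr::select("entity", "indicator", "value") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value")

  dropped <- rel$entity[!complete.cases(rel)]
  if (length(dropped)) {
    warn(sprintf(
      "Dropping %d entit%s with missing values: %s.",
      length(dropped), if (length(dropped) == 1) "y" else "ies",
      paste(dropped, collapse = ", ")
    ))
    rel <- rel[complete.cases(rel), , drop = FALSE]
  }
  attr(rel, "orientation") <- orientation
  rel
}

#' Growth rate and biomass accumulation
#'
#' Derives the two composite growth metrics used alongside direct
#' measurements in cold/salt screening: relative height growth over the
#' treatment window and the fresh-weight gain.
#'
#' @param height_d1,height_d10 Plant height at the start and end of the
#'   10-day window (same units).
#' @param fw_d1,fw_d10 Fresh weight at the start and end of the window.
#' @param denominator Which height normalises the growth rate: `"initial"`
#'   (day-1 height, the default) or `"final"` (day-10 height).
#'
#' @return A tibble with columns `growth_rate` (dimensionless) and
#'   `biomass_accumulation` (fresh-weight units). Inputs are vectorised.
#' @examples
#' derive_growth_metrics(10, 15, 2, 3.5)
#' @export
derive_growth_metrics <- function(height_d1, height_d10, fw_d1, fw_d10,
                                  denominator = c("initial", "final")) {
  denominator <- match.arg(denominator)
  if (any(height_d1 <= 0)) stop_input("`height_d1` must be strictly positive.")
  den <- if (denominator == "initial") height_d1 else height_d10
  if (any(den <= 0)) stop_input("Growth-rate denominator must be positive.")
  tibble::tibble(
    growth_rate = (height_d10 - height_d1) / den,
    biomass_accumulation = fw_d10 - fw_d1
  )
}
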