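#' Minimum inhibitory concentration from a two-fold dilution series
#'
#' The MIC is the lowest concentration at which no growth is detected,
#' with all higher concentrations also growth-free. Growth at the top
#' concentration yields an above-range result (reported as
#' `"> <top> uM"`), the outcome when a peptide shows no activity even at
#' the highest concentration tested. A no-growth well sitting below a
#' growth well (a skipped-well anomaly) is flagged, and the MIC is taken
#' conservatively from the contiguous no-growth run starting at the top
#' concentration.
#'
#' @param concentrations Strictly descending two-fold series in uM
#'   (each step within 1% of halving).
#' @param growth Logical vector, `TRUE` where growth was detected, same
#'   length as `concentrations`.
#' @return A one-row tibble: `mic_um` (NA when above range), `mic_label`,
#'   `above_range`, `anomaly`.
#' @export
#' @examples
#' mic(c(512, 256, 128, 64), growth = c(FALSE, FALSE, FALSE, TRUE))
mic <- function(concentrations, growth) {
  if (length(concentrations) == 0) abort("`concentrations` must be non-empty.")
  if (length(growth) != length(concentrations)) {
    abort("`growth` must match `concentrations` in length.")
  }
  if (any(is.na(concentrations)) || any(is.na(growth))) {
    abort("Missing values are not allowed in a dilution series.")
  }
  if (any(diff(concentrations) >= 0)) {
    abort("`concentrations` must be strictly descending.")
  }
  ratio <- concentrations[-1] / head(concentrations, -1)
  if (any(abs(ratio - 0.5) > 0.005)) {
    abort("Not a two-fold series: each step must halve the previous (within 1%).")
  }

  # anomaly: growth somewhere above a no-growth well
  anomaly <- any(vapply(seq_along(growth), function(i) {
    !growth[i] && any(growth[seq_len(i - 1L)])
  }, logical(1)))

  if (growth[1]) {
    return(tibble(
      mic_um = NA_real_,
      mic_label = sprintf("> %g uM", concentrations[1]),
      above_range = TRUE, anomaly = anomaly
    ))
  }
  run_end <- if (any(growth)) which(growth)[1] - 1L else length(growth)
  tibble(
    mic_um = concentrations[run_end],
    mic_label = sprintf("%g uM", concentrations[run_end]),
    above_range = FALSE, anomaly = anomaly
  )
}

#' Percent cytotoxicity from optical densities
#'
#' The neutral-red viability readout: 100 * (OD_obs - OD_0) /
#' (OD_100 - OD_0), where OD_0 is the negative-control (0% cytotoxicity)
#' mean and OD_100 the full-lysis positive-control mean. In this assay OD
#' falls as cells die, so OD_100 < OD_0 and the formula is applied
#' sign-agnostically, exactly as written. Noisy wells may legitimately
#' fall outside [0, 100]; values are returned unclamped — see
#' [cytotoxicity_table()] for a clamped companion column.
#'
#' @param od_obs Observed OD (vectorised).
#' @param od0 Negative-control OD (0% cytotoxicity).
#' @param od100 Positive-control OD (100% cytotoxicity); must differ from
#'   `od0`.
#' @return Percent cytotoxicity, unclamped.
#' @export
#' @examples
#' cytotoxicity_percent(0.5, od0 = 0.8, od100 = 0.2)  # 50
cytotoxicity_percent <- function(od_obs, od0, od100) {
  if (length(od0) != 1L || length(od100) != 1L) {
    abort("`od0` and `od100` must be single control means.")
  }
  if (isTRUE(all.equal(od0, od100))) {
    abort("Degenerate controls: od0 equals od100.")
  }
  100 * (od_obs - od0) / (od100 - od0)
}

#' Per-well cytotoxicity table
#'
#' Applies [cytotoxicity_percent()] to a plate table and reports both the
#' raw (unclamped) percentage and a [0, 100]-clamped companion column.
#'
#' @param plate Data frame with a column `od_obs` (other columns carried
#'   through).
#' @param od0,od100 Control means, as in [cytotoxicity_percent()].
#' @return The input tibble plus `cytotox_pct` and `cytotox_pct_clamped`.
#' @export
cytotoxicity_table <- function(plate, od0, od100) {
  plate <- as_tibble(plate)
  if (!"od_obs" %in% names(plate)) abort("`plate` needs an `od_obs` column.")
  mutate(plate,
         cytotox_pct = cytotoxicity_percent(.data$od_obs, od0, od100),
         cytotox_pct_clamped = pmin(pmax(.data$cytotox_pct, 0), 100))
}
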