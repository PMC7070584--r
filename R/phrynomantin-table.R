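#' Published phrynomantin peptide panel
#'
#' The 19 peptides predicted from *Phrynomantis bifasciatus* and
#' *P. microps* skin transcripts, as published: sequence, amidation flag,
#' and the reported molecular weight (Da), net charge at pH 7, GRAVY and
#' percent helicity. Three peptides were additionally confirmed in the
#' secretion by LC-MS (`lcms_confirmed`). Useful as a reference input for
#' [peptide_properties()] and as a regression anchor: recomputing the
#' panel from the sequences reproduces the reported values (the
#' phrynomantin-1Ba GRAVY entry differs by 0.01 from the
#' Kyte-Doolittle mean, a rounding/tool artefact in the published table).
#'
#' @return A tibble with columns `peptide`, `seq`, `amidated`, `length`,
#'   `mw_reported`, `net_charge_reported`, `gravy_reported`,
#'   `helicity_pct_reported`, `lcms_confirmed`.
#' @export
#' @examples
#' head(phrynomantin_table())
phrynomantin_table <- function() {
  path <- system.file("extdata", "phrynomantin_panel.tsv",
                      package = "fsapminer", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    peptide = "c", seq = "c", amidated = "l", length = "i",
                    mw_reported = "d", net_charge_reported = "i",
                    gravy_reported = "d", helicity_pct_reported = "d",
                    lcms_confirmed = "l"
                  ))
}
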