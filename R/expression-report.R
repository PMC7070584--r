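#' Summarise expression by protein family
#'
#' Aggregates a contig-level expression table into the family summary a
#' transcriptome survey prints: per family, the number of transcript
#' contigs and the summed expression in transcripts per million (TPM).
#' Family labels come from an annotation table (typically a homology
#' screen performed upstream); contigs without a label are excluded from
#' the family rows and reported in a single `(unannotated)` remainder row,
#' so total TPM is conserved.
#'
#' @param records Data frame with columns `contig_id`, `tpm` and `family`
#'   (NA for unannotated contigs).
#' @return A tibble with columns `family`, `n_contigs`, `sum_tpm`;
#'   family rows sorted by decreasing `sum_tpm`, remainder row last.
#' @export
#' @examples
#' aggregate_family_tpm(data.frame(
#'   contig_id = c("c1", "c2", "c3"), tpm = c(1, 2.5, 96.5),
#'   family = c("FSAP", "FSAP", "FSAP")
#' ))
aggregate_family_tpm <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(family = character(), n_contigs = integer(),
                  sum_tpm = numeric()))
  }
  if (!all(c("contig_id", "tpm", "family") %in% names(records))) {
    abort("`records` needs columns `contig_id`, `tpm`, `family`.")
  }
  dup <- records$contig_id[duplicated(records$contig_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate contig_id(s): %s — collapse redundant contigs upstream.",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (any(records$tpm < 0, na.rm = TRUE)) abort("`tpm` must be non-negative.")

  fam <- records |>
    filter(!is.na(.data$family)) |>
    group_by(.data$family) |>
    summarise(n_contigs = dplyr::n(), sum_tpm = sum(.data$tpm),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$sum_tpm))
  rest <- filter(records, is.na(.data$family))
  if (nrow(rest) > 0) {
    fam <- bind_rows(fam, tibble(family = "(unannotated)",
                                 n_contigs = nrow(rest),
                                 sum_tpm = sum(rest$tpm)))
  }
  fam
}

#' Count contigs above an expression threshold
#'
#' Number of records with TPM strictly greater than `thr` — the
#' "expression levels above 100 TPM" convention of skewed-library
#' summaries.
#'
#' @param records Data frame with a `tpm` column.
#' @param thr Threshold in TPM (default 100).
#' @return Integer count.
#' @export
#' @examples
#' count_above_threshold(data.frame(tpm = c(99, 100, 101)))  # 1
count_above_threshold <- function(records, thr = 100) {
  .assert_number(thr, "thr", min = 0)
  records <- as_tibble(records)
  if (nrow(records) == 0) return(0L)
  if (!"tpm" %in% names(records)) abort("`records` needs a `tpm` column.")
  sum(records$tpm > thr)
}
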