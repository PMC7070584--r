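#' Default pipeline configuration
#'
#' All stage parameters in one serialisable list. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' The pipeline's `min_nt` default is 132 rather than the 150 used when
#' translating a library for text search: precursors of this superfamily
#' run as short as 44 residues, i.e. a 135-nt span including the stop
#' codon, which a 150-nt cutoff would silently discard.
#'
#' @param ... Overrides for: `min_nt` (ORF span cutoff, nt), `strands`,
#'   `signal` ("builtin" or an external call table), `min_core_hydropathy`,
#'   `de_spacer`, `de_acidic`, `min_peptide_len`, `include_low_confidence`,
#'   `ms_tol` (m/z), `z_min`, `z_max`, `mz_window`, `tpm_threshold`.
#' @return A named list of class `fsap_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_nt = 132L, strands = c("+", "-"),
    signal = "builtin", min_core_hydropathy = 2.0,
    de_spacer = 0.30, de_acidic = 0.30,
    min_peptide_len = 4L, include_low_confidence = FALSE,
    ms_tol = 0.5, z_min = 1L, z_max = 3L, mz_window = c(100, 3000),
    tpm_threshold = 100
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown pipeline config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  defaults[names(dots)] <- dots
  structure(defaults, class = "fsap_pipeline_config")
}

#' Run the peptide-discovery pipeline end to end
#'
#' Contigs to confirmed peptides in one call: ORF finding and
#' translation, precursor annotation (signal peptide, cleavage motifs,
#' spacer classification), mature-peptide prediction, the physicochemical
#' property panel, optional LC-MS confirmation against a peak list, and
#' an optional per-family expression summary. Deterministic given the
#' inputs and config; every stage's output is kept on the returned object
#' so stages can be inspected or rerun individually.
#'
#' @param contigs Data frame with `contig_id`, `seq_nt` and optionally
#'   `tpm` (e.g. from [read_contigs()] or
#'   [generate_transcriptome()]`$contigs`).
#' @param peaks Optional LC-MS peak list (data frame with `mz`) for
#'   confirmation.
#' @param annotation Optional family annotation (data frame with
#'   `contig_id`, `family`) for the expression summary.
#' @param config A [pipeline_config()].
#' @return An object of class `fsap_run` with elements `config`, `orfs`,
#'   `annotations`, `peptides`, `properties`, `ms` (or NULL), `family_report`
#'   (or NULL), `expression_above_threshold` (or NA), and `manifest`.
#' @export
#' @examples
#' tx <- generate_transcriptome(2, 6, seed = 1)
#' run <- run_pipeline(tx$contigs, annotation = tx$annotation)
#' glance(run)
run_pipeline <- function(contigs, peaks = NULL, annotation = NULL,
                         config = pipeline_config()) {
  if (!inherits(config, "fsap_pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  contigs <- as_tibble(contigs)

  orfs <- find_orfs(contigs, min_nt = config$min_nt, strands = config$strands)

  annotations <- annotate_precursors(
    orfs |> rename(protein_id = "orf_id"),
    signal = config$signal,
    min_core_hydropathy = config$min_core_hydropathy,
    de_spacer = config$de_spacer, de_acidic = config$de_acidic
  )
  with_signal <- filter(annotations, !is.na(.data$signal_pos))
  peptides <- predict_peptides(with_signal, min_len = config$min_peptide_len)
  if (!config$include_low_confidence) {
    peptides <- filter(peptides, .data$confidence == "normal")
  }
  peptides <- peptides |>
    mutate(peptide = sprintf("%s|pep%d", .data$precursor_id, .data$ordinal))

  properties <- peptide_properties(peptides)

  ms <- if (!is.null(peaks)) {
    match_peaks(peptides, peaks, tol = config$ms_tol,
                z_min = config$z_min, z_max = config$z_max,
                mz_window = config$mz_window)
  } else NULL

  family_report <- NULL
  above <- NA_integer_
  if ("tpm" %in% names(contigs)) {
    above <- count_above_threshold(contigs, thr = config$tpm_threshold)
    if (!is.null(annotation)) {
      records <- contigs |>
        select("contig_id", "tpm") |>
        left_join(as_tibble(annotation), by = "contig_id")
      family_report <- aggregate_family_tpm(records)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fsapminer")),
    config = unclass(config),
    n_contigs = nrow(contigs),
    contig_hash = rlang::hash(contigs),
    peaks_hash = if (is.null(peaks)) NA_character_ else rlang::hash(as_tibble(peaks)),
    annotation_hash = if (is.null(annotation)) NA_character_ else
      rlang::hash(as_tibble(annotation)),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  out <- list(
    config = config, orfs = orfs, annotations = annotations,
    peptides = peptides, properties = properties, ms = ms,
    family_report = family_report, expression_above_threshold = above,
    manifest = manifest
  )
  class(out) <- "fsap_run"
  out
}

#' @export
print.fsap_run <- function(x, ...) {
  cat("<fsap_run>\n")
  cat(sprintf("  contigs: %d   ORFs: %d   precursors with signal: %d\n",
              x$manifest$n_contigs, nrow(x$orfs),
              sum(!is.na(x$annotations$signal_pos))))
  cat(sprintf("  predicted peptides: %d (%d amidated)\n",
              nrow(x$peptides), sum(x$peptides$amidated)))
  if (!is.null(x$ms)) {
    cat(sprintf("  LC-MS confirmed: %d/%d\n",
                sum(x$ms$summary$confirmed), nrow(x$ms$summary)))
  }
  invisible(x)
}

#' Tidy the per-peptide results of a pipeline run
#'
#' One row per predicted peptide with its property panel and, when a peak
#' list was supplied, its LC-MS confirmation status.
#'
#' @param x An `fsap_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fsap_run
#' @export
tidy.fsap_run <- function(x, ...) {
  out <- x$peptides |>
    left_join(x$properties |>
                select(-"seq", -"amidated"), by = "peptide")
  if (!is.null(x$ms)) {
    out <- left_join(out,
                     x$ms$summary |> select("peptide", "confirmed", "n_matches"),
                     by = "peptide")
  }
  out
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.fsap_run
#' @return A one-row tibble with stage-level counts.
#' @method glance fsap_run
#' @export
glance.fsap_run <- function(x, ...) {
  tibble(
    n_contigs = x$manifest$n_contigs,
    n_orfs = nrow(x$orfs),
    n_signal_calls = sum(!is.na(x$annotations$signal_pos)),
    n_peptides = nrow(x$peptides),
    n_amidated = sum(x$peptides$amidated),
    n_confirmed = if (is.null(x$ms)) NA_integer_ else
      sum(x$ms$summary$confirmed),
    n_above_tpm_threshold = x$expression_above_threshold
  )
}

#' Write a pipeline run's reports to a directory
#'
#' Emits plain-text deliverables: `peptides.tsv`, `properties.tsv`,
#' `precursors.faa`, and where available `ms_matches.tsv`,
#' `family_report.tsv`, plus `manifest.txt` (resolved config, input
#' hashes, package version).
#'
#' @param run An `fsap_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "fsap_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$peptides, file.path(dir, "peptides.tsv"))
  readr::write_tsv(run$properties, file.path(dir, "properties.tsv"))
  with_signal <- filter(run$annotations, !is.na(.data$signal_pos))
  if (nrow(with_signal) > 0) {
    write_protein_fasta(with_signal, file.path(dir, "precursors.faa"))
  }
  if (!is.null(run$ms)) {
    readr::write_tsv(run$ms$matches, file.path(dir, "ms_matches.tsv"))
    readr::write_tsv(run$ms$summary, file.path(dir, "ms_summary.tsv"))
  }
  if (!is.null(run$family_report)) {
    readr::write_tsv(run$family_report, file.path(dir, "family_report.tsv"))
  }
  m <- run$manifest
  cfg <- vapply(m$config, function(v) paste(format(v), collapse = ","),
                character(1))
  writeLines(c(
    sprintf("package_version\t%s", m$package_version),
    sprintf("n_contigs\t%d", m$n_contigs),
    sprintf("contig_hash\t%s", m$contig_hash),
    sprintf("peaks_hash\t%s", m$peaks_hash),
    sprintf("annotation_hash\t%s", m$annotation_hash),
    sprintf("timestamp\t%s", m$timestamp),
    sprintf("config.%s\t%s", names(cfg), cfg)
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}
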