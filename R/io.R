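# Plain-text interchange: FASTA via Biostrings, tables via readr.
# Every intermediate the pipeline writes is re-readable by these functions,
# so each stage can be rerun from disk.

#' Write a synthetic transcriptome to disk
#'
#' Emits `contigs.fasta`, `expression.tsv` (contig_id, tpm),
#' `annotation.tsv` (contig_id, family), and the ground-truth sidecars
#' `ground_truth_peptides.tsv` and `ground_truth_precursors.tsv`.
#' Output is byte-deterministic for a given object.
#'
#' @param x A `fsap_synthetic_transcriptome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_transcriptome <- function(x, dir) {
  stopifnot(inherits(x, "fsap_synthetic_transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(setNames(x$contigs$seq_nt, x$contigs$contig_id))
  Biostrings::writeXStringSet(dna, file.path(dir, "contigs.fasta"), width = 70L)
  readr::write_tsv(x$contigs[, c("contig_id", "tpm")],
                   file.path(dir, "expression.tsv"))
  readr::write_tsv(x$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(x$truth, file.path(dir, "ground_truth_peptides.tsv"))
  readr::write_tsv(x$precursor_meta, file.path(dir, "ground_truth_precursors.tsv"))
  invisible(dir)
}

#' Read contigs from FASTA with an optional expression table
#'
#' @param fasta Path to a contig FASTA file.
#' @param expression Optional path to a tab-delimited table with columns
#'   `contig_id` and `tpm`.
#' @return A tibble with `contig_id`, `seq_nt` and, when supplied, `tpm`.
#' @export
read_contigs <- function(fasta, expression = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  out <- tibble(
    contig_id = sub("\\s.*$", "", names(dna)),
    seq_nt = unname(as.character(dna))
  )
  if (!is.null(expression)) {
    expr <- readr::read_tsv(expression, show_col_types = FALSE)
    if (!all(c("contig_id", "tpm") %in% names(expr))) {
      abort("Expression table needs columns `contig_id` and `tpm`.")
    }
    out <- left_join(out, expr[, c("contig_id", "tpm")], by = "contig_id")
  }
  out
}

#' Write a peptide table as protein FASTA
#'
#' @param peptides Data frame with an id column (first argument of
#'   `id_col`) and a sequence column `seq_col`.
#' @param path Output FASTA path.
#' @param id_col,seq_col Column names to use.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(peptides, path, id_col = "protein_id",
                                seq_col = "aa_seq") {
  aa <- Biostrings::AAStringSet(
    setNames(as.character(peptides[[seq_col]]),
             as.character(peptides[[id_col]]))
  )
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read a protein FASTA into a tibble
#'
#' @param path FASTA path.
#' @return A tibble with `protein_id` and `aa_seq`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(protein_id = sub("\\s.*$", "", names(aa)),
         aa_seq = unname(as.character(aa)))
}

#' Write / read an LC-MS peak list
#'
#' Peak lists are tab-delimited with columns `rt_min`, `mz`, `intensity`.
#'
#' @param x For writing: a `fsap_synthetic_peaks` object or a data frame
#'   of peaks.
#' @param path File path.
#' @return `path` (write) or a tibble of peaks (read).
#' @export
write_peak_list <- function(x, path) {
  peaks <- if (inherits(x, "fsap_synthetic_peaks")) x$peaks else as_tibble(x)
  readr::write_tsv(peaks, path)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  pk <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"mz" %in% names(pk)) abort("Peak list needs an `mz` column.")
  pk
}
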