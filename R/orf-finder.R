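# codon table: standard genetic code, extended so that a codon containing N
# still translates when every resolution agrees (e.g. GGN -> G), else X
.codon_table <- local({
  base <- Biostrings::GENETIC_CODE
  tab <- as.character(base)
  names(tab) <- names(base)
  tab
})

.translate_codon <- function(codon) {
  aa <- .codon_table[codon]
  if (!is.na(aa)) return(unname(aa))
  if (grepl("N", codon, fixed = TRUE)) {
    pos <- gregexpr("N", codon, fixed = TRUE)[[1]]
    combos <- expand.grid(rep(list(c("A", "C", "G", "T")), length(pos)),
                          stringsAsFactors = FALSE)
    res <- apply(combos, 1L, function(subs) {
      cc <- strsplit(codon, "", fixed = TRUE)[[1]]
      cc[pos] <- subs
      .codon_table[paste(cc, collapse = "")]
    })
    if (length(unique(res)) == 1L) return(unname(res[1])) else return("X")
  }
  "X"
}

#' Translate a nucleotide sequence
#'
#' Codon-by-codon translation under the standard genetic code; stop codons
#' render as `*`. Codons containing `N` translate to the unambiguous amino
#' acid when all resolutions agree (e.g. `GGN` is Gly) and to `X`
#' otherwise.
#'
#' @param seq_nt Nucleotide string over ACGTN (case-insensitive); length
#'   must be a multiple of 3.
#' @return Amino-acid string (with `*` for stops).
#' @export
#' @examples
#' translate_nt("ATGAAACGT")  # "MKR"
translate_nt <- function(seq_nt) {
  if (length(seq_nt) != 1L || is.na(seq_nt)) {
    abort("`seq_nt` must be a single string.")
  }
  s <- toupper(seq_nt)
  n <- nchar(s)
  if (n %% 3 != 0) {
    abort(sprintf("Sequence length (%d) is not divisible by 3.", n))
  }
  if (n == 0) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table[codons]
  miss <- which(is.na(aa))
  if (length(miss) > 0) {
    aa[miss] <- vapply(codons[miss], .translate_codon, character(1))
  }
  paste(aa, collapse = "")
}

.revcomp <- function(seq_nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_nt)))
}

.validate_contig_seq <- function(seq_nt, contig_id) {
  s <- toupper(seq_nt)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0) {
    abort(sprintf(
      "Contig '%s' has a non-ACGTN character ('%s') at offset %d.",
      contig_id, substr(s, bad, bad), as.integer(bad) - 1L
    ))
  }
  s
}

# ORFs in one orientation of a single sequence; coordinates in that
# orientation, 0-based half-open, stop codon included in the span
.orfs_one_strand <- function(s, min_nt, all_orfs) {
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    sub <- substr(s, frame + 1L, frame + 3L * ncod)
    aa <- strsplit(translate_nt(sub), "", fixed = TRUE)[[1]]
    stops <- which(aa == "*")
    starts <- which(aa == "M")
    prev <- 0L
    for (st in stops) {
      ms <- starts[starts > prev & starts < st]
      if (length(ms) > 0) {
        use <- if (all_orfs) ms else ms[1]
        for (m in use) {
          span_nt <- (st - m + 1L) * 3L
          if (span_nt > min_nt) {
            res[[length(res) + 1L]] <- list(
              frame = frame,
              start = frame + (m - 1L) * 3L,
              end = frame + st * 3L,
              aa_seq = paste(aa[m:(st - 1L)], collapse = "")
            )
          }
        }
      }
      prev <- st
    }
  }
  res
}

#' Find open reading frames in transcript contigs
#'
#' Scans contigs for ATG-initiated, stop-terminated reading frames whose
#' nucleotide span (stop codon included) strictly exceeds `min_nt` — the
#' "> 150 bp" convention of transcriptome peptide screens. Both strands
#' are scanned by default because contig orientation after de novo assembly
#' is not guaranteed. By default only the longest ORF per (strand, frame,
#' stop codon) is reported, i.e. the first in-frame ATG after the previous
#' stop; set `all_orfs = TRUE` to emit every internal ATG as well.
#'
#' Coordinates are 0-based half-open on the input strand, for minus-strand
#' ORFs too. Codons containing N translate to X and such ORFs are still
#' reported, flagged via `has_ambiguous`.
#'
#' @param contigs Data frame with columns `contig_id` and `seq_nt`
#'   (ACGTN alphabet); a `tpm` column, when present, is carried through.
#' @param min_nt Strict lower bound on the nucleotide span (default 150).
#' @param strands Character subset of `c("+", "-")`.
#' @param all_orfs Report every internal ATG, not just the longest ORF per
#'   stop codon.
#' @return A tibble with columns `contig_id`, `orf_id`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `aa_seq`, `has_ambiguous`, and `tpm` when
#'   supplied; sorted by contig, then (strand, nt_start).
#' @export
#' @examples
#' contigs <- data.frame(contig_id = "c1",
#'                       seq_nt = paste0("AAAA", "ATGAAACGTAAACGTTAA", "AA"))
#' find_orfs(contigs, min_nt = 12)
find_orfs <- function(contigs, min_nt = 150L, strands = c("+", "-"),
                      all_orfs = FALSE) {
  min_nt <- .assert_count(min_nt, "min_nt", min = 3L)
  if (!all(strands %in% c("+", "-")) || length(strands) == 0) {
    abort("`strands` must be a non-empty subset of c(\"+\", \"-\").")
  }
  contigs <- as_tibble(contigs)
  if (!all(c("contig_id", "seq_nt") %in% names(contigs))) {
    abort("`contigs` needs columns `contig_id` and `seq_nt`.")
  }
  has_tpm <- "tpm" %in% names(contigs)

  rows <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    id <- as.character(contigs$contig_id[i])
    s <- .validate_contig_seq(contigs$seq_nt[i], id)
    L <- nchar(s)
    out <- list()
    for (strand in strands) {
      oriented <- if (strand == "+") s else .revcomp(s)
      found <- .orfs_one_strand(oriented, min_nt, all_orfs)
      for (o in found) {
        if (strand == "+") {
          nt_start <- o$start; nt_end <- o$end
        } else {
          nt_start <- L - o$end; nt_end <- L - o$start
        }
        out[[length(out) + 1L]] <- tibble(
          contig_id = id,
          strand = strand,
          frame = o$frame,
          nt_start = nt_start,
          nt_end = nt_end,
          aa_seq = o$aa_seq,
          has_ambiguous = grepl("X", o$aa_seq, fixed = TRUE),
          tpm = if (has_tpm) as.numeric(contigs$tpm[i]) else NA_real_
        )
      }
    }
    if (length(out) == 0) NULL else bind_rows(out)
  })

  if (nrow(rows) == 0) {
    rows <- tibble(
      contig_id = character(), strand = character(), frame = integer(),
      nt_start = integer(), nt_end = integer(), aa_seq = character(),
      has_ambiguous = logical(), tpm = numeric()
    )
  }
  rows <- rows |>
    arrange(.data$contig_id, .data$strand, .data$nt_start) |>
    mutate(orf_id = sprintf("%s|%s|%d|%d-%d", .data$contig_id, .data$strand,
                            .data$frame, .data$nt_start, .data$nt_end)) |>
    select("contig_id", "orf_id", "strand", "frame", "nt_start", "nt_end",
           "aa_seq", "has_ambiguous", dplyr::any_of(if (has_tpm) "tpm" else character()))
  rows
}
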