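# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different machinery than the package code paths
# they check (Biostrings translation, regex ORF scans, direct mismatch
# counting), so agreement is evidence rather than tautology.

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# translation oracle: Biostrings, fuzzy codons resolved where unambiguous
oracle_translate <- function(seq_nt) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq_nt),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
}

# ORF oracle: regex scan of each translated frame. "M[^*]*\\*" picks, per
# stop codon, the first in-frame Met after the previous stop — i.e. the
# longest ATG-initiated ORF per (strand, frame, stop). All six frames are
# translated in one Biostrings call.
oracle_find_orfs <- function(seq_nt, min_nt = 150L, strands = c("+", "-")) {
  seq_nt <- toupper(seq_nt)
  L <- nchar(seq_nt)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_nt)))
  frames <- list()
  meta <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq_nt else rc
    for (frame in 0:2) {
      ncod <- (nchar(s) - frame) %/% 3
      if (ncod < 2) next
      frames[[length(frames) + 1L]] <- substr(s, frame + 1L, frame + 3L * ncod)
      meta[[length(meta) + 1L]] <- list(strand = strand, frame = frame)
    }
  }
  if (length(frames) == 0) {
    return(data.frame(strand = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  aas <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unlist(frames)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  rows <- list()
  for (f in seq_along(aas)) {
    aa <- aas[f]
    strand <- meta[[f]]$strand
    frame <- meta[[f]]$frame
    m <- gregexpr("M[^*]*\\*", aa)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      span_nt <- 3L * len[k]
      if (span_nt <= min_nt) next
      start_s <- frame + (as.integer(m[k]) - 1L) * 3L
      end_s <- start_s + span_nt
      if (strand == "+") {
        nt_start <- start_s; nt_end <- end_s
      } else {
        nt_start <- L - end_s; nt_end <- L - start_s
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, frame = frame,
        nt_start = nt_start, nt_end = nt_end,
        aa_seq = substr(aa, as.integer(m[k]), as.integer(m[k]) + len[k] - 2L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$strand, c("+", "-")), out$nt_start), , drop = FALSE]
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# direct <=1-mismatch scan of a protein for a query, as an alternative to
# searching with the expanded variant library
oracle_scan_1mm <- function(query, protein) {
  L <- nchar(query); n <- nchar(protein)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (off in 0:(n - L)) {
    win <- substr(protein, off + 1L, off + L)
    if (hamming(query, win) <= 1) hits <- c(hits, off)
  }
  hits
}

# contig with exactly one plus-strand ORF: ATG + n_codons non-stop codons
# + TAA, embedded in flanks free of interfering reading frames
make_orf_contig <- function(n_codons, flank5 = 11L, flank3 = 10L) {
  body <- paste(rep("GCT", n_codons), collapse = "")  # Ala codons, no stops
  paste0(
    paste(rep("C", flank5), collapse = ""),
    "ATG", body, "TAA",
    paste(rep("C", flank3), collapse = "")
  )
}

# assemble a protein from explicit architecture parts (for rule-trace tests)
make_protein <- function(signal, ...) paste0(signal, ...)

SIGNAL_FIXTURE <- "MKTLLLIVLLFIGTQQ"  # Met + 15 aa: hydrophobic core, no AGSC
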