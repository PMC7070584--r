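# Seeded generator of transcriptome-like inputs with known ground truth.
#
# The generator emulates what the downstream stages consume: Trinity-style
# contig FASTA with a heavily skewed TPM profile, in which a handful of
# contigs embed FSAP-like precursor CDS (signal peptide + acidic spacer +
# 1-3 tandem peptides bounded by KR/RR/RXXR, precursor length 44-110 aa,
# optional Gly amidation donor), surrounded by decoy contigs.

.SIGNAL_PRE_POOL <- c("K", "N", "T", "Q")
.SIGNAL_CORE_POOL <- c("L", "I", "V", "F")
.SIGNAL_TAIL_POOL <- c("T", "N", "Q", "Y", "H")
.SPACER_LIGHT_POOL <- c("N", "S", "Q", "T", "P", "A", "L", "V")
# composition loosely matching reported frog skin peptides
.PEPTIDE_POOL <- c(
  G = 3, L = 4, V = 3, P = 2, D = 2, E = 1, N = 2, S = 2, T = 1,
  A = 1, F = 1, Y = 1, W = 0.5, K = 1, R = 1, Q = 0.5, I = 1, M = 0.2,
  H = 0.3, C = 0.2
)
.MOTIF_TYPES <- c(KR = 0.4, RR = 0.4, RXXR = 0.2)

.sample_chars <- function(pool, n, weights = NULL) {
  if (is.null(weights)) {
    paste(sample(pool, n, replace = TRUE), collapse = "")
  } else {
    paste(sample(pool, n, replace = TRUE, prob = weights), collapse = "")
  }
}

.sample_signal <- function() {
  pre <- .sample_chars(.SIGNAL_PRE_POOL, .sample_range(2L, 4L))
  core <- .sample_chars(.SIGNAL_CORE_POOL, .sample_range(10L, 14L))
  tail <- .sample_chars(.SIGNAL_TAIL_POOL, .sample_range(2L, 5L))
  paste0("M", pre, core, tail)
}

.sample_spacer <- function(len_range, min_de) {
  for (i in 1:200) {
    n <- .sample_range(len_range[1], len_range[2])
    body <- vapply(seq_len(n - 1L), function(j) {
      if (runif(1) < 0.75) sample(c("D", "E"), 1) else
        sample(.SPACER_LIGHT_POOL, 1)
    }, character(1))
    sp <- paste0("S", paste(body, collapse = ""))
    chars <- strsplit(sp, "", fixed = TRUE)[[1]]
    if (mean(chars %in% c("D", "E")) >= min_de &&
        classify_segment(sp) == "spacer") {
      return(sp)
    }
  }
  abort("Could not sample a spacer satisfying the acidity constraint.")
}

.has_motif <- function(seq) {
  grepl("KR|RR|R[^R]{2}R", seq, perl = TRUE)
}

.sample_peptide <- function(len_range) {
  pool <- names(.PEPTIDE_POOL)
  w <- unname(.PEPTIDE_POOL)
  edge_pool <- setdiff(pool, c("K", "R"))
  edge_w <- w[match(edge_pool, pool)]
  for (i in 1:500) {
    n <- .sample_range(len_range[1], len_range[2])
    chars <- character(n)
    for (j in seq_len(n)) {
      if (j <= 3 || j > n - 3) {
        chars[j] <- sample(edge_pool, 1, prob = edge_w)
      } else {
        chars[j] <- sample(pool, 1, prob = w)
      }
    }
    p <- paste(chars, collapse = "")
    if (endsWith(p, "G")) next
    if (.has_motif(p)) next
    if (classify_segment(p) != "peptide-candidate") next
    return(p)
  }
  abort("Could not sample a peptide under the boundary/motif constraints.")
}

.sample_motif <- function() {
  type <- sample(names(.MOTIF_TYPES), 1, prob = .MOTIF_TYPES)
  seq <- switch(type,
    KR = "KR",
    RR = "RR",
    RXXR = paste0("R", .sample_chars(setdiff(.SPACER_LIGHT_POOL, "S"), 2), "R")
  )
  list(type = type, seq = seq)
}

#' Configuration for the synthetic precursor generator
#'
#' @param n_peptides Number of tandem peptides per precursor (1-3); a
#'   length-2 vector gives a range sampled per precursor.
#' @param peptide_len Length-2 range of mature peptide lengths (default
#'   6-18, the span reported for this peptide family).
#' @param spacer_len Length-2 range of acidic spacer lengths.
#' @param min_spacer_de Minimum Asp+Glu fraction of emitted spacers.
#' @param amidation_prob Probability that a peptide carries a Gly
#'   amidation donor.
#' @param inter_spacer_prob Probability of an extra acidic spacer between
#'   tandem peptides.
#' @return A list of class `fsap_precursor_config`.
#' @export
precursor_config <- function(n_peptides = c(1L, 3L), peptide_len = c(6L, 18L),
                             spacer_len = c(8L, 13L), min_spacer_de = 0.5,
                             amidation_prob = 0.3, inter_spacer_prob = 0.25) {
  if (length(n_peptides) == 1L) n_peptides <- rep(n_peptides, 2L)
  if (any(n_peptides < 1L) || any(n_peptides > 3L)) {
    abort("`n_peptides` must lie in 1..3.")
  }
  if (peptide_len[1] < 4L) abort("`peptide_len` minimum must be >= 4.")
  structure(
    list(n_peptides = as.integer(n_peptides),
         peptide_len = as.integer(peptide_len),
         spacer_len = as.integer(spacer_len),
         min_spacer_de = min_spacer_de,
         amidation_prob = amidation_prob,
         inter_spacer_prob = inter_spacer_prob),
    class = "fsap_precursor_config"
  )
}

.check_length_feasible <- function(config) {
  # achievable precursor lengths given the config, against the 44-110 window
  n_min <- config$n_peptides[1]; n_max <- config$n_peptides[2]
  min_total <- 15 + config$spacer_len[1] + 2 +
    n_min * config$peptide_len[1] + (n_min - 1) * 2
  max_total <- 24 + config$spacer_len[2] + 4 +
    n_max * (config$peptide_len[2] + 1) + n_max * 4 +
    (n_max - 1) * (config$spacer_len[2] + 4) + 5
  if (min_total > 110 || max_total < 44) {
    abort(sprintf(
      paste("Config cannot produce a precursor of 44-110 residues",
            "(achievable range %d-%d); adjust peptide/spacer lengths or",
            "peptide count."), min_total, max_total
    ))
  }
  invisible(TRUE)
}

#' Generate one synthetic FSAP-like precursor with known architecture
#'
#' Draws a precursor protein — Met-initiated signal peptide with a
#' hydrophobic core, acidic spacer, and 1-3 tandem peptides bounded by
#' KR/RR/RXXR cleavage motifs, with optional Gly amidation donors — plus
#' a CDS obtained by seeded uniform choice over synonymous codons. Total
#' protein length is constrained to the 44-110 residue window typical of
#' this precursor superfamily; a configuration that cannot reach the
#' window is rejected with an error.
#'
#' @param config A [precursor_config()].
#' @param seed Optional integer seed for reproducibility.
#' @param id Precursor identifier.
#' @return A list of class `fsap_truth_precursor` with elements
#'   `precursor_id`, `signal_seq`, `spacer_seqs`, `peptides` (tibble:
#'   `ordinal`, `seq`, `amidated`), `cleavage_motifs` (tibble: `position`,
#'   `motif`), `protein_seq`, `cds_nt`.
#' @export
#' @examples
#' p <- generate_precursor(precursor_config(n_peptides = 2), seed = 1)
#' p$peptides
generate_precursor <- function(config = precursor_config(), seed = NULL,
                               id = "precursor_1") {
  if (!inherits(config, "fsap_precursor_config")) {
    abort("`config` must come from precursor_config().")
  }
  .check_length_feasible(config)
  .with_seed(seed, {
    for (attempt in 1:300) {
      n_pep <- .sample_range(config$n_peptides[1], config$n_peptides[2])
      signal <- .sample_signal()
      spacers <- character(0)
      parts <- list(signal)
      motifs <- list()   # (position, motif) accumulated during assembly
      pep_tbl <- list()

      add <- function(x) parts[[length(parts) + 1L]] <<- x
      cur_len <- function() sum(nchar(unlist(parts)))
      add_motif <- function() {
        m <- .sample_motif()
        motifs[[length(motifs) + 1L]] <<- list(position = cur_len(),
                                               motif = m$type)
        add(m$seq)
      }

      sp1 <- .sample_spacer(config$spacer_len, config$min_spacer_de)
      spacers <- c(spacers, sp1)
      add(sp1)
      add_motif()
      for (k in seq_len(n_pep)) {
        pep <- .sample_peptide(config$peptide_len)
        amid <- runif(1) < config$amidation_prob
        pep_tbl[[k]] <- tibble(ordinal = k, seq = pep, amidated = amid)
        add(pep)
        if (amid) {
          add("G")
          add_motif()
        } else if (k < n_pep) {
          add_motif()
        }
        if (k < n_pep && runif(1) < config$inter_spacer_prob) {
          sp <- .sample_spacer(config$spacer_len, config$min_spacer_de)
          spacers <- c(spacers, sp)
          add(sp)
          add_motif()
        }
      }
      protein <- paste(unlist(parts), collapse = "")
      if (nchar(protein) >= 44 && nchar(protein) <= 110) {
        cds <- .reverse_translate(protein)
        out <- list(
          precursor_id = id,
          signal_seq = signal,
          spacer_seqs = spacers,
          peptides = bind_rows(pep_tbl),
          cleavage_motifs = purrr::map_dfr(motifs, as_tibble),
          protein_seq = protein,
          cds_nt = cds
        )
        class(out) <- "fsap_truth_precursor"
        return(out)
      }
    }
    abort("Could not assemble a precursor inside the 44-110 residue window.")
  })
}

# seeded uniform synonymous-codon choice; appends a stop codon
.reverse_translate <- function(protein) {
  inv <- .codons_by_aa()
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  opts <- inv[chars]
  k <- lengths(opts)
  pick <- pmax(1L, ceiling(runif(length(chars)) * k))
  codons <- mapply(function(o, i) o[i], opts, pick)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
  paste0(paste(codons, collapse = ""), stop_codon)
}

.codons_by_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), as.character(gc))
    }
    cache
  }
})

#' @export
print.fsap_truth_precursor <- function(x, ...) {
  cat(sprintf("<fsap_truth_precursor> %s: %d aa, %d peptide(s), %d motif(s)\n",
              x$precursor_id, nchar(x$protein_seq), nrow(x$peptides),
              nrow(x$cleavage_motifs)))
  invisible(x)
}

# ---- whole-transcriptome generation -----------------------------------------

.random_nt <- function(n) .sample_chars(c("A", "C", "G", "T"), n)

# embed a CDS in random flanks with an in-frame stop immediately upstream of
# the ATG, so the ORF finder recovers exactly the intended reading frame
.embed_cds <- function(cds, flank_len) {
  f5 <- .sample_range(flank_len[1], flank_len[2])
  f3 <- .sample_range(flank_len[1], flank_len[2])
  flank5 <- paste0(.random_nt(f5), "TAA")
  flank3 <- .random_nt(f3)
  list(seq = paste0(flank5, cds, flank3), cds_start = nchar(flank5))
}

.decoy_families <- c("keratin", "ribosomal-protein", "serine-protease-inhibitor")

.make_decoy <- function(kind, decoy_len, flank_len) {
  if (kind == "noncoding") {
    return(list(seq = .random_nt(.sample_range(decoy_len[1], decoy_len[2])),
                kind = kind))
  }
  protein <- if (kind == "orf_no_signal") {
    paste0("M", .sample_chars(c("D", "E", "N", "Q", "S", "T", "G", "P", "H", "K"),
                              .sample_range(40L, 80L)))
  } else {  # orf_signal_no_motif
    paste0(.sample_signal(),
           .sample_chars(c("N", "Q", "S", "T", "G", "P", "A", "L", "V", "D", "E"),
                         .sample_range(30L, 60L)))
  }
  emb <- .embed_cds(.reverse_translate(protein), flank_len)
  list(seq = emb$seq, kind = kind)
}

#' Solve the log-normal spread that yields a target high-expression tail
#'
#' For TPM values drawn log-normally and renormalised to sum to one
#' million over `n` contigs, returns the `sdlog` for which the expected
#' fraction of contigs above `thr` TPM equals `tail_prob`. Where two
#' spreads satisfy the constraint the lighter-tailed one is returned.
#'
#' @param n Library size (number of contigs).
#' @param tail_prob Target fraction of contigs above `thr`.
#' @param thr TPM threshold (default 100).
#' @return `sdlog` for [stats::rlnorm()].
#' @export
tpm_sdlog_for_tail <- function(n, tail_prob = 0.004, thr = 100) {
  n <- .assert_count(n, "n", min = 1L)
  z <- qnorm(1 - tail_prob)
  t <- thr * n / 1e6
  disc <- z^2 - 2 * log(t)
  if (disc < 0) {
    abort(sprintf(
      "No log-normal spread reaches a %.4g tail above %g TPM at n = %d.",
      tail_prob, thr, n
    ))
  }
  roots <- z + c(-1, 1) * sqrt(disc)
  pos <- roots[roots > 1e-9]
  if (length(pos) == 0) {
    abort("Degenerate tail configuration (sdlog would be 0).")
  }
  min(pos)
}

#' Generate a synthetic skin transcriptome with known ground truth
#'
#' Emits Trinity-style contigs embedding `n_precursors` FSAP-like
#' precursor CDS (with an in-frame stop guarding the true start codon)
#' among `n_decoys` decoy contigs cycling through three categories:
#' random non-coding sequence, ORFs without a signal peptide, and ORFs
#' with a signal peptide but no cleavage motifs. TPM values are drawn
#' log-normally and renormalised to sum to one million, giving the
#' heavily skewed expression profile of a real skin library in which only
#' a small fraction of contigs exceeds 100 TPM.
#'
#' @param n_precursors,n_decoys Non-negative counts.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param config A [precursor_config()].
#' @param tpm_tail_prob Target fraction of contigs above 100 TPM (see
#'   [tpm_sdlog_for_tail()]); ignored when `tpm_sdlog` is given.
#' @param tpm_sdlog Optional explicit log-normal spread.
#' @param flank_len,decoy_len Length-2 nucleotide length ranges for CDS
#'   flanks and non-coding decoys.
#' @return A list of class `fsap_synthetic_transcriptome`: `contigs`
#'   (tibble: `contig_id`, `seq_nt`, `tpm`), `truth` (tibble, one row per
#'   ground-truth peptide: `precursor_id`, `contig_id`, `ordinal`, `seq`,
#'   `amidated`), `precursor_meta` (tibble: `precursor_id`, `contig_id`,
#'   `protein_seq`, `signal_len`, `cds_nt`, `cds_start`), `annotation`
#'   (tibble: `contig_id`, `family`), `seed`.
#' @export
#' @examples
#' tx <- generate_transcriptome(2, 10, seed = 1)
#' tx$truth
generate_transcriptome <- function(n_precursors, n_decoys, seed = 1L,
                                   config = precursor_config(),
                                   tpm_tail_prob = 0.004, tpm_sdlog = NULL,
                                   flank_len = c(20L, 80L),
                                   decoy_len = c(200L, 600L)) {
  n_precursors <- .assert_count(n_precursors, "n_precursors")
  n_decoys <- .assert_count(n_decoys, "n_decoys")
  n <- n_precursors + n_decoys
  if (n == 0) abort("Nothing to generate: both counts are zero.")

  .with_seed(seed, {
    precs <- purrr::map(seq_len(n_precursors), function(i) {
      generate_precursor(config, seed = NULL,
                         id = sprintf("PREC_%03d", i))
    })
    decoy_kinds <- rep(c("noncoding", "orf_no_signal", "orf_signal_no_motif"),
                       length.out = n_decoys)
    decoys <- purrr::map(decoy_kinds, .make_decoy,
                         decoy_len = decoy_len, flank_len = flank_len)

    seqs <- character(n)
    cds_start <- rep(NA_integer_, n)
    is_prec <- c(rep(TRUE, n_precursors), rep(FALSE, n_decoys))
    for (i in seq_len(n_precursors)) {
      emb <- .embed_cds(precs[[i]]$cds_nt, flank_len)
      seqs[i] <- emb$seq
      cds_start[i] <- emb$cds_start
    }
    for (j in seq_len(n_decoys)) {
      seqs[n_precursors + j] <- decoys[[j]]$seq
    }

    ord <- sample.int(n)                        # shuffle precursors among decoys
    contig_ids <- sprintf("TRINITY_DN%d_c0_g1_i1", seq_len(n))

    sdlog <- tpm_sdlog %||% tpm_sdlog_for_tail(n, tpm_tail_prob)
    raw <- rlnorm(n, meanlog = 0, sdlog = sdlog)
    tpm <- 1e6 * raw / sum(raw)

    contigs <- tibble(
      contig_id = contig_ids,
      seq_nt = seqs[ord],
      tpm = tpm
    )

    slot_of <- match(seq_len(n), ord)           # original index -> contig row
    meta <- purrr::map_dfr(seq_len(n_precursors), function(i) {
      p <- precs[[i]]
      tibble(
        precursor_id = p$precursor_id,
        contig_id = contig_ids[slot_of[i]],
        protein_seq = p$protein_seq,
        signal_len = nchar(p$signal_seq),
        cds_nt = p$cds_nt,
        cds_start = cds_start[i]
      )
    })
    truth <- purrr::map_dfr(seq_len(n_precursors), function(i) {
      p <- precs[[i]]
      mutate(p$peptides,
             precursor_id = p$precursor_id,
             contig_id = contig_ids[slot_of[i]]) |>
        select("precursor_id", "contig_id", "ordinal", "seq", "amidated")
    })
    if (n_precursors == 0) {
      meta <- tibble(precursor_id = character(), contig_id = character(),
                     protein_seq = character(), signal_len = integer(),
                     cds_nt = character(), cds_start = integer())
      truth <- tibble(precursor_id = character(), contig_id = character(),
                      ordinal = integer(), seq = character(),
                      amidated = logical())
    }

    family <- rep(NA_character_, n)
    family[seq_len(n_precursors)] <- "FSAP"
    if (n_decoys > 0) {
      fam_draw <- sample(c(.decoy_families, NA_character_), n_decoys,
                         replace = TRUE, prob = c(0.15, 0.15, 0.10, 0.60))
      family[n_precursors + seq_len(n_decoys)] <- fam_draw
    }
    annotation <- tibble(contig_id = contig_ids, family = family[ord])

    out <- list(contigs = contigs, truth = truth, precursor_meta = meta,
                annotation = annotation, seed = as.integer(seed))
    class(out) <- "fsap_synthetic_transcriptome"
    out
  })
}

#' @export
print.fsap_synthetic_transcriptome <- function(x, ...) {
  cat(sprintf(
    "<fsap_synthetic_transcriptome> %d contigs (%d precursor-bearing), %d ground-truth peptides, seed %d\n",
    nrow(x$contigs), nrow(x$precursor_meta), nrow(x$truth), x$seed
  ))
  invisible(x)
}

#' Generate a synthetic LC-MS peak list for predicted peptides
#'
#' Emits one peak per in-window [M + zH]^z+ charge state of each peptide
#' (monoisotopic masses), jittered by Gaussian m/z noise, plus uniformly
#' distributed decoy peaks, all inside the ESI+ scan window. The
#' ground-truth peak-to-peptide mapping is returned alongside.
#'
#' @param peptides Data frame with `seq` and optionally `amidated`,
#'   `peptide`; may have zero rows (decoy-only list).
#' @param charges Integer charge states, a subset of 1..5.
#' @param mz_noise_sd Gaussian m/z jitter (>= 0) applied to true peaks.
#' @param n_decoy_peaks Number of uniform decoy peaks.
#' @param seed Optional integer seed.
#' @param mz_window ESI+ scan window (default 100-3000 m/z).
#' @return A list of class `fsap_synthetic_peaks`: `peaks` (tibble:
#'   `rt_min`, `mz`, `intensity`) and `truth` (tibble: `peak_row`,
#'   `peptide`, `seq`, `z`, `mz_true`).
#' @export
generate_peak_list <- function(peptides, charges = 1:3, mz_noise_sd = 0,
                               n_decoy_peaks = 0, seed = NULL,
                               mz_window = c(100, 3000)) {
  if (!all(charges %in% 1:5) || length(charges) == 0) {
    abort("`charges` must be a non-empty subset of 1..5.")
  }
  .assert_number(mz_noise_sd, "mz_noise_sd", min = 0)
  n_decoy_peaks <- .assert_count(n_decoy_peaks, "n_decoy_peaks")
  peptides <- as_tibble(peptides)

  .with_seed(seed, {
    truth0 <- if (nrow(peptides) == 0) NULL else {
      amidated <- if ("amidated" %in% names(peptides)) peptides$amidated else
        rep(FALSE, nrow(peptides))
      name <- if ("peptide" %in% names(peptides)) as.character(peptides$peptide) else
        paste0("peptide_", seq_len(nrow(peptides)))
      purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
        lad <- mz_ladder(monoisotopic_mass(peptides$seq[i], amidated[i]),
                         min(charges), max(charges), mz_window)
        lad <- filter(lad, .data$z %in% charges)
        if (nrow(lad) == 0) return(NULL)
        tibble(peptide = name[i], seq = toupper(peptides$seq[i]),
               z = lad$z, mz_true = lad$mz)
      })
    }
    if (is.null(truth0) || nrow(truth0) == 0) {
      truth0 <- tibble(peptide = character(), seq = character(),
                       z = integer(), mz_true = numeric())
    }

    mz_obs <- truth0$mz_true + rnorm(nrow(truth0), 0, mz_noise_sd)
    inside <- mz_obs >= mz_window[1] & mz_obs <= mz_window[2]
    truth0 <- truth0[inside, , drop = FALSE]
    mz_obs <- mz_obs[inside]

    n_true <- nrow(truth0)
    all_mz <- c(mz_obs, runif(n_decoy_peaks, mz_window[1], mz_window[2]))
    n_all <- length(all_mz)
    rt <- runif(n_all, 1, 60)
    intensity <- rlnorm(n_all, meanlog = log(1e4), sdlog = 1)

    ord <- sample.int(n_all)
    peaks <- tibble(rt_min = rt, mz = all_mz, intensity = intensity)[ord, ]
    peak_row <- match(seq_len(n_true), ord)
    truth <- mutate(truth0, peak_row = peak_row) |>
      select("peak_row", "peptide", "seq", "z", "mz_true")

    out <- list(peaks = peaks, truth = truth)
    class(out) <- "fsap_synthetic_peaks"
    out
  })
}

#' @export
print.fsap_synthetic_peaks <- function(x, ...) {
  cat(sprintf("<fsap_synthetic_peaks> %d peaks (%d true, %d decoy)\n",
              nrow(x$peaks), nrow(x$truth), nrow(x$peaks) - nrow(x$truth)))
  invisible(x)
}
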