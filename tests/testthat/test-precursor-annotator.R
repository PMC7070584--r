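test_that("the hydropathy heuristic calls a signal peptide on a Leu core", {
  call <- detect_signal_peptide("MKLLLLLLLLLASAQQQQQ")
  expect_false(is.null(call))
  # first small residue (A/G/S/C) after the hydrophobic window, position >= 10
  expect_equal(call$cleavage_pos, 11L)
  expect_gte(call$score, 2.0)
  expect_equal(call$source, "builtin")
})

test_that("hydrophilic N-termini and short proteins get no signal call", {
  expect_null(detect_signal_peptide(strrep("MD", 10)))       # max window < 2.0
  expect_null(detect_signal_peptide("MKLLLLLLLLLASA"))        # 14 aa, too short
  expect_warning(detect_signal_peptide(paste0("K", strrep("L", 20))), "Met")
})

test_that("cleavage-motif scanning finds and resolves KR, RR and RXXR", {
  one <- scan_cleavage_sites("AAKRAA")
  expect_equal(one$motif, "KR")
  expect_equal(c(one$start, one$end), c(2L, 4L))

  # overlapping KR/RR: leftmost wins
  res <- scan_cleavage_sites("AAKRRAA")
  expect_equal(nrow(res), 1L)
  expect_equal(res$motif, "KR")
  expect_equal(c(res$start, res$end), c(2L, 4L))

  rxxr <- scan_cleavage_sites("ARVVRA")
  expect_equal(rxxr$motif, "RXXR")
  expect_equal(c(rxxr$start, rxxr$end), c(1L, 5L))

  # at equal starts RXXR outranks the dibasics
  tie <- scan_cleavage_sites("RVVRR")
  expect_equal(tie$motif[1], "RXXR")

  expect_equal(nrow(scan_cleavage_sites("AAAAAA")), 0L)
})

test_that("resolved sites never overlap and match their motif pattern", {
  withr::with_seed(21, {
    for (i in 1:50) {
      p <- random_peptide(sample(20:80, 1))
      sites <- scan_cleavage_sites(p)
      if (nrow(sites) < 1) next
      expect_true(all(diff(sites$start) > 0))
      if (nrow(sites) > 1) {
        expect_true(all(sites$start[-1] >= sites$end[-nrow(sites)]))
      }
      for (j in seq_len(nrow(sites))) {
        span <- substr(p, sites$start[j] + 1, sites$end[j])
        pattern <- switch(sites$motif[j], KR = "^KR$", RR = "^RR$",
                          RXXR = "^R[^R]{2}R$")
        expect_match(span, pattern)
      }
    }
  })
})

test_that("segments classify by acidity thresholds", {
  expect_equal(classify_segment("DEEDSEE"), "spacer")          # D/E 6/7
  expect_equal(classify_segment("GLVTNLLSSVR"), "peptide-candidate")
  expect_equal(classify_segment("DLPVDL"), "spacer")           # 2/6 = 0.33
  # the acidic-charge arm is inert at defaults (anionic peptides survive) …
  expect_equal(classify_segment("DAEAAAAAAL"), "peptide-candidate")
  expect_equal(classify_segment("DYEAVSL"), "peptide-candidate")
  # … but can be re-armed via config: charge -2 with D/E >= 0.20
  expect_equal(classify_segment("DAEAAAAAAL", de_acidic = 0.20), "spacer")
})

test_that("mature peptides follow the processing rule trace", {
  protein <- make_protein(SIGNAL_FIXTURE, "EEDDSE", "KR", "AEWRLLKN", "G",
                          "KR", "DYEAVSL")
  ext <- data.frame(protein_id = "p1", cleavage_pos = nchar(SIGNAL_FIXTURE))
  ann <- annotate_precursors(data.frame(protein_id = "p1", aa_seq = protein),
                             signal = ext)
  peps <- predict_peptides(ann)
  expect_equal(peps$seq, c("AEWRLLKN", "DYEAVSL"))
  expect_equal(peps$amidated, c(TRUE, FALSE))
  expect_equal(peps$ordinal, c(1L, 2L))
  expect_equal(peps$confidence, c("normal", "normal"))
})

test_that("tandem identical peptides keep distinct ordinals", {
  protein <- make_protein(SIGNAL_FIXTURE, "EEDDSE", "KR", "GLVTNLLSSVQ",
                          "KR", "GLVTNLLSSVQ")
  ext <- data.frame(protein_id = "p1", cleavage_pos = nchar(SIGNAL_FIXTURE))
  ann <- annotate_precursors(data.frame(protein_id = "p1", aa_seq = protein),
                             signal = ext)
  peps <- predict_peptides(ann)
  expect_equal(peps$seq, rep("GLVTNLLSSVQ", 2))
  expect_equal(peps$ordinal, 1:2)
})

test_that("a signal without motifs yields one low-confidence peptide", {
  protein <- make_protein(SIGNAL_FIXTURE, "NTLVPNEQSTVANN")
  ext <- data.frame(protein_id = "p1", cleavage_pos = nchar(SIGNAL_FIXTURE))
  ann <- annotate_precursors(data.frame(protein_id = "p1", aa_seq = protein),
                             signal = ext)
  peps <- predict_peptides(ann)
  expect_equal(nrow(peps), 1L)
  expect_equal(peps$confidence, "low")
  expect_equal(peps$seq, "NTLVPNEQSTVANN")
})

test_that("predicting without a signal call is an instructive error", {
  ann <- annotate_precursors(
    data.frame(protein_id = "p", aa_seq = strrep("MD", 30)))
  expect_true(is.na(ann$signal_pos))
  expect_error(predict_peptides(ann), "filter")
})

test_that("short fragments are dropped by the minimum-length rule", {
  protein <- make_protein(SIGNAL_FIXTURE, "EEDDSE", "KR", "AEW", "KR", "DYEAVSL")
  ext <- data.frame(protein_id = "p1", cleavage_pos = nchar(SIGNAL_FIXTURE))
  ann <- annotate_precursors(data.frame(protein_id = "p1", aa_seq = protein),
                             signal = ext)
  peps <- predict_peptides(ann, min_len = 4)
  expect_equal(peps$seq, "DYEAVSL")
  expect_equal(peps$ordinal, 1L)
})

test_that("segments plus motifs reassemble the annotated protein exactly", {
  withr::with_seed(31, {
    for (i in 1:40) {
      p <- generate_precursor(seed = NULL, id = "t")
      ext <- data.frame(protein_id = "t", cleavage_pos = nchar(p$signal_seq))
      ann <- annotate_precursors(
        data.frame(protein_id = "t", aa_seq = p$protein_seq), signal = ext)
      segs <- ann$segments[[1]]
      sites <- ann$sites[[1]]
      pieces <- rbind(
        data.frame(start = 0L, end = ann$signal_pos,
                   seq = substr(p$protein_seq, 1, ann$signal_pos)),
        data.frame(start = segs$start, end = segs$end, seq = segs$seq),
        data.frame(start = sites$start, end = sites$end,
                   seq = substring(p$protein_seq, sites$start + 1, sites$end))
      )
      pieces <- pieces[order(pieces$start), ]
      expect_equal(paste(pieces$seq, collapse = ""), p$protein_seq)
      expect_equal(pieces$start[-1], pieces$end[-nrow(pieces)])
    }
  })
})

test_that("predicted peptides never retain an unresolved dibasic", {
  withr::with_seed(32, {
    for (i in 1:40) {
      p <- generate_precursor(seed = NULL, id = "t")
      ext <- data.frame(protein_id = "t", cleavage_pos = nchar(p$signal_seq))
      ann <- annotate_precursors(
        data.frame(protein_id = "t", aa_seq = p$protein_seq), signal = ext)
      peps <- predict_peptides(ann)
      expect_false(any(grepl("KR|RR", peps$seq)))
    }
  })
})

test_that("oracle signal positions recover synthetic peptide lists exactly", {
  withr::with_seed(33, {
    hits <- 0L; total <- 100L
    for (i in seq_len(total)) {
      p <- generate_precursor(seed = NULL, id = "t")
      ext <- data.frame(protein_id = "t", cleavage_pos = nchar(p$signal_seq))
      ann <- annotate_precursors(
        data.frame(protein_id = "t", aa_seq = p$protein_seq), signal = ext)
      peps <- predict_peptides(ann)
      ok <- nrow(peps) == nrow(p$peptides) &&
        identical(peps$seq, p$peptides$seq) &&
        identical(peps$amidated, p$peptides$amidated)
      hits <- hits + ok
    }
    expect_gte(hits / total, 0.95)
  })
})

test_that("the builtin heuristic lands within 3 residues of the true cleavage", {
  withr::with_seed(34, {
    close_calls <- 0L; total <- 100L
    for (i in seq_len(total)) {
      p <- generate_precursor(seed = NULL, id = "t")
      call <- detect_signal_peptide(p$protein_seq)
      if (!is.null(call) && abs(call$cleavage_pos - nchar(p$signal_seq)) <= 3) {
        close_calls <- close_calls + 1L
      }
    }
    expect_gte(close_calls / total, 0.9)
  })
})

test_that("adding a decoy contig never changes other predictions", {
  tx <- generate_transcriptome(3, 5, seed = 7)
  base <- run_pipeline(tx$contigs)
  decoy <- data.frame(
    contig_id = "EXTRA_DECOY", tpm = 1,
    seq_nt = withr::with_seed(99, paste(sample(c("A", "C", "G", "T"), 400,
                                               replace = TRUE), collapse = ""))
  )
  more <- run_pipeline(rbind(tx$contigs[, names(decoy)], decoy))
  base_peps <- base$peptides[order(base$peptides$peptide), ]
  kept <- more$peptides[!grepl("EXTRA_DECOY", more$peptides$precursor_id), ]
  kept <- kept[order(kept$peptide), ]
  expect_equal(kept$seq, base_peps$seq)
  expect_equal(kept$amidated, base_peps$amidated)
})

test_that("external signal tables override the heuristic", {
  protein <- make_protein(SIGNAL_FIXTURE, "EEDDSE", "KR", "AEWRLLKN")
  ext <- data.frame(protein_id = "p1", cleavage_pos = 16L, score = 0.99)
  ann <- annotate_precursors(data.frame(protein_id = "p1", aa_seq = protein),
                             signal = ext)
  expect_equal(ann$signal_source, "external")
  expect_equal(ann$signal_pos, 16L)
  expect_error(
    annotate_precursors(data.frame(protein_id = "p1", aa_seq = protein),
                        signal = data.frame(protein_id = "p1",
                                            cleavage_pos = 500L)),
    "out of range"
  )
})
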