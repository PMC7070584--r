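test_that("precursor architecture honours the config", {
  one <- generate_precursor(precursor_config(n_peptides = 1,
                                             amidation_prob = 0), seed = 1)
  expect_equal(nrow(one$peptides), 1L)
  expect_false(any(one$peptides$amidated))
  expect_true(all(one$cleavage_motifs$motif %in% c("KR", "RR", "RXXR")))

  three <- generate_precursor(precursor_config(n_peptides = 3), seed = 7)
  expect_equal(nrow(three$peptides), 3L)

  p <- generate_precursor(seed = 42)
  expect_gte(nchar(p$protein_seq), 44L)
  expect_lte(nchar(p$protein_seq), 110L)
  # signal peptide: length 15-25 with a strongly hydrophobic central 8-mer
  expect_gte(nchar(p$signal_seq), 15L)
  expect_lte(nchar(p$signal_seq), 25L)
  mid <- nchar(p$signal_seq) %/% 2
  core <- substr(p$signal_seq, mid - 3, mid + 4)
  expect_gte(mean(kyte_doolittle()[strsplit(core, "")[[1]]]), 2.0)
})

test_that("infeasible length configurations are rejected up front", {
  expect_error(generate_precursor(precursor_config(n_peptides = 3,
                                                   peptide_len = c(40, 60))),
               "44-110")
})

test_that("the CDS translates to the protein plus one stop", {
  withr::with_seed(51, {
    for (i in 1:20) {
      p <- generate_precursor(seed = NULL)
      expect_equal(translate_nt(p$cds_nt), paste0(p$protein_seq, "*"))
      # motif spans in the protein match their recorded type
      for (j in seq_len(nrow(p$cleavage_motifs))) {
        pos <- p$cleavage_motifs$position[j]
        type <- p$cleavage_motifs$motif[j]
        len <- if (type == "RXXR") 4L else 2L
        span <- substr(p$protein_seq, pos + 1, pos + len)
        expect_match(span, switch(type, KR = "^KR$", RR = "^RR$",
                                  RXXR = "^R[^R]{2}R$"))
      }
    }
  })
})

test_that("emitted spacers and peptides respect their constraints", {
  withr::with_seed(52, {
    cfg <- precursor_config(peptide_len = c(8, 14), min_spacer_de = 0.5)
    for (i in 1:25) {
      p <- generate_precursor(cfg, seed = NULL)
      for (sp in p$spacer_seqs) {
        chars <- strsplit(sp, "")[[1]]
        expect_gte(mean(chars %in% c("D", "E")), 0.5)
      }
      expect_true(all(nchar(p$peptides$seq) >= 8))
      expect_true(all(nchar(p$peptides$seq) <= 14))
      # amidated peptides are followed in the protein by Gly then a motif
      for (j in seq_len(nrow(p$peptides))) {
        if (!p$peptides$amidated[j]) next
        pos1 <- regexpr(paste0(p$peptides$seq[j], "G"), p$protein_seq,
                        fixed = TRUE)
        expect_gt(pos1, 0)
        after_g0 <- (as.integer(pos1) - 1L) + nchar(p$peptides$seq[j]) + 1L
        expect_true(after_g0 %in% p$cleavage_motifs$position)
      }
    }
  })
})

test_that("transcriptomes embed each true CDS in exactly one contig", {
  tx <- generate_transcriptome(5, 50, seed = 2)
  expect_equal(nrow(tx$contigs), 55L)
  hits <- vapply(tx$precursor_meta$cds_nt, function(cds) {
    sum(vapply(tx$contigs$seq_nt, function(s) grepl(cds, s, fixed = TRUE),
               logical(1)))
  }, numeric(1))
  expect_equal(unname(hits), rep(1, 5))
  # the recorded contig and offset are right
  for (i in seq_len(nrow(tx$precursor_meta))) {
    m <- tx$precursor_meta[i, ]
    contig_seq <- tx$contigs$seq_nt[tx$contigs$contig_id == m$contig_id]
    expect_equal(substr(contig_seq, m$cds_start + 1,
                        m$cds_start + nchar(m$cds_nt)), m$cds_nt)
  }
})

test_that("seeded generation is byte-reproducible on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_transcriptome(generate_transcriptome(5, 50, seed = 2), d1)
  write_transcriptome(generate_transcriptome(5, 50, seed = 2), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = f)
  }
  # and a different seed differs
  d3 <- withr::local_tempdir()
  write_transcriptome(generate_transcriptome(5, 50, seed = 3), d3)
  expect_false(identical(
    readBin(file.path(d1, "contigs.fasta"), "raw", 1e6),
    readBin(file.path(d3, "contigs.fasta"), "raw", 1e6)
  ))
})

test_that("TPM is a normalised heavy-tailed profile", {
  tx <- generate_transcriptome(0, 500, seed = 11)
  expect_equal(sum(tx$contigs$tpm), 1e6, tolerance = 1e-9)
  expect_true(all(tx$contigs$tpm >= 0))
  # skew: the top contig dwarfs the median
  expect_gt(max(tx$contigs$tpm) / stats::median(tx$contigs$tpm), 10)
})

test_that("decoy-only transcriptomes predict no mature peptides from a/c decoys", {
  tx <- generate_transcriptome(0, 10, seed = 1)
  expect_equal(nrow(tx$truth), 0L)
  run <- run_pipeline(tx$contigs)
  expect_equal(nrow(run$peptides), 0L)
})

test_that("round-trip: written transcriptome reloads identically", {
  tx <- generate_transcriptome(3, 9, seed = 4)
  d <- withr::local_tempdir()
  write_transcriptome(tx, d)
  back <- read_contigs(file.path(d, "contigs.fasta"),
                       file.path(d, "expression.tsv"))
  expect_equal(back$contig_id, tx$contigs$contig_id)
  expect_equal(back$seq_nt, tx$contigs$seq_nt)
  expect_equal(back$tpm, tx$contigs$tpm, tolerance = 1e-12)
})
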