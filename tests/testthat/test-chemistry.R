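# Expected values below were either verified against the published peptide
# panel before freezing, or computed with closed-form arithmetic on the
# residue tables (single-residue and additivity identities).

test_that("average mass reproduces published peptide panel rows", {
  expect_equal(average_mass("GLVTNLLSSVR"), 1158.4, tolerance = 0.1 / 1158)
  expect_equal(average_mass("AEWRLLKN", amidated = TRUE), 1028.2,
               tolerance = 0.1 / 1028)
  # single residue closed form: Gly residue + one water
  expect_equal(average_mass("G"), 57.0519 + 18.01524, tolerance = 1e-9)
})

test_that("monoisotopic mass has the standard closed-form values", {
  expect_equal(monoisotopic_mass("G"), 75.0320, tolerance = 1e-4)
  # additivity: mass(AG) = mass(A) + mass(G) - water
  expect_equal(monoisotopic_mass("AG"),
               monoisotopic_mass("A") + monoisotopic_mass("G") - 18.010565,
               tolerance = 1e-9)
  expect_equal(average_mass("AG"),
               average_mass("A") + average_mass("G") - 18.01524,
               tolerance = 1e-9)
})

test_that("mass additivity and amidation shift hold on random peptides", {
  withr::with_seed(11, {
    for (i in 1:30) {
      a <- random_peptide(sample(3:15, 1))
      b <- random_peptide(sample(3:15, 1))
      expect_equal(average_mass(paste0(a, b)),
                   average_mass(a) + average_mass(b) - 18.01524,
                   tolerance = 1e-9)
      expect_equal(monoisotopic_mass(paste0(a, b)),
                   monoisotopic_mass(a) + monoisotopic_mass(b) - 18.010565,
                   tolerance = 1e-9)
      # amidation shifts average mass by -0.98 (within 0.005)
      expect_equal(average_mass(a, amidated = TRUE) - average_mass(a),
                   -0.98, tolerance = 0.005 / 0.98)
      # monoisotopic never exceeds average
      expect_lte(monoisotopic_mass(a), average_mass(a) + 1e-9)
    }
  })
})

test_that("non-standard residues are rejected by name", {
  expect_error(average_mass("ACX"), "X")
  expect_error(net_charge("ABBA"), "B")
})

test_that("formal net charge counts K/R, D/E and the termini", {
  expect_equal(net_charge("SEWPPVRGDNGEYDVEL"), -4L)
  expect_equal(net_charge("AEWRLLKN", amidated = TRUE), 2L)
  expect_equal(net_charge("AEWRLLKN", amidated = FALSE), 1L)
  expect_equal(net_charge("AAAA"), 0L)
  # permutation invariance
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- random_peptide(sample(5:20, 1))
      perm <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
      expect_equal(net_charge(p), net_charge(perm))
    }
  })
})

test_that("GRAVY is the Kyte-Doolittle mean and reversal-invariant", {
  expect_equal(gravy("DYEAVSL"), 0.10, tolerance = 0.005 / 0.1)
  expect_equal(gravy("GIVNNLLSTVL"), 1.40, tolerance = 0.005 / 1.4)
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("R"), -4.5)
  withr::with_seed(13, {
    for (i in 1:20) {
      p <- random_peptide(sample(5:20, 1))
      revp <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
      expect_equal(gravy(p), gravy(revp))
      expect_gte(gravy(p), -4.5)
      expect_lte(gravy(p), 4.5)
    }
  })
})

test_that("helicity percentage is the H-state fraction", {
  expect_equal(helicity_percent("CHHHHHHHHCC"), 100 * 8 / 11)
  expect_equal(helicity_percent(strrep("C", 12)), 0)
  expect_equal(helicity_percent(paste0(strrep("H", 8), strrep("C", 4))),
               100 * 8 / 12)
  expect_error(helicity_percent("HHH", peptide = "ACDE"), "length")
  expect_error(helicity_percent("HZH"), "state")
})

test_that("the ESI+ ladder applies (m + z p)/z inside the scan window", {
  lad <- mz_ladder(1705.0, 1, 3)
  expect_equal(lad$z, 1:3)
  expect_equal(lad$mz, (1705.0 + (1:3) * 1.00728) / (1:3), tolerance = 1e-12)
  expect_equal(round(lad$mz, 1), c(1706.0, 853.5, 569.3))
  # algebraic inverse recovers the neutral mass
  expect_equal(lad$mz * lad$z - lad$z * 1.00728, rep(1705.0, 3),
               tolerance = 1e-6 / 1705)
  # everything above the window is dropped
  expect_equal(nrow(mz_ladder(100000, 1, 5)), 0L)
  # singly charged small mass below 100 is dropped too
  expect_equal(nrow(mz_ladder(50, 1, 1)), 0L)
})

test_that("zero-noise peak lists are matched exactly and completely", {
  peps <- data.frame(peptide = c("a", "b", "c"),
                     seq = c("GLVTNLLSSVR", "DYEAVSL", "AEWRLLKN"),
                     amidated = c(FALSE, FALSE, TRUE))
  pl <- generate_peak_list(peps, charges = 1:2, mz_noise_sd = 0,
                           n_decoy_peaks = 0, seed = 5)
  res <- match_peaks(peps, pl$peaks, tol = 0.1, z_min = 1, z_max = 2)
  expect_true(all(res$summary$confirmed))
  expect_equal(nrow(res$unmatched_peaks), 0L)
  # single peptide, single charge: one peak at the theoretical [M+2H]2+
  one <- generate_peak_list(peps[1, ], charges = 2, mz_noise_sd = 0,
                            n_decoy_peaks = 0, seed = 5)
  expect_equal(nrow(one$peaks), 1L)
  expect_equal(one$peaks$mz,
               (monoisotopic_mass("GLVTNLLSSVR") + 2 * 1.00728) / 2,
               tolerance = 1e-12)
})

test_that("noisy peak lists with decoys still recover the true peptides", {
  peps <- data.frame(seq = c("GLVKNLNLPVDVPVDL", "NTENFFNPFNPFV",
                             "SEWPPVRGDNGEYDVEL"))
  pl <- generate_peak_list(peps, charges = 1:3, mz_noise_sd = 0.1,
                           n_decoy_peaks = 50, seed = 3)
  res <- match_peaks(peps, pl$peaks, tol = 0.5, z_min = 1, z_max = 3)
  expect_true(all(res$summary$confirmed))
  # truth mapping points at peaks that indeed match their peptide
  truthful <- dplyr::inner_join(
    res$matches, pl$truth,
    by = c("peak_id" = "peak_row", "z" = "z")
  )
  expect_gt(nrow(truthful), 0L)
  expect_true(all(truthful$seq.x == truthful$seq.y))
})

test_that("degenerate tolerance and empty inputs behave", {
  peps <- data.frame(seq = "GLVTNLLSSVR")
  pl <- generate_peak_list(peps, charges = 1:2, mz_noise_sd = 0.05,
                           n_decoy_peaks = 5, seed = 9)
  expect_equal(nrow(match_peaks(peps, pl$peaks, tol = 0)$matches), 0L)
  empty <- match_peaks(peps, data.frame(mz = numeric()), tol = 0.5)
  expect_false(any(empty$summary$confirmed))
  decoy_only <- generate_peak_list(data.frame(seq = character()),
                                   n_decoy_peaks = 10, seed = 2)
  expect_equal(nrow(decoy_only$truth), 0L)
  expect_equal(nrow(decoy_only$peaks), 10L)
})

test_that("peak assignment is unique per peak, ties to the lower charge", {
  # two peptides with ladders straddling one observed peak: the closer wins
  peaks <- data.frame(mz = (monoisotopic_mass("DYEAVSL") + 1.00728) / 1 + 0.02)
  peps <- data.frame(peptide = c("near", "far"),
                     seq = c("DYEAVSL", "DYEPASL"))
  res <- match_peaks(peps, peaks, tol = 5, z_min = 1, z_max = 1)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$matches$peptide, "near")
})

test_that("the property panel assembles all columns at full precision", {
  panel <- peptide_properties(data.frame(
    seq = c("DYEAVSL", "AEWRLLKN"), amidated = c(FALSE, TRUE),
    ss = c("CCCCCCC", NA)
  ))
  expect_equal(nrow(panel), 2L)
  expect_equal(panel$length, c(7L, 8L))
  expect_equal(panel$net_charge, c(-2L, 2L))
  expect_equal(panel$helicity_pct, c(0, NA_real_))
  expect_equal(panel$avg_mass[2], average_mass("AEWRLLKN", TRUE))
  expect_equal(nrow(peptide_properties(data.frame(seq = character()))), 0L)
})
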