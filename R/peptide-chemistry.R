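#' Average (chemical) mass of a peptide
#'
#' Sums ExPASy-standard average residue masses and adds one water
#' (18.01524 Da). An amidated C-terminus (alpha-amide replacing the
#' carboxylate hydroxyl) shifts the mass by -0.98476 Da. This is the "MW"
#' a peptide property table reports; monoisotopic mass is kept separate for
#' high-accuracy MS matching. Values are returned at full precision —
#' round only when reporting.
#'
#' @param seq Amino-acid sequence (single string, 20 standard residues).
#' @param amidated Is the C-terminus alpha-amidated?
#' @return Average mass in Da.
#' @seealso [monoisotopic_mass()], [peptide_properties()]
#' @export
#' @examples
#' average_mass("GLVTNLLSSVR")          # ~1158.4
#' average_mass("AEWRLLKN", amidated = TRUE)  # ~1028.2
average_mass <- function(seq, amidated = FALSE) {
  .assert_flag(amidated, "amidated")
  chars <- .residues(seq)
  sum(.AVG_RESIDUE_MASS[chars]) + .WATER_AVG +
    if (amidated) .AMIDE_SHIFT_AVG else 0
}

#' Monoisotopic mass of a peptide
#'
#' As [average_mass()] but with monoisotopic residue masses, water
#' 18.010565 Da and an amidation shift of -0.98402 Da. Used for theoretical
#' m/z ladders in LC-MS confirmation.
#'
#' @inheritParams average_mass
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("G")  # 75.0320
monoisotopic_mass <- function(seq, amidated = FALSE) {
  .assert_flag(amidated, "amidated")
  chars <- .residues(seq)
  sum(.MONO_RESIDUE_MASS[chars]) + .WATER_MONO +
    if (amidated) .AMIDE_SHIFT_MONO else 0
}

#' Formal net charge at neutral pH
#'
#' Integer counting model matching how peptide tables print whole-number
#' charges at pH 7: +1 per Lys or Arg, -1 per Asp or Glu, His counted 0.
#' The free termini cancel (+1 amine, -1 carboxylate); an amidated
#' C-terminus removes the carboxylate charge so the termini contribute +1
#' net. Not a Henderson–Hasselbalch titration model.
#'
#' @inheritParams average_mass
#' @param pH Only 7 is supported by the formal counting model; present to
#'   make the modelling assumption explicit at call sites.
#' @return Integer net charge.
#' @export
#' @examples
#' net_charge("SEWPPVRGDNGEYDVEL")            # -4
#' net_charge("AEWRLLKN", amidated = TRUE)    # +2
net_charge <- function(seq, amidated = FALSE, pH = 7.0) {
  .assert_flag(amidated, "amidated")
  if (!isTRUE(all.equal(pH, 7.0))) {
    abort("The formal counting charge model is defined at pH 7 only.")
  }
  chars <- .residues(seq)
  side <- sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
  termini <- if (amidated) 1L else 0L
  as.integer(side + termini)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence. Bounded by the scale:
#' -4.5 (Arg) to 4.5 (Ile).
#'
#' @inheritParams average_mass
#' @return GRAVY value (dimensionless, full precision).
#' @export
#' @examples
#' gravy("DYEAVSL")  # 0.10
gravy <- function(seq) {
  chars <- .residues(seq)
  mean(.KYTE_DOOLITTLE[chars])
}

#' Percent helicity from a secondary-structure state string
#'
#' Converts a per-residue three-state prediction (H = helix, E = strand,
#' C = coil) from an external structure predictor into the percentage of
#' helical residues a property table reports. The prediction itself is out
#' of scope; only the conversion lives here.
#'
#' @param ss_string Per-residue states, one character each, from {H, E, C}.
#' @param peptide Optional peptide sequence; when supplied its length must
#'   equal `nchar(ss_string)`.
#' @return Percent of residues in state H, full precision.
#' @export
#' @examples
#' helicity_percent("CHHHHHHHHCC")  # 8/11 -> 72.7
helicity_percent <- function(ss_string, peptide = NULL) {
  if (length(ss_string) != 1L || is.na(ss_string) || !nzchar(ss_string)) {
    abort("`ss_string` must be a single non-empty string.")
  }
  states <- strsplit(toupper(ss_string), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(states), c("H", "E", "C"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown secondary-structure state(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(peptide) && nchar(peptide) != length(states)) {
    abort(sprintf(
      "Secondary-structure string length (%d) does not match peptide length (%d).",
      length(states), nchar(peptide)
    ))
  }
  100 * sum(states == "H") / length(states)
}

#' Theoretical ESI+ charge-state ladder
#'
#' m/z of the [M + zH]^z+ ions of a neutral mass, keeping only charge
#' states whose m/z falls inside the instrument scan window (default
#' 100–3000, the usual single-quadrupole/Q-Tof ESI+ range).
#'
#' @param mass Neutral mass in Da (average or monoisotopic, caller's choice).
#' @param z_min,z_max Charge-state range (z >= 1).
#' @param mz_window Length-2 numeric scan window in m/z.
#' @return A tibble with columns `z` and `mz`.
#' @export
#' @examples
#' mz_ladder(1705.0, 1, 3)
mz_ladder <- function(mass, z_min = 1L, z_max = 3L, mz_window = c(100, 3000)) {
  .assert_number(mass, "mass", min = 0)
  z_min <- .assert_count(z_min, "z_min", min = 1L)
  z_max <- .assert_count(z_max, "z_max", min = z_min)
  if (length(mz_window) != 2L || mz_window[1] >= mz_window[2]) {
    abort("`mz_window` must be c(lo, hi) with lo < hi.")
  }
  z <- seq.int(z_min, z_max)
  mz <- (mass + z * .PROTON_MASS) / z
  keep <- mz >= mz_window[1] & mz <= mz_window[2]
  tibble(z = as.integer(z[keep]), mz = mz[keep])
}

#' Build the physicochemical property panel for a peptide table
#'
#' The per-peptide panel a peptidomics report prints: length, average mass
#' ("MW"), monoisotopic mass, formal net charge at pH 7, GRAVY, and
#' (when a secondary-structure string is available) percent helicity.
#' Columns are full precision; round at the reporting layer.
#'
#' @param peptides A data frame with columns `seq` and optionally
#'   `amidated` (logical, default FALSE), `peptide` (a display name) and
#'   `ss` (secondary-structure state strings, NA when unavailable).
#' @return A tibble, one row per input row, with columns `peptide`, `seq`,
#'   `amidated`, `length`, `avg_mass`, `mono_mass`, `net_charge`, `gravy`,
#'   `helicity_pct`.
#' @export
#' @examples
#' peptide_properties(data.frame(seq = c("DYEAVSL", "AEWRLLKN"),
#'                               amidated = c(FALSE, TRUE)))
peptide_properties <- function(peptides) {
  peptides <- as_tibble(peptides)
  if (!"seq" %in% names(peptides)) {
    abort("`peptides` must have a `seq` column.")
  }
  if (nrow(peptides) == 0) {
    return(tibble(
      peptide = character(), seq = character(), amidated = logical(),
      length = integer(), avg_mass = numeric(), mono_mass = numeric(),
      net_charge = integer(), gravy = numeric(), helicity_pct = numeric()
    ))
  }
  amidated <- if ("amidated" %in% names(peptides)) peptides$amidated else
    rep(FALSE, nrow(peptides))
  name <- if ("peptide" %in% names(peptides)) as.character(peptides$peptide) else
    paste0("peptide_", seq_len(nrow(peptides)))
  ss <- if ("ss" %in% names(peptides)) as.character(peptides$ss) else
    rep(NA_character_, nrow(peptides))
  tibble(
    peptide = name,
    seq = toupper(peptides$seq),
    amidated = amidated,
    length = nchar(peptides$seq),
    avg_mass = purrr::map2_dbl(peptides$seq, amidated, average_mass),
    mono_mass = purrr::map2_dbl(peptides$seq, amidated, monoisotopic_mass),
    net_charge = purrr::map2_int(peptides$seq, amidated, net_charge),
    gravy = purrr::map_dbl(peptides$seq, gravy),
    helicity_pct = purrr::map2_dbl(
      ss, peptides$seq,
      function(s, p) if (is.na(s)) NA_real_ else helicity_percent(s, p)
    )
  )
}

#' Match predicted peptides against an observed LC-MS peak list
#'
#' Confirms predicted peptides by theoretical m/z: each peptide's
#' monoisotopic [M + zH]^z+ ladder is compared with observed peaks, and a
#' peptide counts as confirmed when at least one ladder entry lies within
#' `tol` of a peak. Each observed peak is assigned to at most one
#' (peptide, z) pair — the one with the smallest absolute m/z error, ties
#' broken toward the lower charge state; this makes the otherwise manual
#' spectrum inspection deterministic.
#'
#' @param peptides Data frame with columns `seq` and optionally `amidated`,
#'   `peptide`.
#' @param peaks Data frame with a column `mz` (and anything else, e.g.
#'   `rt_min`, `intensity`, carried through).
#' @param tol Match tolerance in m/z units (> 0).
#' @param z_min,z_max Charge states to consider.
#' @param mz_window Scan window passed to [mz_ladder()].
#' @return A list of class `fsap_ms_match` with elements `matches` (tibble:
#'   `peak_id`, `mz_obs`, `peptide`, `seq`, `z`, `mz_theoretical`, `delta`),
#'   `summary` (tibble: one row per peptide with `confirmed` and
#'   `n_matches`), and `unmatched_peaks`.
#' @export
match_peaks <- function(peptides, peaks, tol = 0.5, z_min = 1L, z_max = 3L,
                        mz_window = c(100, 3000)) {
  .assert_number(tol, "tol", min = 0)
  if (tol <= 0 && tol != 0) abort("`tol` must be > 0.")
  peptides <- as_tibble(peptides)
  peaks <- as_tibble(peaks)
  if (nrow(peptides) > 0 && !"seq" %in% names(peptides)) {
    abort("`peptides` must have a `seq` column.")
  }
  if (nrow(peaks) > 0 && !"mz" %in% names(peaks)) {
    abort("`peaks` must have an `mz` column.")
  }
  amidated <- if ("amidated" %in% names(peptides)) peptides$amidated else
    rep(FALSE, nrow(peptides))
  name <- if ("peptide" %in% names(peptides)) as.character(peptides$peptide) else
    paste0("peptide_", seq_len(nrow(peptides)))

  ladder <- purrr::pmap_dfr(
    list(name, peptides$seq %||% character(), amidated),
    function(nm, s, am) {
      l <- mz_ladder(monoisotopic_mass(s, am), z_min, z_max, mz_window)
      mutate(l, peptide = nm, seq = toupper(s))
    }
  )

  empty_matches <- tibble(
    peak_id = integer(), mz_obs = numeric(), peptide = character(),
    seq = character(), z = integer(), mz_theoretical = numeric(),
    delta = numeric()
  )
  if (nrow(peaks) == 0 || nrow(ladder) == 0 || tol <= 0) {
    out <- list(
      matches = empty_matches,
      summary = tibble(peptide = name, seq = toupper(peptides$seq %||% character()),
                       confirmed = rep(FALSE, nrow(peptides)),
                       n_matches = rep(0L, nrow(peptides))),
      unmatched_peaks = mutate(peaks, peak_id = row_number())
    )
    class(out) <- "fsap_ms_match"
    return(out)
  }

  # all candidate (peak, ladder-entry) pairs within tolerance
  cand <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    d <- peaks$mz[i] - ladder$mz
    hit <- which(abs(d) <= tol)
    if (length(hit) == 0) return(NULL)
    tibble(
      peak_id = i, mz_obs = peaks$mz[i],
      peptide = ladder$peptide[hit], seq = ladder$seq[hit],
      z = ladder$z[hit], mz_theoretical = ladder$mz[hit], delta = d[hit]
    )
  })

  matches <- if (is.null(cand) || nrow(cand) == 0) empty_matches else {
    cand |>
      group_by(.data$peak_id) |>
      arrange(abs(.data$delta), .data$z, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup() |>
      arrange(.data$peak_id)
  }

  summary <- tibble(peptide = name, seq = toupper(peptides$seq)) |>
    left_join(
      matches |> count(.data$peptide, name = "n_matches"),
      by = "peptide"
    ) |>
    mutate(
      n_matches = dplyr::coalesce(.data$n_matches, 0L),
      confirmed = .data$n_matches > 0L
    ) |>
    select("peptide", "seq", "confirmed", "n_matches")

  out <- list(
    matches = matches,
    summary = summary,
    unmatched_peaks = peaks |>
      mutate(peak_id = row_number()) |>
      filter(!.data$peak_id %in% matches$peak_id)
  )
  class(out) <- "fsap_ms_match"
  out
}

#' @export
print.fsap_ms_match <- function(x, ...) {
  cat(sprintf(
    "<fsap_ms_match> %d/%d peptides confirmed; %d peak assignments, %d unmatched peaks\n",
    sum(x$summary$confirmed), nrow(x$summary),
    nrow(x$matches), nrow(x$unmatched_peaks)
  ))
  invisible(x)
}
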