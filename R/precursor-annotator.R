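# hydropathy lookup tolerant of X (ambiguous translation): X scores 0
.hydropathy <- function(chars) {
  h <- .KYTE_DOOLITTLE[chars]
  h[is.na(h)] <- 0
  unname(h)
}

#' Detect an N-terminal signal peptide (built-in heuristic)
#'
#' A deliberately simple, fully documented stand-in for an external
#' signal-peptide predictor, built on the one property every secretory
#' signal peptide shares: a hydrophobic core near the N-terminus. The
#' heuristic finds the 8-residue window starting at (0-based) positions
#' 1–35 with maximal mean Kyte-Doolittle hydropathy. If that mean is below
#' `min_core_hydropathy` (default 2.0) no signal peptide is called.
#' Otherwise the cleavage position — the index of the first mature residue
#' — is the first position at or after the window end holding a small
#' residue (A, G, S or C, the residues that dominate real -1/+1 cleavage
#' contexts) within positions 10–40; if no such residue exists the
#' fallback is window end + 5, capped at 40. Proteins shorter than 15
#' residues cannot host a signal peptide and return no call.
#'
#' External predictions (e.g. from a dedicated predictor run outside R)
#' always take precedence: supply them to [annotate_precursors()] as a
#' table and the heuristic is bypassed.
#'
#' @param protein Amino-acid string; a warning is raised if it does not
#'   start with Met, but scanning proceeds.
#' @param min_core_hydropathy Threshold on the best window's mean
#'   hydropathy (default 2.0).
#' @return A list with `cleavage_pos` (0-based index of the first mature
#'   residue), `score` (best window mean hydropathy) and `source`
#'   (`"builtin"`), or `NULL` when no signal peptide is called.
#' @export
#' @examples
#' detect_signal_peptide("MKLLLLLLLLLASAAEDDSEKRGLVTNLLSSVR")
detect_signal_peptide <- function(protein, min_core_hydropathy = 2.0) {
  if (length(protein) != 1L || is.na(protein) || !nzchar(protein)) {
    abort("`protein` must be a single non-empty string.")
  }
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n < 15L) return(NULL)
  if (substr(protein, 1L, 1L) != "M") {
    warn(sprintf("Protein does not start with Met: %s...",
                 substr(protein, 1L, 10L)))
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  h <- .hydropathy(chars)

  win <- 8L
  first_start <- 2L                      # 1-based; 0-based position 1
  last_start <- min(36L, n - win + 1L)   # 0-based start <= 35
  if (last_start < first_start) return(NULL)
  starts <- seq.int(first_start, last_start)
  csum <- cumsum(c(0, h))
  means <- (csum[starts + win] - csum[starts]) / win
  best <- which.max(means)
  if (means[best] < min_core_hydropathy) return(NULL)
  win_end0 <- (starts[best] - 1L) + win   # 0-based index just past the window

  small <- which(chars %in% c("A", "G", "S", "C"))
  small0 <- small - 1L
  cand <- small0[small0 >= win_end0 & small0 >= 10L & small0 <= 40L &
                   small0 <= n - 2L]     # at least one mature residue left
  cleavage_pos <- if (length(cand) > 0) cand[1] else min(win_end0 + 5L, 40L)
  if (cleavage_pos < 10L || cleavage_pos > n - 1L) return(NULL)
  list(cleavage_pos = as.integer(cleavage_pos),
       score = unname(means[best]), source = "builtin")
}

#' Scan a protein for prohormone-convertase cleavage motifs
#'
#' Finds all occurrences of the dibasic motifs KR and RR and the
#' furin-like RXXR (X = any residue except Arg, which prevents nested RR
#' from being counted twice), then resolves overlaps leftmost-first with
#' priority RXXR > KR > RR at equal starts. Spans are 0-based half-open.
#'
#' @param protein Amino-acid string.
#' @return A tibble with columns `motif` ("KR", "RR", "RXXR"), `start`,
#'   `end`, sorted by `start`; zero rows when nothing matches.
#' @export
#' @examples
#' scan_cleavage_sites("AAKRRAA")  # KR at [2,4) wins over RR at [3,5)
scan_cleavage_sites <- function(protein) {
  if (length(protein) != 1L || is.na(protein)) {
    abort("`protein` must be a single string.")
  }
  protein <- toupper(protein)
  find_all <- function(pattern, len, motif, priority) {
    m <- gregexpr(paste0("(?=", pattern, ")"), protein, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble(motif = motif, start = as.integer(m) - 1L,
           end = as.integer(m) - 1L + len, priority = priority)
  }
  cand <- bind_rows(
    find_all("R[^R]{2}R", 4L, "RXXR", 1L),
    find_all("KR", 2L, "KR", 2L),
    find_all("RR", 2L, "RR", 3L)
  )
  if (is.null(cand) || nrow(cand) == 0) {
    return(tibble(motif = character(), start = integer(), end = integer()))
  }
  cand <- arrange(cand, .data$start, .data$priority)
  accepted <- integer(0)
  occupied_until <- -1L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= occupied_until) {
      keep[i] <- TRUE
      occupied_until <- cand$end[i]
    }
  }
  cand[keep, c("motif", "start", "end")]
}

#' Classify a precursor segment as acidic spacer or peptide candidate
#'
#' The segments left between cleavage motifs are either acidic spacers
#' (propeptide filler, removed during processing) or the mature peptides
#' themselves. A segment is called a spacer when its Asp+Glu fraction is
#' at least `de_spacer` (default 0.30), or when its side-chain formal
#' charge (K/R minus D/E; termini are not free on an internal segment) is
#' at most -2 and the Asp+Glu fraction is at least `de_acidic`. The
#' default `de_acidic = 0.30` keeps the charge arm inert — several
#' genuine anionic mature peptides in this family reach charge -4 with a
#' D/E fraction just below 0.30, so a looser acidic-charge arm would
#' swallow them; lower `de_acidic` to re-arm it for precursor families
#' with milder peptide acidity. The defaults keep every reported
#' mature-peptide composition on the peptide side while canonical acidic
#' spacers classify as spacers.
#'
#' @param segment Amino-acid string (non-empty).
#' @param de_spacer,de_acidic Asp+Glu fraction thresholds.
#' @return `"spacer"` or `"peptide-candidate"`.
#' @export
#' @examples
#' classify_segment("DEEDSEE")      # spacer
#' classify_segment("GLVTNLLSSVR")  # peptide-candidate
classify_segment <- function(segment, de_spacer = 0.30, de_acidic = 0.30) {
  if (length(segment) != 1L || is.na(segment) || !nzchar(segment)) {
    abort("`segment` must be a single non-empty string.")
  }
  chars <- strsplit(toupper(segment), "", fixed = TRUE)[[1]]
  de_frac <- mean(chars %in% c("D", "E"))
  side_charge <- sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
  if (de_frac >= de_spacer || (side_charge <= -2L && de_frac >= de_acidic)) {
    "spacer"
  } else {
    "peptide-candidate"
  }
}

#' Annotate translated ORFs as secretory peptide precursors
#'
#' For each protein: call (or look up) the signal peptide, scan the mature
#' region for cleavage motifs, and tile the post-signal region into
#' classified segments. This is the precursor-architecture annotation that
#' [predict_peptides()] turns into mature peptide sequences.
#'
#' @param proteins Data frame with columns `protein_id` and `aa_seq`
#'   (e.g. `find_orfs()` output with `orf_id` renamed, or any protein
#'   table).
#' @param signal Either `"builtin"` (the heuristic of
#'   [detect_signal_peptide()]) or a data frame of external calls with
#'   columns `protein_id` and `cleavage_pos` (0-based first mature
#'   residue; optional `score`). External calls bypass the heuristic;
#'   proteins absent from the table get no signal call.
#' @param min_core_hydropathy Passed to [detect_signal_peptide()].
#' @param de_spacer,de_acidic Passed to [classify_segment()].
#' @return A tibble with one row per protein: `protein_id`, `aa_seq`,
#'   `signal_pos`, `signal_score`, `signal_source` (NA when no call),
#'   `n_sites`, and list-columns `sites` (tibbles from
#'   [scan_cleavage_sites()], restricted to the post-signal region) and
#'   `segments` (tibbles with `start`, `end`, `seq`, `class`,
#'   `followed_by`).
#' @export
annotate_precursors <- function(proteins, signal = "builtin",
                                min_core_hydropathy = 2.0,
                                de_spacer = 0.30, de_acidic = 0.30) {
  proteins <- as_tibble(proteins)
  if ("orf_id" %in% names(proteins) && !"protein_id" %in% names(proteins)) {
    proteins <- rename(proteins, protein_id = "orf_id")
  }
  if (!all(c("protein_id", "aa_seq") %in% names(proteins))) {
    abort("`proteins` needs columns `protein_id` (or `orf_id`) and `aa_seq`.")
  }
  external <- NULL
  if (is.data.frame(signal)) {
    external <- as_tibble(signal)
    if (!all(c("protein_id", "cleavage_pos") %in% names(external))) {
      abort("External signal table needs columns `protein_id` and `cleavage_pos`.")
    }
  } else if (!identical(signal, "builtin")) {
    abort("`signal` must be \"builtin\" or a data frame of external calls.")
  }

  empty_ann <- tibble(
    protein_id = character(), aa_seq = character(), signal_pos = integer(),
    signal_score = numeric(), signal_source = character(),
    n_sites = integer(), sites = list(), segments = list()
  )
  if (nrow(proteins) == 0) return(empty_ann)

  rows <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    id <- as.character(proteins$protein_id[i])
    aa <- toupper(as.character(proteins$aa_seq[i]))
    n <- nchar(aa)

    if (is.null(external)) {
      call <- detect_signal_peptide(aa, min_core_hydropathy)
    } else {
      hit <- which(external$protein_id == id)
      call <- if (length(hit) == 0) NULL else list(
        cleavage_pos = as.integer(external$cleavage_pos[hit[1]]),
        score = if ("score" %in% names(external))
          as.numeric(external$score[hit[1]]) else NA_real_,
        source = "external"
      )
      if (!is.null(call) &&
          (call$cleavage_pos < 1L || call$cleavage_pos > n - 1L)) {
        abort(sprintf(
          "External cleavage_pos %d out of range for protein '%s' (length %d).",
          call$cleavage_pos, id, n
        ))
      }
    }

    if (is.null(call)) {
      return(tibble(
        protein_id = id, aa_seq = aa,
        signal_pos = NA_integer_, signal_score = NA_real_,
        signal_source = NA_character_, n_sites = NA_integer_,
        sites = list(NULL), segments = list(NULL)
      ))
    }

    sig <- call$cleavage_pos
    sites <- scan_cleavage_sites(aa)
    sites <- filter(sites, .data$start >= sig)

    # tile the post-signal region around the motif spans
    segs <- list()
    prev <- sig
    bounds <- rbind(
      if (nrow(sites) > 0) cbind(sites$start, sites$end) else NULL,
      c(n, n)
    )
    for (j in seq_len(nrow(bounds))) {
      s0 <- bounds[j, 1]; s1 <- bounds[j, 2]
      if (s0 > prev) {
        seq_j <- substr(aa, prev + 1L, s0)
        segs[[length(segs) + 1L]] <- tibble(
          start = prev, end = s0, seq = seq_j,
          class = classify_segment(seq_j, de_spacer, de_acidic),
          followed_by = if (s0 == n) "end" else "motif"
        )
      }
      prev <- s1
    }
    segments <- if (length(segs) > 0) bind_rows(segs) else
      tibble(start = integer(), end = integer(), seq = character(),
             class = character(), followed_by = character())

    tibble(
      protein_id = id, aa_seq = aa,
      signal_pos = as.integer(sig), signal_score = call$score,
      signal_source = call$source, n_sites = nrow(sites),
      sites = list(sites), segments = list(segments)
    )
  })
  rows
}

#' Predict mature peptides from annotated precursors
#'
#' Applies standard prohormone processing rules to each annotated
#' precursor: the post-signal region is split at the cleavage motifs
#' (motif residues are excised and belong to neither flank), acidic
#' spacer segments are dropped, and the remaining segments become mature
#' peptides numbered N- to C-terminally. A glycine immediately preceding
#' a cleavage motif (or closing the protein's C-terminus) is read as the
#' amide donor: the peptide is flagged `amidated` and the Gly removed.
#' A precursor carrying a signal peptide but no cleavage motif yields a
#' single low-confidence peptide spanning the whole post-signal region.
#'
#' @param annotations Output of [annotate_precursors()]; every row must
#'   carry a signal-peptide call — filter the no-call rows first.
#' @param min_len Peptides shorter than this after processing are
#'   discarded (default 4).
#' @param keep_dibasic Retain the cleavage motif on the upstream fragment
#'   instead of excising it (non-default convention, for comparison with
#'   reports that keep the dibasic on the peptide).
#' @return A tibble with columns `precursor_id`, `ordinal`, `seq`,
#'   `amidated`, `confidence` ("normal" or "low").
#' @export
predict_peptides <- function(annotations, min_len = 4L, keep_dibasic = FALSE) {
  min_len <- .assert_count(min_len, "min_len", min = 1L)
  annotations <- as_tibble(annotations)
  needed <- c("protein_id", "aa_seq", "signal_pos", "segments", "sites")
  if (!all(needed %in% names(annotations))) {
    abort("`annotations` must come from annotate_precursors().")
  }
  if (nrow(annotations) > 0 && anyNA(annotations$signal_pos)) {
    abort(paste(
      "Some annotations have no signal-peptide call;",
      "filter to rows with a call (e.g. !is.na(signal_pos)) before predicting."
    ))
  }

  empty_pep <- tibble(
    precursor_id = character(), ordinal = integer(), seq = character(),
    amidated = logical(), confidence = character()
  )
  if (nrow(annotations) == 0) return(empty_pep)

  res <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    id <- annotations$protein_id[i]
    aa <- annotations$aa_seq[i]
    sig <- annotations$signal_pos[i]
    segments <- annotations$segments[[i]]
    sites <- annotations$sites[[i]]
    n <- nchar(aa)

    if (nrow(sites) == 0) {
      whole <- substr(aa, sig + 1L, n)
      amid <- endsWith(whole, "G") && nchar(whole) > 1L
      if (amid) whole <- substr(whole, 1L, nchar(whole) - 1L)
      if (nchar(whole) < min_len) return(NULL)
      return(tibble(precursor_id = id, ordinal = 1L, seq = whole,
                    amidated = amid, confidence = "low"))
    }

    peps <- filter(segments, .data$class == "peptide-candidate")
    if (nrow(peps) == 0) return(NULL)
    out <- purrr::map_dfr(seq_len(nrow(peps)), function(j) {
      s <- peps$seq[j]
      if (keep_dibasic && peps$followed_by[j] == "motif") {
        site <- sites[sites$start == peps$end[j], ]
        if (nrow(site) == 1) s <- paste0(s, substr(aa, site$start + 1L, site$end))
      }
      amid <- !keep_dibasic && endsWith(s, "G") && nchar(s) > 1L
      if (amid) s <- substr(s, 1L, nchar(s) - 1L)
      tibble(seq = s, amidated = amid)
    })
    out <- filter(out, nchar(.data$seq) >= min_len)
    if (nrow(out) == 0) return(NULL)
    mutate(out, precursor_id = id, ordinal = row_number(),
           confidence = "normal") |>
      select("precursor_id", "ordinal", "seq", "amidated", "confidence")
  })
  if (nrow(res) == 0) empty_pep else res
}
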