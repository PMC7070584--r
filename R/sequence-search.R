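#' Expand peptides into a single-substitution variant library
#'
#' For each query peptide of length L, emits the original plus the 19 x L
#' sequences obtained by substituting every position with every
#' alternative residue — the library used to search translated
#' transcript collections for close isoforms of a known peptide. For
#' mutually non-overlapping originals the library size is exactly
#' sum(1 + 19 L); variants shared between originals are stored once.
#'
#' @param peptides Character vector of amino-acid sequences (or a data
#'   frame with a `seq` column), each non-empty over the 20-letter
#'   alphabet. Names, if present, become query ids.
#' @return A list of class `fsap_variant_library`: `originals` (tibble:
#'   `query_id`, `seq`), `members` (tibble: `seq`, `n_origins`), and
#'   `provenance` (tibble: `seq`, `query_id`, `pos` 1-based, `sub`; the
#'   original itself has `pos = NA`).
#' @export
#' @examples
#' lib <- expand_single_substitution_variants(c("ACDEFGHIKL", "MNPQRSTVWY"))
#' nrow(lib$members)  # 382
expand_single_substitution_variants <- function(peptides) {
  if (is.data.frame(peptides)) peptides <- setNames(peptides$seq,
                                                    peptides$query_id %||% NULL)
  if (length(peptides) == 0) abort("`peptides` must be non-empty.")
  ids <- names(peptides) %||% paste0("query_", seq_along(peptides))
  if (is.null(names(peptides))) names(peptides) <- ids

  prov <- purrr::map2_dfr(peptides, ids, function(p, id) {
    chars <- .residues(p, what = "query peptide")
    L <- length(chars)
    rows <- list(tibble(seq = .paste_seq(chars), query_id = id,
                        pos = NA_integer_, sub = NA_character_))
    for (i in seq_len(L)) {
      alts <- setdiff(.AA_ORDER, chars[i])
      v <- vapply(alts, function(a) {
        cc <- chars; cc[i] <- a; .paste_seq(cc)
      }, character(1))
      rows[[i + 1L]] <- tibble(seq = unname(v), query_id = id,
                               pos = i, sub = alts)
    }
    bind_rows(rows)
  })

  members <- prov |>
    group_by(.data$seq) |>
    summarise(n_origins = dplyr::n_distinct(.data$query_id), .groups = "drop")
  out <- list(
    originals = tibble(query_id = ids, seq = toupper(unname(peptides))),
    members = members,
    provenance = prov
  )
  class(out) <- "fsap_variant_library"
  out
}

#' @export
print.fsap_variant_library <- function(x, ...) {
  cat(sprintf("<fsap_variant_library> %d original(s), %d unique member sequences\n",
              nrow(x$originals), nrow(x$members)))
  invisible(x)
}

#' Search a protein collection for variant-library members
#'
#' Exact (case-insensitive) substring search of every library member
#' against every protein — the in-silico equivalent of screening a
#' translated transcript library in a text editor with the peptides as
#' search strings, widened to one-mismatch isoforms by the variant
#' expansion. Proteins containing `X` wildcards never match (strict
#' equality).
#'
#' @param library A `fsap_variant_library` (or a character vector of
#'   sequences, searched as-is).
#' @param proteins Data frame with `protein_id` and `aa_seq`.
#' @return A list of class `fsap_search_result`: `hits` (tibble: `seq`,
#'   `protein_id`, `offset` 0-based, `query_id`, `is_original`) and
#'   `summary` (tibble, one row per original: `query_id`, `seq`,
#'   `found_direct`, `found_variant`).
#' @export
search_library <- function(library, proteins) {
  if (is.character(library)) {
    library <- expand_single_substitution_variants(library)
    library$members <- filter(library$provenance, is.na(.data$pos)) |>
      distinct(.data$seq) |> mutate(n_origins = 1L)
    library$provenance <- filter(library$provenance, is.na(.data$pos))
  }
  stopifnot(inherits(library, "fsap_variant_library"))
  proteins <- as_tibble(proteins)
  if (nrow(proteins) > 0 &&
      !all(c("protein_id", "aa_seq") %in% names(proteins))) {
    abort("`proteins` needs columns `protein_id` and `aa_seq`.")
  }

  hits <- if (nrow(proteins) == 0 || nrow(library$members) == 0) NULL else {
    seqs <- toupper(proteins$aa_seq)
    purrr::map_dfr(library$members$seq, function(q) {
      found <- purrr::map_dfr(seq_along(seqs), function(i) {
        m <- gregexpr(q, seqs[i], fixed = TRUE)[[1]]
        if (m[1] == -1) return(NULL)
        tibble(seq = q, protein_id = as.character(proteins$protein_id[i]),
               offset = as.integer(m) - 1L)
      })
      found
    })
  }
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- tibble(seq = character(), protein_id = character(),
                   offset = integer())
  }

  prov <- library$provenance
  hits <- hits |>
    left_join(prov |> select("seq", "query_id", "pos") |>
                distinct(.data$seq, .data$query_id, .keep_all = TRUE),
              by = "seq", relationship = "many-to-many") |>
    mutate(is_original = is.na(.data$pos)) |>
    select("seq", "protein_id", "offset", "query_id", "is_original")

  summary <- purrr::map_dfr(seq_len(nrow(library$originals)), function(k) {
    qid <- library$originals$query_id[k]
    oseq <- library$originals$seq[k]
    direct <- any(hits$seq == oseq)
    variant <- any(hits$query_id == qid & hits$seq != oseq, na.rm = TRUE)
    tibble(query_id = qid, seq = oseq,
           found_direct = direct, found_variant = variant)
  })

  out <- list(hits = hits, summary = summary)
  class(out) <- "fsap_search_result"
  out
}

#' @export
print.fsap_search_result <- function(x, ...) {
  cat(sprintf("<fsap_search_result> %d hit(s); %d/%d originals found directly\n",
              nrow(x$hits), sum(x$summary$found_direct), nrow(x$summary)))
  invisible(x)
}
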