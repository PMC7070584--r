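# shared helpers

.assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

.assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(as.numeric(x))
}

# Run `expr` under a seed without disturbing the caller's RNG state.
# A NULL seed leaves the ambient RNG in charge.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

.paste_seq <- function(chars) paste(chars, collapse = "")

# uniform integer in [lo, hi] that is safe when lo == hi (unlike sample(lo:hi))
.sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}
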