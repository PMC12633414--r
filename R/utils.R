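# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Map A,C,G,T -> 1..4; anything else (gap, N, ambiguity) -> 0 ("absent").
encode_bases <- function(x) {
  code <- match(toupper(x), BASES)
  code[is.na(code)] <- 0L
  as.integer(code)
}

decode_bases <- function(code, absent = "-") {
  out <- rep(absent, length(code))
  out[code > 0L] <- BASES[code[code > 0L]]
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}

# Validate a tidy interval table (0-based half-open).
check_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with chrom/start/end columns.", arg))
  }
  if (nrow(x) > 0L) {
    if (any(x$start < 0)) abort(sprintf("`%s`: start must be >= 0.", arg))
    if (any(x$end <= x$start)) abort(sprintf("`%s`: end must exceed start.", arg))
  }
  invisible(x)
}

# Seeded evaluation that restores the caller's RNG state afterwards, so every
# generator is a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}
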