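# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make e.g. psi = 10% of 5 active blocks select 0 instead of 1.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Deterministically mix a user seed with one or more integer keys into a seed
# in [0, 2^31). Small multiplier keeps every intermediate product exactly
# representable in doubles, so the stream derivation is platform stable.
mix_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 69069 + as.numeric(k) + 12345) %% m
  }
  as.integer(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards (same contract as withr::with_seed, kept local so
# the package controls the RNG kind).
with_stage_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stop_invalid <- function(msg) {
  abort(msg, class = "bumfdr_invalid_input")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop_invalid(sprintf("`%s` must be a whole number.", name))
  }
  invisible(as.integer(x))
}
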