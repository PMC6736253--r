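# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is restored afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

assert_prob <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1,
              sprintf("`%s` must be a single probability in [0, 1]", name))
}

# Half-up rounding (round-half-away-from-zero for positive values), used for
# display percentages; regular round() is banker's rounding.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
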