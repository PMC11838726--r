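# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit. All exported stochastic operations route their randomness through
# this, so no function perturbs global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Unit conversion constants: interfaces use mN/m and um, internals are SI.
.MN_PER_M_TO_N_PER_M <- 1e-3
.UM_TO_M <- 1e-6

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_field(field, "must be finite and > 0")
  }
  invisible(x)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_field(field, "must be a single value in [0, 1]")
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
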