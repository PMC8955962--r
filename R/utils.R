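# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers are not perturbed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive independent child seeds (< 2^31) from a root seed, by substream name.
# All package randomness flows from one root seed through here.
derive_seeds <- function(seed, n, stream = "default") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  with_seed((abs(as.integer(seed)) + offset) %% .Machine$integer.max,
            sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; the comparison arithmetic in the
#' method table uses conventional half-up rounding to reproduce printed
#' deltas exactly.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Stop with a consistent error class so tests can assert on failures.
sq_stop <- function(msg, ..., class = "synquant_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
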