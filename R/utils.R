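# Internal helpers: classed errors and scoped RNG control.

ecg_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ecgvae_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ecg_check <- function(cond, msg, class = "ecgvae_invalid_argument") {
  if (!isTRUE(cond)) ecg_abort(msg, class)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic operations in the package route through this so the
# determinism contracts (same seed => same output) hold regardless of what
# the user did with .Random.seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item seed derivation from a master seed (Knuth-style
# multiplicative hash, kept below 2^31 so it is a valid R integer seed).
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) + 1
  ((s * 48271 + as.numeric(index) * 2246822519) %% m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
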