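# Seed plumbing shared by all generators. Every exported stochastic
# operation takes an explicit `seed`; the global RNG state is restored on
# exit so library code never perturbs a caller's stream.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `code`, and restores the previous state (or removes the seed if none
#' existed).
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed and a label
#'
#' Deterministically maps `(master, label)` to an integer in `[1, 2^31 - 2]`
#' so that pipeline stages consume independent, reproducible substreams.
#' Different labels give different streams for the same master seed.
#'
#' @param master Integer master seed.
#' @param label Character stage label, e.g. `"cohort"`.
#' @return Integer seed.
#' @export
#' @examples
#' derive_seed(1, "cohort") != derive_seed(1, "eeg")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(as.integer(master)) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Internal: clamp with an optional warning used by effect maps.
clip <- function(x, lo, hi, warn_label = NULL) {
  out <- pmin(pmax(x, lo), hi)
  if (!is.null(warn_label) && any(out != x)) {
    warning(sprintf("%s clipped to [%g, %g] for %d value(s)",
                    warn_label, lo, hi, sum(out != x)), call. = FALSE)
  }
  out
}
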