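#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state on exit, so seeded helpers do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from a master seed
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` distinct seeds in `[1, 2^31 - 2]`.
#' @keywords internal
child_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Overflow-safe inverse logit; clamped away from exact 0/1 so downstream
# window selection and log-likelihoods stay finite.
sigmoid <- function(eta) {
  p <- stats::plogis(eta)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
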