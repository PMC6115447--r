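#' Expanding-window selection schedule
#'
#' The schedule is controlled by a step size SZ and a maximum iteration count
#' C with SZ * C = 1. At iteration t the self-training (SSL) window covers
#' probabilities within t*SZ/4 of 0 or 1, and the active-learning (AL)
#' window covers probabilities within t*SZ/4 of 0.5, so the total
#' probability mass covered grows by SZ per iteration and reaches the whole
#' (0, 1) interval at t = C.
#'
#' @param step_size SZ, in (0, 1]. Exactly one of `step_size` /
#'   `max_iterations` may be given; the other is derived.
#' @param max_iterations C, a positive integer. Default C = 10 (SZ = 0.1).
#' @return An object of class `assl_schedule`.
#' @export
new_schedule <- function(step_size = NULL, max_iterations = NULL) {
  if (is.null(step_size) && is.null(max_iterations)) max_iterations <- 10L
  if (!is.null(step_size) && (step_size <= 0 || step_size > 1)) {
    stop("step_size must be in (0, 1]")
  }
  if (!is.null(max_iterations) && max_iterations < 1) {
    stop("max_iterations must be >= 1")
  }
  if (is.null(step_size)) step_size <- 1 / max_iterations
  if (is.null(max_iterations)) max_iterations <- round(1 / step_size)
  max_iterations <- as.integer(max_iterations)
  if (abs(step_size * max_iterations - 1) > 1e-12) {
    stop("schedule requires step_size * max_iterations = 1")
  }
  structure(list(step_size = step_size, max_iterations = max_iterations),
            class = "assl_schedule")
}

#' @exportS3Method print assl_schedule
print.assl_schedule <- function(x, ...) {
  cat("Expanding-window schedule: SZ =", x$step_size,
      ", C =", x$max_iterations, "\n")
  invisible(x)
}

#' Selection windows at a given iteration
#'
#' Returns the SSL and AL half-widths for iteration `t`: both equal
#' `t * SZ / 4` (capped at 0.25). The SSL window is the pair of tails
#' `[0, gamma] U [1 - gamma, 1]`; the AL window is the open band
#' `(0.5 - alpha, 0.5 + alpha)`. With SZ = 0.2 this reproduces the
#' iteration-1 windows (0, 0.05) U (0.95, 1) for SSL and (0.45, 0.55)
#' for AL, and covers all of (0, 1) at t = 5.
#'
#' @param schedule An `assl_schedule`.
#' @param iteration Iteration number t, `1 <= t <= max_iterations`.
#' @return List with `ssl_halfwidth` (gamma) and `al_halfwidth` (alpha).
#' @export
windows_at <- function(schedule, iteration) {
  stopifnot(inherits(schedule, "assl_schedule"))
  t <- iteration
  if (length(t) != 1L || t < 1L || t > schedule$max_iterations ||
      t != round(t)) {
    stop("iteration must be an integer in [1, max_iterations]")
  }
  h <- min(t * schedule$step_size / 4, 0.25)
  list(ssl_halfwidth = h, al_halfwidth = h)
}

#' High-confidence (self-training) selection
#'
#' Selects samples whose predicted probability lies in the closed tails
#' `prob <= gamma` or `prob >= 1 - gamma` -- the high-confidence samples a
#' self-training step would pseudo-label.
#'
#' @param probs Probability vector in (0, 1).
#' @param gamma SSL half-width in `[0, 0.25]`.
#' @return Integer indices of selected samples (possibly empty).
#' @export
select_confident <- function(probs, gamma) {
  stopifnot(gamma >= 0, gamma <= 0.25)
  which(probs <= gamma | probs >= 1 - gamma)
}

#' Uncertainty (active-learning) selection
#'
#' Selects samples in the open band `0.5 - alpha < prob < 0.5 + alpha` --
#' the most uncertain samples nearest the decision boundary. Strict
#' inequalities keep this band disjoint from the closed SSL tails when
#' `gamma + alpha = 0.5`.
#'
#' @param probs Probability vector in (0, 1).
#' @param alpha AL half-width in `[0, 0.25]`.
#' @return Integer indices of selected samples (possibly empty).
#' @export
select_uncertain <- function(probs, alpha) {
  stopifnot(alpha >= 0, alpha <= 0.25)
  which(probs > 0.5 - alpha & probs < 0.5 + alpha)
}

#' Pseudo-label assignment
#'
#' Assigns class 1 when the predicted probability exceeds 0.5, else class 0;
#' a probability of exactly 0.5 receives class 0 (a fixed, documented tie
#' rule -- such a sample sits in the AL window and is flip-checked on later
#' iterations).
#'
#' @param probs Probability vector.
#' @param indices Indices to label.
#' @return Integer 0/1 labels, one per index.
#' @export
assign_pseudo_labels <- function(probs, indices) {
  as.integer(probs[indices] > 0.5)
}
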