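#' Weighted L1-penalized binary logistic regression
#'
#' Fits the lasso-penalized logistic model
#' \deqn{\min_\beta \; -\sum_i w_i \,\ell(y_i, \beta_0 + x_i^T\beta)
#'   + \lambda \|\beta\|_1}
#' where \eqn{\ell} is the Bernoulli log-likelihood, the intercept is
#' unpenalized, and the penalty \eqn{\lambda} is expressed on the summed
#' (not averaged) log-likelihood scale, so it is invariant to duplicating a
#' sample versus doubling its weight.
#'
#' Genes are standardized to zero weighted mean and unit weighted variance on
#' the fitting samples before the penalty is applied; returned coefficients
#' are on the original expression scale. Coefficients whose standardized
#' magnitude falls below 1e-8 are set to exact zero, and the nonzero pattern
#' defines the selected genes.
#'
#' @param X Expression matrix (samples x genes), see [as_expression_matrix()].
#' @param y Binary 0/1 label vector, length `nrow(X)`.
#' @param weights Nonnegative sample weights; samples with weight 0 are
#'   removed before fitting and cannot influence the result. Default all 1.
#' @param penalty Nonnegative lasso penalty \eqn{\lambda}.
#' @return An object of class `assl_model`: list with `intercept`,
#'   `coefficients` (named numeric, length p), `penalty`, `gene_ids`.
#' @export
fit_l1_logistic <- function(X, y, weights = NULL, penalty) {
  X <- as_expression_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("y must have one label per sample")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || anyNA(weights)) {
    stop("weights must be nonnegative, length n")
  }
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0) {
    stop("penalty must be a single nonnegative number")
  }

  keep <- weights > 0
  if (!any(keep)) stop("all sample weights are zero")
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  wk <- weights[keep]
  if (length(unique(yk)) < 2L) {
    stop("degenerate fit: only one class present among positive-weight samples")
  }

  std <- standardize_cols(Xk, wk)
  ybar <- stats::weighted.mean(yk, wk)

  # Large penalty: closed-form full-shrinkage solution, avoids solver edge
  # cases at lambda beyond lambda_max.
  lmax <- lambda_max(std$X, yk, wk)
  if (penalty >= lmax) {
    beta <- stats::setNames(numeric(p), colnames(X))
    return(new_assl_model(stats::qlogis(ybar), beta, penalty, colnames(X)))
  }

  # Warm-started path from lambda_max down to the requested penalty: much
  # faster than a cold single-lambda fit and yields the same minimizer.
  lam_path <- if (penalty > 0 && penalty < 0.95 * lmax) {
    exp(seq(log(lmax), log(penalty), length.out = 15L))
  } else {
    penalty
  }
  fit <- glmnet::glmnet(
    std$X, yk,
    family = "binomial", weights = wk,
    lambda = lam_path / sum(wk),
    standardize = FALSE, thresh = 1e-12, maxit = 1e5
  )
  b_std <- as.numeric(fit$beta[, length(lam_path)])
  b0_std <- as.numeric(fit$a0[length(lam_path)])
  b_std[abs(b_std) < 1e-8] <- 0

  beta <- b_std / std$scale
  intercept <- b0_std - sum(beta * std$center)
  new_assl_model(intercept, stats::setNames(beta, colnames(X)),
                 penalty, colnames(X))
}

new_assl_model <- function(intercept, coefficients, penalty, gene_ids) {
  structure(
    list(intercept = intercept, coefficients = coefficients,
         penalty = penalty, gene_ids = gene_ids),
    class = "assl_model"
  )
}

# Weighted column standardization; constant columns get scale 1 so they pass
# through unchanged (and pick up a zero coefficient).
standardize_cols <- function(X, w) {
  sw <- sum(w)
  center <- as.numeric(crossprod(w, X)) / sw
  Xc <- sweep(X, 2L, center, "-")
  scale <- sqrt(as.numeric(crossprod(w, Xc^2)) / sw)
  scale[scale < 1e-12] <- 1
  list(X = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

#' Smallest penalty with an all-zero coefficient vector
#'
#' For the intercept-only fit (fitted probability equal to the weighted label
#' mean), the Karush-Kuhn-Tucker conditions give
#' \eqn{\lambda_{max} = \max_j |\sum_i w_i x_{ij}(y_i - \bar y_w)|}.
#'
#' @param X Numeric matrix (already standardized if that is the fitting
#'   scale).
#' @param y Binary labels.
#' @param w Positive weights.
#' @return The penalty threshold on the summed-log-likelihood scale.
#' @keywords internal
lambda_max <- function(X, y, w) {
  ybar <- stats::weighted.mean(y, w)
  max(abs(as.numeric(crossprod(X, w * (y - ybar)))))
}

#' Predict class-1 probabilities
#'
#' Evaluates the logistic link \eqn{P(y=1|x) = e^{\eta}/(1+e^{\eta})} with
#' \eqn{\eta = \beta_0 + x^T\beta}, overflow-safely.
#'
#' @param model An `assl_model`.
#' @param X Expression matrix with the same genes the model was fit on.
#' @return Probability vector in (0, 1), one entry per row of `X`.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "assl_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$coefficients)) {
    stop("gene dimension mismatch between model and matrix")
  }
  eta <- model$intercept + as.numeric(X %*% model$coefficients)
  sigmoid(eta)
}

#' @exportS3Method predict assl_model
predict.assl_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_prob(object, newdata)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @exportS3Method print assl_model
print.assl_model <- function(x, ...) {
  cat("L1-penalized logistic model:", sum(x$coefficients != 0), "of",
      length(x$coefficients), "genes selected, lambda =",
      format(x$penalty, digits = 4), "\n")
  invisible(x)
}

#' Choose the lasso penalty by cross-validation
#'
#' Splits the positive-weight samples into class-stratified folds, fits the
#' penalty path on each training split, and scores the held-out samples.
#' Two scoring types are available: `"loglik"` (weighted held-out Bernoulli
#' log-likelihood) and `"class"` (held-out misclassification rate at the 0.5
#' threshold). With `rule = "min"` the best-scoring grid value is returned,
#' ties going to the larger penalty (the sparser model); with `rule = "1se"`
#' the largest penalty whose mean score is within one standard error of the
#' best is returned.
#'
#' The self-training loop tunes with `type = "class", rule = "1se"`: the
#' log-likelihood optimum at these sample sizes under-penalizes, producing
#' fits that reproduce their own training labels exactly, which would make
#' pseudo-label flip detection vacuous (see the methods vignette).
#'
#' @param X Expression matrix.
#' @param y Binary labels.
#' @param weights Nonnegative sample weights (default all 1).
#' @param grid Increasing vector of candidate penalties. Default: 50
#'   log-spaced values from `1e-3 * lambda_max` up to `lambda_max`, computed
#'   on the standardized fitting samples.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param type Held-out score: `"loglik"` or `"class"`.
#' @param rule `"min"` (best score, ties to larger penalty) or `"1se"`.
#' @return The selected penalty (a single number from `grid`).
#' @export
tune_penalty <- function(X, y, weights = NULL, grid = NULL, folds = 5L,
                         seed = 1L, type = c("loglik", "class"),
                         rule = c("min", "1se")) {
  type <- match.arg(type)
  rule <- match.arg(rule)
  X <- as_expression_matrix(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (folds < 2L) stop("folds must be >= 2")
  keep <- which(weights > 0)
  if (length(keep) < folds) stop("fewer positive-weight samples than folds")
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  wk <- weights[keep]

  if (is.null(grid)) {
    std <- standardize_cols(Xk, wk)
    lmax <- lambda_max(std$X, yk, wk)
    grid <- exp(seq(log(1e-3 * lmax), log(lmax), length.out = 50L))
  }
  if (is.unsorted(grid) || any(grid <= 0)) {
    stop("grid must be positive and increasing")
  }

  fold_id <- with_seed(seed, stratified_folds(yk, folds))
  # Per-fold scores per grid value (higher is better), grid order.
  scores <- matrix(NA_real_, folds, length(grid))
  lam_desc <- rev(grid)  # glmnet expects a decreasing path
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    std <- standardize_cols(Xk[tr, , drop = FALSE], wk[tr])
    fit <- glmnet::glmnet(
      std$X, yk[tr],
      family = "binomial", weights = wk[tr],
      lambda = lam_desc / sum(wk[tr]),
      standardize = FALSE, thresh = 1e-10, maxit = 1e5
    )
    Xte <- sweep(sweep(Xk[te, , drop = FALSE], 2L, std$center, "-"),
                 2L, std$scale, "/")
    eta <- sweep(as.matrix(Xte %*% fit$beta), 2L, as.numeric(fit$a0), "+")
    sc <- if (type == "loglik") {
      pr <- sigmoid(eta)
      as.numeric(crossprod(wk[te] * yk[te], log(pr)) +
                   crossprod(wk[te] * (1 - yk[te]), log(1 - pr))) / sum(wk[te])
    } else {
      -as.numeric(crossprod(wk[te], (eta > 0) != yk[te])) / sum(wk[te])
    }
    scores[f, ] <- rev(sc)
  }
  m <- colMeans(scores)
  if (rule == "min") {
    # which.max on the reversed vector finds the last (largest-lambda) max.
    best <- length(grid) + 1L - which.max(rev(m))
  } else {
    se <- apply(scores, 2L, stats::sd) / sqrt(folds)
    top <- which.max(m)
    best <- max(which(m >= m[top] - se[top]))
  }
  grid[best]
}

# Class-stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Serialize a fitted model to JSON
#'
#' @param model An `assl_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "assl_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.numeric(model$coefficients),
         penalty = model$penalty,
         gene_ids = model$gene_ids),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON file path.
#' @return An `assl_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_assl_model(obj$intercept,
                 stats::setNames(as.numeric(obj$coefficients), obj$gene_ids),
                 obj$penalty, obj$gene_ids)
}
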