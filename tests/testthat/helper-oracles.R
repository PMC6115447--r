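# Independent oracles and small fixture builders used across the suite.

# Unregularized logistic MLE by Newton-Raphson iteration on (1, X).
# Independent of the glmnet-based fitting path.
newton_logistic <- function(X, y, weights = rep(1, nrow(X)),
                            tol = 1e-12, max_iter = 100L) {
  Z <- cbind(1, X)
  beta <- numeric(ncol(Z))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- weights * mu * (1 - mu)
    grad <- as.numeric(crossprod(Z, weights * (y - mu)))
    H <- crossprod(Z, Z * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

# AUC by exhaustive positive-negative pair counting (ties count half).
auc_brute <- function(probs, truth) {
  pos <- probs[truth == 1]
  neg <- probs[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Well-conditioned non-separable logistic toy, deterministic per seed.
make_toy <- function(n = 20, p = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
    eta <- 0.8 * X[, 1] - 0.5 * X[, min(2, p)]
    y <- rbinom(n, 1, plogis(eta))
    # regenerate until both classes present and not separable-looking
    while (length(unique(y)) < 2) y <- rbinom(n, 1, plogis(eta))
    list(X = X, y = y)
  })
}

# Small labeled/unlabeled pool with a clear two-class structure in p dims.
make_small_pool <- function(n_lab = 30, n_unl = 20, p = 5, sep = 3,
                            seed = 1) {
  withr::with_seed(seed, {
    n <- n_lab + n_unl
    cls <- rep(0:1, length.out = n)
    X <- matrix(rnorm(n * p), n, p) + sep * cls
    dimnames(X) <- list(paste0("s", 1:n), paste0("g", 1:p))
    status <- c(rep("labeled", n_lab), rep("unlabeled", n_unl))
    label <- ifelse(status == "labeled", cls, NA_integer_)
    new_pool(X, status, label, truth = cls)
  })
}

# Eq.-3-scale penalized objective, for direct objective comparisons.
lasso_objective <- function(model, X, y, weights = rep(1, nrow(X))) {
  eta <- model$intercept + as.numeric(X %*% model$coefficients)
  nll <- -sum(weights * (y * eta - log1p(exp(eta))))
  nll + model$penalty * sum(abs(model$coefficients))
}
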