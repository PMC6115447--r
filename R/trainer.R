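#' Construct a labeled/unlabeled sample pool
#'
#' Bundles the expression matrix with per-sample training status and labels.
#' Status is one of `labeled` (original manual label), `unlabeled` (in the
#' selection pool), `pseudo_ssl` / `pseudo_al` (pseudo-labeled by the
#' classifier through the SSL or AL window), or `oracle_labeled` (hidden
#' truth revealed under a manual-labeling budget). Originally-labeled
#' samples never change status or label during training.
#'
#' @param X Expression matrix (samples x genes).
#' @param status Character vector: `"labeled"` or `"unlabeled"` per sample.
#' @param label Integer 0/1 labels; must be present exactly for labeled
#'   samples (NA for unlabeled).
#' @param truth Optional hidden true labels (simulation only), used for
#'   oracle labeling and evaluation.
#' @return An object of class `assl_pool`.
#' @export
new_pool <- function(X, status, label, truth = NULL) {
  X <- as_expression_matrix(X)
  n <- nrow(X)
  if (length(status) != n || length(label) != n) {
    stop("status and label must have one entry per sample")
  }
  if (!all(status %in% c("labeled", "unlabeled"))) {
    stop("initial status must be 'labeled' or 'unlabeled'")
  }
  label <- as.integer(label)
  if (any(status == "labeled" & is.na(label))) {
    stop("labeled samples must carry a 0/1 label")
  }
  if (any(status == "unlabeled" & !is.na(label))) {
    stop("unlabeled samples must have label NA")
  }
  if (!all(label[!is.na(label)] %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!is.null(truth)) {
    truth <- as.integer(truth)
    if (length(truth) != n || !all(truth %in% c(0L, 1L))) {
      stop("truth must be a binary vector of length n")
    }
  }
  structure(list(X = X, status = status, label = label, truth = truth,
                 original_status = status, original_label = label),
            class = "assl_pool")
}

#' Build a pool from a synthetic dataset
#'
#' Labeled samples receive their true label; unlabeled samples keep the
#' hidden truth for oracle labeling and evaluation only.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @return An `assl_pool`.
#' @export
pool_from_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  label <- ifelse(dataset$status == "labeled", dataset$truth, NA_integer_)
  new_pool(dataset$X, dataset$status, label, truth = dataset$truth)
}

#' Build a pool from an expression matrix and a label table
#'
#' @param X Expression matrix.
#' @param labels Data frame from [read_labels()]; NA labels mark unlabeled
#'   samples. Sample ids must match the matrix rows (any order).
#' @return An `assl_pool` (no hidden truth, so oracle-labeling variants
#'   cannot run on it).
#' @export
pool_from_labels <- function(X, labels) {
  X <- as_expression_matrix(X)
  if (!setequal(labels$sample_id, rownames(X))) {
    stop("label file sample ids do not match the expression matrix")
  }
  lab <- labels$label[match(rownames(X), labels$sample_id)]
  status <- ifelse(is.na(lab), "unlabeled", "labeled")
  new_pool(X, status, lab)
}

#' @exportS3Method print assl_pool
print.assl_pool <- function(x, ...) {
  cat("Sample pool:", nrow(x$X), "samples x", ncol(x$X), "genes;",
      sum(x$status == "labeled"), "labeled,",
      sum(x$status == "unlabeled"), "unlabeled\n")
  invisible(x)
}

#' Trainer configuration for the six comparison variants
#'
#' Variants: `logistic` (single lasso-logistic fit on the labeled samples),
#' `al_lo` (active learning only; selected samples oracle-labeled under a
#' budget), `ssl_lo` (self-training only; pseudo-labels), `assl_lo` (both
#' windows; AL selections oracle-labeled under the budget, SSL selections
#' pseudo-labeled), `auto_assl_a` (both windows, everything pseudo-labeled
#' by the classifier, no update mechanism), `auto_assl_b` (as A plus the
#' pseudo-label update mechanism). All looping variants share the same
#' expanding-window schedule.
#'
#' @param variant One of the six variant names above.
#' @param schedule An `assl_schedule`; default C = 10.
#' @param oracle_budget_fraction Fraction of the unlabeled pool that may be
#'   oracle-labeled (al_lo / assl_lo only); default 0.4.
#' @param penalty Optional fixed lasso penalty; if NULL it is tuned once by
#'   cross-validation on the initial labeled set and held fixed across
#'   iterations.
#' @param folds CV folds for penalty tuning.
#' @param seed Integer seed (drives fold assignment and any tie shuffling).
#' @return A list of class `trainer_config`.
#' @export
trainer_config <- function(variant = c("auto_assl_b", "logistic", "al_lo",
                                       "ssl_lo", "assl_lo", "auto_assl_a"),
                           schedule = new_schedule(),
                           oracle_budget_fraction = 0.4,
                           penalty = NULL, folds = 5L, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(schedule, "assl_schedule"))
  if (oracle_budget_fraction < 0 || oracle_budget_fraction > 1) {
    stop("oracle_budget_fraction must be in [0, 1]")
  }
  structure(list(variant = variant, schedule = schedule,
                 oracle_budget_fraction = oracle_budget_fraction,
                 update_mechanism = (variant == "auto_assl_b"),
                 penalty = penalty, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "trainer_config")
}

empty_records <- function() {
  data.frame(sample_index = integer(0), selector = character(0),
             iteration_assigned = integer(0), prob_at_assignment = numeric(0),
             current_label = integer(0), revision_count = integer(0),
             active = logical(0), stringsAsFactors = FALSE)
}

#' Detect pseudo-labels contradicted by the current model
#'
#' A pseudo-label record flips when the label implied by the current model's
#' predicted probability (via the 0.5 rule of [assign_pseudo_labels()])
#' differs from the record's current label.
#'
#' @param model Current `assl_model`.
#' @param records Pseudo-label record data frame (active rows are checked).
#' @param X Expression matrix the records index into.
#' @return Data frame of flips: `sample_index`, `selector`, `new_prob`,
#'   `implied_label`.
#' @export
detect_flips <- function(model, records, X) {
  act <- records[records$active, , drop = FALSE]
  if (nrow(act) == 0L) {
    return(data.frame(sample_index = integer(0), selector = character(0),
                      new_prob = numeric(0), implied_label = integer(0),
                      stringsAsFactors = FALSE))
  }
  probs <- predict_prob(model, X[act$sample_index, , drop = FALSE])
  implied <- as.integer(probs > 0.5)
  hit <- implied != act$current_label
  data.frame(sample_index = act$sample_index[hit],
             selector = act$selector[hit],
             new_prob = probs[hit], implied_label = implied[hit],
             stringsAsFactors = FALSE)
}

#' Route flipped pseudo-labels (the update mechanism)
#'
#' SSL-selected flips are returned to the unlabeled pool (label removed,
#' record retired, to be selected afresh later); AL-selected flips have
#' their label revised in place and stay in the training set.
#' Originally-labeled samples are never touched.
#'
#' @param pool An `assl_pool`.
#' @param flips Data frame from [detect_flips()].
#' @param records Pseudo-label record data frame.
#' @return List with updated `pool` and `records`, plus counts `returned`
#'   (SSL flips sent back to the pool) and `revised` (AL labels negated).
#' @export
apply_update_mechanism <- function(pool, flips, records) {
  returned <- 0L
  revised <- 0L
  for (k in seq_len(nrow(flips))) {
    i <- flips$sample_index[k]
    if (!pool$status[i] %in% c("pseudo_ssl", "pseudo_al")) {
      stop("flip refers to a sample that is not pseudo-labeled")
    }
    r <- which(records$active & records$sample_index == i)
    if (flips$selector[k] == "SSL") {
      pool$status[i] <- "unlabeled"
      pool$label[i] <- NA_integer_
      records$active[r] <- FALSE
      returned <- returned + 1L
    } else {
      pool$label[i] <- 1L - pool$label[i]
      records$current_label[r] <- pool$label[i]
      records$revision_count[r] <- records$revision_count[r] + 1L
      revised <- revised + 1L
    }
  }
  list(pool = pool, records = records, returned = returned, revised = revised)
}

#' Reveal hidden true labels under a manual-labeling budget
#'
#' Emulates manual expert annotation in simulation: up to `budget_remaining`
#' of the requested samples receive their hidden true label, prioritized by
#' proximity of their predicted probability to 0.5 (the most uncertain
#' first). Indices beyond the budget are skipped and stay in the pool.
#'
#' @param pool An `assl_pool` with hidden truth.
#' @param indices Candidate sample indices.
#' @param budget_remaining Nonnegative integer.
#' @param probs Predicted probabilities for `indices` (same order), used for
#'   the priority ranking.
#' @return List with `indices` (the labeled subset), `labels` (their true
#'   labels) and `budget_remaining` after consumption.
#' @export
oracle_label <- function(pool, indices, budget_remaining, probs) {
  if (is.null(pool$truth)) {
    stop("no hidden truth available: supply manual labels for these samples")
  }
  stopifnot(budget_remaining >= 0, length(probs) == length(indices))
  take <- min(length(indices), budget_remaining)
  # equal distances from 0.5 are broken toward the lower probability
  ord <- order(abs(probs - 0.5), probs)[seq_len(take)]
  chosen <- indices[ord]
  list(indices = chosen, labels = pool$truth[chosen],
       budget_remaining = budget_remaining - take)
}

#' Run one training variant on a pool
#'
#' Implements the select-retrain-update workflow: fit an initial lasso
#' logistic model on the labeled samples; per iteration t, score the pool,
#' select through the SSL tail window and/or the AL boundary window at the
#' iteration-t half-widths, attach pseudo-labels (or oracle labels for the
#' budgeted variants), refit on the enlarged training set, and -- for the
#' update-mechanism variant -- flip-check all active pseudo-labels against
#' the new model and route the contradicted ones. The loop stops after C
#' iterations or as soon as the pool empties.
#'
#' @param pool An `assl_pool`.
#' @param config A `trainer_config`.
#' @return List of class `assl_fit`: `model` (final `assl_model`), `log`
#'   (one data-frame row per iteration), `records` (pseudo-label records
#'   with provenance), `pool` (final pool state), `penalty` (the penalty
#'   used), `config`.
#' @export
run_variant <- function(pool, config) {
  stopifnot(inherits(pool, "assl_pool"), inherits(config, "trainer_config"))
  lab0 <- pool$status == "labeled"
  if (length(unique(pool$label[lab0])) < 2L) {
    stop("initial labeled set must contain both classes")
  }

  penalty <- config$penalty
  if (is.null(penalty)) {
    penalty <- tune_penalty(pool$X[lab0, , drop = FALSE], pool$label[lab0],
                            folds = config$folds, seed = config$seed,
                            type = "class", rule = "1se")
  }
  model <- fit_l1_logistic(pool$X[lab0, , drop = FALSE], pool$label[lab0],
                           penalty = penalty)

  log_rows <- list()
  records <- empty_records()

  if (config$variant == "logistic") {
    log_rows[[1]] <- data.frame(
      iteration = 0L, train_size = sum(lab0), pool_size = sum(!lab0),
      n_ssl = 0L, n_al = 0L, n_oracle = 0L,
      flips_detected = 0L, flips_returned = 0L, flips_revised = 0L)
    return(structure(list(model = model, log = do.call(rbind, log_rows),
                          records = records, pool = pool, penalty = penalty,
                          config = config),
                     class = "assl_fit"))
  }

  n2 <- sum(pool$status == "unlabeled")
  budget <- if (config$variant %in% c("al_lo", "assl_lo")) {
    as.integer(round(config$oracle_budget_fraction * n2))
  } else {
    0L
  }
  use_ssl <- config$variant %in% c("ssl_lo", "assl_lo", "auto_assl_a",
                                   "auto_assl_b")
  use_al <- config$variant %in% c("al_lo", "assl_lo", "auto_assl_a",
                                  "auto_assl_b")
  al_is_oracle <- config$variant %in% c("al_lo", "assl_lo")

  C <- config$schedule$max_iterations
  for (t in seq_len(C)) {
    pool_idx <- which(pool$status == "unlabeled")
    if (length(pool_idx) == 0L) break  # pool exhausted: early termination

    probs <- predict_prob(model, pool$X[pool_idx, , drop = FALSE])
    win <- windows_at(config$schedule, t)

    ssl_loc <- if (use_ssl) select_confident(probs, win$ssl_halfwidth)
               else integer(0)
    al_loc <- if (use_al) select_uncertain(probs, win$al_halfwidth)
              else integer(0)

    n_oracle_t <- 0L
    if (length(ssl_loc) > 0L) {
      idx <- pool_idx[ssl_loc]
      labs <- assign_pseudo_labels(probs, ssl_loc)
      pool$status[idx] <- "pseudo_ssl"
      pool$label[idx] <- labs
      records <- rbind(records, data.frame(
        sample_index = idx, selector = "SSL", iteration_assigned = t,
        prob_at_assignment = probs[ssl_loc], current_label = labs,
        revision_count = 0L, active = TRUE, stringsAsFactors = FALSE))
    }
    if (length(al_loc) > 0L) {
      idx <- pool_idx[al_loc]
      if (al_is_oracle) {
        got <- oracle_label(pool, idx, budget, probs[al_loc])
        budget <- got$budget_remaining
        n_oracle_t <- length(got$indices)
        if (n_oracle_t > 0L) {
          pool$status[got$indices] <- "oracle_labeled"
          pool$label[got$indices] <- got$labels
        }
        # beyond-budget candidates stay unlabeled in the pool
      } else {
        labs <- assign_pseudo_labels(probs, al_loc)
        pool$status[idx] <- "pseudo_al"
        pool$label[idx] <- labs
        records <- rbind(records, data.frame(
          sample_index = idx, selector = "AL", iteration_assigned = t,
          prob_at_assignment = probs[al_loc], current_label = labs,
          revision_count = 0L, active = TRUE, stringsAsFactors = FALSE))
      }
    }

    train <- pool$status != "unlabeled"
    model <- fit_l1_logistic(pool$X[train, , drop = FALSE],
                             pool$label[train], penalty = penalty)

    n_flip <- 0L; n_ret <- 0L; n_rev <- 0L
    if (config$update_mechanism) {
      flips <- detect_flips(model, records, pool$X)
      n_flip <- nrow(flips)
      if (n_flip > 0L) {
        upd <- apply_update_mechanism(pool, flips, records)
        pool <- upd$pool
        records <- upd$records
        n_ret <- upd$returned
        n_rev <- upd$revised
      }
    }

    log_rows[[t]] <- data.frame(
      iteration = t,
      train_size = sum(pool$status != "unlabeled"),
      pool_size = sum(pool$status == "unlabeled"),
      n_ssl = length(ssl_loc),
      n_al = if (al_is_oracle) n_oracle_t else length(al_loc),
      n_oracle = n_oracle_t,
      flips_detected = n_flip, flips_returned = n_ret, flips_revised = n_rev)
  }

  structure(list(model = model, log = do.call(rbind, log_rows),
                 records = records, pool = pool, penalty = penalty,
                 config = config),
            class = "assl_fit")
}

#' @exportS3Method print assl_fit
print.assl_fit <- function(x, ...) {
  cat("Variant", x$config$variant, "-", nrow(x$log), "iteration(s),",
      "final training size", x$log$train_size[nrow(x$log)], "of",
      nrow(x$pool$X), "samples\n")
  print(x$model)
  invisible(x)
}
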