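#' Gene-selection (support recovery) metrics
#'
#' Counts selected genes from the nonzero pattern of the fitted coefficient
#' vector (intercept excluded): NC is the number of true causal genes
#' selected, NS the total number selected; sensitivity = TP/(TP+FN) =
#' NC/n_true and specificity = TN/(TN+FP) = 1 - (NS-NC)/(p-n_true), both at
#' the gene level.
#'
#' @param model An `assl_model`.
#' @param true_support Indices of the causal genes.
#' @param p Total gene count (defaults to the model's).
#' @return Data frame row with `nc`, `ns`, `sensitivity`, `specificity`.
#' @export
gene_selection_metrics <- function(model, true_support,
                                   p = length(model$coefficients)) {
  stopifnot(inherits(model, "assl_model"), all(true_support %in% seq_len(p)))
  nz <- which(model$coefficients != 0)
  nc <- length(intersect(nz, true_support))
  ns <- length(nz)
  n_true <- length(true_support)
  data.frame(nc = nc, ns = ns,
             sensitivity = nc / n_true,
             specificity = 1 - (ns - nc) / (p - n_true))
}

#' Area under the ROC curve by the rank statistic
#'
#' Midrank (Wilcoxon) estimator: the probability that a random positive
#' outranks a random negative, with ties counted half.
#'
#' @param probs Predicted probabilities or scores.
#' @param truth Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(probs, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: truth has a single class")
  r <- rank(probs)  # midranks for ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique scores, from the strictest (nothing
#' called positive) to the loosest (everything positive), producing a
#' monotone staircase from (0, 0) to (1, 1).
#'
#' @inheritParams auc_rank
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(probs, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) stop("ROC undefined: truth has a single class")
  ord <- order(probs, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1)
  fp <- cumsum(truth[ord] == 0)
  last <- !duplicated(probs[ord][seq_along(ord)], fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
}

#' Classification metrics on a held-out set
#'
#' Accuracy uses the 0.5 threshold with probability exactly 0.5 mapped to
#' class 0 (consistent with pseudo-label assignment); AUC is the midrank
#' rank statistic, and the ROC staircase is returned for plotting.
#'
#' @inheritParams auc_rank
#' @return List with `accuracy`, `auc`, `roc` (data frame of fpr/tpr).
#' @export
classification_metrics <- function(probs, truth) {
  if (length(probs) != length(truth)) stop("probs and truth lengths differ")
  pred <- as.integer(probs > 0.5)
  list(accuracy = mean(pred == truth),
       auc = auc_rank(probs, truth),
       roc = roc_points(probs, truth))
}

all_variants <- function() {
  c("logistic", "al_lo", "ssl_lo", "assl_lo", "auto_assl_a", "auto_assl_b")
}

#' Run a replicate-averaged comparison experiment
#'
#' For each replicate a child seed is derived from the master seed, one
#' dataset is simulated per group, and every requested variant is trained on
#' the identical dataset and mask (paired design) with the lasso penalty
#' tuned once on the shared initial labeled set. Classification metrics are
#' scored on the originally-unlabeled samples against the hidden truth;
#' gene-selection metrics come from each variant's final model.
#'
#' @param groups Character vector of group designs ("A", "B").
#' @param variants Variant names (default all six).
#' @param replicates Number of replicates (default 20).
#' @param master_seed Integer master seed.
#' @param schedule An `assl_schedule` shared by all looping variants.
#' @param config_args Extra arguments passed to [sim_config()] (e.g. a
#'   non-default `beta_true`).
#' @return List of class `assl_experiment`: `summary` (per group x variant
#'   means and standard deviations over replicates), `raw` (one row per
#'   replicate x group x variant), `replicates`, `master_seed`.
#' @export
run_experiment <- function(groups = "A", variants = all_variants(),
                           replicates = 20L, master_seed = 1L,
                           schedule = new_schedule(), config_args = list()) {
  stopifnot(replicates >= 1L)
  variants <- match.arg(variants, all_variants(), several.ok = TRUE)
  seeds <- matrix(child_seeds(master_seed, replicates * length(groups)),
                  nrow = replicates)
  rows <- list()
  for (gi in seq_along(groups)) {
    for (r in seq_len(replicates)) {
      res <- tryCatch(
        run_replicate(groups[gi], variants, seeds[r, gi], schedule,
                      config_args),
        error = function(e) {
          warning("replicate ", r, " group ", groups[gi], " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        res$replicate <- r
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  raw <- do.call(rbind, rows)
  structure(list(summary = summarize_experiment(raw), raw = raw,
                 replicates = replicates, master_seed = master_seed),
            class = "assl_experiment")
}

# One paired replicate: simulate once, share the tuned penalty, run each
# variant on an identical pool.
run_replicate <- function(group, variants, seed, schedule, config_args) {
  cfg <- do.call(sim_config, c(list(group = group, seed = seed), config_args))
  ds <- simulate_dataset(cfg)
  pool <- pool_from_dataset(ds)
  lab <- pool$status == "labeled"
  unl <- which(pool$status == "unlabeled")
  penalty <- tune_penalty(pool$X[lab, , drop = FALSE], pool$label[lab],
                          seed = seed, type = "class", rule = "1se")
  out <- lapply(variants, function(v) {
    fit <- run_variant(pool, trainer_config(
      variant = v, schedule = schedule, penalty = penalty, seed = seed))
    probs <- predict_prob(fit$model, pool$X[unl, , drop = FALSE])
    cls <- classification_metrics(probs, pool$truth[unl])
    gene <- gene_selection_metrics(fit$model, ds$true_support)
    # secondary figure: accuracy over the subset never oracle-labeled
    still <- fit$pool$status[unl] != "oracle_labeled"
    acc_excl <- if (any(still)) {
      mean((probs[still] > 0.5) == pool$truth[unl][still])
    } else {
      NA_real_
    }
    data.frame(group = group, variant = v, seed = seed,
               accuracy = cls$accuracy,
               accuracy_excl_oracle = acc_excl,
               auc = cls$auc,
               nc = gene$nc, ns = gene$ns,
               sensitivity = gene$sensitivity,
               specificity = gene$specificity,
               iterations = nrow(fit$log),
               penalty = penalty,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

summarize_experiment <- function(raw) {
  metrics <- c("accuracy", "auc", "nc", "ns", "sensitivity", "specificity")
  out <- list()
  for (g in unique(raw$group)) {
    for (v in unique(raw$variant)) {
      sub <- raw[raw$group == g & raw$variant == v, , drop = FALSE]
      row <- data.frame(group = g, variant = v, n_replicates = nrow(sub))
      for (m in metrics) {
        row[[paste0(m, "_mean")]] <- mean(sub[[m]])
        row[[paste0(m, "_sd")]] <- stats::sd(sub[[m]])
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' @exportS3Method print assl_experiment
print.assl_experiment <- function(x, ...) {
  cat("Comparison experiment:", x$replicates, "replicate(s), groups",
      paste(unique(x$summary$group), collapse = ", "), "\n")
  cols <- c("group", "variant", "accuracy_mean", "auc_mean", "nc_mean",
            "ns_mean", "sensitivity_mean", "specificity_mean")
  print(x$summary[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write experiment tables as TSV
#'
#' Emits `gene_selection.tsv` (NC, NS, sensitivity, specificity means and
#' sds), `auc.tsv`, `accuracy.tsv`, and `raw_replicates.tsv`, plus a
#' `schema.txt` documenting the columns. All files are UTF-8 TSV with '.'
#' as the decimal mark.
#'
#' @param experiment An `assl_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "assl_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- experiment$summary
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(s[, c("group", "variant", "n_replicates", "nc_mean", "nc_sd", "ns_mean",
           "ns_sd", "sensitivity_mean", "sensitivity_sd",
           "specificity_mean", "specificity_sd")], "gene_selection.tsv")
  wt(s[, c("group", "variant", "n_replicates", "auc_mean", "auc_sd")],
     "auc.tsv")
  wt(s[, c("group", "variant", "n_replicates", "accuracy_mean",
           "accuracy_sd")], "accuracy.tsv")
  wt(experiment$raw, "raw_replicates.tsv")
  writeLines(c(
    "gene_selection.tsv: per group x variant replicate means/sds of gene-level",
    "  selection counts (nc = causal genes selected, ns = genes selected) and",
    "  support-recovery sensitivity/specificity.",
    "auc.tsv: replicate mean/sd of the unlabeled-set AUC (midrank statistic).",
    "accuracy.tsv: replicate mean/sd of unlabeled-set classification accuracy.",
    "raw_replicates.tsv: one row per replicate x group x variant;",
    "  accuracy_excl_oracle excludes samples revealed by oracle labeling.",
    "All values are fractions in [0,1] unless the column is a count."),
    file.path(dir, "schema.txt"))
  invisible(dir)
}
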