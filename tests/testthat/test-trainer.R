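record_row <- function(idx, selector, label, prob = 0.9, active = TRUE) {
  data.frame(sample_index = idx, selector = selector,
             iteration_assigned = 1L, prob_at_assignment = prob,
             current_label = label, revision_count = 0L, active = active,
             stringsAsFactors = FALSE)
}

test_that("flip detection compares current labels with the model's implied labels", {
  X <- matrix(c(-2, 5, 0.5), ncol = 1, dimnames = list(paste0("s", 1:3), "g1"))
  # model with positive slope: probs ~ 0.12 / 0.99 / 0.62
  m <- autoassl:::new_assl_model(0, setNames(1, "g1"), 0, "g1")
  recs <- rbind(record_row(1L, "SSL", 1L),   # prob 0.12 -> implied 0: flip
                record_row(2L, "AL", 1L),    # prob 0.99 -> implied 1: no flip
                record_row(3L, "AL", 0L))    # prob 0.62 -> implied 1: flip
  flips <- detect_flips(m, recs, X)
  expect_equal(flips$sample_index, c(1L, 3L))
  expect_equal(flips$selector, c("SSL", "AL"))
  expect_equal(detect_flips(m, autoassl:::empty_records(), X)$sample_index,
               integer(0))
  # retired records are not flip-checked
  recs$active <- FALSE
  expect_equal(nrow(detect_flips(m, recs, X)), 0L)
})

test_that("the update mechanism routes SSL flips to the pool and revises AL flips in place", {
  pool <- make_small_pool(n_lab = 8, n_unl = 2, seed = 2)
  i_ssl <- which(pool$status == "unlabeled")[1]
  i_al <- which(pool$status == "unlabeled")[2]
  pool$status[i_ssl] <- "pseudo_ssl"; pool$label[i_ssl] <- 1L
  pool$status[i_al] <- "pseudo_al"; pool$label[i_al] <- 1L
  recs <- rbind(record_row(i_ssl, "SSL", 1L), record_row(i_al, "AL", 1L))
  flips <- data.frame(sample_index = c(i_ssl, i_al),
                      selector = c("SSL", "AL"),
                      new_prob = c(0.2, 0.3), implied_label = c(0L, 0L),
                      stringsAsFactors = FALSE)
  before_pool <- sum(pool$status == "unlabeled")
  upd <- apply_update_mechanism(pool, flips, recs)
  # SSL flip: back to the pool, label wiped, record retired
  expect_equal(upd$pool$status[i_ssl], "unlabeled")
  expect_true(is.na(upd$pool$label[i_ssl]))
  expect_false(upd$records$active[1])
  expect_equal(sum(upd$pool$status == "unlabeled"), before_pool + 1L)
  # AL flip: label negated in place, still in the training set
  expect_equal(upd$pool$status[i_al], "pseudo_al")
  expect_equal(upd$pool$label[i_al], 0L)
  expect_equal(upd$records$revision_count[2], 1L)
  expect_equal(c(upd$returned, upd$revised), c(1L, 1L))

  # zero flips: untouched pool
  none <- apply_update_mechanism(pool, flips[0, ], recs)
  expect_identical(none$pool, pool)

  # flips must reference pseudo-labeled samples
  bad <- flips
  bad$sample_index[1] <- 1L  # an originally-labeled sample
  expect_error(apply_update_mechanism(pool, bad, recs), "pseudo")
})

test_that("oracle labeling honours the budget with closest-to-0.5 priority", {
  pool <- make_small_pool(n_lab = 10, n_unl = 5, seed = 3)
  idx <- which(pool$status == "unlabeled")[1:3]
  probs <- c(0.50, 0.52, 0.48)
  none <- oracle_label(pool, idx, 0, probs)
  expect_length(none$indices, 0)
  two <- oracle_label(pool, idx, 2, probs)
  expect_setequal(two$indices, idx[c(1, 3)])  # distances 0.00 and 0.02
  expect_equal(two$labels, pool$truth[two$indices])
  expect_equal(two$budget_remaining, 0)
  all3 <- oracle_label(pool, idx, 10, probs)
  expect_setequal(all3$indices, idx)
  expect_equal(all3$budget_remaining, 7)

  no_truth <- new_pool(pool$X, pool$original_status, pool$original_label)
  expect_error(oracle_label(no_truth, idx, 2, probs), "truth")
})

test_that("the plain logistic variant performs a single fit with no selections", {
  pool <- make_small_pool(seed = 4)
  fit <- run_variant(pool, trainer_config("logistic", penalty = 2, seed = 1))
  expect_equal(nrow(fit$log), 1L)
  expect_equal(fit$log$n_ssl + fit$log$n_al, 0L)
  expect_equal(nrow(fit$records), 0L)
  expect_s3_class(fit$model, "assl_model")
})

test_that("a well-separated pool is absorbed by SSL in one iteration and terminates early", {
  pool <- make_small_pool(n_lab = 30, n_unl = 20, sep = 8, seed = 7)
  fit <- run_variant(pool, trainer_config("auto_assl_b", penalty = 0.1,
                                          seed = 1))
  expect_equal(nrow(fit$log), 1L)  # pool emptied at t = 1
  expect_equal(fit$log$n_ssl[1], 20L)
  expect_equal(sum(fit$pool$status == "unlabeled"), 0L)
  expect_true(all(fit$pool$status[pool$status == "unlabeled"] == "pseudo_ssl"))
})

test_that("without flips the update mechanism changes nothing relative to variant A", {
  pool <- make_small_pool(n_lab = 30, n_unl = 20, sep = 8, seed = 8)
  fa <- run_variant(pool, trainer_config("auto_assl_a", penalty = 0.1, seed = 1))
  fb <- run_variant(pool, trainer_config("auto_assl_b", penalty = 0.1, seed = 1))
  expect_equal(sum(fb$log$flips_detected), 0L)
  expect_equal(fa$model$coefficients, fb$model$coefficients, tolerance = 1e-8)
  expect_equal(fa$model$intercept, fb$model$intercept, tolerance = 1e-8)
})

test_that("sample conservation and label provenance hold across variants", {
  cfg <- sim_config(n1 = 40, n2 = 40, p = 60, n_true = 5,
                    beta_true = rep(2.5, 5), seed = 31)
  ds <- simulate_dataset(cfg)
  pool <- pool_from_dataset(ds)
  n <- nrow(pool$X)
  orig_lab <- which(pool$status == "labeled")
  for (v in c("ssl_lo", "al_lo", "assl_lo", "auto_assl_a", "auto_assl_b")) {
    fit <- run_variant(pool, trainer_config(v, penalty = 3, seed = 5))
    expect_true(all(fit$log$train_size + fit$log$pool_size == n),
                info = v)
    expect_lte(nrow(fit$log), 10L)
    expect_equal(fit$pool$label[orig_lab], pool$label[orig_lab], info = v)
    expect_equal(fit$pool$status[orig_lab], rep("labeled", length(orig_lab)),
                 info = v)
  }
})

test_that("non-oracle variants empty the pool by the final iteration", {
  cfg <- sim_config(n1 = 40, n2 = 40, p = 60, n_true = 5,
                    beta_true = rep(2.5, 5), seed = 32)
  pool <- pool_from_dataset(simulate_dataset(cfg))
  for (v in c("ssl_lo", "auto_assl_a", "auto_assl_b")) {
    fit <- run_variant(pool, trainer_config(v, penalty = 3, seed = 5))
    if (v == "ssl_lo") {
      # SSL alone covers only the tails; whatever remains sat inside the
      # final AL band at selection time. The last refit can drift those
      # probabilities slightly, hence the margin around (0.25, 0.75).
      left <- which(fit$pool$status == "unlabeled")
      if (length(left) > 0) {
        pr <- predict_prob(fit$model, fit$pool$X[left, , drop = FALSE])
        expect_true(all(pr > 0.15 & pr < 0.85))
      }
    } else {
      expect_equal(sum(fit$pool$status == "unlabeled"), 0L)
    }
  }
})

test_that("the oracle budget caps manual labeling in al_lo and assl_lo", {
  cfg <- sim_config(n1 = 40, n2 = 40, p = 60, n_true = 5,
                    beta_true = rep(2.5, 5), seed = 33)
  pool <- pool_from_dataset(simulate_dataset(cfg))
  for (v in c("al_lo", "assl_lo")) {
    fit <- run_variant(pool, trainer_config(v, penalty = 3, seed = 5))
    expect_lte(sum(fit$pool$status == "oracle_labeled"), round(0.4 * 40))
  }
})

test_that("pool construction validates status and label consistency", {
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("s", 1:10), c("g1", "g2")))
  status <- rep(c("labeled", "unlabeled"), 5)
  label <- ifelse(status == "labeled", 1L, NA_integer_)
  label[1] <- 0L
  expect_s3_class(new_pool(X, status, label), "assl_pool")
  expect_error(new_pool(X, status, rep(1L, 10)), "NA")
  bad_lab <- label
  bad_lab[1] <- NA_integer_
  expect_error(new_pool(X, status, bad_lab), "0/1")
  expect_error(run_variant(new_pool(X, status, ifelse(status == "labeled",
                                                      1L, NA_integer_)),
                           trainer_config("logistic", penalty = 1)),
               "both classes")
})
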