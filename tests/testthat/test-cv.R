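cv_sim <- function(seed, task = "classification") {
  simulate_dataset(n_samples = 50, n_features = 15, task = task, seed = seed)
}
cv_ctl <- function(...) pirf_control(n_trees = 60, n_trees_cluster = 50, ...)

test_that("rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 40
      labels <- factor(sample(c("neg", "pos"), n, replace = TRUE))
      scores <- stats::runif(n) + 0.5 * (labels == "pos")
    })
    ref <- suppressMessages(
      as.numeric(pROC::auc(labels, scores, levels = c("neg", "pos"),
                           direction = "<")))
    expect_equal(rank_auc(scores, labels), ref, tolerance = 1e-12)
  }
  # tie handling gets half credit
  expect_equal(rank_auc(c(1, 1, 1, 1), factor(c("a", "a", "b", "b"))), 0.5)
})

test_that("fold assignments partition samples and respect stratification", {
  y <- factor(rep(c("a", "b"), c(30, 20)))
  folds <- make_folds(y, 5, "classification", seed = 2)
  expect_length(folds, 50L)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f), 10L)
    expect_setequal(unique(y[folds != f]), c("a", "b"))
  }
  # deterministic given the seed
  expect_identical(folds, make_folds(y, 5, "classification", seed = 2))
  # too few minority samples to stratify over 5 folds
  y_bad <- factor(rep(c("a", "b"), c(19, 1)))
  expect_error(make_folds(y_bad, 5, "classification", seed = 1), "absent")
})

test_that("cross-validation reports are deterministic and well-formed", {
  sim <- cv_sim(1)
  cv1 <- run_cv(sim$counts, sim$tree, sim$y, "classification",
                control = cv_ctl(), seed = 3)
  cv2 <- run_cv(sim$counts, sim$tree, sim$y, "classification",
                control = cv_ctl(), seed = 3)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(nrow(cv1$metrics), 5L)
  expect_equal(cv1$summary$mean[cv1$summary$metric == "error_rate"],
               mean(cv1$metrics$error_rate))
  expect_equal(cv1$summary$sd[cv1$summary$metric == "auc"],
               stats::sd(cv1$metrics$auc))
})

test_that("every fold obeys RMSE >= MAE in regression", {
  sim <- cv_sim(2, task = "regression")
  cv <- run_cv(sim$counts, sim$tree, sim$y, "regression",
               control = cv_ctl(), seed = 4)
  expect_true(all(cv$metrics$rmse >= cv$metrics$mae))
})

test_that("a null regression effect scores near the outcome spread", {
  sim <- simulate_dataset(n_samples = 50, n_features = 15,
                          task = "regression", effect_size = 0, seed = 9)
  cv <- run_cv(sim$counts, sim$tree, sim$y, "regression",
               control = cv_ctl(clustering = "disjoint"), seed = 9)
  rmse <- cv$summary$mean[cv$summary$metric == "rmse"]
  expect_lt(abs(rmse - stats::sd(sim$y)), 0.35 * stats::sd(sim$y))
})

test_that("per-fold results are exactly reproducible from train-only fits", {
  # the harness must touch no test row before prediction: refitting from
  # scratch on the training rows alone, with the fold's derived seed, must
  # give the identical metrics row
  sim <- cv_sim(3)
  ctl <- cv_ctl(preprocess = FALSE)
  rel <- sim$counts / rowSums(sim$counts)
  cv <- run_cv(rel, sim$tree, sim$y, "classification", control = ctl,
               seed = 6)
  f <- 2L
  train <- cv$folds != f
  refit <- pirf_fit(rel[train, , drop = FALSE], sim$tree, sim$y[train],
                    "classification", control = ctl,
                    seed = pirf:::derive_seed(6, "fold", f))
  pr <- predict(refit, rel[!train, , drop = FALSE], type = "prob")
  pred <- factor(refit$classes[max.col(pr, ties.method = "first")],
                 levels = refit$classes)
  ytest <- factor(sim$y[!train], levels = refit$classes)
  expect_identical(cv$metrics$error_rate[f], mean(pred != ytest))
  expect_identical(cv$metrics$auc[f], rank_auc(pr[, 2], ytest))

  # corrupting the held-out rows cannot change the trained model
  rel_poisoned <- rel
  rel_poisoned[!train, ] <- 1 / ncol(rel)
  refit2 <- pirf_fit(rel_poisoned[train, , drop = FALSE], sim$tree,
                     sim$y[train], "classification", control = ctl,
                     seed = pirf:::derive_seed(6, "fold", f))
  expect_identical(refit2$forest$trees, refit$forest$trees)
  expect_identical(refit2$probabilities$w, refit$probabilities$w)
})

test_that("variant comparison shares folds and orders probability variance", {
  sim <- cv_sim(4)
  cmp <- compare_variants(sim$counts, sim$tree, sim$y, "classification",
                          control = cv_ctl(), seed = 8)
  expect_setequal(unique(cmp$report$variant),
                  c("pirf", "uniform", "onecluster"))
  # shared folds: all variants carry the same assignment
  expect_identical(cmp$cv$pirf$folds, cmp$cv$uniform$folds)
  expect_identical(cmp$cv$pirf$folds, cmp$cv$onecluster$folds)
  # uniform probabilities have exactly zero variance
  expect_identical(unique(cmp$report$prob_variance[
    cmp$report$variant == "uniform"]), 0)
  # phylogenetic clustering sits between uniform and one-cluster
  expect_true(all(cmp$cv$pirf$prob_variance >= 0))
  expect_gte(mean(cmp$cv$onecluster$prob_variance),
             mean(cmp$cv$pirf$prob_variance))
})

test_that("cross-validation input contracts are enforced", {
  sim <- cv_sim(5)
  expect_error(run_cv(sim$counts[1:8, ], sim$tree, sim$y[1:8],
                      "classification", control = cv_ctl()), "at least 10")
})
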