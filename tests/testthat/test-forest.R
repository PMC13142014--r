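sep_classif <- function(seed = 1, n = 100) {
  # linearly separable two-feature problem with three noise features
  withr::with_seed(seed, {
    x1 <- c(stats::rnorm(n / 2, -2), stats::rnorm(n / 2, 2))
    X <- cbind(x1, matrix(stats::rnorm(n * 4), n, 4))
    colnames(X) <- paste0("f", 1:5)
    list(X = X, y = factor(rep(c("a", "b"), each = n / 2)))
  })
}

test_that("uniform weights reproduce standard random-forest behavior", {
  dat <- sep_classif()
  f <- grow_forest(dat$X, dat$y, "classification", n_trees = 120, seed = 4)
  expect_lt(oob_error(f, dat$X, dat$y), 0.10)
  pr <- predict(f, dat$X, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(dat$X)), tolerance = 1e-12)
  expect_equal(colnames(pr), c("a", "b"))
})

test_that("zero-probability features never appear as split variables", {
  dat <- sep_classif(2)
  w <- c(1, 0, 0, 0, 0)
  f <- grow_forest(dat$X, dat$y, "classification", n_trees = 60,
                   mtry = 1, weights = w, seed = 9)
  expect_identical(forest_used_features(f), 1L)

  w2 <- c(0.5, 0, 0.3, 0, 0.2)
  f2 <- grow_forest(dat$X, dat$y, "classification", n_trees = 60,
                    mtry = 3, weights = w2, seed = 9)
  expect_true(all(forest_used_features(f2) %in% c(1L, 3L, 5L)))
})

test_that("regression forests track a linear signal on OOB samples", {
  withr::with_seed(7, {
    n <- 150
    X <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- X[, 1]
  })
  f <- grow_forest(X, y, "regression", n_trees = 150, seed = 7)
  agg <- pirf:::cpp_oob_aggregate(f$trees, X, FALSE, 0L)
  keep <- agg$count > 0
  oob_pred <- agg$agg[keep, 1] / agg$count[keep]
  expect_gt(stats::cor(oob_pred, y[keep]), 0.8)
})

test_that("degenerate ensembles predict their constant leaves", {
  n <- 30
  X <- matrix(stats::runif(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  f <- grow_forest(X, rep(5, n), "regression", n_trees = 10, seed = 1)
  expect_equal(unname(predict(f, X)), rep(5, n))
})

test_that("a one-tree forest equals that tree's leaf lookup", {
  dat <- sep_classif(5, n = 40)
  f <- grow_forest(dat$X, dat$y, "classification", n_trees = 1, seed = 12)
  pred_r <- predict_tree_r(f$trees[[1]], dat$X, "classification", f$classes)
  expect_equal(as.character(predict(f, dat$X)), pred_r)

  fr <- grow_forest(dat$X, as.numeric(dat$y == "b"), "regression",
                    n_trees = 1, seed = 12)
  pred_rr <- predict_tree_r(fr$trees[[1]], dat$X, "regression")
  expect_equal(unname(predict(fr, dat$X)), pred_rr)
})

test_that("OOB error equals an R-side vote tally on a tiny fixture", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- factor(c("a", "a", "b", "b", "b"))
  })
  f <- grow_forest(X, y, "classification", n_trees = 25, seed = 31)
  # recompute the aggregated OOB vote in plain R from the stored trees
  agg <- matrix(0, 5, 2)
  cnt <- integer(5)
  for (tr in f$trees) {
    for (i in tr$oob + 1L) {
      node <- 1L
      while (tr$feature[node] >= 0L) {
        fidx <- tr$feature[node] + 1L
        node <- if (X[i, fidx] <= tr$threshold[node]) tr$left[node] + 1L
                else tr$right[node] + 1L
      }
      agg[i, ] <- agg[i, ] + tr$probs[node, ]
      cnt[i] <- cnt[i] + 1L
    }
  }
  keep <- cnt > 0
  pred <- f$classes[max.col(agg[keep, , drop = FALSE], ties.method = "first")]
  expected <- mean(pred != as.character(y)[keep])
  expect_equal(oob_error(f, X, y), expected)
})

test_that("root splits match exhaustive enumeration on tiny instances", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      n <- sample(8:20, 1)
      p <- sample(2:3, 1)
      X <- matrix(stats::rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("f", seq_len(p))))
      task <- sample(c("classification", "regression"), 1)
      y <- if (task == "classification")
        factor(sample(c("a", "b"), n, replace = TRUE)) else stats::rnorm(n)
    })
    if (task == "classification" && length(unique(y)) < 2) next
    # full-sample trees with all features as candidates: the root split is
    # the global best split
    f <- grow_forest(X, y, task, n_trees = 1, mtry = p, seed = seed,
                     bootstrap = FALSE, min_node_size = if (task == "regression") 5 else 1)
    oracle <- best_split_oracle(X, y, task)
    tr <- f$trees[[1]]
    if (is.na(oracle$feature)) {
      expect_identical(tr$feature[1], -1L)
    } else {
      expect_identical(tr$feature[1] + 1L, oracle$feature)
      expect_equal(tr$threshold[1], oracle$threshold, tolerance = 1e-12)
    }
  }
})

test_that("permutation importance singles out the driving feature", {
  hits <- 0L
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 80
      X <- matrix(stats::rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
      y <- factor(ifelse(X[, 3] > 0, "hi", "lo"))
    })
    f <- grow_forest(X, y, "classification", n_trees = 100, seed = seed)
    imp <- permutation_importance(f, X, y, seed = seed)
    if (which.max(imp) == 3L) hits <- hits + 1L
  }
  expect_equal(hits, 10L)
})

test_that("a feature used by no tree has importance exactly zero", {
  dat <- sep_classif(8)
  w <- c(0.6, 0.4, 0, 0, 0)
  f <- grow_forest(dat$X, dat$y, "classification", n_trees = 50,
                   mtry = 2, weights = w, seed = 2)
  imp <- permutation_importance(f, dat$X, dat$y, seed = 2)
  expect_identical(unname(imp[3:5]), c(0, 0, 0))
  expect_error(permutation_importance(f, dat$X, dat$y, n_permutations = 0),
               "n_permutations")
})

test_that("pure-noise features score near zero on average", {
  imps <- numeric(20)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 60
      X <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, paste0("f", 1:3)))
      y <- X[, 1] * 2 + stats::rnorm(n, 0, 0.3)
    })
    f <- grow_forest(X, y, "regression", n_trees = 80, seed = seed)
    imps[seed] <- permutation_importance(f, X, y, seed = seed)[3]
  }
  se <- stats::sd(imps) / sqrt(length(imps))
  expect_lt(abs(mean(imps)), 2 * se + 1e-3)
})

test_that("forests are bit-reproducible under a fixed seed", {
  dat <- sep_classif(6, n = 60)
  f1 <- grow_forest(dat$X, dat$y, "classification", n_trees = 40, seed = 99)
  f2 <- grow_forest(dat$X, dat$y, "classification", n_trees = 40, seed = 99)
  expect_identical(f1$trees, f2$trees)
  f3 <- grow_forest(dat$X, dat$y, "classification", n_trees = 40, seed = 100)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("forest input validation catches contract violations", {
  dat <- sep_classif(1, n = 20)
  expect_error(grow_forest(dat$X, dat$y, "classification", weights = rep(0, 5)),
               "zero")
  expect_error(grow_forest(dat$X, factor(rep("a", 20)), "classification"),
               "single class")
  expect_error(grow_forest(dat$X, dat$y, "classification", mtry = 0), "mtry")
  expect_error(grow_forest(dat$X, dat$y[1:5], "classification"), "length")
  expect_error(oob_error(grow_forest(dat$X, dat$y, "classification",
                                     n_trees = 5, seed = 1,
                                     bootstrap = FALSE), dat$X, dat$y),
               "out-of-bag")
})
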