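test_that("two tight groups on a line are split cleanly with k = 2", {
  d <- line_groups_dist()
  cl <- pam_clusters(d, 2)
  expect_equal(unname(cl$cluster_of[1:3]), rep(cl$cluster_of[[1]], 3))
  expect_equal(unname(cl$cluster_of[4:6]), rep(cl$cluster_of[[4]], 3))
  expect_false(cl$cluster_of[[1]] == cl$cluster_of[[4]])
  # PAM attains the exhaustive optimum here
  med_idx <- match(cl$medoids, cl$labels)
  expect_equal(pam_cost(d, med_idx), exhaustive_pam2_cost(d))
})

test_that("the single medoid at k = 1 minimizes total distance", {
  for (seed in 1:5) {
    d <- random_line_dist(9, seed)
    cl <- pam_clusters(d, 1)
    med <- match(cl$medoids, cl$labels)
    costs <- vapply(seq_len(nrow(d)), function(m) sum(d[, m]), numeric(1))
    expect_equal(sum(d[, med]), min(costs))
    expect_equal(unname(cl$cluster_of), rep(1L, 9))
  }
})

test_that("degenerate all-zero distances give a deterministic assignment", {
  d <- matrix(0, 5, 5, dimnames = list(paste0("f", 1:5), paste0("f", 1:5)))
  cl1 <- pam_clusters(d, 2)
  cl2 <- pam_clusters(d, 2)
  expect_identical(cl1$cluster_of, cl2$cluster_of)
  expect_equal(sum(cl1$cluster_sizes), 5L)
  med_idx <- match(cl1$medoids, cl1$labels)
  expect_equal(pam_cost(d, med_idx), 0)
})

test_that("invalid clustering inputs are rejected", {
  d <- line_groups_dist()
  expect_error(pam_clusters(d, 7), "between 1 and")
  expect_error(pam_clusters(matrix(1:6, 2, 3), 2), "square")
  asym <- d; asym[1, 2] <- 99
  expect_error(pam_clusters(asym, 2), "symmetric")
})

test_that("SWAP never worsens the BUILD objective", {
  for (seed in 1:10) {
    d <- random_line_dist(12, seed)
    build <- cluster::pam(stats::as.dist(d), k = 3, diss = TRUE,
                          do.swap = FALSE)
    full <- cluster::pam(stats::as.dist(d), k = 3, diss = TRUE)
    expect_lte(pam_cost(d, full$id.med), pam_cost(d, build$id.med) + 1e-12)
  }
})

test_that("PAM reaches the exhaustive 2-medoid optimum on most instances", {
  # instances are cophenetic matrices of the package's own tree model;
  # BUILD+SWAP is a local optimizer, so rare misses are tolerated provided
  # they are genuine swap-local optima (no improving single swap exists)
  hits <- 0L
  n_inst <- 100L
  for (seed in seq_len(n_inst)) {
    p <- 4 + seed %% 5
    d <- cophenetic_matrix(simulate_tree(p, seed = 1000 + seed))
    cl <- pam_clusters(d, 2)
    med <- match(cl$medoids, cl$labels)
    cost <- pam_cost(d, med)
    opt <- exhaustive_pam2_cost(d)
    if (abs(cost - opt) < 1e-12) {
      hits <- hits + 1L
    } else {
      expect_lte(cost, 1.05 * opt + 1e-12)
      for (m in 1:2) {
        for (j in setdiff(seq_len(p), med)) {
          cand <- med
          cand[m] <- j
          expect_gte(pam_cost(d, cand), cost - 1e-12)
        }
      }
    }
  }
  expect_gte(hits / n_inst, 0.95)
})

test_that("silhouette matches its defining formula", {
  # perfectly separated clusters: a = 0, b = 10 -> s = 1
  d <- matrix(10, 6, 6) - diag(10, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("f", 1:6), paste0("f", 1:6))
  cl <- make_clusters(c(1, 1, 1, 2, 2, 2))
  expect_equal(avg_silhouette_width(d, cl), 1)

  # all pairwise distances equal: a = b -> s = 0
  d_eq <- matrix(5, 6, 6) - diag(5, 6)
  dimnames(d_eq) <- dimnames(d)
  expect_equal(avg_silhouette_width(d_eq, cl), 0)

  # line example against the per-point oracle
  dl <- line_groups_dist()
  cl2 <- pam_clusters(dl, 2)
  expect_equal(avg_silhouette_width(dl, cl2),
               silhouette_oracle(dl, cl2$cluster_of), tolerance = 1e-10)

  expect_error(avg_silhouette_width(dl, pam_clusters(dl, 1)), "undefined")
})

test_that("silhouette agrees with the cluster package and stays in [-1, 1]", {
  for (seed in 1:10) {
    p <- sample(6:15, 1)
    d <- random_line_dist(p, 2000 + seed)
    k <- sample(2:4, 1)
    cl <- pam_clusters(d, k)
    s <- avg_silhouette_width(d, cl)
    expect_gte(s, -1); expect_lte(s, 1)
    ref <- mean(cluster::silhouette(cl$cluster_of, stats::as.dist(d))[, 3])
    expect_equal(s, ref, tolerance = 1e-10)
  }
})

test_that("singleton clusters contribute zero silhouette", {
  d <- line_groups_dist()
  cl <- make_clusters(c(1, 2, 2, 3, 3, 3))
  oracle <- silhouette_oracle(d, cl$cluster_of)
  expect_equal(avg_silhouette_width(d, cl), oracle, tolerance = 1e-12)
})

test_that("silhouette selection recovers the planted number of clusters", {
  # three well-separated blobs of five points each
  centers <- c(0, 50, 100)
  x <- withr::with_seed(11, as.vector(sapply(centers, function(m)
    m + stats::runif(5))))
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("f", 1:15), paste0("f", 1:15))
  cl <- select_k_phylo(d)
  expect_equal(cl$k, 3L)
  expect_equal(sort(cl$cluster_sizes), c(5L, 5L, 5L))
  profile <- attr(cl, "silhouette_by_k")
  expect_equal(unname(which.max(profile)), 2L) # k = 3 is second in 2..10
  expect_equal(cl$avg_silhouette, max(profile))
})

test_that("a two-clade tree yields two phylogenetic clusters", {
  nwk <- paste0("((", paste0("a", 1:8, ":0.1", collapse = ","), "):5,(",
                paste0("b", 1:8, ":0.1", collapse = ","), "):5);")
  tr <- read_tree_newick(nwk)
  cl <- select_k_phylo(cophenetic_matrix(tr))
  expect_equal(cl$k, 2L)
  expect_equal(sort(cl$cluster_sizes), c(8L, 8L))
})

test_that("k-range handling: tiny p collapses the range; p < 3 errors", {
  d <- random_line_dist(3, 5)
  cl <- select_k_phylo(d)
  expect_equal(cl$k, 2L)
  expect_error(select_k_phylo(random_line_dist(2, 5)), "at least 3")
})

test_that("cluster selection is invariant to label permutation", {
  d <- random_line_dist(12, 77)
  perm <- withr::with_seed(3, sample(12))
  dp <- d[perm, perm]
  cl <- select_k_phylo(d)
  clp <- select_k_phylo(dp)
  expect_equal(clp$k, cl$k)
  # same partition after relabeling
  part <- split(cl$labels, cl$cluster_of)
  partp <- split(clp$labels, clp$cluster_of)
  expect_setequal(
    unname(sapply(part, function(g) paste(sort(g), collapse = ","))),
    unname(sapply(partp, function(g) paste(sort(g), collapse = ","))))
})
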