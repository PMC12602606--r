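# Two well-separated point clouds in feature space, labels in names.
make_blobs <- function(n_per, n_feat = 50, centers = c(-2, 2), sd = 0.3, seed = 1) {
  set.seed(seed)
  k <- length(centers)
  x <- do.call(cbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_feat * n_per, mean = centers[j] * rep(c(1, -1), length.out = n_feat),
                 sd = sd), n_feat)
  }))
  dimnames(x) <- list(paste0("f", seq_len(n_feat)),
                      paste0("s", seq_len(k * n_per)))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

test_that("separable clouds give a 0/1 block consensus matrix and exact recovery", {
  bl <- make_blobs(6, centers = c(-2, 2))
  res <- consensus_cluster(bl$x, k_range = 2:3, reps = 50, seed = 7)
  cm <- res$consensus$k2
  same <- outer(bl$truth, bl$truth, "==")
  expect_true(all(cm[same] == 1))
  expect_true(all(cm[!same] == 0))
  expect_equal(ari_oracle(res$assignments$k2, bl$truth), 1)
})

test_that("p_item = 1 removes resampling randomness entirely", {
  bl <- make_blobs(5, centers = c(-1, 0, 1.5))
  res <- consensus_cluster(bl$x, k_range = 2:4, reps = 5, p_item = 1, seed = 1)
  for (cm in res$consensus) expect_true(all(cm %in% c(0, 1)))
})

test_that("consensus is label-invariant under sample permutation", {
  bl <- make_blobs(5)
  res1 <- consensus_cluster(bl$x, k_range = 2, reps = 40, seed = 3)
  perm <- c(4, 9, 1, 10, 2, 6, 8, 3, 7, 5)
  res2 <- consensus_cluster(bl$x[, perm], k_range = 2, reps = 40, seed = 3)
  s <- colnames(bl$x)
  # separable clouds: consensus entries are exactly 0/1, so reindexing the
  # permuted result must reproduce the original matrix
  expect_equal(res2$consensus$k2[s, s], res1$consensus$k2)
  # same-seed rerun is exactly identical
  res3 <- consensus_cluster(bl$x, k_range = 2, reps = 40, seed = 3)
  expect_identical(res1$consensus, res3$consensus)
})

test_that("constant features are dropped with a warning and preconditions hold", {
  bl <- make_blobs(4)
  x <- rbind(bl$x, const = rep(1, ncol(bl$x)))
  expect_warning(res <- consensus_cluster(x, k_range = 2, reps = 10, seed = 1),
                 "constant")
  expect_equal(ari_oracle(res$assignments$k2, bl$truth), 1)
  expect_error(consensus_cluster(bl$x[, 1:3], k_range = 2:4, reps = 5), "samples")
  expect_error(consensus_cluster(bl$x, k_range = 1:2, reps = 5), ">= 2")
})

test_that("final_assignments recovers blocks and renumbers by first occurrence", {
  m <- diag(6); m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  cl <- final_assignments(m, 2)
  expect_equal(unname(cl), c(1, 1, 1, 2, 2, 2))
  expect_equal(names(cl), paste0("s", 1:6))
  expect_equal(unname(final_assignments(m, 1)), rep(1, 6))
  expect_error(final_assignments(m, 7), "exceeds")
  # first-occurrence renumbering: reversing sample order flips labels
  rev_m <- m[6:1, 6:1]
  expect_equal(unname(final_assignments(rev_m, 2)), c(1, 1, 1, 2, 2, 2))
})

test_that("CDF and delta-area match the closed-form step-function case", {
  # construct a consensus_result by hand: entries all 0 or 1
  n <- 8
  cm1 <- diag(n); cm1[1:4, 1:4] <- 1; cm1[5:8, 5:8] <- 1
  dimnames(cm1) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- structure(list(consensus = list(k2 = cm1, k3 = cm1),
                        assignments = NULL,
                        params = list(k_range = 2:3)),
                   class = "consensus_result")
  out <- cdf_and_delta_area(res)
  f0 <- mean(cm1[upper.tri(cm1)] == 0)
  expect_equal(unname(out$area["k2"]), f0)
  expect_equal(unname(out$delta_area["k3"]), 0) # identical matrices
  # CDF properties
  for (cdf in out$cdf) {
    expect_true(all(diff(cdf$cdf) >= 0))
    expect_equal(cdf$cdf[nrow(cdf)], 1)
  }
})
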