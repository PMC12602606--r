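test_that("signature scores are rank sums with the stated edge cases", {
  expr <- matrix(c(10, 20, 30), 1, dimnames = list("g1", paste0("s", 1:3)))
  sc <- signature_score(expr, "g1")
  expect_equal(sc$score, c(1, 2, 3))
  # two genes both maximal in one sample over n = 4
  expr2 <- rbind(g1 = c(9, 1, 2, 3), g2 = c(8, 2, 3, 1))
  colnames(expr2) <- paste0("s", 1:4)
  sc2 <- signature_score(expr2, c("g1", "g2"))
  expect_equal(sc2$score[sc2$sample_id == "s1"], 8)
  # all-tied expression: every score g(n+1)/2
  expr3 <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_equal(signature_score(expr3, c("g1", "g2"))$score, rep(5, 4))
  expect_warning(signature_score(expr2, c("g1", "missing")), "missing")
  expect_error(signature_score(expr2, "nope"), "no signature gene")
  # score bounds for a g-gene signature over n samples
  set.seed(4)
  e <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  s <- signature_score(e, paste0("g", 1:4))$score
  expect_true(all(s >= 4 * 1 & s <= 4 * 10))
  # monotone invariance
  expect_equal(signature_score(exp(e), paste0("g", 1:4))$score, s)
})

test_that("GSEA enrichment score equals the hand-stepped running sum", {
  ranked <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("g", 1:10))
  sets <- list(top = c("g1", "g2", "g3"), mid = c("g4", "g7"),
               spread = c("g2", "g5", "g9"))
  res <- gsea_preranked(ranked, sets, n_perm = 50, min_size = 2, seed = 1)
  for (nm in names(sets)) {
    in_set <- names(sort(ranked, decreasing = TRUE)) %in% sets[[nm]]
    want <- gsea_walk_oracle(sort(ranked, decreasing = TRUE), in_set)
    expect_equal(res$es[res$set == nm], want, tolerance = 1e-12)
  }
  # extreme case: set = top genes drives ES towards 1
  extreme <- gsea_preranked(setNames(c(100, 90, 80, rep(0.001, 37)),
                                     paste0("g", 1:40)),
                            list(s = c("g1", "g2", "g3")), n_perm = 50,
                            min_size = 2, seed = 1)
  expect_gt(extreme$es, 0.95)
})

test_that("GSEA ES agrees with the fgsea statistic and p is seed-reproducible", {
  set.seed(12)
  ranked <- setNames(sort(rnorm(60), decreasing = TRUE), paste0("g", 1:60))
  sets <- list(a = paste0("g", c(1, 4, 9, 15, 22)),
               b = paste0("g", c(50, 53, 57, 59, 60)))
  res <- gsea_preranked(ranked, sets, n_perm = 100, seed = 5)
  for (nm in names(sets)) {
    ref <- fgsea::calcGseaStat(ranked, which(names(ranked) %in% sets[[nm]]))
    expect_equal(res$es[res$set == nm], ref, tolerance = 1e-9)
  }
  res2 <- gsea_preranked(ranked, sets, n_perm = 100, seed = 5)
  expect_identical(res, res2)
  res3 <- gsea_preranked(ranked, sets, n_perm = 100, seed = 6)
  expect_false(identical(res$p_value, res3$p_value))
})

test_that("weight 0 reduces the ES to the classical KS statistic", {
  set.seed(13)
  ranked <- setNames(sort(rnorm(20), decreasing = TRUE), paste0("g", 1:20))
  in_set <- c(1, 5, 8, 13, 17)
  res <- gsea_preranked(ranked, list(s = names(ranked)[in_set]), weight = 0,
                        n_perm = 20, seed = 1)
  # brute-force KS-style running sum with equal hit increments
  g <- length(in_set); n <- length(ranked)
  running <- cumsum(ifelse(seq_len(n) %in% in_set, 1 / g, -1 / (n - g)))
  expect_equal(res$es, running[which.max(abs(running))], tolerance = 1e-12)
})

test_that("small sets are skipped and set_ora shares the hypergeometric oracle", {
  ranked <- setNames(11:1, paste0("g", 1:11))
  expect_message(res <- gsea_preranked(ranked, list(tiny = c("g1", "g2")),
                                       n_perm = 10, seed = 1), "below min_size")
  expect_equal(nrow(res), 0)
  uni <- paste0("g", 1:20)
  out <- set_ora(uni[1:8], uni, list(s = uni[c(1:6, 15, 16)]))
  expect_equal(out$p_value, hypergeom_tail_oracle(6, 2, 2, 10), tolerance = 1e-12)
  empty <- set_ora(character(0), uni, list(s = uni[1:5]))
  expect_equal(empty$p_value, 1)
})
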