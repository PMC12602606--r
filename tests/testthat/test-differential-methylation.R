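test_that("dmp_test matches the closed-form two-sample t-test", {
  set.seed(1)
  n <- 10
  beta <- rbind(
    flat = rep(0.5, 2 * n) + rnorm(2 * n, sd = 0.01),
    shifted = c(rep(0.2, n), rep(0.8, n)) + rnorm(2 * n, sd = 0.005)
  )
  colnames(beta) <- paste0("s", seq_len(2 * n))
  beta <- pmin(pmax(beta, 0), 1)
  grp <- factor(rep(c("a", "b"), each = n))
  res <- dmp_test(beta, grp)
  # OLS on a group indicator is the pooled-variance two-sample t-test
  tt <- t.test(beta["shifted", grp == "b"], beta["shifted", grp == "a"],
               var.equal = TRUE)
  expect_equal(res$t_statistic[res$probe_id == "shifted"],
               unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value[res$probe_id == "shifted"], tt$p.value,
               tolerance = 1e-10)
  expect_equal(res$delta_beta[res$probe_id == "shifted"], 0.6, tolerance = 0.01)
  expect_true(res$significant[res$probe_id == "shifted"])
  expect_false(res$significant[res$probe_id == "flat"])
})

test_that("dmp_test agrees with limma's unmoderated fit", {
  set.seed(2)
  beta <- matrix(runif(300, 0.2, 0.8), 30,
                 dimnames = list(paste0("p", 1:30), paste0("s", 1:10)))
  grp <- factor(rep(c("a", "b"), each = 5))
  res <- dmp_test(beta, grp)
  design <- model.matrix(~grp)
  fit <- limma::lmFit(beta, design)
  ord_t <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  expect_equal(res$t_statistic, unname(ord_t), tolerance = 1e-10)
})

test_that("dmp_test handles missing values, covariates and singular designs", {
  set.seed(3)
  beta <- matrix(runif(100, 0.3, 0.7), 10,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:10)))
  grp <- factor(rep(c("a", "b"), each = 5))
  beta[1, 1:2] <- NA
  res <- dmp_test(beta, grp)
  expect_false(is.na(res$p_value[1]))
  full <- dmp_test(beta[-1, , drop = FALSE], grp)
  expect_equal(res$t_statistic[-1], full$t_statistic)
  # covariates enter the model
  cov <- data.frame(age = rnorm(10))
  res_cov <- dmp_test(beta, grp, covariates = cov)
  expect_false(all(res_cov$p_value[-1] == res$p_value[-1]))
  # collinear covariate errors with the column named
  expect_error(dmp_test(beta, grp,
                        covariates = data.frame(dup = as.numeric(grp == "b"))),
               "singular|collinear")
})

test_that("structural region classification follows the window rules", {
  g <- tiny_genome() # 10 Mb chroms, centromere 4.8-5.2 Mb
  man <- tiny_manifest()
  rmap <- define_structural_regions(g, man, tel_window_bp = 2e6, cen_window_bp = 2e6)
  expect_equal(unname(rmap["cg1"]), "subtelomeric")      # pos 100
  expect_equal(unname(rmap["cg2"]), "pericentromeric")   # pos 5e6 inside centromere
  expect_equal(unname(rmap["cg3"]), "subtelomeric")      # pos 9.95e6, near end
  expect_equal(unname(rmap["cg5"]), "pericentromeric")   # 4.5e6, within 2 Mb flank
  expect_equal(unname(rmap["cg6"]), "pericentromeric")   # 7e6 <= 5.2e6 + 2 Mb
  # narrower windows leave cg6 mid-arm
  rmap2 <- define_structural_regions(g, man, tel_window_bp = 1e6, cen_window_bp = 1e6)
  expect_false("cg6" %in% names(rmap2))
  expect_error(define_structural_regions(g, man, tel_window_bp = 0), "> 0")
  expect_error(define_structural_regions(g, man, tel_window_bp = 6e6), "half")
  # windows that leave no neutral arm error out
  g2 <- toy_genome(n_chrom = 2, length_bp = 9e6, cen_start_bp = 4e6, cen_end_bp = 5e6)
  expect_error(define_structural_regions(g2, tiny_manifest(), tel_window_bp = 2.5e6,
                                         cen_window_bp = 2e6), "entirely")
})

test_that("region medians aggregate correctly and respect per-chromosome mode", {
  man <- tiny_manifest()
  g <- tiny_genome()
  rmap <- define_structural_regions(g, man)
  beta <- matrix(0.7, 6, 2, dimnames = list(man$probe_id, c("s1", "s2")))
  beta["cg1", "s2"] <- 0.1
  beta["cg3", "s2"] <- 0.9
  med <- region_medians(beta, rmap)
  expect_equal(med$median_beta[med$region_class == "subtelomeric" &
                                 med$sample_id == "s1"], 0.7)
  # subtelomeric probes are cg1, cg3, cg4: s2 has (0.1, 0.9, 0.7) -> 0.7
  expect_equal(med$median_beta[med$region_class == "subtelomeric" &
                                 med$sample_id == "s2"], 0.7)
  per_chr <- region_medians(beta, rmap, manifest = man, per_chromosome = TRUE)
  # chr1 subtelomeric probes cg1, cg3 in s2: median of (0.1, 0.9) = 0.5
  expect_equal(per_chr$median_beta[per_chr$region_class == "subtelomeric" &
                                     per_chr$chromosome == "chr1" &
                                     per_chr$sample_id == "s2"], 0.5)
})

test_that("region group test is calibrated under the null and powered under shift", {
  set.seed(11)
  null_p <- replicate(200, {
    med <- data.frame(sample_id = paste0("s", 1:20),
                      region_class = "subtelomeric", chromosome = "all",
                      median_beta = rnorm(20, 0.5, 0.05))
    grp <- setNames(rep(c("a", "b"), each = 10), med$sample_id)
    region_group_test(med, grp)$p_value
  })
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)
  # 3-sd shift at n = 20/group
  med <- data.frame(sample_id = paste0("s", 1:40),
                    region_class = "subtelomeric", chromosome = "all",
                    median_beta = c(rnorm(20, 0.5, 0.02), rnorm(20, 0.56, 0.02)))
  grp <- setNames(rep(c("a", "b"), each = 20), med$sample_id)
  expect_lt(region_group_test(med, grp)$p_value, 0.01)
})

test_that("dmp null calibration holds under permuted labels", {
  set.seed(21)
  g <- toy_genome()
  man <- make_manifest(g, 1000, seed = 2)
  sim <- simulate_methylation(man, g, groups = c(a = 15, b = 15), n_dmp = 0,
                              region_delta_beta = 0, noise_sd = 0.2, seed = 3)
  perm <- sample(colnames(sim$beta))
  grp <- factor(rep(c("a", "b"), each = 15))
  res <- dmp_test(sim$beta[, perm], grp)
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})
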