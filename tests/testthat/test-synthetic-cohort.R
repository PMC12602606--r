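test_that("make_manifest respects state fractions, seeds and preconditions", {
  g <- toy_genome()
  man <- make_manifest(g, 1000, seed = 3)
  expect_s3_class(man, "probe_manifest")
  # enhancer fraction 0.2 -> about 200 probes (binomial spread)
  n_enh <- sum(man$state == "enhancer")
  expect_true(abs(n_enh - 200) < 4 * sqrt(1000 * 0.2 * 0.8))
  # promoter probes all linked, others not
  is_prom <- man$state %in% c("active_promoter", "weak_promoter")
  expect_true(all(!is.na(man$gene[is_prom])))
  expect_true(all(is.na(man$gene[!is_prom])))
  # identical seeds are byte-identical
  expect_identical(man, make_manifest(g, 1000, seed = 3))
  expect_false(identical(man, make_manifest(g, 1000, seed = 4)))
  bad <- default_state_fractions() * 0.9
  expect_error(make_manifest(g, 1000, state_fractions = bad), "sum to 1")
  expect_error(make_manifest(g, 50), ">= 100")
})

test_that("simulate_methylation plants the stated beta shifts", {
  g <- toy_genome()
  man <- make_manifest(g, 3000, seed = 5)
  sim <- simulate_methylation(man, g, groups = c(a = 20, b = 20),
                              n_dmp = 500, dmp_delta_beta = 0.3,
                              region_delta_beta = 0, noise_sd = 0.05, seed = 9)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  in_b <- sim$truth$sample_group == "b"
  dmp <- sim$truth$dmp_probes$b
  diff <- rowMeans(sim$beta[dmp, in_b]) - rowMeans(sim$beta[dmp, !in_b])
  expect_equal(mean(diff), 0.3, tolerance = 0.02)
  # reproducibility
  sim2 <- simulate_methylation(man, g, groups = c(a = 20, b = 20),
                               n_dmp = 500, dmp_delta_beta = 0.3,
                               region_delta_beta = 0, noise_sd = 0.05, seed = 9)
  expect_identical(sim$beta, sim2$beta)
})

test_that("null region effect leaves group medians apart only by noise", {
  g <- toy_genome()
  man <- make_manifest(g, 2000, seed = 5)
  sim <- simulate_methylation(man, g, groups = c(a = 15, b = 15), n_dmp = 0,
                              region_delta_beta = 0, noise_sd = 0.1, seed = 2)
  rmap <- define_structural_regions(g, man)
  med <- region_medians(sim$beta, rmap)
  rt <- region_group_test(med, sim$truth$sample_group)
  expect_true(all(abs(rt$mean_diff) < 0.02))
})

test_that("simulate_expression plants no effect under a null config", {
  subt <- setNames(rep(c("X", "Y"), each = 10), paste0("s", 1:20))
  sim <- simulate_expression(subt, n_genes = 400, de_config = list(),
                             signature_subtypes = character(0), seed = 4)
  expect_true(all(sim$counts >= 0))
  expect_identical(storage.mode(sim$counts), "integer")
  sf <- exp(log(sim$truth$size_factors_true) -
              mean(log(sim$truth$size_factors_true)))
  norm <- sweep(sim$counts, 2, sim$truth$size_factors_true, "/")
  ratio <- rowMeans(norm[, subt == "X"]) / rowMeans(norm[, subt == "Y"])
  expect_equal(median(ratio, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("near-zero dispersion approaches Poisson mean-variance", {
  subt <- setNames(rep("X", 50), paste0("s", 1:50))
  sim <- simulate_expression(subt, n_genes = 500, de_config = list(),
                             signature_subtypes = character(0),
                             nb_dispersion = 1e-6, seed = 8)
  norm <- sweep(sim$counts, 2, sim$truth$size_factors_true, "/")
  m <- rowMeans(norm); v <- apply(norm, 1, var)
  keep <- m > 20
  expect_equal(median(v[keep] / m[keep]), 1, tolerance = 0.15)
})

test_that("coupled pairs realize their target anti-correlation", {
  g <- toy_genome()
  man <- make_manifest(g, 600, seed = 1)
  prom <- man[man$state %in% c("active_promoter", "weak_promoter"), ]
  prom <- prom[!duplicated(prom$gene), ][1:10, ]
  hits <- 0; total <- 0
  for (s in 1:15) {
    meth <- simulate_methylation(man, g, groups = c(x = 15, y = 15), n_dmp = 0,
                                 region_delta_beta = 0,
                                 intermediate_probes = prom$probe_id,
                                 noise_sd = 0.3, seed = s)
    coup <- data.frame(gene = prom$gene, probe = prom$probe_id,
                       target_rho = -0.9, stringsAsFactors = FALSE)
    sim <- simulate_expression(setNames(rep("X", 30), colnames(meth$beta)),
                               n_genes = 600, de_config = list(),
                               signature_subtypes = character(0),
                               coupling = coup, manifest = man, beta = meth$beta,
                               nb_dispersion = 0.05, seed = s + 100)
    mv <- beta_to_m(meth$beta)
    for (i in seq_len(nrow(coup))) {
      r <- suppressWarnings(
        cor(rank(mv[coup$probe[i], ]), rank(sim$counts[coup$gene[i], ])))
      total <- total + 1
      if (!is.na(r) && r <= -0.6) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("coupling validates probe-gene links", {
  g <- toy_genome()
  man <- make_manifest(g, 300, seed = 1)
  enh <- man$probe_id[man$state == "enhancer"][1]
  coup <- data.frame(gene = "g0001", probe = enh, target_rho = -0.8)
  beta <- matrix(0.5, 1, 4, dimnames = list(enh, paste0("s", 1:4)))
  expect_error(simulate_expression(setNames(rep("X", 4), paste0("s", 1:4)),
                                   n_genes = 10, de_config = list(),
                                   signature_subtypes = character(0),
                                   coupling = coup, manifest = man, beta = beta),
               "promoter")
})

test_that("simulate_survival honours censoring and hazard structure", {
  ids <- paste0("s", 1:400)
  grp <- setNames(rep(c("A", "B"), each = 200), ids)
  s0 <- simulate_survival(ids, grp, c(A = 0.1, B = 0.1), censor_rate = 0, seed = 1)
  expect_true(all(s0$dfs_event == 1))
  s <- simulate_survival(ids, grp, c(A = 0.1, B = 0.1), censor_rate = 0.4, seed = 1)
  expect_equal(mean(s$dfs_event == 0), 0.4, tolerance = 0.08)
  # hazard ratio 3 gives detectable separation
  s3 <- simulate_survival(ids, grp, c(A = 0.1, B = 0.3), censor_rate = 0.1, seed = 2)
  lr <- logrank_test(s3$dfs_time, s3$dfs_event, grp[s3$sample_id])
  expect_lt(lr$p_value, 0.01)
  expect_error(simulate_survival(ids, grp, c(A = -1, B = 1)), "hazards")
})

test_that("the full cohort ledger is consistent with its matrices", {
  co <- simulate_cohort(n_alpha = 5, n_adm = 10,
                        adm_split = c(ADM1 = 4, ADM2 = 3, ADM3 = 3),
                        n_probes = 500, n_genes = 300, n_dmp = 40,
                        n_coupled = 5, seed = 6)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_true(all(co$counts >= 0))
  expect_setequal(colnames(co$beta), co$sheet$sample_id)
  expect_setequal(colnames(co$counts), co$sheet$sample_id)
  # every coupled gene is a planted DEG of some subtype
  all_de <- unlist(lapply(co$truth$de_genes, `[[`, "gene"))
  expect_true(all(co$truth$coupled_pairs$gene %in% all_de))
  # planted DMPs exist in the manifest
  expect_true(all(unlist(co$truth$dmp_probes) %in% co$manifest$probe_id))
  # determinism of the whole cohort
  co2 <- simulate_cohort(n_alpha = 5, n_adm = 10,
                         adm_split = c(ADM1 = 4, ADM2 = 3, ADM3 = 3),
                         n_probes = 500, n_genes = 300, n_dmp = 40,
                         n_coupled = 5, seed = 6)
  expect_identical(co$beta, co2$beta)
  expect_identical(co$counts, co2$counts)
  expect_identical(co$sheet, co2$sheet)
})
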