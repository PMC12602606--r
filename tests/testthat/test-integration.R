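test_that("spearman_test matches hand-ranked formula and enumeration for n <= 7", {
  st <- spearman_test(1:4, c(2, 1, 4, 3))
  expect_equal(st$rho, 0.6) # 1 - 6*4/(4*15)
  expect_equal(st$method, "exact")
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    x <- sample(1:5, n, replace = TRUE) # ties included
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_test(x, y)
    want <- spearman_enumeration_oracle(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("spearman_test extremes, t-approximation and degenerate input", {
  dec <- spearman_test(1:10, 10:1)
  expect_equal(dec$rho, -1)
  big <- spearman_test(1:30, (1:30)^2 + rnorm(30, sd = 50))
  expect_equal(big$method, "t")
  ct <- cor.test(1:30, (1:30)^2, method = "spearman")
  ours <- spearman_test(1:30, (1:30)^2)
  expect_equal(ours$rho, unname(ct$estimate))
  const <- spearman_test(rep(1, 6), 1:6)
  expect_true(is.na(const$rho))
  expect_error(spearman_test(1:3, 3:1), ">= 4")
})

test_that("promoter_probe_pairs keeps only promoter probes of significant DEGs", {
  man <- tiny_manifest() # promoters: cg1 -> gA, cg4 -> gB
  man <- rbind(man, data.frame(probe_id = "cg7", chrom = "chr1", pos = 500L,
                               state = "active_promoter", gene = "gA"))
  deg <- data.frame(gene_id = c("gA", "gB", "gC"),
                    log2_fold_change = c(2, -1.5, 3),
                    significant = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  pairs <- promoter_probe_pairs(man, deg)
  expect_equal(nrow(pairs), 3) # gA x 2 probes, gB x 1
  expect_setequal(pairs$probe_id[pairs$gene_id == "gA"], c("cg1", "cg7"))
  expect_equal(pairs$direction[pairs$gene_id == "gB"], "down")
  expect_false("gC" %in% pairs$gene_id)
  none <- deg; none$significant <- FALSE
  expect_warning(empty <- promoter_probe_pairs(man, none), "no significant")
  expect_equal(nrow(empty), 0)
})

test_that("anticorrelation screen flags planted pairs and is monotone-invariant", {
  set.seed(7)
  n <- 30
  m <- matrix(rnorm(10 * n), 10, dimnames = list(paste0("cg", 1:10),
                                                 paste0("s", 1:n)))
  expr <- matrix(rnorm(10 * n), 10, dimnames = list(paste0("g", 1:10),
                                                    paste0("s", 1:n)))
  # plant strong anti-correlation in the first 3 pairs
  for (i in 1:3) expr[i, ] <- -2 * m[i, ] + rnorm(n, sd = 0.3)
  pairs <- data.frame(gene_id = paste0("g", 1:10), probe_id = paste0("cg", 1:10),
                      direction = "up", stringsAsFactors = FALSE)
  out <- anticorrelation_screen(m, expr, pairs)
  expect_true(all(out$passes[1:3]))
  expect_true(all(!out$passes[4:10] | out$rho[4:10] < -0.6))
  expect_equal(unname(attr(out, "summary")["up"]),
               length(unique(out$gene_id[out$passes])))
  # strictly monotone transform of expression changes nothing
  out2 <- anticorrelation_screen(m, exp(expr / 2), pairs)
  expect_equal(out2$rho, out$rho)
  expect_equal(out2$passes, out$passes)
})

test_that("BH monotonicity: adding a p = 1 pair never rescues a failing pair", {
  set.seed(8)
  n <- 20
  m <- matrix(rnorm(6 * n), 6, dimnames = list(paste0("cg", 1:6), paste0("s", 1:n)))
  expr <- -m + matrix(rnorm(6 * n, sd = 1.2), 6)
  rownames(expr) <- paste0("g", 1:6)
  colnames(expr) <- colnames(m)
  pairs <- data.frame(gene_id = paste0("g", 1:6), probe_id = paste0("cg", 1:6),
                      direction = "up", stringsAsFactors = FALSE)
  base <- anticorrelation_screen(m, expr, pairs)
  # append a null pair (constant-free random noise, p near 1)
  m2 <- rbind(m, cgX = rnorm(n)); expr2 <- rbind(expr, gX = rnorm(n))
  pairs2 <- rbind(pairs, data.frame(gene_id = "gX", probe_id = "cgX",
                                    direction = "up"))
  ext <- anticorrelation_screen(m2, expr2, pairs2)
  common <- match(paste(base$gene_id, base$probe_id),
                  paste(ext$gene_id, ext$probe_id))
  expect_true(all(ext$passes[common] >= base$passes |
                    ext$p_adjusted[common] >= base$p_adjusted))
  expect_false(any(!base$passes & ext$passes[common]))
})

test_that("degenerate screens return empty tables", {
  m <- matrix(0.5, 2, 10, dimnames = list(c("cg1", "cg2"), paste0("s", 1:10)))
  expr <- matrix(rnorm(20), 2, dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  pairs <- data.frame(gene_id = c("g1", "g2"), probe_id = c("cg1", "cg2"),
                      direction = "up", stringsAsFactors = FALSE)
  out <- anticorrelation_screen(m, expr, pairs) # constant methylation
  expect_equal(nrow(out), 0)
  empty <- anticorrelation_screen(m, expr, pairs[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "summary")), c(0L, 0L))
})
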