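# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# Heap's algorithm: all permutations of 1..n, independent of the package's
# recursive enumerator.
heap_permutations <- function(n) {
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  a <- seq_len(n)
  recurse <- function(k) {
    if (k == 1L) {
      row <<- row + 1L
      out[row, ] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      recurse(k - 1L)
      if (k %% 2L == 0L) {
        tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
      } else {
        tmp <- a[1L]; a[1L] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  recurse(n)
  out
}

# Exact two-sided Spearman p by full enumeration, rho via stats::cor.
spearman_enumeration_oracle <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  perms <- heap_permutations(n)
  rho_null <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  list(rho = rho,
       p = mean(abs(rho_null) >= abs(rho) - 1e-12))
}

# One-sided hypergeometric upper-tail p for a 2x2 table (a selected+in,
# b selected+out, c unselected+in, d unselected+out), by direct summation
# of binomial coefficients.
hypergeom_tail_oracle <- function(a, b, c, d) {
  k <- a + b          # selected draws
  K <- a + c          # category size
  N <- a + b + c + d
  xs <- a:min(k, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, k - xs) - lchoose(N, k)))
}

# Hand-stepped GSEA running sum (weight 1): returns the signed maximum
# deviation, walking the sorted list explicitly.
gsea_walk_oracle <- function(stats_sorted, in_set) {
  nr <- sum(abs(stats_sorted[in_set]))
  n_miss <- sum(!in_set)
  running <- 0
  best <- 0
  for (i in seq_along(stats_sorted)) {
    if (in_set[i]) {
      running <- running + abs(stats_sorted[[i]]) / nr
    } else {
      running <- running - 1 / n_miss
    }
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Tiny manifest + genome for IO and region tests.
tiny_genome <- function() toy_genome(n_chrom = 2, length_bp = 10e6,
                                     cen_start_bp = 4.8e6, cen_end_bp = 5.2e6)

tiny_manifest <- function() {
  data.frame(
    probe_id = paste0("cg", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    pos = as.integer(c(100, 5e6, 9.95e6, 100, 4.5e6, 7e6)),
    state = c("active_promoter", "enhancer", "heterochromatin",
              "weak_promoter", "other", "lowly_methylated"),
    gene = c("gA", NA, NA, "gB", NA, NA),
    stringsAsFactors = FALSE
  )
}
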