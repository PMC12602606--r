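#' Candidate gene-promoter probe pairs for the anti-correlation screen
#'
#' Pairs every significant DEG with each of its annotated promoter probes
#' (chromatin state `active_promoter` or `weak_promoter`, probe's gene
#' link equal to the DEG). A gene with several promoter probes yields
#' several pairs.
#'
#' @param manifest Probe manifest with promoter gene links.
#' @param deg_table [nb_test_one_vs_rest()] output (needs `gene_id`,
#'   `significant`, `log2_fold_change`).
#' @return data.frame: `gene_id`, `probe_id`, `direction` (`up`/`down`
#'   from the DEG's fold change). Empty (with a warning) when there are
#'   no significant DEGs.
#' @export
promoter_probe_pairs <- function(manifest, deg_table) {
  degs <- deg_table[which(deg_table$significant), , drop = FALSE]
  if (nrow(degs) == 0) {
    warning("no significant DEGs; returning zero pairs")
    return(data.frame(gene_id = character(0), probe_id = character(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  prom <- manifest[manifest$state %in% c("active_promoter", "weak_promoter") &
                     !is.na(manifest$gene), , drop = FALSE]
  hit <- prom[prom$gene %in% degs$gene_id, , drop = FALSE]
  out <- data.frame(
    gene_id = hit$gene, probe_id = hit$probe_id,
    direction = ifelse(degs$log2_fold_change[match(hit$gene, degs$gene_id)] > 0,
                       "up", "down"),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman correlation with exact small-sample p-value
#'
#' Rho is computed from mid-ranks (ties supported). For `n` complete
#' pairs up to `exact_n` the two-sided p-value is exact: the full
#' permutation distribution of rho under independence is enumerated and
#' `p = P(|rho*| >= |rho|)`. For larger n the usual t-approximation on
#' rho with `n - 2` degrees of freedom is used.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped pairwise.
#' @param exact_n Largest n for exact enumeration (default 9).
#' @return List: `rho`, `p_value`, `n`, `method` (`"exact"`/`"t"`).
#'   `NULL` rho with a message when either vector is constant.
#' @export
spearman_test <- function(x, y, exact_n = 9) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "constant"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    # rho for every permutation of y-ranks against fixed x-ranks
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.vector((matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, n = n, method = "exact")
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    list(rho = rho, p_value = min(p, 1), n = n, method = "t")
  }
}

# All permutations of 1..n as an n!-by-n matrix (n <= 9).
all_permutations <- function(n) {
  if (n > 9) stop("permutation enumeration limited to n <= 9")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      block <- block[, c(seq_len(pos - 1), n, pos:(n - 1)), drop = FALSE]
    }
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Promoter methylation vs expression anti-correlation screen
#'
#' For each candidate (gene, probe) pair, the Spearman correlation between
#' the probe's M-values and the gene's expression across the shared
#' samples, with BH adjustment pooled across all tested pairs. A pair
#' passes when `rho < rho_threshold` (strict) and adjusted p <
#' `p_adj_threshold` — the selection used to nominate epigenetically
#' regulated DEGs. Pairs with a constant M or expression profile are
#' skipped and reported.
#'
#' @param m_matrix Probe-by-sample M-value matrix.
#' @param expr_matrix Gene-by-sample expression matrix, same samples in
#'   the same order (use [align_omics()] upstream).
#' @param pairs [promoter_probe_pairs()] output.
#' @param rho_threshold,p_adj_threshold Pass thresholds (defaults
#'   rho < -0.6, BH p < 0.05).
#' @param bh_scope `"pooled"` adjusts across all pairs (default, stricter);
#'   `"per_gene"` adjusts within each gene's pairs.
#' @return data.frame: `gene_id`, `probe_id`, `rho`, `p_value`,
#'   `p_adjusted`, `direction`, `passes`; `attr(, "skipped")` lists pairs
#'   with undefined correlation, `attr(, "summary")` counts distinct
#'   up-/down-regulated genes with at least one passing probe.
#' @export
anticorrelation_screen <- function(m_matrix, expr_matrix, pairs,
                                   rho_threshold = -0.6, p_adj_threshold = 0.05,
                                   bh_scope = c("pooled", "per_gene")) {
  bh_scope <- match.arg(bh_scope)
  if (!identical(colnames(m_matrix), colnames(expr_matrix))) {
    stop("matrices must be sample-aligned (same samples, same order)")
  }
  if (nrow(pairs) == 0) {
    out <- data.frame(gene_id = character(0), probe_id = character(0),
                      rho = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), direction = character(0),
                      passes = logical(0), stringsAsFactors = FALSE)
    attr(out, "summary") <- c(up = 0L, down = 0L)
    return(out)
  }
  missing_probe <- !(pairs$probe_id %in% rownames(m_matrix))
  missing_gene <- !(pairs$gene_id %in% rownames(expr_matrix))
  if (any(missing_probe | missing_gene)) {
    pairs <- pairs[!(missing_probe | missing_gene), , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    spearman_test(m_matrix[pairs$probe_id[i], ], expr_matrix[pairs$gene_id[i], ])
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p_value")
  skipped <- is.na(rho)
  out <- data.frame(gene_id = pairs$gene_id, probe_id = pairs$probe_id,
                    rho = rho, p_value = p,
                    direction = pairs$direction, stringsAsFactors = FALSE)
  out <- out[!skipped, , drop = FALSE]
  if (bh_scope == "pooled") {
    out$p_adjusted <- bh_adjust(out$p_value)
  } else {
    out$p_adjusted <- NA_real_
    for (g in unique(out$gene_id)) {
      sel <- out$gene_id == g
      out$p_adjusted[sel] <- bh_adjust(out$p_value[sel])
    }
  }
  out$passes <- out$rho < rho_threshold & out$p_adjusted < p_adj_threshold
  out <- out[, c("gene_id", "probe_id", "rho", "p_value", "p_adjusted",
                 "direction", "passes")]
  rownames(out) <- NULL
  passing <- out[out$passes, , drop = FALSE]
  attr(out, "summary") <- c(
    up = length(unique(passing$gene_id[passing$direction == "up"])),
    down = length(unique(passing$gene_id[passing$direction == "down"])))
  if (any(skipped)) {
    attr(out, "skipped") <- pairs[skipped, c("gene_id", "probe_id"), drop = FALSE]
  }
  out
}
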