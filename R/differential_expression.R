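#' Filter low-count genes
#'
#' Keeps a gene iff at least `min_samples` samples have at least
#' `min_reads` reads, the usual pre-filter before count-based testing.
#'
#' @param counts Gene-by-sample integer matrix.
#' @param min_samples Minimum number of qualifying samples (default 2).
#' @param min_reads Minimum reads per qualifying sample (default 5).
#' @return Filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_samples = 2, min_reads = 5) {
  check_feature_matrix(counts, "counts")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  keep <- rowSums(counts >= min_reads) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The standard count normalization: per sample, the median over genes
#' (restricted to genes with positive geometric mean across samples) of
#' the ratio of the gene's count to its geometric mean.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named positive numeric vector of per-sample size factors. A
#'   single-sample matrix gets factor 1.
#' @export
size_factors <- function(counts) {
  check_feature_matrix(counts, "counts")
  if (ncol(counts) == 1) {
    return(stats::setNames(1, colnames(counts)))
  }
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene has nonzero counts in every sample; filter first")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Shifted-log variance-stabilizing transform
#'
#' `log2(count / size_factor + 1)` — a monotone, normalization-aware
#' transform used for clustering, correlation and signature scoring.
#' Downstream uses in this pipeline are rank-based or
#' correlation-structural, where any strictly monotone per-gene transform
#' gives the same answer.
#'
#' @param counts Gene-by-sample count matrix.
#' @param sf Size factors from [size_factors()] (computed when `NULL`).
#' @return Expression matrix, same dimnames.
#' @export
vst_like <- function(counts, sf = NULL) {
  check_feature_matrix(counts, "counts")
  if (is.null(sf)) sf <- size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be > 0")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Negative-binomial one-vs-rest differential expression
#'
#' Tests each gene for differential expression between `target_subtype`
#' and all remaining samples pooled. The model is a NB log-linear fit
#' with `log(size factor)` offset and a group indicator; the gene-wise
#' dispersion is a method-of-moments estimate shrunk 50/50 toward a
#' fitted mean-dispersion trend `a0 + a1 / mean` (floored at 1e-8), and
#' the reported p-value is a Wald test on the group coefficient. This is
#' a transparent substitute for the full shrinkage machinery of the large
#' count-model packages; it is validated by parameter recovery on
#' synthetic NB data rather than numeric equality with any of them.
#'
#' @param counts Gene-by-sample count matrix (pre-filtered).
#' @param subtype Named or positional vector of subtype labels per sample.
#' @param target_subtype The label contrasted against the rest.
#' @param sf Size factors (computed when `NULL`).
#' @param lfc_threshold,p_adj_threshold Thresholds for the `significant`
#'   flag (defaults |log2FC| > 1, BH p < 0.05).
#' @return data.frame: `gene_id`, `base_mean` (mean normalized count),
#'   `log2_fold_change` (target vs rest), `p_value`, `p_adjusted`,
#'   `significant`. Genes whose fit fails get `NA` p-values and are
#'   excluded from the BH family.
#' @export
nb_test_one_vs_rest <- function(counts, subtype, target_subtype, sf = NULL,
                                lfc_threshold = 1, p_adj_threshold = 0.05) {
  check_feature_matrix(counts, "counts")
  if (length(subtype) != ncol(counts)) stop("subtype length must match samples")
  in_target <- subtype == target_subtype
  if (sum(in_target) < 2 || sum(!in_target) < 2) {
    stop("need >= 2 samples in the target group and in the rest")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  # method-of-moments dispersion, pooled over the two groups
  disp_mom <- apply(norm, 1, function(q) {
    m1 <- mean(q[in_target]); v1 <- stats::var(q[in_target])
    m0 <- mean(q[!in_target]); v0 <- stats::var(q[!in_target])
    n1 <- sum(in_target); n0 <- sum(!in_target)
    num <- (n1 - 1) * (v1 - m1) + (n0 - 1) * (v0 - m0)
    den <- (n1 - 1) * m1^2 + (n0 - 1) * m0^2
    if (den <= 0) return(NA_real_)
    num / den
  })
  pos <- is.finite(disp_mom) & disp_mom > 0 & base_mean > 0
  # mean-dispersion trend a0 + a1/mean, least squares on genes with a
  # positive raw estimate
  if (sum(pos) >= 10) {
    tr <- stats::lm(disp_mom[pos] ~ I(1 / base_mean[pos]))
    a0 <- max(stats::coef(tr)[1], 0)
    a1 <- max(stats::coef(tr)[2], 0)
  } else {
    a0 <- stats::median(disp_mom[pos], na.rm = TRUE)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 0
  }
  disp_trend <- a0 + a1 / pmax(base_mean, 1e-8)
  disp_raw <- ifelse(is.finite(disp_mom) & disp_mom > 0, disp_mom, disp_trend)
  dispersion <- pmax(0.5 * disp_raw + 0.5 * disp_trend, 1e-8)

  group <- factor(ifelse(in_target, "target", "rest"), levels = c("rest", "target"))
  off <- log(sf)
  fit_one <- function(y, disp) {
    fam <- MASS::negative.binomial(theta = 1 / disp)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ group + offset(off), family = fam)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
    # dispersion is carried by the NB variance function; fix the GLM scale
    # at 1 so Wald SEs are not rescaled by a Pearson estimate
    sm <- summary(fit, dispersion = 1)$coefficients
    c(sm["grouptarget", "Estimate"], sm["grouptarget", "Std. Error"])
  }
  est <- t(vapply(seq_len(nrow(counts)),
                  function(i) fit_one(counts[i, ], dispersion[i]),
                  numeric(2)))
  wald <- est[, 1] / est[, 2]
  pval <- 2 * stats::pnorm(-abs(wald))
  n_failed <- sum(is.na(pval))
  if (n_failed > 0) {
    warning(n_failed, " gene(s) failed to converge; p set to NA")
  }
  out <- data.frame(gene_id = rownames(counts), base_mean = unname(base_mean),
                    log2_fold_change = unname(est[, 1] / log(2)),
                    dispersion = unname(dispersion),
                    wald_statistic = unname(wald),
                    p_value = unname(pval), p_adjusted = bh_adjust(pval),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_adjusted) &
    abs(out$log2_fold_change) > lfc_threshold & out$p_adjusted < p_adj_threshold
  rownames(out) <- NULL
  out
}
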