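#' Probe-level differential methylation between two groups
#'
#' Per probe, an ordinary least-squares fit of the beta value on the group
#' indicator (plus optional covariates), with a two-sided t-test on the
#' group coefficient and BH adjustment across all tested probes. The
#' effect size `delta_beta` is the raw group mean difference on the beta
#' scale, `mean(group2) - mean(group1)` with groups in factor-level order
#' (e.g. ADM minus alpha-like). A plain OLS t-test is used rather than
#' empirical-Bayes moderation; at cohort-scale group sizes the two agree
#' closely and the unmoderated test keeps the model transparent.
#'
#' Probes with missing values are fitted on their complete samples; probes
#' with fewer than 3 residual degrees of freedom are dropped with a
#' warning.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param group Factor (or coercible) of length `ncol(beta)` with exactly
#'   two levels; the contrast is level 2 minus level 1.
#' @param covariates Optional data.frame of additional model columns.
#' @param p_adj_threshold,delta_threshold Significance thresholds for the
#'   `significant` flag (defaults: BH p < 0.001 and |delta beta| > 0.2).
#' @return data.frame: `probe_id`, `delta_beta`, `t_statistic`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
dmp_test <- function(beta, group, covariates = NULL,
                     p_adj_threshold = 0.001, delta_threshold = 0.2) {
  check_feature_matrix(beta, "beta")
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (length(group) != ncol(beta)) stop("group length must match samples")
  if (any(table(group) < 2)) stop("each group needs >= 2 samples")

  design <- stats::model.matrix(~group)
  if (!is.null(covariates)) {
    cov_mm <- stats::model.matrix(~., data = covariates)[, -1, drop = FALSE]
    design <- cbind(design, cov_mm)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }

  coef_idx <- 2L # the group indicator
  n <- ncol(beta)
  complete <- !anyNA(beta)
  run_fit <- function(y_mat, X) {
    fit <- stats::lm.fit(X, t(y_mat))
    cf <- if (is.matrix(fit$coefficients)) fit$coefficients else as.matrix(fit$coefficients)
    res <- if (is.matrix(fit$residuals)) fit$residuals else as.matrix(fit$residuals)
    df <- nrow(X) - fit$rank
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtx_inv[coef_idx, coef_idx])
    tt <- cf[coef_idx, ] / se
    list(t = tt, df = df)
  }

  probes <- rownames(beta)
  tstat <- rep(NA_real_, length(probes))
  pval <- rep(NA_real_, length(probes))
  if (complete) {
    ft <- run_fit(beta, design)
    tstat <- ft$t
    pval <- 2 * stats::pt(-abs(ft$t), ft$df)
  } else {
    has_na <- apply(beta, 1, anyNA)
    if (any(!has_na)) {
      ft <- run_fit(beta[!has_na, , drop = FALSE], design)
      tstat[!has_na] <- ft$t
      pval[!has_na] <- 2 * stats::pt(-abs(ft$t), ft$df)
    }
    for (i in which(has_na)) {
      ok <- !is.na(beta[i, ])
      if (sum(ok) - ncol(design) < 3 || nlevels(droplevels(group[ok])) < 2) next
      ft <- run_fit(beta[i, ok, drop = FALSE], design[ok, , drop = FALSE])
      tstat[i] <- ft$t
      pval[i] <- 2 * stats::pt(-abs(ft$t), ft$df)
    }
    if (anyNA(pval)) {
      warning(sum(is.na(pval)), " probe(s) with insufficient complete samples dropped")
    }
  }

  g2 <- group == levels(group)[2]
  delta <- rowMeans(beta[, g2, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, !g2, drop = FALSE], na.rm = TRUE)
  padj <- bh_adjust(pval)
  out <- data.frame(probe_id = probes, delta_beta = unname(delta),
                    t_statistic = unname(tstat), p_value = unname(pval),
                    p_adjusted = unname(padj), stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_adjusted) &
    out$p_adjusted < p_adj_threshold & abs(out$delta_beta) > delta_threshold
  rownames(out) <- NULL
  out
}

#' Chromatin-state over-representation of DMPs
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of each
#' chromatin state among the differentially methylated probes, against
#' the universe of all tested probes; odds ratio > 1 means the state is
#' enriched in the DMPs. Shares its engine with [set_ora()].
#'
#' @param dmp_probes Character vector of DMP ids (subset of the universe).
#' @param manifest Probe manifest covering at least the universe.
#' @param universe Character vector of all tested probe ids; defaults to
#'   every manifest probe.
#' @return data.frame per state: `category`, `n_selected`, `n_category`,
#'   `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
chromatin_state_ora <- function(dmp_probes, manifest, universe = manifest$probe_id) {
  states <- split(manifest$probe_id, manifest$state)
  ora_test(dmp_probes, universe, states)
}

#' Map probes to sub-telomeric / peri-centromeric region classes
#'
#' A probe is sub-telomeric when its position is within `tel_window_bp` of
#' either chromosome end (`pos <= tel` or `pos > length - tel`), and
#' peri-centromeric when within `cen_window_bp` of the centromere
#' interval (the interval itself included). A probe matching both — only
#' possible with very wide windows — is classed peri-centromeric with a
#' warning. Window sizes default to 2 Mb.
#'
#' @param genome A [toy_genome()] or data.frame with `chrom`, `length_bp`,
#'   `cen_start_bp`, `cen_end_bp`.
#' @param manifest Probe manifest.
#' @param tel_window_bp,cen_window_bp Window sizes in bp (> 0, each less
#'   than half the chromosome length).
#' @return Named character vector probe_id -> `"subtelomeric"` /
#'   `"pericentromeric"`; probes in neither region are absent.
#' @export
define_structural_regions <- function(genome, manifest,
                                      tel_window_bp = 2e6, cen_window_bp = 2e6) {
  if (tel_window_bp <= 0 || cen_window_bp <= 0) stop("windows must be > 0")
  if (any(tel_window_bp >= genome$length_bp / 2) ||
      any(cen_window_bp >= genome$length_bp / 2)) {
    stop("windows must be smaller than half the chromosome length")
  }
  gi <- match(manifest$chrom, genome$chrom)
  if (anyNA(gi)) stop("manifest chromosomes missing from genome")
  len <- genome$length_bp[gi]
  cs <- genome$cen_start_bp[gi]
  ce <- genome$cen_end_bp[gi]
  # windows jointly covering a whole chromosome leave no neutral arm
  covered <- (cs - cen_window_bp) <= tel_window_bp &
    (ce + cen_window_bp) > (len - tel_window_bp)
  if (any(covered)) {
    stop("tel/cen windows cover chromosome(s) entirely: ",
         paste(unique(manifest$chrom[covered]), collapse = ", "))
  }
  subtel <- manifest$pos <= tel_window_bp | manifest$pos > len - tel_window_bp
  pericen <- manifest$pos >= cs - cen_window_bp & manifest$pos <= ce + cen_window_bp
  both <- subtel & pericen
  if (any(both)) {
    warning(sum(both), " probe(s) in both windows classed peri-centromeric")
  }
  cls <- ifelse(pericen, "pericentromeric",
                ifelse(subtel, "subtelomeric", NA_character_))
  keep <- !is.na(cls)
  stats::setNames(cls[keep], manifest$probe_id[keep])
}

#' Per-sample median methylation of structural regions
#'
#' For each sample and region class (optionally per chromosome), the
#' median beta over the region's probes, missing values excluded.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param region_map Output of [define_structural_regions()].
#' @param manifest Manifest (needed only when `per_chromosome = TRUE`).
#' @param per_chromosome Emit one row per chromosome instead of pooling.
#' @return data.frame: `sample_id`, `region_class`, `chromosome`
#'   (`"all"` when pooled), `median_beta`.
#' @export
region_medians <- function(beta, region_map, manifest = NULL,
                           per_chromosome = FALSE) {
  check_feature_matrix(beta, "beta")
  region_map <- region_map[names(region_map) %in% rownames(beta)]
  if (length(region_map) == 0) stop("no region probes present in the matrix")
  groups <- if (per_chromosome) {
    if (is.null(manifest)) stop("per-chromosome summaries need the manifest")
    chrom <- manifest$chrom[match(names(region_map), manifest$probe_id)]
    split(names(region_map), list(region_map, chrom), sep = "|", drop = TRUE)
  } else {
    split(names(region_map), paste0(region_map, "|all"))
  }
  rows <- lapply(names(groups), function(nm) {
    probes <- groups[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    med <- apply(beta[probes, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    data.frame(sample_id = colnames(beta), region_class = parts[1],
               chromosome = parts[2], median_beta = unname(med),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison of structural-region median methylation
#'
#' Welch two-sample t-test on the per-sample region medians, one test per
#' region class (and chromosome if present): the comparison of
#' sub-telomeric / peri-centromeric methylation between alpha-like and
#' ADM tumors.
#'
#' @param medians [region_medians()] output.
#' @param group Named vector sample_id -> group label (two groups).
#' @return data.frame: `region_class`, `chromosome`, `mean_diff`
#'   (group2 - group1 in factor-level order), `t_statistic`, `p_value`.
#' @export
region_group_test <- function(medians, group) {
  g <- droplevels(as.factor(group[medians$sample_id]))
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  key <- paste(medians$region_class, medians$chromosome, sep = "|")
  rows <- lapply(unique(key), function(k) {
    sel <- key == k
    gi <- g[sel]
    if (any(table(gi) < 2)) stop("each group needs >= 2 samples per region")
    x <- medians$median_beta[sel][gi == levels(g)[2]]
    y <- medians$median_beta[sel][gi == levels(g)[1]]
    tt <- stats::t.test(x, y) # Welch by default
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(region_class = parts[1], chromosome = parts[2],
               mean_diff = mean(x) - mean(y),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
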