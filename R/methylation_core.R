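#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` with beta clipped to `[epsilon,
#' 1 - epsilon]` first, the usual variance-stabilizing logit transform for
#' array methylation. Missing values stay missing. The epsilon used is
#' recorded as an attribute so downstream outputs can report it.
#'
#' @param beta Numeric matrix (or vector) of beta values in `[0, 1]`.
#' @param epsilon Clipping bound, `0 < epsilon < 0.5`. Default 0.001.
#' @return M-value matrix, `attr(, "epsilon")` set.
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0 and 2
#' @export
beta_to_m <- function(beta, epsilon = 0.001) {
  if (!(epsilon > 0 && epsilon < 0.5)) stop("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  attributes(m) <- attributes(beta)
  attr(m, "epsilon") <- epsilon
  m
}

#' Convert M-values back to beta values
#' @param m M-value matrix or vector.
#' @return Beta values `2^m / (2^m + 1)`.
#' @export
m_to_beta <- function(m) {
  b <- 2^m / (2^m + 1)
  attributes(b) <- attributes(m)
  attr(b, "epsilon") <- NULL
  b
}

#' Filter probes by detection failure and chromosome
#'
#' Mirrors array QC: a probe is kept iff its detection-failure fraction is
#' at most `max_fail_fraction` ("more than 10% of samples" excludes, so
#' equality keeps) and it lies on an autosome. The failure mask is
#' consumed as input (e.g. a pOOBAH mask computed upstream).
#'
#' @param beta Probe-by-sample beta matrix.
#' @param fail_mask Logical probe-by-sample matrix, `TRUE` = failed;
#'   `NULL` means no failures.
#' @param max_fail_fraction Maximum tolerated failure fraction (default 0.10).
#' @param manifest Optional manifest supplying probe chromosomes.
#' @param autosomes Character vector of autosomal chromosome names; probes
#'   on other chromosomes are removed (requires `manifest`).
#' @return Filtered beta matrix; `attr(, "removed")` holds a data.frame of
#'   removed probes and the reason (`fail_fraction` / `non_autosomal`).
#' @export
filter_probes <- function(beta, fail_mask = NULL, max_fail_fraction = 0.10,
                          manifest = NULL, autosomes = NULL) {
  check_feature_matrix(beta, "beta")
  reason <- character(0)
  probe <- character(0)
  keep <- rep(TRUE, nrow(beta))
  if (!is.null(fail_mask)) {
    if (!identical(dim(fail_mask), dim(beta))) {
      stop("fail_mask dimensions must match the beta matrix")
    }
    frac <- rowMeans(fail_mask)
    drop_fail <- frac > max_fail_fraction
    keep <- keep & !drop_fail
    probe <- c(probe, rownames(beta)[drop_fail])
    reason <- c(reason, rep("fail_fraction", sum(drop_fail)))
  }
  if (!is.null(autosomes)) {
    if (is.null(manifest)) stop("autosome filtering needs a manifest")
    chrom <- manifest$chrom[match(rownames(beta), manifest$probe_id)]
    drop_chr <- is.na(chrom) | !(chrom %in% autosomes)
    newly <- drop_chr & keep
    keep <- keep & !drop_chr
    probe <- c(probe, rownames(beta)[newly])
    reason <- c(reason, rep("non_autosomal", sum(newly)))
  }
  out <- beta[keep, , drop = FALSE]
  attr(out, "removed") <- data.frame(probe_id = probe, reason = reason,
                                     stringsAsFactors = FALSE)
  out
}

#' Combine beta matrices from several array platforms
#'
#' Restricts each matrix to the probes present in all of them, then
#' concatenates samples — how beta values measured on different Illumina
#' array generations are merged into one cohort matrix.
#'
#' @param matrices List of >= 2 probe-by-sample beta matrices.
#' @return Combined matrix over the shared probes.
#' @export
intersect_platforms <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) stop("need >= 2 matrices")
  for (m in matrices) check_feature_matrix(m, "beta")
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) == 0) stop("no probes shared across all platforms")
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample ids across platforms: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  do.call(cbind, lapply(matrices, function(m) m[shared, , drop = FALSE]))
}

#' Select the most variable features by MAD
#'
#' Ranks features by the raw median absolute deviation
#' `median(|x - median(x)|)` (no consistency constant — only the ranking
#' matters for feature selection), missing values excluded per feature.
#' Ties are broken by feature id ascending so the selection is
#' deterministic and sample-order invariant.
#'
#' @param x Feature-by-sample matrix.
#' @param n Number of features to return (default 2000).
#' @return Character vector of `n` feature ids, MAD descending.
#' @export
select_top_mad <- function(x, n = 2000) {
  check_feature_matrix(x, "matrix")
  if (n > nrow(x)) stop("n exceeds the number of features")
  med <- apply(x, 1, stats::median, na.rm = TRUE)
  mad_raw <- apply(abs(x - med), 1, stats::median, na.rm = TRUE)
  ord <- order(-mad_raw, rownames(x))
  rownames(x)[ord][seq_len(n)]
}
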