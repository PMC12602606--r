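#' Resampling-based consensus clustering
#'
#' For each of `reps` resampling runs, a fraction `p_item` of the samples
#' (and optionally `p_feature` of the features) is drawn without
#' replacement, the subsampled samples are clustered by agglomerative
#' hierarchical clustering on the Pearson-correlation dissimilarity
#' `d(i, j) = 1 - cor(x_i, x_j)` with ward.D2 inner linkage, and the tree
#' is cut at each `k` in `k_range`. The consensus matrix entry for a
#' sample pair at a given k is the number of runs in which the pair was
#' assigned to the same cluster divided by the number of runs in which
#' both were drawn; the diagonal is 1, and pairs never co-drawn (possible
#' at small `reps`) are set to 0 with a warning. Final per-k assignments
#' come from [final_assignments()] (average linkage on `1 - consensus`).
#'
#' Defaults follow the standard scheme (reps = 1000, pItem = 0.8,
#' pFeature = 1, Pearson distance, ward.D2 inner / average final linkage).
#' Note that Ward linkage formally assumes squared Euclidean distances;
#' applying it to a correlation dissimilarity is a widely used but
#' mathematically improper convention, reproduced here deliberately.
#'
#' @param x Feature-by-sample numeric matrix (e.g. the top-MAD subset).
#' @param k_range Integer vector of cluster numbers (all >= 2).
#' @param reps Number of resampling runs.
#' @param p_item Fraction of samples drawn per run (ceiling applied).
#' @param p_feature Fraction of features drawn per run (1 = no feature
#'   resampling).
#' @param seed Integer seed; per-run sub-seeds are derived from it so
#'   results are reproducible.
#' @return A `consensus_result`: list with `consensus` (named list of
#'   sample-by-sample matrices, one per k), `assignments` (named list of
#'   integer cluster vectors), `params`.
#' @export
consensus_cluster <- function(x, k_range = 2:6, reps = 1000, p_item = 0.8,
                              p_feature = 1.0, seed = 1) {
  check_feature_matrix(x, "matrix")
  n <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range values must be >= 2")
  if (n < max(k_range) + 1) stop("need at least max(k_range) + 1 samples")
  if (nrow(x) < 2) stop("need at least 2 features")
  # constant features carry no correlation signal
  const <- apply(x, 1, function(r) stats::sd(r, na.rm = TRUE) == 0 || all(is.na(r)))
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped before clustering")
    x <- x[!const, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 non-constant features")
  }
  samples <- colnames(x)
  n_item <- ceiling(p_item * n)
  n_feat <- ceiling(p_feature * nrow(x))
  rep_seeds <- derive_seeds(seed, reps, tag = "consensus")
  # complete matrices take the fast BLAS correlation path
  cor_use <- if (anyNA(x)) "pairwise.complete.obs" else "everything"

  conn <- stats::setNames(vector("list", length(k_range)), paste0("k", k_range))
  for (nm in names(conn)) conn[[nm]] <- matrix(0, n, n, dimnames = list(samples, samples))
  co_sampled <- matrix(0, n, n, dimnames = list(samples, samples))

  for (r in seq_len(reps)) {
    draw <- with_seed(rep_seeds[r], {
      items <- sort(sample.int(n, n_item))
      feats <- if (n_feat < nrow(x)) sort(sample.int(nrow(x), n_feat)) else seq_len(nrow(x))
      list(items = items, feats = feats)
    })
    sub <- x[draw$feats, draw$items, drop = FALSE]
    d <- stats::as.dist(1 - stats::cor(sub, use = cor_use))
    if (anyNA(d)) stop("undefined correlation between samples (constant sample profile)")
    hc <- stats::hclust(d, method = "ward.D2")
    co_sampled[draw$items, draw$items] <- co_sampled[draw$items, draw$items] + 1
    for (ki in seq_along(k_range)) {
      cl <- stats::cutree(hc, k = k_range[ki])
      same <- outer(cl, cl, "==")
      conn[[ki]][draw$items, draw$items] <- conn[[ki]][draw$items, draw$items] + same
    }
  }

  never <- co_sampled == 0
  diag(never) <- FALSE
  if (any(never)) {
    warning(sum(never) / 2, " sample pair(s) never co-sampled; consensus set to 0")
  }
  consensus <- lapply(conn, function(cm) {
    m <- ifelse(co_sampled > 0, cm / co_sampled, 0)
    diag(m) <- 1
    dimnames(m) <- list(samples, samples)
    m
  })
  assignments <- stats::setNames(
    lapply(seq_along(k_range), function(ki) {
      final_assignments(consensus[[ki]], k_range[ki])
    }),
    names(consensus))

  structure(list(consensus = consensus, assignments = assignments,
                 params = list(k_range = k_range, reps = reps, p_item = p_item,
                               p_feature = p_feature, distance = "pearson",
                               inner_linkage = "ward.D2",
                               final_linkage = "average", seed = seed)),
            class = "consensus_result")
}

#' Final cluster assignments from a consensus matrix
#'
#' Agglomerative clustering with average linkage on the dissimilarity
#' `1 - consensus`, cut at `k`. Labels are renumbered by first occurrence
#' in sample order, so they are stable across runs.
#'
#' @param consensus Symmetric sample-by-sample consensus matrix in `[0, 1]`
#'   with unit diagonal.
#' @param k Number of clusters (`1 <= k <= n`).
#' @return Named integer vector of cluster labels `1..k`.
#' @export
final_assignments <- function(consensus, k) {
  if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus)) {
    stop("consensus must be a square matrix")
  }
  n <- nrow(consensus)
  if (k > n) stop("k exceeds the number of samples")
  if (k == 1) {
    return(stats::setNames(rep(1L, n), rownames(consensus)))
  }
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  cl <- stats::cutree(hc, k = k)
  relabel_first_occurrence(cl)
}

# Renumber cluster labels by order of first appearance.
relabel_first_occurrence <- function(cl) {
  stats::setNames(as.integer(match(cl, unique(cl))), names(cl))
}

#' Consensus CDF curves and delta-area model-selection statistics
#'
#' For each k, the empirical CDF of the off-diagonal upper-triangle
#' consensus entries is computed, its area is integrated exactly (left-step
#' sum over the sorted entry grid on `[0, 1]`), and the relative
#' delta-area is reported: `delta(k_min) = A(k_min)` and for subsequent k
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)`. A clean clustering at the true
#' k shows a large area gain up to that k and little beyond.
#'
#' @param result A [consensus_cluster()] result.
#' @return List with `cdf` (per-k function-ready data.frames of `value`,
#'   `cdf`), `area` (named numeric), `delta_area` (named numeric).
#' @export
cdf_and_delta_area <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  ks <- result$params$k_range
  if (length(ks) < 2) stop("need >= 2 values of k")
  ut <- function(m) m[upper.tri(m)]
  areas <- numeric(length(ks))
  cdfs <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    v <- sort(ut(result$consensus[[i]]))
    grid <- unique(c(0, v, 1))
    cdf <- vapply(grid, function(c0) mean(v <= c0), numeric(1))
    # the CDF is a right-continuous step function, so the exact area under
    # it is the left-step sum over the entry grid (an all-0/1 matrix with
    # fraction f at 0 then has area exactly f)
    areas[i] <- sum(diff(grid) * utils::head(cdf, -1))
    cdfs[[i]] <- data.frame(value = grid, cdf = cdf)
  }
  names(areas) <- names(cdfs) <- paste0("k", ks)
  delta <- numeric(length(ks))
  delta[1] <- areas[1]
  if (length(ks) > 1) {
    delta[-1] <- diff(areas) / utils::head(areas, -1)
  }
  names(delta) <- names(areas)
  list(cdf = cdfs, area = areas, delta_area = delta)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering result\n")
  cat("  samples:", nrow(x$consensus[[1]]), "\n")
  cat("  k:", paste(x$params$k_range, collapse = ", "), "\n")
  cat("  reps:", x$params$reps, " pItem:", x$params$p_item,
      " pFeature:", x$params$p_feature, "\n")
  invisible(x)
}
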