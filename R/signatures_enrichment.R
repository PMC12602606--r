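#' Rank-sum signature score
#'
#' The metastasis-like-primary-style score: each gene is ranked across
#' samples ascending (mid-ranks for ties), and a sample's score is the
#' sum of its ranks over the signature genes. Higher score = higher
#' overall signature expression. Being rank-based, the score is invariant
#' under any strictly monotone per-gene transform of the expression
#' matrix.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param genes Character vector of signature gene ids; members missing
#'   from the matrix are dropped and reported via a warning.
#' @param name Signature name carried into the output.
#' @return data.frame: `sample_id`, `signature`, `score`, `n_genes`
#'   (genes actually scored).
#' @export
signature_score <- function(expr, genes, name = "signature") {
  check_feature_matrix(expr, "expr")
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) stop("no signature gene present in the matrix")
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " signature gene(s) missing from matrix")
  }
  ranks <- t(apply(expr[present, , drop = FALSE], 1, rank))
  score <- colSums(ranks)
  data.frame(sample_id = colnames(expr), signature = name,
             score = unname(score), n_genes = length(present),
             stringsAsFactors = FALSE)
}

# Weighted KS-style running-sum enrichment score for one set.
# Returns the signed maximum deviation and the running sum itself.
gsea_running_sum <- function(stats_sorted, in_set, weight = 1) {
  hit_w <- abs(stats_sorted)^weight
  hit_w[!in_set] <- 0
  total_hit <- sum(hit_w)
  n_miss <- sum(!in_set)
  if (total_hit == 0 || n_miss == 0) return(list(es = NA_real_, running = NULL))
  step <- ifelse(in_set, hit_w / total_hit, -1 / n_miss)
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum GSEA on a preranked gene list: genes are
#' ordered by the ranking statistic (decreasing); walking down the list,
#' set members increment the running sum by their normalized
#' `|stat|^weight` and non-members decrement it by `1/(N - g)`; the
#' enrichment score ES is the maximum deviation from zero. Significance
#' is assessed by gene-label permutation: `n_perm` random sets of the
#' same size, p-value one-tailed within the permuted scores of the same
#' sign as the observed ES (with the +1 correction), and
#' `NES = ES / mean(|permuted ES| of that sign)`. BH adjustment across
#' sets.
#'
#' @param ranked Named numeric vector gene -> ranking statistic (finite,
#'   unique names).
#' @param sets Gene-set collection (named list of gene id vectors).
#' @param weight Hit-weight exponent (1 = classic weighted; 0 = the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm Number of gene-label permutations.
#' @param min_size Sets with fewer overlapping genes are skipped.
#' @param seed Integer seed; permutation p-values are bit-reproducible.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p_value`,
#'   `p_adjusted`, `leading_edge` (comma-separated gene list).
#' @export
gsea_preranked <- function(ranked, sets, weight = 1, n_perm = 1000,
                           min_size = 5, seed = 1) {
  if (anyNA(ranked) || any(!is.finite(ranked))) stop("ranking stats must be finite")
  if (is.null(names(ranked)) || anyDuplicated(names(ranked))) {
    stop("ranked must be named with unique gene ids")
  }
  ord <- order(ranked, decreasing = TRUE)
  stats_sorted <- ranked[ord]
  genes_sorted <- names(stats_sorted)
  n <- length(ranked)

  sizes <- vapply(sets, function(s) sum(genes_sorted %in% s), integer(1))
  usable <- sizes >= min_size
  if (any(!usable)) {
    message(sum(!usable), " set(s) below min_size skipped: ",
            paste(names(sets)[!usable], collapse = ", "))
  }
  sets <- sets[usable]
  sizes <- sizes[usable]
  if (length(sets) == 0) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), leading_edge = character(0),
                      stringsAsFactors = FALSE))
  }

  perm_seeds <- derive_seeds(seed, n_perm, tag = "gsea")
  # one permutation = one random gene set per observed size; draw index
  # sets once per permutation and reuse across set sizes
  uniq_sizes <- sort(unique(sizes))
  perm_es <- matrix(NA_real_, n_perm, length(uniq_sizes),
                    dimnames = list(NULL, as.character(uniq_sizes)))
  for (p in seq_len(n_perm)) {
    shuffle <- with_seed(perm_seeds[p], sample.int(n, max(uniq_sizes)))
    for (j in seq_along(uniq_sizes)) {
      in_set <- logical(n)
      in_set[shuffle[seq_len(uniq_sizes[j])]] <- TRUE
      perm_es[p, j] <- gsea_running_sum(stats_sorted, in_set, weight)$es
    }
  }

  rows <- lapply(names(sets), function(nm) {
    in_set <- genes_sorted %in% sets[[nm]]
    rs <- gsea_running_sum(stats_sorted, in_set, weight)
    es <- rs$es
    null_es <- perm_es[, as.character(sum(in_set))]
    same_sign <- null_es * sign(es) > 0
    n_same <- sum(same_sign, na.rm = TRUE)
    p <- (1 + sum(same_sign & abs(null_es) >= abs(es), na.rm = TRUE)) / (1 + n_same)
    nes <- if (n_same > 0) es / mean(abs(null_es[same_sign]), na.rm = TRUE) else NA_real_
    peak <- which.max(abs(rs$running))
    le <- if (es >= 0) {
      genes_sorted[seq_len(peak)][in_set[seq_len(peak)]]
    } else {
      genes_sorted[peak:n][in_set[peak:n]]
    }
    data.frame(set = nm, size = sum(in_set), es = es, nes = nes, p_value = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[, c("set", "size", "es", "nes", "p_value", "p_adjusted", "leading_edge")]
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation of a DEG list
#'
#' One-sided Fisher exact enrichment of each gene set among the DEGs over
#' the tested gene universe; the same contract and engine as
#' [chromatin_state_ora()].
#'
#' @param deg_genes Character vector of significant DEG ids.
#' @param universe All tested gene ids.
#' @param sets Gene-set collection.
#' @return data.frame per set, see [ora_test()].
#' @export
set_ora <- function(deg_genes, universe, sets) {
  ora_test(deg_genes, universe, as.list(sets))
}
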