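#' Benjamini-Hochberg adjusted p-values
#'
#' One shared false-discovery-rate routine used pipeline-wide: the
#' definitional step-up construction (sorted `p * m / rank`, running minimum
#' from the largest p downward, capped at 1). `NA` p-values are carried
#' through unadjusted and do not count towards the family size `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of BH-adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}

# Derive n reproducible integer sub-seeds from one master seed. Sub-streams
# keep per-stage randomness independent of evaluation order; seeds stay
# below 2^31 - 1 so they are valid R integers.
derive_seeds <- function(seed, n, tag = "") {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (nzchar(tag)) {
    # fold a stage tag into the stream so stages never share a sub-seed
    offset <- sum(utf8ToInt(tag)) %% 1000L
    discard <- stats::runif(offset + 1L)
  }
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run an expression under a local RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

#' Shared over-representation test (one-sided Fisher / hypergeometric)
#'
#' For each category, builds the 2x2 table (selected/not x in-category/not)
#' over a finite universe and computes the one-sided (enrichment) Fisher
#' exact p-value as the hypergeometric upper tail, the sample odds ratio
#' `(a*d)/(b*c)` (with a 0.5 continuity correction added to every cell iff
#' any cell is zero), and BH-adjusted p-values across categories. This is
#' the engine behind both chromatin-state enrichment of differentially
#' methylated probes and gene-set over-representation of DEG lists.
#'
#' @param selected Character vector of selected element ids (e.g. DMPs,
#'   DEGs); must be a subset of `universe`.
#' @param universe Character vector of all tested element ids.
#' @param categories Named list mapping category name to the character
#'   vector of member ids.
#' @return A data.frame with one row per category: `category`, `n_selected`
#'   (selected in category), `n_category` (universe in category),
#'   `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
ora_test <- function(selected, universe, categories) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  selected <- unique(as.character(selected))
  if (!all(selected %in% universe)) {
    stop("selected ids must be a subset of the universe")
  }
  if (!is.list(categories) || is.null(names(categories))) {
    stop("categories must be a named list")
  }
  keep <- vapply(categories, function(m) any(m %in% universe), logical(1))
  if (any(!keep)) {
    warning(sprintf("skipping %d categor%s with no members in the universe: %s",
                    sum(!keep), if (sum(!keep) == 1) "y" else "ies",
                    paste(names(categories)[!keep], collapse = ", ")))
    categories <- categories[keep]
  }
  n_sel <- length(selected)
  n_uni <- length(universe)
  rows <- lapply(names(categories), function(nm) {
    members <- intersect(categories[[nm]], universe)
    a <- sum(selected %in% members)          # selected, in category
    b <- n_sel - a                           # selected, not in category
    cc <- length(members) - a                # not selected, in category
    d <- (n_uni - n_sel) - cc                # not selected, not in category
    p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    data.frame(category = nm, n_selected = a, n_category = length(members),
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

# Internal: check a beta/expression-style matrix has unique dimnames.
check_feature_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x)) stop(what, " must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate feature ids in ", what)
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in ", what)
  invisible(x)
}
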