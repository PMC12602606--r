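#' Kaplan-Meier disease-free-survival curves per group
#'
#' Product-limit estimates computed via the survival package, returned as
#' a tidy table (one row per distinct event/censor time per group) with
#' at-risk counts, events and the survival estimate. Ties are handled by
#' simultaneous events, the standard product-limit convention.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @param group Group labels (a single group is allowed).
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimate <- function(times, events, group = rep("all", length(times))) {
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  group <- as.character(group)
  if (any(table(group) == 0) || length(times) == 0) stop("empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  if (is.null(fit$strata)) {
    strata <- rep(unique(group), length(fit$time))
  } else {
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             survival = fit$surv, stringsAsFactors = FALSE)
}

#' Multi-group log-rank test
#'
#' The standard log-rank comparison of survival across two or more
#' groups: at every event time, observed minus hypergeometric-expected
#' events per group, chi-square statistic with `groups - 1` degrees of
#' freedom (via the survival package).
#'
#' @param times,events As in [km_estimate()].
#' @param group Group labels, at least two distinct values.
#' @return List: `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stop("need >= 2 groups")
  if (sum(events) < 1) stop("need >= 1 event overall")
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(fit$n) - 1
  list(chi_square = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Pearson chi-squared test with simulated p-value
#'
#' Pearson's X² on an r-by-c contingency table with the p-value obtained
#' by Monte-Carlo simulation of tables with fixed margins (Patefield's
#' algorithm, as in [stats::chisq.test()]), using the add-one convention
#' `p = (1 + #{X²* >= X²}) / (1 + n_sim)` so p is never zero. Zero-margin
#' rows/columns are dropped with a warning. Used e.g. for the association
#' between transcriptomic subtype and dichotomized tumor size.
#'
#' @param table Matrix of non-negative integer counts.
#' @param n_sim Number of simulated tables (default 2000).
#' @param seed Integer seed; fixed seed gives reproducible p-values.
#' @return List: `statistic` (X²), `p_simulated`, `n_sim`.
#' @export
chisq_simulated <- function(table, n_sim = 2000, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    stop("table must contain non-negative integers")
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping zero-margin rows/columns")
    table <- table[rs > 0, cs > 0, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2x2 after dropping")
  res <- with_seed(seed,
                   stats::chisq.test(table, simulate.p.value = TRUE, B = n_sim))
  list(statistic = unname(res$statistic), p_simulated = res$p.value, n_sim = n_sim)
}

#' Dichotomize tumor size at a cutoff
#'
#' Splits sizes into `"small"` (< cutoff) and `"large"` (>= cutoff; the
#' boundary value is assigned to "large"). Default cutoff 2.5 cm.
#'
#' @param size_cm Numeric sizes; `NA` stays `NA`.
#' @param cutoff_cm Cutoff in cm.
#' @return Character vector of `"small"`/`"large"`.
#' @export
dichotomize_size <- function(size_cm, cutoff_cm = 2.5) {
  ifelse(is.na(size_cm), NA_character_,
         ifelse(size_cm < cutoff_cm, "small", "large"))
}
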