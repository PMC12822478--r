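#' @title Statistical primitives shared by all pipeline stages
#' @description Thin, contract-enforcing wrappers around base R and the
#'   survival package: rank tests, BH adjustment, Spearman correlation,
#'   Fisher/hypergeometric tests, Kaplan-Meier curves and the log-rank test.
#'   Every function returns plain lists/data frames so downstream stages can
#'   assemble flat TSV artifacts.
#' @name stats-core
NULL

new_test_result <- function(statistic, p_value, method, n_used, exact_flag) {
  stopifnot(is.finite(p_value), p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(
      statistic = unname(statistic),
      p_value = min(unname(p_value), 1),
      method = method,
      n_used = n_used,
      exact_flag = isTRUE(exact_flag)
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf(
    "<test_result> %s: statistic = %.6g, p = %.4g (%s)\n",
    x$method, x$statistic, x$p_value,
    if (x$exact_flag) "exact" else "approximate"
  ))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum test for unpaired group comparisons
#' (e.g. C1 vs C2 subtype contrasts). Uses exact enumeration when the
#' smaller group has at most 8 observations and there are no ties across
#' the pooled sample; otherwise the normal approximation with tie
#' correction and 0.5 continuity correction.
#'
#' @param x,y Numeric vectors, one per group; missing values must be removed
#'   upstream (an error is raised if any remain).
#' @param alternative Currently only `"two.sided"`.
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact branch;
#'   `NULL` (default) applies the min(n) <= 8 & tie-free rule.
#' @return A `test_result` list: `statistic` (W), `p_value`, `method`,
#'   `n_used` (per-group counts), `exact_flag`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided", exact = NULL) {
  alternative <- match.arg(alternative, "two.sided")
  if (length(x) < 1 || length(y) < 1) stop("each group needs at least one value")
  if (anyNA(x) || anyNA(y)) stop("missing values must be removed before testing")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; p set to 1")
    return(new_test_result(length(x) * length(y) / 2, 1, "wilcoxon_rank_sum:degenerate",
                           c(n_x = length(x), n_y = length(y)), FALSE))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- if (is.null(exact)) min(length(x), length(y)) <= 8 && !ties else isTRUE(exact)
  if (use_exact && ties) use_exact <- FALSE
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = use_exact, correct = TRUE
  ))
  new_test_result(
    res$statistic, res$p.value,
    paste0("wilcoxon_rank_sum:", if (use_exact) "exact" else "normal_approx_cc"),
    c(n_x = length(x), n_y = length(y)), use_exact
  )
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired-sample test on per-patient differences (e.g. LM minus T within a
#' patient). Zero differences are dropped (Wilcoxon convention); exact
#' enumeration of sign assignments when at most 15 nonzero differences with
#' untied magnitudes remain, otherwise the tie-corrected normal
#' approximation.
#'
#' @param diffs Numeric vector of paired differences (no missing values).
#' @param alternative Currently only `"two.sided"`.
#' @param exact See [wilcoxon_rank_sum()].
#' @return A `test_result` list.
#' @export
wilcoxon_signed_rank <- function(diffs, alternative = "two.sided", exact = NULL) {
  alternative <- match.arg(alternative, "two.sided")
  if (anyNA(diffs)) stop("missing values must be removed before testing")
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L) {
    warning("all differences are zero; p set to 1")
    return(new_test_result(0, 1, "wilcoxon_signed_rank:degenerate",
                           c(n = length(diffs)), FALSE))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  use_exact <- if (is.null(exact)) length(nz) <= 15 && !ties else isTRUE(exact)
  if (use_exact && ties) use_exact <- FALSE
  res <- suppressWarnings(stats::wilcox.test(
    nz, alternative = alternative, exact = use_exact, correct = TRUE
  ))
  new_test_result(
    res$statistic, res$p.value,
    paste0("wilcoxon_signed_rank:", if (use_exact) "exact" else "normal_approx_cc"),
    c(n = length(nz)), use_exact
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values, order-preserving with the input. NA p-values
#' propagate to NA q-values and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties, pairwise deletion of missing values, and a
#' two-sided p from t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df. A constant
#' vector yields `rho = NA` with `degenerate = TRUE` rather than zero.
#'
#' @param x,y Numeric vectors of equal length; NAs removed pairwise.
#' @param min_pairs Minimum complete pairs required (default 4).
#' @return List with `rho`, `p`, `n`, `degenerate`.
#' @export
spearman_corr <- function(x, y, min_pairs = 4) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_pairs) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities no larger than
#' the observed table's probability (the classical definition, via
#' [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (conditional MLE) and `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  res <- stats::fisher.test(table, alternative = "two.sided")
  list(odds_ratio = unname(res$estimate), p = res$p.value)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= overlap) for drawing `selected` features from a `universe`
#' containing `set_size` set members — the over-representation test used
#' for pathway ORA against the quantified-feature universe.
#'
#' @param overlap Observed intersection size.
#' @param set_size Number of universe features in the set.
#' @param selected Number of selected features.
#' @param universe Universe size.
#' @return Upper-tail p-value.
#' @export
hypergeom_enrich <- function(overlap, set_size, selected, universe) {
  vals <- c(overlap, set_size, selected, universe)
  if (any(vals < 0) || any(vals != round(vals))) stop("counts must be non-negative integers")
  if (overlap > min(set_size, selected) || max(set_size, selected) > universe) {
    stop("inconsistent counts: need overlap <= min(set_size, selected) <= universe")
  }
  stats::phyper(overlap - 1, set_size, universe - set_size, selected, lower.tail = FALSE)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()]; censoring at an event
#' time is processed after the events at that time (the survfit convention).
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators in \{0, 1\} (1 = death/progression).
#' @return A `survival_curve`: data frame with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, plus `n` and `median` attributes.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times and events must have equal length")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  med <- unname(summary(fit)$table["median"])
  structure(curve, class = c("survival_curve", "data.frame"),
            n = length(times), median = med)
}

#' Median survival of a curve
#' @param curve A `survival_curve` from [km_curve()].
#' @return Median survival time (NA if S(t) never reaches 0.5).
#' @export
km_median <- function(curve) attr(curve, "median")

#' Two-group log-rank test
#'
#' Chi-square statistic sum (O-E)^2/V with the hypergeometric variance at
#' each distinct event time (via [survival::survdiff()]), p from
#' chi-square(1). If neither group has any event the test is degenerate and
#' p = 1 with a warning.
#'
#' @param times_a,events_a Group A follow-up and event indicators.
#' @param times_b,events_b Group B follow-up and event indicators.
#' @return A `test_result` list (statistic = chi-square).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either group; log-rank p set to 1")
    return(new_test_result(0, 1, "logrank:degenerate",
                           c(n_a = length(times_a), n_b = length(times_b)), FALSE))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  new_test_result(chisq, p, "logrank",
                  c(n_a = length(times_a), n_b = length(times_b)), FALSE)
}

#' Median-split survival comparison
#'
#' Splits samples at the median of a per-sample score (ties go to the low
#' stratum), fits a KM curve per stratum and runs the log-rank test. This
#' is the stratification used for signature scores, biomarker abundances
#' and PSI values throughout the pipeline.
#'
#' @param scores Named numeric vector (names = sample/patient ids).
#' @param times,events Survival endpoint aligned with `scores`.
#' @return List with `curve_low`, `curve_high`, `test` (a `test_result`),
#'   `strata` (factor low/high per sample) and `direction` (+1 if the high
#'   stratum has shorter median survival — a "poor prognosis" marker).
#' @export
median_split_survival <- function(scores, times, events) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  keep <- !is.na(scores) & !is.na(times) & !is.na(events)
  scores <- scores[keep]; times <- times[keep]; events <- events[keep]
  if (length(scores) < 4) stop("need at least 4 complete observations to stratify")
  med <- stats::median(scores)
  high <- scores > med
  if (all(high) || !any(high)) stop("degenerate split: scores do not separate at the median")
  test <- logrank_test(times[!high], events[!high], times[high], events[high])
  curve_low <- km_curve(times[!high], events[!high])
  curve_high <- km_curve(times[high], events[high])
  m_low <- km_median(curve_low); m_high <- km_median(curve_high)
  direction <- if (is.na(m_low) || is.na(m_high) || m_low == m_high) 0L
               else if (m_high < m_low) 1L else -1L
  list(
    curve_low = curve_low, curve_high = curve_high, test = test,
    strata = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
    direction = direction
  )
}
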