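#' Clopper-Pearson exact binomial prevalence estimate
#'
#' Exact two-sided confidence interval for a binomial proportion, obtained
#' by inverting the binomial tail probabilities; computed through the
#' standard beta-quantile characterization
#' (lower = `qbeta(alpha/2, k, n - k + 1)`,
#' upper = `qbeta(1 - alpha/2, k + 1, n - k)`), with the conventional
#' boundary values 0 at `k = 0` and 1 at `k = n`.  All quantities are
#' reported in percent.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return data.frame of class `prevalence_estimate` with columns `k`, `n`,
#'   `proportion`, `ci_low`, `ci_high` (percent).
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  alpha <- 1 - level
  lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  out <- data.frame(k = k, n = n, proportion = 100 * k / n,
                    ci_low = 100 * lo, ci_high = 100 * hi)
  class(out) <- c("prevalence_estimate", "data.frame")
  out
}

#' Two-group comparison tests
#'
#' Thin dispatcher over the standard two-sided tests used for group
#' comparisons: Pearson's chi-squared with Yates continuity correction and
#' Fisher's exact test for 2x2 tables, and the t and Mann-Whitney
#' (Wilcoxon rank-sum) tests for continuous variables.
#'
#' @param x for `"chi2"`/`"fisher"`: a 2x2 matrix of counts (rows =
#'   characteristic yes/no, columns = group); for `"t"`/`"mannwhitney"`:
#'   numeric values for group 1.
#' @param kind one of `"chi2"`, `"fisher"`, `"t"`, `"mannwhitney"`.
#' @param y numeric values for group 2 (continuous kinds only).
#' @return Two-sided p-value.
#' @export
two_group_tests <- function(x, kind = c("chi2", "fisher", "t", "mannwhitney"),
                            y = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("chi2", "fisher")) {
    x <- as.matrix(x)
    if (any(dim(x) != 2L)) stop("contingency table must be 2x2")
    if (any(x < 0) || any(x != round(x))) stop("cell counts must be non-negative integers")
    if (any(rowSums(x) == 0) || any(colSums(x) == 0))
      stop("contingency table has an empty margin")
    if (kind == "chi2")
      stats::chisq.test(x, correct = TRUE)$p.value
    else
      stats::fisher.test(x)$p.value
  } else {
    if (is.null(y) || length(x) == 0 || length(y) == 0)
      stop("both groups must be non-empty for continuous comparisons")
    if (kind == "t")
      stats::t.test(x, y)$p.value
    else
      stats::wilcox.test(x, y, exact = FALSE)$p.value
  }
}

#' Sample size for estimating a proportion to a given precision
#'
#' Smallest n such that the normal-approximation half-width of a
#' `level` confidence interval for a proportion `p` is at most
#' `half_width`: `ceiling(z^2 p (1 - p) / half_width^2)` with `z` the
#' two-sided normal quantile.  Maximal at `p = 0.5` for fixed precision.
#'
#' @param p anticipated prevalence, strictly between 0 and 1.
#' @param half_width desired CI half-width on the proportion scale
#'   (e.g. 0.10 for +/-10 percentage points).
#' @param level confidence level (default 0.95).
#' @return Required sample size (integer).
#' @export
sample_size_for_proportion <- function(p, half_width, level = 0.95) {
  if (p <= 0 || p >= 1) stop("p must be strictly between 0 and 1")
  if (half_width <= 0) stop("half_width must be > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / half_width^2))
}

#' Cohort endpoint prevalence summary
#'
#' Computes the study's five prevalence endpoints with exact binomial
#' confidence intervals: IIH and FDG+/PSMA- lesion carriage and PSMA-RPT
#' eligibility over all enrolled patients, and NED (DOTATATE positivity)
#' and DOTATATE-RPT eligibility over the DOTATATE-scanned subcohort.
#'
#' @param profiles output of [build_profiles()].
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `endpoint`, `k`, `n`, `proportion`,
#'   `ci_low`, `ci_high` (percent).
#' @export
endpoint_summary <- function(profiles, level = 0.95) {
  sub <- profiles[profiles$dotatate_scanned, , drop = FALSE]
  n_all <- nrow(profiles)
  n_sub <- nrow(sub)
  rows <- list(
    iih = c(sum(profiles$iih), n_all),
    fdg_pos_psma_neg = c(sum(profiles$has_fdg_pos_psma_neg), n_all),
    ned = c(if (n_sub) sum(sub$ned) else 0L, n_sub),
    psma_rpt_eligible = c(sum(profiles$psma_rpt_eligible), n_all),
    dotatate_rpt_eligible = c(if (n_sub) sum(sub$dotatate_rpt_eligible) else 0L, n_sub)
  )
  rows <- rows[vapply(rows, function(r) r[2] > 0, logical(1))]
  est <- clopper_pearson(vapply(rows, `[`, numeric(1), 1),
                         vapply(rows, `[`, numeric(1), 2), level)
  cbind(data.frame(endpoint = names(rows), stringsAsFactors = FALSE),
        as.data.frame(est))
}
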