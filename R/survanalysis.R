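#' Kaplan-Meier fit with median overall survival
#'
#' Product-limit estimate of the survival function, overall or by group,
#' with the median OS (earliest time the curve reaches 0.5) and its
#' log-log-transformed 95% confidence interval.  A median of `NA` means the
#' curve never drops to 0.5 ("not reached").
#'
#' @param time follow-up times in months (>= 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @param group optional stratification labels.
#' @param conf_level confidence level for the median CI (default 0.95).
#' @return List with `fit` (the underlying [survival::survfit] object),
#'   `median` (named numeric, `NA` = not reached), `median_ci` (matrix with
#'   columns `lower`, `upper`), and `curve` (data.frame `group`, `time`,
#'   `surv`).
#' @export
km_fit <- function(time, event, group = NULL, conf_level = 0.95) {
  if (any(time < 0)) stop("survival times must be >= 0")
  if (is.null(group)) group <- rep("all", length(time))
  df <- data.frame(time = time, event = event, group = as.factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) {  # single stratum
    tab <- t(as.matrix(tab))
    rownames(tab) <- levels(df$group)[1]
  }
  lcl <- grep("LCL$", colnames(tab), value = TRUE)[1]
  ucl <- grep("UCL$", colnames(tab), value = TRUE)[1]
  med <- tab[, "median"]
  ci <- tab[, c(lcl, ucl), drop = FALSE]
  colnames(ci) <- c("lower", "upper")
  grp_names <- sub("^group=", "", rownames(tab))
  names(med) <- rownames(ci) <- grp_names
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep(grp_names[1], length(s$time))
            else sub("^group=", "", as.character(s$strata))
  list(fit = fit, median = med, median_ci = ci,
       curve = data.frame(group = strata, time = s$time, surv = s$surv))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank comparison of two survival
#' curves; identical groups give statistic 0 and p = 1.
#'
#' @inheritParams km_fit
#' @param group binary group labels (both levels non-empty).
#' @return List with `chisq` and `p` (two-sided).
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0)) stop("survival times must be >= 0")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test requires exactly two non-empty groups")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chisq = unname(sd$chisq),
       p = unname(stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)))
}

#' Cox proportional-hazards model for a single binary covariate
#'
#' Maximum partial-likelihood hazard-ratio estimate with Efron handling of
#' tied event times and a Wald confidence interval on the log scale.  The
#' fit is flagged non-estimable when there are no events or when the groups
#' are completely separated (the estimate diverges).
#'
#' @inheritParams logrank_test
#' @param conf_level confidence level (default 0.95).
#' @return List with `hr`, `ci` (length-2), `beta`, `se`, `p` (Wald),
#'   `score_chisq` (the Cox score test statistic), and `estimable`.
#' @export
cox_binary <- function(time, event, group, conf_level = 0.95) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("cox_binary requires exactly two non-empty groups")
  if (sum(event) == 0)
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), beta = NA_real_,
                se = NA_real_, p = NA_real_, score_chisq = NA_real_,
                estimable = FALSE))
  df <- data.frame(time = time, event = event, group = group)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = df,
                    ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  # divergent estimate => complete separation; partial likelihood has no
  # interior maximum
  estimable <- is.finite(beta) && abs(beta) < 15 && is.finite(se)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * z * se),
       beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       score_chisq = unname(fit$score),
       estimable = estimable)
}

#' Phenotype-stratified survival contrast
#'
#' Runs the full survival comparison for one binary stratification of a
#' profile table: Kaplan-Meier medians per group, log-rank p, and the Cox
#' hazard ratio with 95% CI.
#'
#' @param profiles output of [build_profiles()] including `os_months` and
#'   `event` columns.
#' @param stratify one of `"iih"` (excludes the all-negative class, whose
#'   IIH status is undefined for group comparison), `"fdg_pos_psma_neg"`
#'   (ditto), or `"dotatate_pos"` (DOTATATE-scanned patients only).
#' @return List with `stratify`, `n`, `groups`, `median`, `median_ci`,
#'   `logrank_p`, `hr`, `hr_ci`, `estimable`.
#' @export
survival_contrast <- function(profiles,
                              stratify = c("iih", "fdg_pos_psma_neg", "dotatate_pos")) {
  stratify <- match.arg(stratify)
  if (!all(c("os_months", "event") %in% names(profiles)))
    stop("profiles must carry os_months and event columns")
  df <- switch(stratify,
    iih = {
      d <- profiles[profiles$combination != "all-negative", ]
      d$strat <- factor(ifelse(d$iih, "IIH", "no IIH"), c("no IIH", "IIH"))
      d
    },
    fdg_pos_psma_neg = {
      d <- profiles[profiles$combination != "all-negative", ]
      d$strat <- factor(ifelse(d$has_fdg_pos_psma_neg, "F+/P- present", "absent"),
                        c("absent", "F+/P- present"))
      d
    },
    dotatate_pos = {
      d <- profiles[profiles$dotatate_scanned, ]
      d$strat <- factor(ifelse(d$ned, "D+ present", "absent"),
                        c("absent", "D+ present"))
      d
    })
  km <- km_fit(df$os_months, df$event, df$strat)
  lr <- logrank_test(df$os_months, df$event, df$strat)
  cx <- cox_binary(df$os_months, df$event, df$strat)
  list(stratify = stratify, n = nrow(df), groups = levels(df$strat),
       median = km$median, median_ci = km$median_ci,
       logrank_p = lr$p, hr = cx$hr, hr_ci = cx$ci, estimable = cx$estimable)
}
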