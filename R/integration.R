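#' @name integration_stats
#' @title Six-group signature overlap and cohort statistics
#'
#' @description
#' Overlays the cell-of-origin label, the MYC activity class and the
#' consensus-cluster call into six mutually exclusive expression groups,
#' and provides the association and survival statistics used to
#' characterize them: proportions at printed precision, Fisher's exact and
#' chi-square tests, confusion-table metrics, Spearman correlation,
#' Kaplan-Meier estimates and Cox proportional-hazards fits.
NULL

#' Assign samples to the six overlap groups
#'
#' The precedence rule: COO-Unclassified samples form their own group;
#' ABC samples split by MYC class; GCB samples are `GCB/MYC-high` when MYC
#' is High (MYC takes precedence over the cluster call), otherwise `GCB/HR`
#' or `GCB/non-HR` by the consensus cluster.
#'
#' @param coo per-sample `"GCB"`/`"ABC"`/`"Unclassified"`.
#' @param myc_class per-sample `"High"`/`"Low"`.
#' @param monti per-sample consensus cluster, `"HR"` or `"non-HR"`.
#' @return Character vector of group labels; `NA` (unassignable) where a
#'   required component is missing.
#' @export
assign_six_groups <- function(coo, myc_class, monti) {
  n <- max(length(coo), length(myc_class), length(monti))
  coo <- rep_len(coo, n); myc_class <- rep_len(myc_class, n)
  monti <- rep_len(monti, n)
  vapply(seq_len(n), function(i) {
    if (is.na(coo[i])) return(NA_character_)
    if (coo[i] == "Unclassified") return("COO-Unclassified")
    if (is.na(myc_class[i])) return(NA_character_)
    if (coo[i] == "ABC") {
      return(if (myc_class[i] == "High") "ABC/MYC-high" else "ABC/MYC-low")
    }
    if (myc_class[i] == "High") return("GCB/MYC-high")
    if (is.na(monti[i])) return(NA_character_)
    if (monti[i] == "HR") "GCB/HR" else "GCB/non-HR"
  }, "")
}

#' Tabulate six-group counts and percentages
#'
#' @param groups output of [assign_six_groups()].
#' @param decimals decimal places for the percentage (default 0, the
#'   printed convention).
#' @return `data.frame(group, n, percent)` over the six canonical groups;
#'   percentages use the number of assignable samples as denominator.
#' @export
six_group_table <- function(groups, decimals = 0) {
  levels <- c("GCB/MYC-high", "GCB/HR", "GCB/non-HR", "COO-Unclassified",
              "ABC/MYC-high", "ABC/MYC-low")
  ok <- !is.na(groups)
  counts <- table(factor(groups[ok], levels = levels))
  data.frame(
    group = levels,
    n = as.integer(counts),
    percent = proportion(as.integer(counts), sum(ok), decimals),
    stringsAsFactors = FALSE
  )
}

#' Percentage at printed precision
#'
#' `100 * numerator / denominator`, rounded half away from zero to
#' `decimals` places.
#'
#' @param numerator,denominator counts (`denominator > 0`).
#' @param decimals decimal places (default 1).
#' @return Numeric percentage(s).
#' @export
proportion <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass criterion (sum of
#' hypergeometric probabilities of tables, at fixed margins, no more
#' probable than the observed one); the odds ratio is the sample
#' cross-product `(a*d)/(b*c)` with the usual infinity/zero conventions.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("cell counts must be non-negative")
  p <- stats::fisher.test(table)$p.value
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  list(p_value = p, odds_ratio = or)
}

#' Pearson chi-square test
#'
#' Uncorrected Pearson statistic with `(r-1)(c-1)` degrees of freedom.
#' Rejects tables with a zero expected count (use [fisher_exact()]).
#'
#' @param table r x c matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("cell counts must be non-negative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("zero expected count; use fisher_exact() instead")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Confusion-table metrics
#'
#' @param pred,truth logical vectors (the truth must contain at least one
#'   positive and one negative).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
sensitivity_specificity <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  pred <- as.logical(pred[ok]); truth <- as.logical(truth[ok])
  if (!any(truth) || all(truth)) {
    stop("truth must contain both positives and negatives")
  }
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks after pairwise deletion of missing
#' values; needs at least 3 complete pairs. A constant vector has no
#' defined rank correlation and returns `NA`.
#'
#' @param x,y numeric vectors.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("at least 3 complete pairs are required")
  if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Kaplan-Meier estimate and five-year survival
#'
#' Product-limit estimator of the survival function, with the survival
#' probability read off at five time units (years in the standard
#' configuration).
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param horizon time at which to report survival (default 5).
#' @return List with `steps` (`data.frame(time, n_risk, n_event, surv)`)
#'   and `five_year_os` (survival at `horizon`; 1 if no event by then).
#' @export
km_estimate <- function(time, event, horizon = 5) {
  if (any(time < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  before <- steps$surv[steps$time <= horizon & steps$n_event > 0]
  five <- if (length(before) == 0) 1 else min(before)
  list(steps = steps, five_year_os = five)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie correction, as one
#' multivariable model or a series of univariable models.
#'
#' @param time,event survival outcome.
#' @param covariates data frame of numeric or two-level covariates.
#' @param mode `"univariate"` (one model per covariate) or
#'   `"multivariate"` (one joint model).
#' @return `data.frame(term, coef, hr, se, p_value)`.
#' @export
cox_fit <- function(time, event, covariates,
                    mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  if (sum(event, na.rm = TRUE) < 2) stop("at least 2 events are required")
  covariates <- as.data.frame(covariates)
  surv <- survival::Surv(time, event)
  fit_one <- function(df) {
    fit <- survival::coxph(surv ~ ., data = df, ties = "efron")
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), coef = s[, "coef"],
               hr = s[, "exp(coef)"], se = s[, "se(coef)"],
               p_value = s[, "Pr(>|z|)"], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  if (mode == "multivariate") {
    fit_one(covariates)
  } else {
    do.call(rbind, lapply(names(covariates), function(v) {
      fit_one(covariates[, v, drop = FALSE])
    }))
  }
}
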