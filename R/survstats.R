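## Survival and association statistics: Kaplan-Meier, log-rank,
## univariate Cox, Harrell's C-index, ROC AUC.

#' Load (or filter) a survival table
#'
#' Applies the study inclusion filter: survival time must exceed
#' `min_days` (default 30); excluded records are reported.
#'
#' @param surv data.frame with columns sample, time (days), event (0/1),
#'   or a path to such a TSV.
#' @param min_days exclusion threshold (default 30).
#' @return filtered data.frame.
#' @export
load_survival <- function(surv, min_days = 30) {
  if (is.character(surv)) surv <- utils::read.delim(surv)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(surv)))
    stopf("survival table needs columns %s", paste(need, collapse = ", "))
  if (!all(surv$event %in% c(0, 1))) stopf("event must be 0/1")
  drop <- surv$time <= min_days
  if (any(drop))
    message(sprintf("excluding %d record(s) with survival time <= %g days",
                    sum(drop), min_days))
  surv[!drop, , drop = FALSE]
}

#' Kaplan-Meier curves with median survival
#'
#' Product-limit estimator per group (via `survival::survfit`).
#'
#' @param surv data.frame: sample, time, event.
#' @param groups group label per row (single group if NULL).
#' @return list: `curves` (data.frame group, time, surv, n_risk, n_event),
#'   `median` (named vector of median survival per group), `fit`.
#' @export
km_curve <- function(surv, groups = NULL) {
  groups <- groups %||% rep("all", nrow(surv))
  stopifnot(length(groups) == nrow(surv))
  if (any(table(groups) == 0)) stopf("empty group")
  df <- data.frame(time = surv$time, event = surv$event,
                   group = as.character(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit)
  grp <- if (is.null(sm$strata)) rep(unique(df$group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, surv = sm$surv,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       stringsAsFactors = FALSE)
  med <- summary(fit)$table
  med <- if (is.null(dim(med))) stats::setNames(med["median"],
                                                unique(df$group))
         else stats::setNames(med[, "median"],
                              sub("^group=", "", rownames(med)))
  list(curves = curves, median = med, fit = fit)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square over event times
#' (via `survival::survdiff`), two-sided p on K-1 degrees of freedom.
#'
#' @param surv data.frame: time, event.
#' @param groups group label per row (>= 2 groups).
#' @return list: chi2, df, p.
#' @export
logrank <- function(surv, groups) {
  stopifnot(length(groups) == nrow(surv))
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2) stopf("need >= 2 groups")
  if (sum(surv$event) == 0) {
    warning("all samples censored; log-rank undefined, returning p = 1")
    return(list(chi2 = 0, df = k - 1, p = 1))
  }
  df <- data.frame(time = surv$time, event = surv$event, group = groups)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chi2 = unname(sd$chisq), df = k - 1,
       p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling
#' (via `survival::coxph`); Wald z and p.  Monotone-likelihood /
#' non-convergence is flagged, not silently returned.
#'
#' @param surv data.frame: time, event.
#' @param covariate numeric vector, one value per row of `surv`.
#' @return list: beta, hr, se, z, p, c_index (on the fitting data),
#'   converged.
#' @export
cox_univariate <- function(surv, covariate) {
  stopifnot(length(covariate) == nrow(surv), all(is.finite(covariate)))
  if (sum(surv$event) == 0) stopf("no events; Cox fit undefined")
  df <- data.frame(time = surv$time, event = surv$event, x = covariate)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)),
       hr = unname(exp(stats::coef(fit))),
       se = unname(s$coefficients[, "se(coef)"]),
       z = unname(s$coefficients[, "z"]),
       p = unname(s$coefficients[, "Pr(>|z|)"]),
       c_index = c_index(surv, covariate),
       converged = converged)
}

#' Harrell's concordance index
#'
#' Fraction of usable sample pairs whose risk ordering agrees with their
#' survival ordering.  A pair is usable when the shorter observed time
#' belongs to a sample with an event and the times differ; risk ties count
#' 0.5.
#'
#' @param surv data.frame: time, event.
#' @param risk numeric risk score per row (higher = worse expected
#'   survival).
#' @return concordance in \[0, 1\].
#' @export
c_index <- function(surv, risk) {
  t <- surv$time; e <- surv$event
  stopifnot(length(risk) == length(t))
  ## usable pairs: t_i < t_j and event_i == 1
  ti <- outer(t, t, "<")
  usable <- ti & matrix(e == 1, length(t), length(t))
  if (!any(usable)) stopf("no comparable pairs; C-index undefined")
  ri <- outer(risk, risk, "-")[usable]  # risk_i - risk_j for usable (i,j)
  (sum(ri > 0) + 0.5 * sum(ri == 0)) / length(ri)
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' `AUC = U / (n1 * n0)` with U from average ranks, so score ties receive
#' 0.5 credit.
#'
#' @param binary_label logical or 0/1 vector (TRUE/1 = positive class).
#' @param score numeric score per sample.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(binary_label, score) {
  y <- as.logical(binary_label)
  stopifnot(length(y) == length(score))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
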