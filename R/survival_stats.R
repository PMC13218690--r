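# Survival layer: thin, validated wrappers around the survival package
# (the field-standard implementation of the product-limit estimator,
# log-rank test and Cox partial likelihood), exposing exactly the surface
# the subtyping pipeline needs.

validate_survival <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("sample_id", "time", "event") %in% names(surv)))
  if (anyDuplicated(surv$sample_id)) {
    stop("duplicated sample IDs in survival table", call. = FALSE)
  }
  if (any(!is.finite(surv$time)) || any(surv$time <= 0)) {
    stop("survival times must be positive and finite", call. = FALSE)
  }
  if (!all(surv$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  invisible(surv)
}

#' Kaplan-Meier estimate of survival
#'
#' Product-limit estimator, overall or per group. With no events the
#' estimator is flat at 1 and a warning is raised.
#'
#' @param surv Data frame with columns `sample_id`, `time`, `event`.
#' @param groups Optional group label per row of `surv`.
#' @return Object of class `km_fit`: list with the underlying
#'   `survival::survfit` fit, a tidy `table` (group, time, n_risk, n_event,
#'   n_censor, surv) and `surv_fun`, a named list of right-continuous step
#'   functions S(t) per group (S(0) = 1).
#' @export
km_estimate <- function(surv, groups = NULL) {
  validate_survival(surv)
  if (sum(surv$event) == 0) {
    warning("no events observed; Kaplan-Meier estimate is flat at 1")
  }
  dat <- data.frame(time = surv$time, event = surv$event)
  if (is.null(groups)) {
    dat$group <- "all"
  } else {
    stopifnot(length(groups) == nrow(surv))
    dat$group <- as.character(groups)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(dat$group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  tab <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    surv = sm$surv, stringsAsFactors = FALSE)
  surv_fun <- lapply(split(tab, tab$group), function(d) {
    ev <- d[d$n_event > 0, , drop = FALSE]
    if (nrow(ev) == 0L) return(function(t) rep(1, length(t)))
    stats::stepfun(ev$time, c(1, ev$surv), right = FALSE)
  })
  structure(list(fit = fit, table = tab, surv_fun = surv_fun),
            class = "km_fit")
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected event counts with hypergeometric variance
#' (`survival::survdiff`, rho = 0).
#'
#' @param surv Survival table (see [km_estimate()]).
#' @param groups Group label per row; at least two non-empty groups.
#' @return List with `statistic` (chi-square), `df` and `p_value`.
#' @export
logrank_test <- function(surv, groups) {
  validate_survival(surv)
  stopifnot(length(groups) == nrow(surv))
  g <- factor(groups)
  if (nlevels(g) < 2L) {
    stop("log-rank test needs at least two groups", call. = FALSE)
  }
  if (sum(surv$event) == 0) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  dat <- data.frame(time = surv$time, event = surv$event, group = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards score for one covariate
#'
#' Fits the Cox partial likelihood with Breslow tie handling and reports the
#' Wald p-value (the default the survival package prints); the
#' likelihood-ratio p is also returned.
#'
#' @param surv Survival table (see [km_estimate()]).
#' @param covariate Numeric vector aligned with `surv` rows.
#' @param name Covariate name for the report.
#' @return Object of class `cox_result`: one-row data frame with `covariate`,
#'   `beta`, `hazard_ratio`, `se`, `z`, `p_value`, `p_lrt`, `direction`
#'   ("risk" iff beta > 0 else "protective").
#' @export
cox_univariate <- function(surv, covariate, name = "x") {
  validate_survival(surv)
  stopifnot(length(covariate) == nrow(surv))
  if (any(!is.finite(covariate))) {
    stop("covariate has non-finite values", call. = FALSE)
  }
  if (stats::var(covariate) == 0) {
    stop("degenerate covariate '", name, "': zero variance", call. = FALSE)
  }
  if (sum(surv$event) == 0) {
    stop("Cox regression needs at least one event", call. = FALSE)
  }
  dat <- data.frame(time = surv$time, event = surv$event, x = covariate)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                         ties = "breslow")
  s <- summary(fit)
  co <- s$coefficients
  res <- data.frame(
    covariate = name,
    beta = unname(co[1, "coef"]),
    hazard_ratio = unname(co[1, "exp(coef)"]),
    se = unname(co[1, "se(coef)"]),
    z = unname(co[1, "z"]),
    p_value = unname(co[1, "Pr(>|z|)"]),
    p_lrt = unname(s$logtest["pvalue"]),
    stringsAsFactors = FALSE
  )
  res$direction <- if (res$beta > 0) "risk" else "protective"
  class(res) <- c("cox_result", "data.frame")
  res
}

#' Restricted mean survival time per group
#'
#' Area under the Kaplan-Meier curve up to `tau` (default: largest observed
#' time). Used to orient subtype labels: the better-prognosis cluster has
#' the larger restricted mean.
#'
#' @param surv Survival table.
#' @param groups Group label per row.
#' @param tau Restriction time.
#' @return Named numeric vector of restricted means per group.
#' @export
restricted_mean_survival <- function(surv, groups, tau = max(surv$time)) {
  km <- km_estimate(surv, groups)
  tabs <- split(km$table, km$table$group)
  vapply(tabs, function(d) {
    ev <- d[d$n_event > 0 & d$time <= tau, , drop = FALSE]
    grid <- c(0, ev$time, tau)
    heights <- c(1, ev$surv)  # S is right-continuous, steps at event times
    sum(diff(grid) * heights)
  }, 0)
}
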