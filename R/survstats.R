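#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator with Greenwood variance; confidence bounds and the
#' median-survival interval use the log-log transform (Brookmeyer-Crowley
#' style inversion as implemented by `survival::survfit`). The median is the
#' earliest time at which the survival curve drops to 0.5 or below, reported
#' as not reached (`NA`) when the curve never does. Times are treated as
#' months throughout; no unit conversion is attempted.
#'
#' @param time Non-negative survival times.
#' @param event Status, 1 = event, 0 = censored.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `table` (data frame: time, n_risk, n_event, surv, lower,
#'   upper), `median`, `median_ci` (length-2, `NA` = not reached), `n`,
#'   `n_events`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) < 1L) stop("need at least one observation", call. = FALSE)
  if (any(is.na(time)) || any(time < 0))
    stop("survival times must be non-negative and non-missing", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  med_ci <- c(unname(stats::quantile(fit, probs = 0.5)$lower),
              unname(stats::quantile(fit, probs = 0.5)$upper))
  list(table = tab, median = med, median_ci = med_ci,
       n = length(time), n_events = sum(event))
}

#' Log-rank (Mantel-Cox) test
#'
#' Observed-minus-expected chi-square statistic with hypergeometric variance
#' at each distinct event time; `df = groups - 1`.
#'
#' @param time,event Survival data.
#' @param group Group labels (2+ non-empty groups).
#' @return List with `statistic`, `df`, `p_value`, `observed`, `expected` (per
#'   group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L)
    stop("log-rank test needs at least two groups", call. = FALSE)
  if (sum(event) < 1L) stop("log-rank test needs at least one event",
                            call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson, Efron tie correction, the
#' modern default) with Wald confidence intervals and p-values. Constant
#' covariates, apparent monotone likelihood (infinite coefficients) and
#' non-convergence are errors with a diagnostic rather than silent output.
#'
#' @param time,event Survival data.
#' @param covariates Data frame (or vector) of covariates; factors allowed.
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return An object of class `CoxFit`: data frame `summary` (term, coef, hr,
#'   ci_lower, ci_upper, se, p_value) plus `loglik`, `n`, `n_events`,
#'   `ties = "efron"`.
#' @export
cox_fit <- function(time, event, covariates, conf_level = 0.95) {
  if (!is.data.frame(covariates))
    covariates <- data.frame(x = covariates)
  if (nrow(covariates) != length(time))
    stop("covariates and survival data differ in length", call. = FALSE)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate: ", nm, call. = FALSE)
  }
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates", call. = FALSE)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("monotone likelihood / non-convergence in Cox fit: ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  res <- data.frame(term = names(co), coef = unname(co),
                    hr = exp(unname(co)),
                    ci_lower = exp(unname(co) - z * se),
                    ci_upper = exp(unname(co) + z * se),
                    se = unname(se),
                    p_value = unname(2 * stats::pnorm(-abs(co / se))),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = res, loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_events = fit$nevent, ties = "efron"),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("<CoxFit> n = %d, events = %d, ties = %s\n", x$n, x$n_events,
              x$ties))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a CoxFit as JSON
#'
#' @param fit A `CoxFit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
coxfit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "CoxFit"))
  writeLines(jsonlite::toJSON(unclass(fit), auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, dataframe = "rows"), path)
  invisible(path)
}

#' Write per-group Kaplan-Meier tables
#'
#' One tab-separated (time, at-risk, events, survival, CI) block per group.
#'
#' @param time,event Survival data.
#' @param group Group labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_tables <- function(time, event, group, path) {
  group <- as.factor(group)
  out <- do.call(rbind, lapply(levels(group), function(g) {
    sel <- group == g
    km <- km_estimate(time[sel], event[sel])
    cbind(group = g, km$table)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
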