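#' Cox proportional-hazards fit
#'
#' Efron-tie partial-likelihood maximization with Wald confidence
#' intervals and p-values, packaged with the quantities the pipeline
#' reports (HR, CI, p per covariate). Fitting is delegated to
#' [survival::coxph()].
#'
#' @param time follow-up times.
#' @param event event indicator (1 = progressed, 0 = censored).
#' @param covariates data.frame or matrix of covariates.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `cox_fit`: data.frame (term, coef, hr, ci_low,
#'   ci_high, p) with attributes `loglik`, `n`, `n_events`, `fit`,
#'   `linear_predictor`.
#' @export
cox_fit <- function(time, event, covariates, conf_level = 0.95) {
  if (sum(event) < 1) stop("no events; Cox model is inestimable")
  df <- as.data.frame(covariates)
  ## covariates with no variation are unestimable but harmless: they are
  ## dropped from the fit and reported with coefficient 0 (HR 1)
  constant <- vapply(df, function(x)
    is.numeric(x) && stats::sd(x) == 0, logical(1))
  const_terms <- names(df)[constant]
  df <- df[, !constant, drop = FALSE]
  if (ncol(df) == 0) {
    out <- data.frame(term = const_terms, coef = 0, hr = 1,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(out, loglik = NA_real_, n = length(time),
                     n_events = sum(event),
                     linear_predictor = rep(0, length(time)),
                     class = c("cox_fit", "data.frame")))
  }
  df$.time <- time
  df$.event <- event
  terms <- setdiff(names(df), c(".time", ".event"))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", terms), collapse = "+")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(stats::vcov(fit))) > 1e3))
    stop("monotone partial likelihood (perfect separation); ",
         "consider penalized estimation")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = names(co), coef = unname(co), hr = exp(unname(co)),
    ci_low = exp(unname(co) - z * se), ci_high = exp(unname(co) + z * se),
    p = 2 * stats::pnorm(abs(unname(co) / se), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  if (length(const_terms) > 0) {
    out <- rbind(out, data.frame(term = const_terms, coef = 0, hr = 1,
                                 ci_low = NA_real_, ci_high = NA_real_,
                                 p = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  structure(out, loglik = fit$loglik[2], n = fit$n, n_events = fit$nevent,
            fit = fit,
            linear_predictor = unname(fit$linear.predictors),
            class = c("cox_fit", "data.frame"))
}

#' Kaplan-Meier curves by group with a Cox-based p-value
#'
#' Product-limit survival estimate per group; the between-group p-value
#' comes from a Cox fit on the group indicators.
#'
#' @param time,event follow-up and event indicator.
#' @param groups group labels.
#' @return list with `curves` (data.frame: group, time, n_risk, n_event,
#'   surv) and `cox_p` (NULL for a single group).
#' @export
km_curve <- function(time, event, groups) {
  groups <- factor(groups)
  keep <- !is.na(groups)
  empty <- setdiff(levels(groups), unique(groups[keep]))
  if (length(empty) > 0) groups <- droplevels(groups[keep])
  sf <- survival::survfit(survival::Surv(time[keep], event[keep]) ~
                            groups, conf.type = "none")
  strata_lab <- if (is.null(sf$strata)) {
    rep(levels(groups)[1], length(sf$time))
  } else {
    rep(sub("^groups=", "", names(sf$strata)), sf$strata)
  }
  curves <- data.frame(group = strata_lab, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  cox_p <- NULL
  if (nlevels(groups) > 1) {
    cf <- cox_fit(time[keep], event[keep],
                  data.frame(group = groups[keep]))
    cox_p <- cf$p
    names(cox_p) <- cf$term
  }
  list(curves = curves, cox_p = cox_p)
}

## Kaplan-Meier survival function evaluated at t (right-continuous)
km_at <- function(fit_time, fit_surv, t) {
  if (length(fit_time) == 0) return(1)
  idx <- findInterval(t, fit_time)
  c(1, fit_surv)[idx + 1]
}

#' Cumulative case / dynamic control time-dependent ROC
#'
#' At each evaluation time t, cases are subjects with an event by t and
#' controls are subjects event-free beyond t. Sensitivity and specificity
#' at every marker cutoff are estimated with the Kaplan-Meier method
#' (censored mass redistributed via within-cutoff-group KM curves), and
#' AUC(t) is the trapezoid area over the resulting ROC. Times with no
#' cases or no controls yield `NA`.
#'
#' @param marker numeric risk marker (higher = riskier).
#' @param time,event follow-up and event indicator.
#' @param eval_times evaluation time grid (default: 10 equally spaced
#'   points up to `tau`).
#' @param tau horizon used for the default grid (default max observed
#'   time).
#' @return object of class `time_roc`: data.frame (t, auc) with attribute
#'   `rocs` (per-time ROC coordinate tables).
#' @export
cumulative_dynamic_auc <- function(marker, time, event, eval_times = NULL,
                                   tau = max(time)) {
  if (is.null(eval_times)) eval_times <- seq(tau / 10, tau, length.out = 10)
  if (any(eval_times > max(time)))
    stop("eval_times must lie within observed follow-up")
  n <- length(marker)
  sf_all <- survival::survfit(survival::Surv(time, event) ~ 1,
                              conf.type = "none")
  cuts <- sort(unique(marker))
  ## KM survival within each marker-above-cutoff group, reused across times
  grp_fits_hi <- lapply(cuts, function(c) {
    sel <- marker > c
    if (!any(sel)) return(NULL)
    survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1,
                      conf.type = "none")
  })
  grp_fits_lo <- lapply(cuts, function(c) {
    sel <- marker <= c
    if (!any(sel)) return(NULL)
    survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1,
                      conf.type = "none")
  })
  p_hi <- vapply(cuts, function(c) mean(marker > c), numeric(1))

  rocs <- list()
  auc <- vapply(seq_along(eval_times), function(k) {
    t <- eval_times[k]
    s_t <- km_at(sf_all$time, sf_all$surv, t)
    f_t <- 1 - s_t
    if (f_t <= 0 || s_t <= 0) {
      rocs[k] <<- list(NULL)
      return(NA_real_)
    }
    sens <- vapply(seq_along(cuts), function(i) {
      if (is.null(grp_fits_hi[[i]])) return(0)
      s_g <- km_at(grp_fits_hi[[i]]$time, grp_fits_hi[[i]]$surv, t)
      (1 - s_g) * p_hi[i] / f_t
    }, numeric(1))
    spec <- vapply(seq_along(cuts), function(i) {
      if (is.null(grp_fits_lo[[i]])) return(0)
      s_g <- km_at(grp_fits_lo[[i]]$time, grp_fits_lo[[i]]$surv, t)
      s_g * (1 - p_hi[i]) / s_t
    }, numeric(1))
    ## traverse the ROC from the highest cutoff (0,0) to the lowest (1,1)
    fpr <- c(0, rev(pmin(pmax(1 - spec, 0), 1)), 1)
    tpr <- c(0, rev(pmin(pmax(sens, 0), 1)), 1)
    rocs[[k]] <<- data.frame(t = unname(t), fpr = unname(fpr),
                             tpr = unname(tpr))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }, numeric(1))
  structure(data.frame(t = eval_times, auc = auc),
            rocs = rocs, class = c("time_roc", "data.frame"))
}

#' Uno's censoring-adjusted concordance
#'
#' Inverse-probability-of-censoring-weighted C-statistic truncated at
#' horizon `tau`: over ordered pairs with the earlier subject's event time
#' below `tau`, concordant marker orderings are counted with weights
#' `1 / G(t_i)^2`, where G is the Kaplan-Meier estimate of the censoring
#' distribution evaluated just before the event time. With no censoring
#' all weights are 1 and the statistic equals Harrell's pair-count C.
#'
#' @param marker numeric risk marker (higher = riskier).
#' @param time,event follow-up and event indicator.
#' @param tau truncation horizon (default max observed time).
#' @return the concordance estimate in `[0, 1]`.
#' @export
uno_concordance <- function(marker, time, event, tau = max(time)) {
  if (tau > max(time)) stop("tau exceeds observed follow-up")
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                                conf.type = "none")
  g_at <- function(t) {
    ## left-continuous KM of censoring: G(t-)
    v <- km_at(cens_fit$time, cens_fit$surv, t - 1e-10)
    pmax(v, 1e-10)
  }
  num <- 0
  den <- 0
  idx_i <- which(event == 1 & time < tau)
  for (i in idx_i) {
    w <- 1 / g_at(time[i])^2
    j <- which(time > time[i])
    if (length(j) == 0) next
    conc <- (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
    num <- num + w * sum(conc)
    den <- den + w * length(j)
  }
  if (den == 0) stop("no usable pairs below tau")
  num / den
}

#' Harrell's concordance by direct pair counting
#'
#' Unweighted pair-count C over usable pairs (earlier subject experienced
#' the event); ties in the marker count 1/2.
#'
#' @inheritParams uno_concordance
#' @return concordance in `[0, 1]`.
#' @export
harrell_concordance <- function(marker, time, event) {
  num <- 0; den <- 0
  for (i in which(event == 1)) {
    j <- which(time > time[i])
    if (length(j) == 0) next
    num <- num + sum((marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j]))
    den <- den + length(j)
  }
  if (den == 0) stop("no usable pairs")
  num / den
}
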