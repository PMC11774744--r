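#' Assign 5-year prognostic status from survival follow-up
#'
#' A patient whose event occurred within the horizon is `unfavorable`;
#' a patient who reached the horizon event-free (alive at 5 years with
#' follow-up of at least 5 years) is `favorable`; an event-free patient
#' whose follow-up ended before the horizon is `uncertain` and is excluded
#' from classifier training/testing (but kept, censored, in
#' complete-dataset survival analyses).
#'
#' @param cohort a [CohortTable-class].
#' @param horizon horizon in years (default 5).
#' @param endpoint `"OS"` (overall survival) or `"RFS"` (relapse-free
#'   survival); a label only -- `time_years`/`event` must already encode
#'   the chosen endpoint.
#' @return the [CohortTable-class] with a `prognostic_status` column.
#' @export
definePrognosticStatus <- function(cohort, horizon = 5,
                                   endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  stopifnot(is(cohort, "CohortTable"))
  d <- cohortData(cohort)
  if (any(d$time_years < 0)) stop("negative survival time")
  status <- ifelse(d$event == 1 & d$time_years <= horizon, "unfavorable",
                   ifelse(d$time_years >= horizon, "favorable", "uncertain"))
  d$prognostic_status <- status
  CohortTable(d)
}

#' Kaplan-Meier product-limit curves per group
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; censored
#' subjects leave the risk set after their time.
#'
#' @param times survival times (>= 0).
#' @param events event indicators (1 = event).
#' @param groups group labels (a single group is fine).
#' @return data.frame with class `"KaplanMeierCurves"`: columns `group`,
#'   `time`, `nRisk`, `nEvent`, `nCensor`, `surv`.
#' @export
kaplanMeier <- function(times, events, groups = rep("all", length(times))) {
  if (any(times < 0)) stop("negative survival time")
  groups <- as.character(groups)
  if (length(times) != length(events) || length(times) != length(groups))
    stop("times, events and groups must have equal length")
  counts <- table(groups)
  if (any(counts == 0) || length(counts) == 0) stop("empty group")
  out <- do.call(rbind, lapply(names(counts), function(g) {
    sel <- groups == g
    fit <- survival::survfit(
      survival::Surv(times[sel], events[sel]) ~ 1, conf.type = "none")
    data.frame(group = g, time = fit$time, nRisk = fit$n.risk,
               nEvent = fit$n.event, nCensor = fit$n.censor,
               surv = fit$surv, stringsAsFactors = FALSE)
  }))
  class(out) <- c("KaplanMeierCurves", "data.frame")
  out
}

#' Log-rank test across groups
#'
#' Observed vs expected events per group summed over distinct event times
#' with the hypergeometric variance; the statistic is chi-squared with
#' (number of groups - 1) degrees of freedom under the null.
#'
#' @param times survival times.
#' @param events event indicators.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 non-empty groups")
  if (sum(events) == 0) stop("no events observed; log-rank undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood (Efron tie
#' handling by default), reporting hazard ratios with 95% Wald confidence
#' intervals and per-covariate Wald p-values.
#'
#' @param times survival times.
#' @param events event indicators.
#' @param covariates data.frame of numeric or categorical covariates
#'   (categoricals are one-hot encoded by the model formula).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list with class `"CoxResult"`: `table` (data.frame of
#'   `covariate`, `hr`, `ciLow`, `ciHigh`, `p`), `logLik` (maximized log
#'   partial likelihood), `converged`, `monotone` (monotone-likelihood /
#'   infinite-coefficient flag), `ties`.
#' @export
coxPH <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(events) == 0) stop("no events observed")
  constant <- vapply(covariates, function(col)
    length(unique(col[!is.na(col)])) < 2, logical(1))
  if (any(constant))
    stop("singular design: covariate(s) constant across subjects: ",
         paste(names(covariates)[constant], collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  monotone <- FALSE
  nonconv <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|beta may be", msg)) monotone <<- TRUE
      if (grepl("not converge|iterations", msg)) nonconv <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  aliased <- names(beta)[is.na(beta)]  # collinear terms dropped by coxph
  keep <- !is.na(beta)
  beta <- beta[keep]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[keep]
  tab <- data.frame(covariate = names(beta),
                    hr = exp(beta),
                    ciLow = exp(beta - 1.96 * se),
                    ciHigh = exp(beta + 1.96 * se),
                    p = 2 * pnorm(-abs(beta / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, logLik = fit$loglik[2L],
                 converged = !nonconv,
                 singular = length(aliased) > 0, aliased = aliased,
                 monotone = monotone || any(abs(beta) > 15),
                 ties = ties),
            class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties)%s%s\n", x$ties,
              if (x$monotone) " [monotone likelihood flagged]" else "",
              if (isTRUE(x$singular))
                paste0(" [singular: ", paste(x$aliased, collapse = ", "), "]")
              else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Survival evaluation of classifier-predicted groups
#'
#' Kaplan-Meier curves per predicted group, a log-rank test, and a
#' multivariate Cox model of the predicted status together with supplied
#' clinical covariates (forest-plot-ready table). Patients with uncertain
#' 5-year status belong here (censored), unlike in classifier training.
#'
#' @param cohort a [CohortTable-class] covering all labeled patients.
#' @param labels data.frame from [classifySamples()] (columns `sample_id`,
#'   `label`) or a named character vector of
#'   `"favorable"`/`"unfavorable"` labels.
#' @param covariates optional character vector of covariate column names
#'   in `cohort` to adjust for.
#' @return list with class `"SurvivalEvaluation"`: `km`, `logrank`, `cox`
#'   (NULL where skipped), `degenerate` flag, `groupSizes`.
#' @export
evaluatePredictions <- function(cohort, labels, covariates = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  d <- cohortData(cohort)
  if (is.data.frame(labels))
    labels <- setNames(labels$label, labels$sample_id)
  miss <- setdiff(d$sample_id, names(labels))
  if (length(miss))
    stop("labels missing for patients: ", paste(miss, collapse = ", "))
  lab <- unname(labels[d$sample_id])
  km <- kaplanMeier(d$time_years, d$event, lab)
  degenerate <- length(unique(lab)) < 2
  lr <- NULL; cox <- NULL
  if (degenerate) {
    warning("single predicted group; log-rank and Cox analyses skipped")
  } else {
    lr <- logrankTest(d$time_years, d$event, lab)
    covDf <- data.frame(predicted_status = factor(lab,
                          levels = c("favorable", "unfavorable")))
    if (!is.null(covariates)) {
      bad <- setdiff(covariates, names(d))
      if (length(bad))
        stop("covariates not in cohort: ", paste(bad, collapse = ", "))
      covDf <- cbind(covDf, d[covariates])
    }
    cox <- coxPH(d$time_years, d$event, covDf)
  }
  structure(list(km = km, logrank = lr, cox = cox,
                 degenerate = degenerate, groupSizes = table(lab)),
            class = "SurvivalEvaluation")
}

#' @export
print.SurvivalEvaluation <- function(x, ...) {
  cat("Survival evaluation of predicted groups\n")
  print(x$groupSizes)
  if (x$degenerate) {
    cat("degenerate grouping: single predicted group, KM only\n")
  } else {
    cat(sprintf("log-rank: chisq = %.3f (df %d), p = %.3g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
    print(x$cox)
  }
  invisible(x)
}
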