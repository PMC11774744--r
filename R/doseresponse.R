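#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = lower + (upper - lower) / (1 + (x/e)^slope)`
#' to viability fractions measured at positive doses (micromolar).
#' Replicate wells enter as individual points. The sign convention is that
#' `slope > 0` corresponds to viability decreasing with dose. The optimizer
#' is bounded Levenberg-Marquardt least squares with `e` kept positive by
#' fitting on the log scale.
#'
#' @param doses dose vector, micromolar, all positive; at least 5 distinct
#'   values.
#' @param responses viability fractions (same length as `doses`).
#' @param init optional named list/vector with start values `lower`,
#'   `upper`, `slope`, `e`. Defaults: `lower`/`upper` from the response
#'   range, `e` at the dose closest to mid-response, `slope = 1`.
#' @return A [DoseResponseFit-class]. Degenerate data (e.g. constant
#'   responses) yield `converged = FALSE`.
#' @export
fitLogLogistic4 <- function(doses, responses, init = NULL) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  if (any(doses <= 0)) stop("all doses must be positive")
  if (any(!is.finite(responses))) stop("responses must be finite")
  if (length(unique(doses)) < 5)
    stop("need at least 5 distinct doses")
  if (length(doses) < 5)
    stop("need at least as many points as parameters (and >= 5)")

  rng <- range(responses)
  if (diff(rng) < 1e-12) {
    # flat data: the slope is unidentifiable
    return(new("DoseResponseFit", lower = rng[1L], upper = rng[2L],
               slope = 0, e = stats::median(doses),
               rss = sum((responses - mean(responses))^2),
               converged = FALSE))
  }
  mid <- mean(rng)
  start <- list(lower = rng[1L], upper = rng[2L],
                e = doses[which.min(abs(responses - mid))], slope = 1)
  if (!is.null(init)) {
    init <- as.list(init)
    for (nm in intersect(names(init), names(start))) start[[nm]] <- init[[nm]]
  }
  logx <- log(doses)
  residFn <- function(p)
    responses - (p[1L] + (p[2L] - p[1L]) / (1 + exp(p[3L] * (logx - p[4L]))))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(start$lower, start$upper, start$slope, log(start$e)),
      fn = residFn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("DoseResponseFit", lower = rng[1L], upper = rng[2L],
               slope = 0, e = stats::median(doses), rss = Inf,
               converged = FALSE))
  }
  cf <- fit$par
  lower <- cf[1L]; upper <- cf[2L]; slope <- cf[3L]; e <- exp(cf[4L])
  # canonical orientation: upper > lower, slope sign flips accordingly
  if (lower > upper) {
    tmp <- lower; lower <- upper; upper <- tmp; slope <- -slope
  }
  rss <- fit$deviance
  converged <- fit$info %in% 1:3 && abs(slope) > 1e-6 && is.finite(e) &&
    e > 0
  new("DoseResponseFit", lower = lower, upper = upper, slope = slope,
      e = e, rss = rss, converged = converged)
}

#' Evaluate the four-parameter log-logistic model
#'
#' @param x dose vector (micromolar).
#' @param lower,upper,slope,e model parameters (see [fitLogLogistic4()]).
#' @return predicted response at `x`.
#' @export
logLogistic4 <- function(x, lower, upper, slope, e) {
  lower + (upper - lower) / (1 + (x / e)^slope)
}

#' Extract the IC50 from a dose-response fit
#'
#' `scale = "relative"` returns the inflection concentration `e` (the
#' concentration of half-maximal effect between the two asymptotes, the
#' convention of standard dose-response software). `scale = "absolute"`
#' solves `f(x) = 0.5` in closed form,
#' `x = e * ((upper - 0.5) / (0.5 - lower))^(1/slope)`, and errors if 0.5
#' lies outside the open interval (lower, upper) rather than extrapolating.
#'
#' @param fit a converged [DoseResponseFit-class].
#' @param scale `"relative"` (default) or `"absolute"`.
#' @return IC50 concentration in micromolar.
#' @export
ic50 <- function(fit, scale = c("relative", "absolute")) {
  scale <- match.arg(scale)
  stopifnot(is(fit, "DoseResponseFit"))
  if (!fit@converged) stop("IC50 requires a converged fit")
  if (scale == "relative") return(fit@e)
  if (!(fit@lower < 0.5 && 0.5 < fit@upper))
    stop(sprintf(
      "absolute IC50 undefined: 0.5 outside the asymptote range (%.4g, %.4g)",
      fit@lower, fit@upper))
  fit@e * ((fit@upper - 0.5) / (0.5 - fit@lower))^(1 / fit@slope)
}
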