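#' Specification of a synthetic multi-dataset in vitro panel
#'
#' Describes a set of independent in vitro datasets (organoid- or cell
#' line-like panels) sharing a gene universe in which a chosen subset is
#' truly correlated with log-IC50 at a target Spearman rho; all other
#' genes are null. Defaults emulate the screening setting: a few datasets
#' of small to moderate size with log-normally distributed counts.
#'
#' @param nDatasets number of independent datasets (default 3).
#' @param nSamples samples per dataset; scalar or vector of length
#'   `nDatasets` (default 30).
#' @param nGenes size of the gene universe (default 500); planted genes
#'   are counted inside it.
#' @param planted data.frame with columns `gene`, `direction` (`"+"` or
#'   `"-"`) and `rho` (target absolute Spearman correlation with
#'   log-IC50), or NULL for a pure-null panel.
#' @param dispersion per-gene log-scale standard deviation of expression
#'   (default 0.5).
#' @param logMeanRange range of per-gene natural-log mean counts,
#'   default `log(c(50, 5000))`.
#' @param ic50LogMean,ic50LogSd log-IC50 distribution (micromolar;
#'   defaults: median 10 uM, one log-unit spread).
#' @param drug drug label (default `"drugA"`).
#' @param seed integer seed; the panel is a pure function of this spec.
#' @return list with class `"PanelSpec"`.
#' @export
panelSpec <- function(nDatasets = 3, nSamples = 30, nGenes = 500,
                      planted = NULL, dispersion = 0.5,
                      logMeanRange = log(c(50, 5000)),
                      ic50LogMean = log(10), ic50LogSd = 1,
                      drug = "drugA", seed = 1L) {
  nSamples <- rep(as.integer(nSamples), length.out = nDatasets)
  if (is.null(planted))
    planted <- data.frame(gene = character(), direction = character(),
                          rho = numeric())
  stopifnot(all(c("gene", "direction", "rho") %in% names(planted)))
  if (nrow(planted)) {
    if (!all(planted$direction %in% c("+", "-")))
      stop("planted direction must be '+' or '-'")
    if (!all(planted$rho > 0 & planted$rho < 1))
      stop("target |rho| must lie in (0, 1)")
  }
  structure(list(nDatasets = as.integer(nDatasets), nSamples = nSamples,
                 nGenes = as.integer(nGenes), planted = planted,
                 dispersion = dispersion, logMeanRange = logMeanRange,
                 ic50LogMean = ic50LogMean, ic50LogSd = ic50LogSd,
                 drug = drug, seed = as.integer(seed)),
            class = "PanelSpec")
}

#' Simulate a multi-dataset in vitro drug-response panel
#'
#' For each dataset, log-IC50 is drawn per sample and each planted gene is
#' generated from a bivariate Gaussian copula whose latent Pearson
#' correlation \eqn{2 \sin(\pi \rho / 6)} yields the target Spearman rho
#' (the exact closed form for bivariate normals); the sign follows the
#' planted direction. Latent values are mapped monotonically to log-normal
#' counts (rounded), which preserves the rank correlation up to rounding
#' ties. Null genes are independent of IC50, and datasets are mutually
#' independent, so cross-dataset reproducibility reflects the planted
#' signal only.
#'
#' @param spec a [panelSpec()].
#' @return list of `nDatasets` elements, each
#'   `list(expr = ExpressionMatrix (raw counts), response =
#'   DrugResponseTable)`.
#' @export
simulateInvitroPanel <- function(spec) {
  stopifnot(inherits(spec, "PanelSpec"))
  planted <- spec$planted
  if (nrow(planted) && any(planted$rho >= 0.99))
    warning("target |rho| >= 0.99 may be unreachable after count rounding")
  if (nrow(planted) && min(spec$nSamples) < 8 && any(planted$rho > 0.9))
    warning("target |rho| > 0.9 is unreliable at fewer than 8 samples")
  genes <- paste0("G", seq_len(spec$nGenes))
  if (nrow(planted)) {
    if (!all(planted$gene %in% genes))
      stop("planted genes must lie inside the gene universe G1..G<nGenes>")
  }
  withSeed(spec$seed, {
    logMu <- runif(spec$nGenes, spec$logMeanRange[1L], spec$logMeanRange[2L])
    names(logMu) <- genes
    lapply(seq_len(spec$nDatasets), function(d) {
      n <- spec$nSamples[d]
      sampleIdsD <- sprintf("D%d_S%02d", d, seq_len(n))
      logIc50 <- rnorm(n, spec$ic50LogMean, spec$ic50LogSd)
      zy <- as.numeric(scale(logIc50))
      z <- matrix(rnorm(spec$nGenes * n), spec$nGenes, n,
                  dimnames = list(genes, sampleIdsD))
      if (nrow(planted)) {
        r <- 2 * sin(pi * planted$rho / 6) *
          ifelse(planted$direction == "+", 1, -1)
        for (i in seq_len(nrow(planted))) {
          g <- planted$gene[i]
          z[g, ] <- r[i] * zy + sqrt(1 - r[i]^2) * z[g, ]
        }
      }
      counts <- round(exp(logMu + spec$dispersion * z))
      expr <- ExpressionMatrix(counts, normalization = "raw_counts")
      ic50 <- matrix(exp(logIc50), ncol = 1,
                     dimnames = list(sampleIdsD, spec$drug))
      list(expr = expr, response = DrugResponseTable(ic50))
    })
  })
}

#' Specification of a synthetic patient cohort
#'
#' A cohort whose binary 5-year outcome follows a logistic model on a
#' planted gene subset (standardized log-expression), with right-censored
#' survival times generated consistently with the binary outcome: the
#' event time falls inside the horizon if and only if the outcome is
#' unfavorable, and censoring before the horizon creates
#' uncertain-status patients.
#'
#' @param nPatients cohort size (default 160).
#' @param nGenes gene pool size (default 60).
#' @param signatureGenes genes carrying the signal (default `G1..G5`).
#' @param effects log-odds per SD of expression for each signature gene
#'   (default 1.0 each).
#' @param unfavorableFraction target marginal probability of the
#'   unfavorable outcome (default 0.45).
#' @param censoringRate probability that an event-free patient is censored
#'   before the horizon, producing uncertain status (default 0.15).
#' @param horizonYears dichotomization horizon (default 5).
#' @param followupMax administrative end of follow-up in years
#'   (default 12).
#' @param weibullShape shape of the event-time distribution (1 =
#'   exponential, the default).
#' @param seed integer seed.
#' @return list with class `"CohortSpec"`.
#' @export
cohortSpec <- function(nPatients = 160, nGenes = 60,
                       signatureGenes = paste0("G", 1:5),
                       effects = rep(1, 5), unfavorableFraction = 0.45,
                       censoringRate = 0.15, horizonYears = 5,
                       followupMax = 12, weibullShape = 1, seed = 1L) {
  if (length(effects) != length(signatureGenes))
    stop("effects must match signatureGenes")
  if (!all(is.finite(effects))) stop("effects must be finite")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoringRate must lie in [0, 1)")
  if (unfavorableFraction <= 0 || unfavorableFraction >= 1)
    stop("unfavorableFraction must lie in (0, 1)")
  structure(list(nPatients = as.integer(nPatients),
                 nGenes = as.integer(nGenes),
                 signatureGenes = signatureGenes, effects = effects,
                 unfavorableFraction = unfavorableFraction,
                 censoringRate = censoringRate,
                 horizonYears = horizonYears, followupMax = followupMax,
                 weibullShape = weibullShape, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate a patient cohort with a planted prognostic signature
#'
#' Expression is log-normal per gene (returned on the log2 scale, tagged
#' `external_normalized`). The linear predictor is
#' `eta = sum(effects * z(expression))` over the signature genes; the
#' intercept is solved numerically so the mean unfavorable probability
#' hits the target. The binary outcome is primary (it is the classifier
#' target); survival times are drawn conditionally: unfavorable patients
#' get an event time inside the horizon from a Weibull hazard scaled by
#' `exp(eta)`, favorable patients an event or administrative censoring
#' after the horizon, and a `censoringRate` fraction of event-free
#' patients is censored early, producing uncertain status. Clinical
#' covariates `age` and `sex` are generated independent of outcome.
#'
#' @param spec a [cohortSpec()].
#' @return list with `expr` (an [ExpressionMatrix-class]) and `cohort`
#'   (a [CohortTable-class] with `prognostic_status` assigned), plus
#'   `truth` (list with `eta`, `outcome`, `alpha`).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  genes <- paste0("G", seq_len(spec$nGenes))
  if (!all(spec$signatureGenes %in% genes))
    stop("signature genes must lie inside the gene pool G1..G<nGenes>")
  n <- spec$nPatients
  withSeed(spec$seed, {
    ids <- sprintf("P%03d", seq_len(n))
    mu <- runif(spec$nGenes, 4, 10)
    sdg <- runif(spec$nGenes, 0.5, 1.5)
    v <- matrix(rnorm(spec$nGenes * n, mu, sdg), spec$nGenes, n,
                dimnames = list(genes, ids))
    z <- t(scale(t(v)))
    eta <- as.numeric(crossprod(z[spec$signatureGenes, , drop = FALSE],
                                spec$effects))
    f <- function(a) mean(plogis(a + eta)) - spec$unfavorableFraction
    alpha <- uniroot(f, c(-50, 50), tol = 1e-10)$root
    y <- rbinom(n, 1L, plogis(alpha + eta))

    shape <- spec$weibullShape
    h <- spec$horizonYears
    # baseline scaled so the median event time at eta = 0 is the horizon
    rate <- log(2) / h^shape * exp(eta)
    # inverse-CDF draws from the Weibull conditioned inside/after horizon
    u <- runif(n)
    Fh <- 1 - exp(-rate * h^shape)
    timeIn <- (-log(1 - u * Fh) / rate)^(1 / shape)
    timeOut <- (-log((1 - u) * exp(-rate * h^shape)) / rate)^(1 / shape)

    time <- numeric(n); event <- integer(n)
    for (i in seq_len(n)) {
      if (y[i] == 1L) {
        time[i] <- min(timeIn[i], h - 1e-6)
        event[i] <- 1L
      } else if (runif(1) < spec$censoringRate) {
        time[i] <- runif(1, 0.25, h - 0.01)  # early censoring -> uncertain
        event[i] <- 0L
      } else {
        Ti <- timeOut[i]
        Ci <- runif(1, h, spec$followupMax)
        time[i] <- min(Ti, Ci)
        event[i] <- as.integer(Ti <= Ci)
      }
    }
    cohort <- CohortTable(data.frame(
      sample_id = ids, time_years = time, event = event,
      age = round(rnorm(n, 65, 10)), sex = sample(c("F", "M"), n, TRUE),
      stringsAsFactors = FALSE))
    cohort <- definePrognosticStatus(cohort, horizon = h)
    list(expr = ExpressionMatrix(v, normalization = "external_normalized"),
         cohort = cohort,
         truth = list(eta = setNames(eta, ids), outcome = setNames(y, ids),
                      alpha = alpha))
  })
}

#' Simulate a dose-response plate
#'
#' Viability responses from the four-parameter log-logistic model plus
#' i.i.d. Gaussian noise, with `replicates` wells per dose (triplicates by
#' default, matching standard MTS assays).
#'
#' @param lower,upper,slope,e model parameters (see [fitLogLogistic4()]).
#' @param doses dose vector, micromolar.
#' @param sigma noise standard deviation (>= 0).
#' @param replicates wells per dose (default 3).
#' @param seed integer seed.
#' @return data.frame with columns `dose_um`, `viability`.
#' @export
simulateDoseResponse <- function(lower = 0, upper = 1, slope = 1.5, e = 10,
                                 doses = 10^seq(-1, 2.5, length.out = 7),
                                 sigma = 0.05, replicates = 3, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  d <- rep(doses, each = replicates)
  withSeed(seed, {
    resp <- logLogistic4(d, lower, upper, slope, e) +
      rnorm(length(d), 0, sigma)
    data.frame(dose_um = d, viability = resp)
  })
}
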