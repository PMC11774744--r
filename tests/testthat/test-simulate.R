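test_that("generators are pure functions of their specs", {
  spec <- panelSpec(nDatasets = 2, nSamples = 10, nGenes = 30,
                    planted = data.frame(gene = "G1", direction = "+",
                                         rho = 0.7), seed = 5)
  p1 <- simulateInvitroPanel(spec)
  p2 <- simulateInvitroPanel(spec)
  expect_identical(lapply(p1, function(d) exprValues(d$expr)),
                   lapply(p2, function(d) exprValues(d$expr)))
  expect_identical(lapply(p1, function(d) ic50Values(d$response)),
                   lapply(p2, function(d) ic50Values(d$response)))

  cs <- cohortSpec(nPatients = 50, nGenes = 10, seed = 6,
                   signatureGenes = "G1", effects = 1)
  expect_identical(cohortData(simulateCohort(cs)$cohort),
                   cohortData(simulateCohort(cs)$cohort))

  pl <- simulateDoseResponse(seed = 7)
  expect_identical(pl, simulateDoseResponse(seed = 7))
  expect_equal(nrow(pl), 7 * 3)  # triplicate wells per dose
})

test_that("panel generator hits the target Spearman correlation on average", {
  rhos <- vapply(1:200, function(r) {
    pan <- simulateInvitroPanel(panelSpec(
      nDatasets = 1, nSamples = 50, nGenes = 2,
      planted = data.frame(gene = "G1", direction = "+", rho = 0.7),
      seed = 4000 + r))
    v <- exprValues(pan[[1]]$expr)
    cor(v["G1", ], panelIc50(pan[[1]]), method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.7), 0.05)

  # planted direction carries the sign
  pan <- simulateInvitroPanel(panelSpec(
    nDatasets = 1, nSamples = 60, nGenes = 2,
    planted = data.frame(gene = "G1", direction = "-", rho = 0.8),
    seed = 1))
  v <- exprValues(pan[[1]]$expr)
  expect_lt(cor(v["G1", ], panelIc50(pan[[1]]), method = "spearman"), -0.5)

  expect_warning(simulateInvitroPanel(panelSpec(
    nDatasets = 1, nSamples = 10, nGenes = 2,
    planted = data.frame(gene = "G1", direction = "+", rho = 0.995),
    seed = 1)), "unreachable")
})

test_that("generated panels and cohorts satisfy the data-model invariants", {
  pan <- simulateInvitroPanel(panelSpec(nDatasets = 2, nSamples = 8,
                                        nGenes = 20, seed = 2))
  for (d in pan) {
    expect_s4_class(d$expr, "ExpressionMatrix")      # validity ran
    expect_true(all(exprValues(d$expr) >= 0))
    expect_identical(normalization(d$expr), "raw_counts")
    expect_true(all(ic50Values(d$response) > 0))
  }

  sim <- simulateCohort(cohortSpec(nPatients = 120, nGenes = 15,
                                   signatureGenes = paste0("G", 1:3),
                                   effects = rep(1, 3), seed = 3))
  d <- cohortData(sim$cohort)
  expect_true(all(d$event %in% 0:1))
  expect_true(all(d$time_years >= 0))
})

test_that("cohort status labels are self-consistent with the horizon rule", {
  sim <- simulateCohort(cohortSpec(nPatients = 300, seed = 9))
  d <- cohortData(sim$cohort)
  redone <- definePrognosticStatus(CohortTable(
    d[c("sample_id", "time_years", "event")]))
  expect_identical(cohortData(redone)$prognostic_status,
                   d$prognostic_status)
  # binary outcome is primary: unfavorable status == planted outcome 1
  expect_identical(unname(sim$truth$outcome),
                   as.integer(d$prognostic_status == "unfavorable"))
  # unfavorable fraction near its target
  expect_lt(abs(mean(sim$truth$outcome) - 0.45), 0.12)
})

test_that("planted cohort signal is learnable and null cohorts are not", {
  hits <- vapply(1:10, function(r) {
    csTrain <- cohortSpec(nPatients = 400, nGenes = 10,
                          signatureGenes = paste0("G", 1:5),
                          effects = rep(1, 5), seed = 5000 + r)
    sim <- simulateCohort(csTrain)
    out <- outcomeFromStatus(sim$cohort)
    lc <- labeledCohort(sim$expr[, names(out)], out)
    m <- fitLogistic(paste0("G", 1:5), lc)
    # fresh draw from the same process scores the oracle-gene model
    sim2 <- simulateCohort(cohortSpec(nPatients = 400, nGenes = 10,
                                      signatureGenes = paste0("G", 1:5),
                                      effects = rep(1, 5),
                                      seed = 6000 + r))
    out2 <- outcomeFromStatus(sim2$cohort)
    prob <- classifySamples(m, sim2$expr[, names(out2)])$probability
    rocAuc(prob, out2) >= 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  nullAucs <- vapply(1:10, function(r) {
    sim <- simulateCohort(cohortSpec(nPatients = 200, nGenes = 10,
                                     signatureGenes = "G1", effects = 0,
                                     seed = 7000 + r))
    out <- outcomeFromStatus(sim$cohort)
    lc <- labeledCohort(sim$expr[, names(out)], out)
    m <- fitLogistic(paste0("G", 1:5), lc)
    sim2 <- simulateCohort(cohortSpec(nPatients = 200, nGenes = 10,
                                      signatureGenes = "G1", effects = 0,
                                      seed = 8000 + r))
    out2 <- outcomeFromStatus(sim2$cohort)
    rocAuc(classifySamples(m, sim2$expr[, names(out2)])$probability, out2)
  }, numeric(1))
  expect_lt(mean(nullAucs), 0.6)
})

test_that("noise-free plates reproduce the generating parameters exactly", {
  pl <- simulateDoseResponse(lower = 0.1, upper = 0.95, slope = 2, e = 25,
                             sigma = 0, seed = 1)
  f <- fitLogLogistic4(pl$dose_um, pl$viability)
  expect_lt(abs(f@e - 25) / 25, 1e-6)
  expect_lt(abs(f@lower - 0.1), 1e-6)
  expect_error(simulateDoseResponse(sigma = -1), "sigma")
})
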