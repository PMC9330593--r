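test_that("exchangeTimescale converts rates to milliseconds", {
  expect_equal(exchangeTimescale(810), 1.2)
  expect_equal(exchangeTimescale(1060), 0.9)
  expect_equal(exchangeTimescale(1000), 1.0)
  expect_error(exchangeTimescale(0), "positive")
})

test_that("noiseless subglobal fit recovers the generating parameters", {
  tr <- smallTruth(6, kex = 900, pB = 0.05)
  x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0)
  ds <- dispersionSet(x, fallback = 0.3)
  fit <- fitSubglobal(ds, smallCluster(6))
  expect_lt(abs(kex(fit) - 900) / 900, 0.01)
  expect_lt(abs(pB(fit) - 0.05) / 0.05, 0.01)
  expect_lt(max(abs(deltaPpm(fit) - tr@deltaPpm)), 0.02)
  expect_lt(reducedChisq(fit), 0.05)
  ## the pB / delta shallow valley: despite the near-degeneracy at low pB,
  ## exact data pin down the individual parameters
  r20fit <- fit@r20
  expect_lt(max(abs(r20fit$r2_0 - 15)), 0.05)
})

test_that("single-field fits warn and cluster gaps error", {
  tr <- smallTruth(4)
  x <- simulateDispersionDataset(tr, backboneSchedule(700), noiseSigma = 0)
  ds <- dispersionSet(x, fallback = 0.3)
  expect_warning(fitSubglobal(ds, smallCluster(4)), "single-field")
  x2 <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0)
  ds2 <- dispersionSet(x2, fallback = 0.3)
  expect_error(fitSubglobal(ds2, smallCluster(7)), "without data")
  expect_error(fitSubglobal(ds2, new("ClusterSpec", name = "one",
                                     members = 1L, threshold = 1)),
               "at least 2")
})

test_that("incompatible curves inflate the reduced chi-square", {
  ## two residues generated with very different kex, fitted jointly with
  ## tight uncertainties: the shared-parameter model cannot fit both
  d1 <- setNames(2.5, 1)
  d2 <- setNames(2.5, 2)
  a <- simulateDispersionDataset(twoSiteTruth(300, 0.05, d1, seed = 1L),
                                 backboneSchedule(), noiseSigma = 0)
  b <- simulateDispersionDataset(twoSiteTruth(4000, 0.12, d2, seed = 1L),
                                 backboneSchedule(), noiseSigma = 0)
  tab <- rbind(intensityTable(a), intensityTable(b))
  x <- cpmgExperiment(tab, relaxTime = 0.030)
  ds <- dispersionSet(x, fallback = 0.1)
  fit <- fitSubglobal(ds, smallCluster(2))
  expect_gt(reducedChisq(fit), 10)
})

test_that("multi-start never worsens the objective", {
  tr <- smallTruth(4)
  x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.3,
                                 seed = 77L)
  ds <- dispersionSet(x)
  f1 <- fitSubglobal(ds, smallCluster(4), nStarts = 1)
  f3 <- fitSubglobal(ds, smallCluster(4), nStarts = 3)
  expect_lte(f3@chisq, f1@chisq + 1e-6)
})

test_that("Monte Carlo uncertainties shrink with the noise level", {
  tr <- smallTruth(4)
  sigmas <- vapply(c(0.05, 0.4), function(ns) {
    x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = ns,
                                   seed = 88L)
    ds <- dispersionSet(x, sigmaFloor = ns / 10)
    fit <- fitSubglobal(ds, smallCluster(4))
    fit <- monteCarloUncertainty(fit, ds, nDatasets = 25, seed = 99L)
    kexSigma(fit)
  }, numeric(1))
  expect_lt(sigmas[1], sigmas[2] / 3)
  expect_lt(sigmas[1], 10)
})

test_that("Monte Carlo is deterministic and populates all uncertainties", {
  tr <- smallTruth(4)
  x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.3,
                                 seed = 15L)
  ds <- dispersionSet(x)
  fit <- fitSubglobal(ds, smallCluster(4))
  m1 <- monteCarloUncertainty(fit, ds, nDatasets = 15, seed = 7L)
  m2 <- monteCarloUncertainty(fit, ds, nDatasets = 15, seed = 7L)
  expect_identical(kexSigma(m1), kexSigma(m2))
  expect_true(kexSigma(m1) > 0)
  expect_true(pBSigma(m1) > 0)
  expect_true(all(m1@deltaPpmSigma > 0))
  expect_equal(m1@mc$n, 15)
  expect_error(monteCarloUncertainty(fit, ds, nDatasets = 1), ">= 2")
})

test_that("model comparison prefers two processes only when present", {
  ## two distinct generating processes
  dA <- setNames(seq(1, 3, length.out = 4), 1:4)
  dB <- setNames(seq(1, 3, length.out = 4), 5:8)
  a <- simulateDispersionDataset(twoSiteTruth(1060, 0.079, dA, seed = 3L),
                                 backboneSchedule(), noiseSigma = 0.3,
                                 seed = 61L)
  b <- simulateDispersionDataset(twoSiteTruth(810, 0.013, dB, seed = 3L),
                                 backboneSchedule(), noiseSigma = 0.3,
                                 seed = 62L)
  x <- cpmgExperiment(rbind(intensityTable(a), intensityTable(b)), 0.030)
  ds <- dispersionSet(x)
  un <- new("ClusterSpec", name = "all", members = 1:8, threshold = 1)
  two <- list(smallCluster(4),
              new("ClusterSpec", name = "B", members = 5:8, threshold = 1))
  cmp <- compareModels(ds, un, two)
  expect_true(cmp$two_process_preferred)
  expect_gt(cmp$delta_aic, 10)
  expect_gt(cmp$one_process$red_chisq, max(cmp$two_process$red_chisq))

  ## a single generating process: splitting is not supported
  dAll <- setNames(seq(1, 3, length.out = 8), 1:8)
  u <- simulateDispersionDataset(twoSiteTruth(950, 0.05, dAll, seed = 4L),
                                 backboneSchedule(), noiseSigma = 0.3,
                                 seed = 63L)
  dsu <- dispersionSet(u)
  cmp2 <- compareModels(dsu, un, two)
  expect_false(cmp2$two_process_preferred)
  expect_lte(cmp2$delta_aic, 10)

  ## degenerate consistency: the same partition fitted twice gives the
  ## same chi-square both times
  cmp3 <- compareModels(dsu, un, list(un))
  expect_equal(cmp3$one_process$aic - 2 * cmp3$one_process$fit@npar,
               cmp3$two_process$aic - 2 * cmp3$two_process$fits[[1]]@npar,
               tolerance = 1e-6)
})

test_that("unfolding-shift comparison computes the diagnostics", {
  d <- setNames(runif(10, 0.5, 3), 1:10)
  same <- compareToUnfoldingShifts(d, d * 1.0000001)
  expect_equal(same$correlation, 1, tolerance = 1e-6)
  expect_equal(same$fraction_smaller, 1)
  dom <- compareToUnfoldingShifts(d, 2 * d)
  expect_equal(dom$fraction_smaller, 1)
  expect_true(dom$smaller_than_unfolding)
  expect_equal(unname(dom$ratio), rep(0.5, 10), tolerance = 1e-12)
  inv <- compareToUnfoldingShifts(d, d / 2)
  expect_false(inv$smaller_than_unfolding)
  expect_error(compareToUnfoldingShifts(d[1:2], d[1:2]), "3 shared")
  ## independent vectors are uncorrelated on average
  set.seed(11)
  rs <- replicate(100, {
    a <- setNames(runif(26, 0.3, 3.5), 1:26)
    b <- setNames(runif(26, 0.3, 3.5), 1:26)
    compareToUnfoldingShifts(a, b)$correlation
  })
  expect_lt(mean(abs(rs)), 0.2)
})
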