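test_that("computeR2eff follows the log-ratio formula", {
  expect_equal(computeR2eff(100, 100, 0.030), 0)
  expect_equal(computeR2eff(100 * exp(-1), 100, 0.030), 1 / 0.030,
               tolerance = 1e-12)
  expect_equal(computeR2eff(50, 100, 0.060), log(2) / 0.060,
               tolerance = 1e-12)  # 11.552453
  ## round trip: rate -> intensity -> rate
  r <- c(5, 14.7, 33)
  expect_equal(computeR2eff(100 * exp(-r * 0.03), 100, 0.03), r,
               tolerance = 1e-12)
})

test_that("non-positive intensities are flagged, not dropped", {
  expect_warning(r <- computeR2eff(c(50, -2, 0), 100, 0.03),
                 "unquantifiable")
  expect_equal(is.na(r), c(FALSE, TRUE, TRUE))
  expect_error(computeR2eff(50, 0, 0.03), "referenceIntensity")
  expect_error(computeR2eff(50, 100, 0), "relaxTime")
})

test_that("cpmgFrequency reproduces the experiment schedules", {
  expect_equal(round(cpmgFrequency(4, 0.060), 1), 66.7)
  expect_equal(round(cpmgFrequency(1, 0.030), 1), 33.3)
  expect_equal(cpmgFrequency(120, 0.060), 2000.0)
  expect_equal(scheduleFrequencies(backboneSchedule()),
               c(33.3, 66.7, 100.0, 133.3, 166.7, 200.0, 266.7, 333.3,
                 466.7, 600.0, 733.3, 933.3), tolerance = 1e-3)
  expect_equal(scheduleFrequencies(ligandSchedule()),
               c(66.7, 133.3, 266.7, 400.0, 533.3, 666.7, 800.0, 933.3,
                 1066.7, 1200.0, 1333.3, 1466.7, 1600.0, 1733.3, 1866.7,
                 2000.0), tolerance = 1e-3)
  expect_error(cpmgFrequency(0, 0.03), "nCycles")
})

test_that("sigmaFromRepeats pools pair differences with a floor", {
  ## identical repeats -> sigma = floor
  tr <- smallTruth(2)
  x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0)
  s <- sigmaFromRepeats(x, floor = 0.05)
  expect_equal(s$sigma, rep(0.05, 2))
  expect_equal(s$n_pairs, rep(4L, 2))  # 2 repeat frequencies x 2 fields

  ## a single pair differing by d in rate gives sigma = d / sqrt(2):
  ## construct a one-residue, one-field table with one repeated point
  i0 <- 1000
  tt <- 0.030
  rates <- c(10, 10, 12)  # nu 100 Hz twice: d = 2
  tab <- data.frame(residue = 1,
                    field_mhz = 700,
                    nu_cpmg_hz = c(NA, 100, 100, 200),
                    intensity = c(i0, i0 * exp(-c(rates[2], rates[3]) * tt),
                                  i0 * exp(-11 * tt)),
                    is_reference = c(TRUE, FALSE, FALSE, FALSE),
                    replicate_id = c(1, 1, 2, 1))
  x1 <- cpmgExperiment(tab, relaxTime = tt)
  s1 <- sigmaFromRepeats(x1, floor = 0.05)
  expect_equal(s1$sigma, 2 / sqrt(2), tolerance = 1e-10)

  ## no repeats: error unless fallback
  tab2 <- tab[c(1, 2, 4), ]
  x2 <- cpmgExperiment(tab2, relaxTime = tt)
  expect_error(sigmaFromRepeats(x2), "fallback")
  expect_equal(sigmaFromRepeats(x2, fallback = 0.4)$sigma, 0.4)
})

test_that("repeat-based sigma recovers the injected noise level", {
  ## pooled over many residues, sigma-hat approximates the true noise
  delta <- setNames(runif(26, 0.3, 3.5), 1:26)
  tr <- twoSiteTruth(810, 0.013, delta, seed = 33L)
  pooled <- c()
  for (s in 1:6) {
    x <- simulateDispersionDataset(tr, backboneSchedule(),
                                   noiseSigma = 0.3, seed = 500 + s)
    sg <- sigmaFromRepeats(x, floor = 0.01)
    pooled <- c(pooled, sg$sigma^2)
  }
  expect_lt(abs(sqrt(mean(pooled)) - 0.3) / 0.3, 0.15)
})

test_that("recomputed rates carry the injected Gaussian noise", {
  ## noise calibration across > 1000 draws
  tr <- smallTruth(4, kex = 1000, pB = 0.04)
  resid <- c()
  for (s in 1:10) {
    x <- simulateDispersionDataset(tr, backboneSchedule(),
                                   noiseSigma = 0.3, seed = 700 + s)
    rr <- cpmgrd:::.replicateRates(x)
    model <- do.call(rbind, lapply(seq_len(nrow(rr)), function(i) {
      rc <- as.character(rr$residue[i])
      n <- as.integer(round(rr$nu_cpmg_hz[i] * 0.030))
      data.frame(m = modelR2effNumeric(tr@kex, tr@pB, tr@deltaPpm[rc],
                                       tr@r20[rc, as.character(rr$field_mhz[i])],
                                       tr@r20[rc, as.character(rr$field_mhz[i])],
                                       rr$field_mhz[i], "15N", n, 0.030))
    }))
    resid <- c(resid, rr$r2_eff - model$m)
  }
  expect_gt(length(resid), 1000)
  expect_lt(abs(sd(resid) - 0.3) / 0.3, 0.1)
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("dispersionSet averages replicates and attaches sigma", {
  tr <- smallTruth(3)
  x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.2,
                                 seed = 9L)
  ds <- dispersionSet(x)
  expect_s4_class(ds, "DispersionSet")
  expect_equal(residues(ds), 1:3)
  expect_equal(fieldsMhz(ds), c(600, 700))
  r <- rates(ds)
  expect_equal(nrow(r), 3 * 2 * 12)  # replicates collapsed
  expect_true(all(r$sigma > 0))
  cv <- dispersionCurve(ds, 2, 700)
  expect_s4_class(cv, "DispersionCurve")
  expect_equal(length(cv@nuCpmg), 12)
  expect_error(dispersionCurve(ds, 99, 700), "no data")
})
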