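test_that("truth presets carry the fitted central values and memberships", {
  h <- truthPresets("arah8_helix")
  expect_equal(kex(h), 1060)
  expect_equal(pB(h), 0.079)
  expect_equal(length(deltaPpm(h)), 20)
  s <- truthPresets("arah8_sheet")
  expect_equal(kex(s), 810)
  expect_equal(pB(s), 0.013)
  expect_equal(length(deltaPpm(s)), 26)
  expect_true(all(deltaPpm(h) >= 0.3 & deltaPpm(h) <= 3.5))
  expect_error(truthPresets("nope"), "unknown preset")
})

test_that("simulation is deterministic under a fixed seed", {
  tr <- smallTruth(3)
  a <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.3,
                                 seed = 42L)
  b <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.3,
                                 seed = 42L)
  expect_identical(intensityTable(a), intensityTable(b))
  c <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.3,
                                 seed = 43L)
  expect_false(identical(intensityTable(a), intensityTable(c)))
  t1 <- simulateTitrationSeries(0.76, seed = 5L)
  t2 <- simulateTitrationSeries(0.76, seed = 5L)
  expect_identical(t1@shifts, t2@shifts)
  l1 <- simulateLigandDispersion(1600, seed = 6L)
  l2 <- simulateLigandDispersion(1600, seed = 6L)
  expect_identical(l1@rates, l2@rates)
})

test_that("degenerate truths give flat noiseless profiles", {
  tr0 <- twoSiteTruth(1000, 0, setNames(c(2, 1), 1:2), seed = 1L)
  x <- simulateDispersionDataset(tr0, backboneSchedule(), noiseSigma = 0)
  ds <- dispersionSet(x, fallback = 0.3)
  r <- rates(ds)
  for (res in 1:2)
    for (f in c(600, 700)) {
      v <- r$r2_eff[r$residue == res & r$field_mhz == f]
      expect_lt(diff(range(v)), 1e-9)
    }
  ## delta = 0 for one residue only
  tr1 <- twoSiteTruth(1000, 0.05, setNames(c(0, 2), 1:2), seed = 1L)
  x1 <- simulateDispersionDataset(tr1, backboneSchedule(), noiseSigma = 0)
  r1 <- rates(dispersionSet(x1, fallback = 0.3))
  flat <- r1$r2_eff[r1$residue == 1 & r1$field_mhz == 700]
  disp <- r1$r2_eff[r1$residue == 2 & r1$field_mhz == 700]
  expect_lt(diff(range(flat)), 1e-9)
  expect_gt(diff(range(disp)), 1)
})

test_that("simulation rejects invalid inputs", {
  tr <- smallTruth(2)
  expect_error(simulateDispersionDataset(tr, backboneSchedule(),
                                         noiseSigma = -0.1), "noiseSigma")
  expect_error(twoSiteTruth(1000, 0.6, setNames(1, 1)), "pB")
  expect_error(twoSiteTruth(-5, 0.05, setNames(1, 1)), "kex")
  expect_error(simulateLigandDispersion(1600, saturations = c(0, 0.6)),
               "saturation")
  expect_error(simulateLigandDispersion(-1), "koff")
  expect_error(simulateTitrationSeries(-0.5), "kd")
})

test_that("titration limits behave physically", {
  ## effectively no binding: shifts stay at the free-state values
  far <- simulateTitrationSeries(1e9, noisePpm = 0,
                                 dmsoDrift = data.frame(residue = integer(),
                                                        delta_h_ppm = numeric(),
                                                        delta_n_ppm = numeric()))
  expect_lt(max(abs(far@shifts$delta_h_ppm)), 1e-6)
  ## saturating ligand: shifts approach the endpoint values
  ep <- data.frame(residue = 1, delta_h_ppm = 0.2, delta_n_ppm = 1)
  sat <- simulateTitrationSeries(1e-5, ratios = c(1000, 2000),
                                 endpointShifts = ep,
                                 dmsoDrift = data.frame(residue = 1,
                                                        delta_h_ppm = 0,
                                                        delta_n_ppm = 0),
                                 noisePpm = 0)
  expect_equal(max(sat@shifts$delta_h_ppm), 0.2, tolerance = 1e-3)
})

test_that("ligand dispersion amplitude scales with saturation and field", {
  ## noiseless series: amplitude grows monotonically with bound fraction
  ls <- simulateLigandDispersion(1600, saturations = c(0, 0.04, 0.08, 0.12),
                                 noiseSigma = 0)
  amp <- vapply(ls@samples$sample_id, function(id) {
    sub <- ls@rates[ls@rates$sample_id == id, ]
    diff(range(sub$r2_eff))
  }, numeric(1))
  expect_equal(amp[1], 0)
  expect_true(all(diff(amp) > 0))
})

test_that("intensity tables round-trip through CSV with provenance", {
  tr <- smallTruth(3)
  x <- simulateDispersionDataset(tr, backboneSchedule(), noiseSigma = 0.2,
                                 seed = 12L)
  path <- file.path(withr::local_tempdir(), "intens.csv")
  writeIntensityTable(x, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$truth$kex, 900)
  expect_equal(side$seed, 12)
  y <- readPeakTable(path, "tidy_csv", relaxTime = 0.030)
  expect_equal(intensityTable(y), intensityTable(x), tolerance = 1e-12)
})
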