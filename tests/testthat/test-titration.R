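test_that("combined CSP follows the weighted quadratic mean", {
  expect_equal(combinedCsp(0, 0), 0)
  expect_equal(combinedCsp(0.1, 0.5), 0.1)        # both terms 0.01
  expect_equal(combinedCsp(0, 1.0), sqrt(0.04 / 2), tolerance = 1e-12)
  expect_equal(combinedCsp(0, 1.0), 0.1414, tolerance = 1e-3)
  ## always non-negative, invariant to sign
  set.seed(4)
  h <- rnorm(50); n <- rnorm(50)
  expect_true(all(combinedCsp(h, n) >= 0))
  expect_equal(combinedCsp(h, n), combinedCsp(-h, -n))
})

test_that("bound fraction solves the exact 1:1 quadratic", {
  ## independent oracle: root of (P - x)(L - x) / x = KD by bisection
  oracle <- function(p, l, kd)
    uniroot(function(x) (p - x) * (l - x) - kd * x, c(0, min(p, l)),
            tol = 1e-12)$root
  expect_equal(boundFraction(0.24, 2.0, 0.76)$complex,
               oracle(0.24, 2.0, 0.76), tolerance = 1e-9)
  expect_equal(boundFraction(0.24, 2.0, 0.76)$complex, 0.1695865,
               tolerance = 1e-6)
  ## stoichiometric limit
  expect_equal(boundFraction(0.2, 1, 1e-9)$complex, 0.2, tolerance = 1e-6)
  expect_equal(boundFraction(1, 0.2, 1e-9)$complex, 0.2, tolerance = 1e-6)
  ## weak-binding limit: [PL] -> P L / KD
  expect_equal(boundFraction(0.01, 0.02, 1e3)$complex, 0.01 * 0.02 / 1e3,
               tolerance = 1e-4)
  ## zero totals give zero fractions
  expect_equal(boundFraction(0, 1, 0.5)$protein, 0)
  expect_equal(boundFraction(1, 0, 0.5)$ligand, 0)
  expect_error(boundFraction(-1, 1, 0.5), ">= 0")
  expect_error(boundFraction(1, 1, 0), "kd")
})

test_that("bound fraction is symmetric and monotone", {
  p <- runif(20, 0.01, 2); l <- runif(20, 0.01, 2)
  expect_equal(boundFraction(p, l, 0.76)$complex,
               boundFraction(l, p, 0.76)$complex)
  ## increasing in both totals, decreasing in KD
  base <- boundFraction(0.2, 1, 0.76)$complex
  expect_gt(boundFraction(0.3, 1, 0.76)$complex, base)
  expect_gt(boundFraction(0.2, 2, 0.76)$complex, base)
  expect_lt(boundFraction(0.2, 1, 1.5)$complex, base)
})

test_that("DMSO correction is linear in the volume fraction", {
  ep <- data.frame(residue = 1:2, delta_h_ppm = c(0.2, 0.15),
                   delta_n_ppm = c(1, -0.8))
  drift <- data.frame(residue = 1:2, delta_h_ppm = c(0.04, -0.02),
                      delta_n_ppm = c(0.2, 0.1))
  ts <- simulateTitrationSeries(0.76, endpointShifts = ep, dmsoDrift = drift,
                                noisePpm = 0)
  corr <- dmsoCorrect(ts)
  ## at every point the subtracted amount is (vf / max) * reference;
  ## verify against a by-hand correction of the raw shifts
  vf <- ts@points$dmso_fraction / ts@maxDmsoFraction
  raw <- ts@shifts[ts@shifts$residue == 1, ]
  cor1 <- corr@shifts[corr@shifts$residue == 1, ]
  expect_equal(cor1$delta_h_ppm, raw$delta_h_ppm - vf * 0.04,
               tolerance = 1e-12)
  ## zero volume fraction leaves shifts unchanged (apo-most point has the
  ## smallest fraction; scale comes out proportional)
  expect_true(all(corr@shifts$dmso_corrected))
  ## after correction the drift is exactly removed: shifts equal
  ## boundFraction * endpoint
  fb <- boundFraction(ts@points$protein_mM, ts@points$ligand_mM, 0.76)$protein
  expect_equal(cor1$delta_h_ppm, fb * 0.2, tolerance = 1e-10)
  ## residues without a reference are flagged
  corr2 <- suppressWarnings(dmsoCorrect(ts, reference = drift[1, ]))
  expect_false(all(corr2@shifts$dmso_corrected[corr2@shifts$residue == 2]))
})

test_that("noiseless titrations return the generating KD exactly", {
  ts <- simulateTitrationSeries(0.76, noisePpm = 0)
  fit <- fitKd(ts)
  per <- perResidueKd(fit)
  expect_equal(per$kd_mM[per$qualifies], rep(0.76, sum(per$qualifies)),
               tolerance = 1e-4)
  expect_equal(meanKd(fit), 0.76, tolerance = 1e-5)
  ## residues below the threshold are excluded from the mean
  expect_true(all(per$max_csp_ppm[per$residue %in% fit@residuesUsed] > 0.1))
  weak <- per$residue[per$max_csp_ppm <= 0.1]
  expect_false(any(weak %in% fit@residuesUsed))
})

test_that("noisy titrations recover KD within 10 percent", {
  ts <- simulateTitrationSeries(0.76, noisePpm = 0.005, seed = 71L)
  fit <- fitKd(ts)
  expect_lt(abs(meanKd(fit) - 0.76) / 0.76, 0.1)
  expect_true(sdKd(fit) > 0)
  expect_true(all(perResidueKd(fit)$kd_sigma_mM[perResidueKd(fit)$qualifies] > 0,
                  na.rm = TRUE))
})

test_that("titration sanity checks fire", {
  ts <- simulateTitrationSeries(0.76, noisePpm = 0)
  short <- new("TitrationSeries", points = ts@points[1:4, ],
               shifts = ts@shifts[ts@shifts$point_index <= 4, ],
               dmsoReference = ts@dmsoReference,
               maxDmsoFraction = ts@maxDmsoFraction)
  expect_error(fitKd(short), "5 titration points")
  ## all residues below threshold
  ep <- data.frame(residue = 1, delta_h_ppm = 0.01, delta_n_ppm = 0.05)
  tiny <- simulateTitrationSeries(0.76, endpointShifts = ep, noisePpm = 0)
  expect_error(fitKd(tiny), "threshold")
})

test_that("dilution tracking matches the stated titration protocol", {
  ts <- simulateTitrationSeries(0.76, noisePpm = 0)
  p <- ts@points
  ## 17 points, ratios 0.5 .. 30
  expect_equal(nrow(p), 17)
  expect_equal(range(p$ratio), c(0.5, 30))
  ## at ratio 30: 30 * 0.2 * 450 / 90 = 30 uL added
  expect_equal(max(p$dmso_fraction), 30 / 480, tolerance = 1e-12)
  expect_equal(p$protein_mM[p$ratio == 30], 0.2 * 450 / 480,
               tolerance = 1e-12)
  expect_equal(p$ligand_mM, p$ratio * p$protein_mM, tolerance = 1e-12)
})
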