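mkProfile <- function(amps, missing = NULL, protein = "p") {
  df <- data.frame(residue = seq_along(amps), field_mhz = 700,
                   delta_r2_eff = amps, sigma = 0.3, kex = NA, pB = NA,
                   delta_ppm = NA, r2_0 = 15, red_chisq = 1,
                   converged = TRUE)
  df <- df[!is.na(amps), ]
  flexibilityProfile(df, sequenceLength = length(amps), missing = missing,
                     protein = protein)
}

test_that("protein summaries use evaluable residues as denominator", {
  allFlat <- mkProfile(rep(0, 10))
  s <- summarizeProtein(allFlat)
  expect_equal(s$pct_nonflat, 0)
  expect_equal(s$pct_bins[["<1"]], 100)

  set.seed(5)
  amps <- c(runif(69, 1.5, 15), runif(31, 0, 0.8))[sample(100)]
  s2 <- summarizeProtein(mkProfile(amps))
  expect_equal(s2$pct_nonflat, 69.0)
  expect_equal(sum(s2$pct_bins), 100, tolerance = 0.2)

  ## 2 missing + 8 evaluable of which 4 above 1/s: denominator is 8
  amps3 <- c(NA, NA, 3, 4, 5, 6, 0.2, 0.3, 0.4, 0.5)
  s3 <- summarizeProtein(mkProfile(amps3,
                                   missing = data.frame(residue = 1:2,
                                                        reason = "overlap")))
  expect_equal(s3$n_evaluable, 8)
  expect_equal(s3$pct_nonflat, 50.0)
  expect_equal(s3$n_missing, 2)
})

test_that("assignment completeness reports one-decimal percentages", {
  expect_equal(assignmentCompleteness(144, 146), 98.6)
  expect_equal(assignmentCompleteness(10, 10), 100)
  expect_error(assignmentCompleteness(5, 0), "positive")
  expect_error(assignmentCompleteness(7, 5), "exceeds")
})

test_that("heat-map matrices align profiles and mark gaps", {
  p1 <- mkProfile(c(1, 2, 3, NA, 5), protein = "A")
  hm1 <- heatmapMatrix(list(A = p1))
  expect_equal(dim(hm1$amplitude), c(1, 5))
  expect_equal(as.numeric(hm1$amplitude[1, c(1:3, 5)]), c(1, 2, 3, 5))
  expect_equal(hm1$reason[1, 4], "unassigned")

  ## two proteins, the second mapped with a one-residue gap
  p2 <- mkProfile(c(10, 11, 12, 13), protein = "B")
  map <- rbind(data.frame(protein = "A", residue = 1:5, position = 1:5),
               data.frame(protein = "B", residue = 1:4,
                          position = c(1, 2, 4, 5)))
  hm2 <- heatmapMatrix(list(A = p1, B = p2), residueMap = map)
  expect_equal(dim(hm2$amplitude), c(2, 5))
  expect_equal(hm2$reason[2, 3], "gap")
  expect_true(is.na(hm2$amplitude[2, 3]))
  badMap <- rbind(map, data.frame(protein = "B", residue = 9, position = 5))
  expect_error(heatmapMatrix(list(A = p1, B = p2), residueMap = badMap),
               "duplicate")

  ## a 13-protein synthetic panel has the full matrix shape
  set.seed(6)
  panel <- lapply(1:13, function(i)
    mkProfile(runif(150, 0, 12), protein = paste0("P", i)))
  names(panel) <- paste0("P", 1:13)
  hm3 <- heatmapMatrix(panel)
  expect_equal(dim(hm3$amplitude), c(13, 150))
})

test_that("heat-map CSV round trip is bit-exact", {
  set.seed(7)
  amps <- runif(40, 0, 17)
  amps[c(5, 19)] <- NA
  prof <- mkProfile(amps, missing = data.frame(residue = c(5, 19),
                                               reason = c("proline", "overlap")))
  hm <- heatmapMatrix(list(p = prof))
  path <- file.path(withr::local_tempdir(), "hm.csv")
  writeHeatmapCsv(hm, path)
  back <- readHeatmapCsv(path)
  expect_identical(back$amplitude[1, ], hm$amplitude[1, ])
  expect_identical(back$reason[1, ], hm$reason[1, ])
})

test_that("site enrichment contrasts site and background percentages", {
  set.seed(8)
  amps <- c(runif(15, 6, 20), runif(85, 0, 4))  # site residues 1:15 enriched
  prof <- mkProfile(amps)
  enr <- siteEnrichment(prof, siteResidues = 1:15, thresholds = c(5, 10))
  expect_equal(nrow(enr), 2)
  expect_true(all(enr$site_pct > enr$other_pct))
  ## site = all residues: site percentage equals the overall percentage
  s <- summarizeProtein(prof)
  enrAll <- siteEnrichment(prof, siteResidues = 1:100, thresholds = 1)
  expect_equal(enrAll$site_pct, s$pct_nonflat)
  expect_equal(enrAll$other_n, 0)
  expect_error(siteEnrichment(prof, integer()), "empty")
  ## percentages are permutation-invariant
  perm <- sample(100)
  profP <- mkProfile(amps[perm])
  expect_equal(summarizeProtein(profP)$pct_nonflat, s$pct_nonflat)
})
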