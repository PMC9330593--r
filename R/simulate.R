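#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from a single master seed; stage
#' seeds are derived as `(seed * 7919 + offset) mod (2^31 - 1)` with a
#' fixed, documented offset per stage, keeping every derived seed a valid
#' 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (integer).
#' @return derived integer seed.
#' @export
deriveSeed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}

#' Construct ground-truth exchange parameters
#'
#' @param kex exchange rate constant (1/s).
#' @param pB minor-state population (0 to 0.5).
#' @param deltaPpm named numeric of per-residue |shift differences| (ppm);
#'   names are residue numbers.
#' @param r20 matrix of intrinsic rates (rows = residues, columns = fields
#'   in MHz), or a single number recycled to all residues and fields.
#' @param fields fields in MHz (used when `r20` is scalar).
#' @param nucleus observed nucleus.
#' @param seed integer seed attached to the truth.
#' @return a [TwoSiteTruth-class].
#' @export
twoSiteTruth <- function(kex, pB, deltaPpm, r20 = 15, fields = c(600, 700),
                         nucleus = "15N", seed = 1L) {
  if (is.null(names(deltaPpm)))
    stop("deltaPpm must be named by residue number")
  if (!is.matrix(r20)) {
    r20 <- matrix(r20, nrow = length(deltaPpm), ncol = length(fields),
                  dimnames = list(names(deltaPpm), as.character(fields)))
  }
  new("TwoSiteTruth", kex = as.numeric(kex), pB = as.numeric(pB),
      deltaPpm = deltaPpm, r20 = r20, nucleus = nucleus,
      seed = as.integer(seed))
}

#' Ground-truth presets for the Ara h 8.0101 subglobal clusters
#'
#' Returns the fitted central values of the two subglobal exchange
#' processes in Ara h 8.0101 as simulation ground truth: the three-helix
#' cluster (`"arah8_helix"`: kex = 1060 /s, pB = 0.079, 20 residues) and
#' the beta-sheet/loop cluster (`"arah8_sheet"`: kex = 810 /s, pB = 0.013,
#' 26 residues). Per-residue shift differences are drawn uniformly from
#' `deltaRange` (default 0.3-3.5 ppm) and intrinsic rates from `r20Range`,
#' deterministically from `seed`, unless supplied explicitly.
#'
#' @param name `"arah8_helix"` or `"arah8_sheet"`.
#' @param deltaPpm optional named per-residue shift differences overriding
#'   the random draw.
#' @param deltaRange range (ppm) for the per-residue draw.
#' @param r20Range range (1/s) for intrinsic-rate draws.
#' @param fields fields in MHz.
#' @param seed RNG seed for the draws.
#' @return a [TwoSiteTruth-class].
#' @examples
#' truthPresets("arah8_helix")
#' @export
truthPresets <- function(name, deltaPpm = NULL, deltaRange = c(0.3, 3.5),
                         r20Range = c(12, 18), fields = c(600, 700),
                         seed = 2002L) {
  par <- switch(name,
    arah8_helix = list(kex = 1060, pB = 0.079,
                       residues = .ARAH8_HELIX_RESIDUES),
    arah8_sheet = list(kex = 810, pB = 0.013,
                       residues = .ARAH8_SHEET_RESIDUES),
    stop("unknown preset name: ", name,
         " (expected 'arah8_helix' or 'arah8_sheet')"))
  nres <- length(par$residues)
  withr::with_seed(seed, {
    if (is.null(deltaPpm)) {
      deltaPpm <- setNames(runif(nres, deltaRange[1], deltaRange[2]),
                           par$residues)
    }
    r20 <- matrix(runif(nres * length(fields), r20Range[1], r20Range[2]),
                  nrow = nres,
                  dimnames = list(names(deltaPpm), as.character(fields)))
  })
  twoSiteTruth(par$kex, par$pB, deltaPpm, r20, fields = fields,
               nucleus = "15N", seed = seed)
}

#' Ara h 8.0101 subglobal cluster definitions
#'
#' The packaged residue membership of the two subglobal fits: 26
#' beta-strand/loop residues and 20 alpha-helix residues, selected by
#' dispersion amplitudes above 1/s at 700 MHz.
#'
#' @return named list of two [ClusterSpec-class] objects (`sheet`, `helix`).
#' @export
araH8Clusters <- function() {
  list(sheet = new("ClusterSpec", name = "arah8_sheet",
                   members = .ARAH8_SHEET_RESIDUES, threshold = 1),
       helix = new("ClusterSpec", name = "arah8_helix",
                   members = .ARAH8_HELIX_RESIDUES, threshold = 1))
}

#' Simulate a CPMG intensity dataset from two-site exchange truth
#'
#' Model rates come from the numerical Bloch-McConnell propagator
#' ([modelR2effNumeric()]); noise of standard deviation `noiseSigma` is
#' added on the rate scale (equivalently, multiplicative log-normal noise on
#' intensities), so recomputing rates from the returned intensities yields
#' `R2eff_model + N(0, noiseSigma^2)`. Repeat points in the schedule receive
#' independent noise. Reference intensities are noise-free by construction
#' (rate noise absorbs the reference uncertainty).
#'
#' @param truth a [TwoSiteTruth-class].
#' @param schedule a [CpmgSchedule-class]; its fields must match the columns
#'   of `truth@r20`.
#' @param noiseSigma rate noise in 1/s (>= 0).
#' @param seed RNG seed; defaults to the truth's seed.
#' @param baseIntensity reference-intensity scale (arbitrary units).
#' @param missing optional data.frame (`residue`, `reason`) of positions to
#'   leave unmeasured.
#' @return a [CpmgExperiment-class] with the truth stored in `metadata()`.
#' @export
simulateDispersionDataset <- function(truth, schedule, noiseSigma = 0.3,
                                      seed = NULL, baseIntensity = 1e5,
                                      missing = NULL) {
  stopifnot(is(truth, "TwoSiteTruth"), is(schedule, "CpmgSchedule"))
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (!all(as.character(schedule@fields) %in% colnames(truth@r20)))
    stop("schedule fields not covered by truth r2_0 matrix")
  if (is.null(seed)) seed <- truth@seed
  res <- residues(truth)
  if (!is.null(missing)) res <- setdiff(res, as.integer(missing$residue))
  tt <- schedule@relaxTime
  nu <- scheduleFrequencies(schedule)

  rows <- withr::with_seed(seed, {
    out <- vector("list", length(res) * length(schedule@fields))
    k <- 0L
    for (r in res) {
      rc <- as.character(r)
      i0 <- baseIntensity * runif(1, 0.5, 1.5)
      for (f in schedule@fields) {
        rModel <- modelR2effNumeric(truth@kex, truth@pB, truth@deltaPpm[rc],
                                    truth@r20[rc, as.character(f)],
                                    truth@r20[rc, as.character(f)],
                                    f, truth@nucleus, schedule@nCycles, tt)
        rep1 <- rModel + rnorm(length(rModel), 0, noiseSigma)
        isRep <- schedule@nCycles %in% schedule@repeats
        rep2 <- rModel[isRep] + rnorm(sum(isRep), 0, noiseSigma)
        k <- k + 1L
        out[[k]] <- data.frame(
          residue = r, field_mhz = f,
          nu_cpmg_hz = c(NA, nu, nu[isRep]),
          intensity = c(i0, i0 * exp(-c(rep1, rep2) * tt)),
          is_reference = c(TRUE, rep(FALSE, length(rep1) + length(rep2))),
          replicate_id = c(1L, rep(1L, length(rep1)),
                           rep(2L, length(rep2))))
      }
    }
    do.call(rbind, out)
  })
  cpmgExperiment(rows, relaxTime = tt, nucleus = truth@nucleus,
                 truth = truth, seed = as.integer(seed), missing = missing)
}

#' Simulate a fast-exchange chemical-shift titration
#'
#' Peak-position changes follow population-weighted averaging between the
#' free and bound states: each residue moves by `boundFraction * endpoint`
#' plus a linear co-solvent drift and Gaussian noise. Sample composition
#' tracks the stepwise addition of ligand from a concentrated co-solvent
#' stock, including dilution.
#'
#' @param kd dissociation constant (mM).
#' @param proteinConc starting protein concentration (mM).
#' @param ratios ligand:protein molar ratios of the titration points
#'   (increasing); the default is the 17-point series 0.5, 1, 2, ..., 30.
#' @param endpointShifts data.frame (`residue`, `delta_h_ppm`,
#'   `delta_n_ppm`): bound-minus-free shift changes. `NULL` draws a default
#'   panel of 12 binding-site and 8 remote residues.
#' @param dmsoDrift data.frame (`residue`, `delta_h_ppm`, `delta_n_ppm`):
#'   drift at the maximum co-solvent fraction. `NULL` draws small defaults.
#' @param noisePpm 1H shift noise sd in ppm (15N noise is 5x larger,
#'   mirroring the relative shift scales).
#' @param startVolumeUl starting sample volume (µL).
#' @param stockConc ligand stock concentration (mM).
#' @param seed RNG seed.
#' @return a [TitrationSeries-class].
#' @export
simulateTitrationSeries <- function(kd, proteinConc = 0.2,
                                    ratios = c(0.5, 1, 2, 4, 6, 8, 10, 12, 14,
                                               16, 18, 20, 22, 24, 26, 28, 30),
                                    endpointShifts = NULL, dmsoDrift = NULL,
                                    noisePpm = 0.005, startVolumeUl = 450,
                                    stockConc = 90, seed = 3003L) {
  if (kd <= 0) stop("kd must be positive")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (proteinConc < 0 || stockConc <= 0) stop("negative concentrations")
  ratios <- sort(ratios)

  ## composition with dilution by titrant addition
  vAdd <- ratios * proteinConc * startVolumeUl / stockConc
  vTot <- startVolumeUl + vAdd
  protein <- proteinConc * startVolumeUl / vTot
  ligand <- ratios * protein
  dmsoFrac <- vAdd / vTot
  maxDmso <- max(dmsoFrac)
  points <- data.frame(point_index = seq_along(ratios), ratio = ratios,
                       protein_mM = protein, ligand_mM = ligand,
                       dmso_fraction = dmsoFrac)

  withr::with_seed(seed, {
    if (is.null(endpointShifts)) {
      strong <- 12L; weak <- 8L
      resid <- sort(sample(5:150, strong + weak))
      sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
      endpointShifts <- data.frame(
        residue = resid,
        delta_h_ppm = c(runif(strong, 0.10, 0.35) * sgn(strong),
                        runif(weak, 0.005, 0.04) * sgn(weak)),
        delta_n_ppm = c(runif(strong, 0.5, 2.5) * sgn(strong),
                        runif(weak, 0.02, 0.2) * sgn(weak)))
    }
    if (is.null(dmsoDrift)) {
      n <- nrow(endpointShifts)
      dmsoDrift <- data.frame(residue = endpointShifts$residue,
                              delta_h_ppm = runif(n, -0.02, 0.02),
                              delta_n_ppm = runif(n, -0.1, 0.1))
    }
    fb <- boundFraction(protein, ligand, kd)$protein
    shifts <- do.call(rbind, lapply(seq_len(nrow(endpointShifts)), function(i) {
      drift <- dmsoDrift[dmsoDrift$residue == endpointShifts$residue[i], ]
      driftH <- if (nrow(drift)) drift$delta_h_ppm[1] else 0
      driftN <- if (nrow(drift)) drift$delta_n_ppm[1] else 0
      dh <- fb * endpointShifts$delta_h_ppm[i] +
        (dmsoFrac / maxDmso) * driftH +
        rnorm(length(fb), 0, noisePpm)
      dn <- fb * endpointShifts$delta_n_ppm[i] +
        (dmsoFrac / maxDmso) * driftN +
        rnorm(length(fb), 0, 5 * noisePpm)
      data.frame(residue = endpointShifts$residue[i],
                 point_index = points$point_index,
                 delta_h_ppm = dh, delta_n_ppm = dn)
    }))
  })
  new("TitrationSeries", points = points, shifts = shifts,
      dmsoReference = dmsoDrift, maxDmsoFraction = maxDmso)
}

#' Simulate a ligand-observed 1H dispersion series
#'
#' The ligand is a two-site free/bound exchanger with bound population equal
#' to the saturation level and back-rate `koff` (so the per-sample total
#' exchange rate is `koff / (1 - saturation)`). Dispersion curves come from
#' the numerical Bloch-McConnell propagator on 1H with distinct free and
#' bound intrinsic rates, plus Gaussian rate noise.
#'
#' @param koff ligand release rate (1/s).
#' @param saturations bound fractions per sample, each in [0, 0.5); must
#'   include 0 (the protein-free control).
#' @param deltaOmegaH free/bound 1H shift difference (ppm).
#' @param r2Free,r2Bound intrinsic 1H rates of the free and bound ligand
#'   (1/s).
#' @param schedule a [CpmgSchedule-class] (default [ligandSchedule()]).
#' @param noiseSigma rate noise sd (1/s).
#' @param ligandConc ligand concentration (mM), used to back-compute the
#'   protein concentrations under the stoichiometric convention.
#' @param proton proton label.
#' @param seed RNG seed.
#' @return a [LigandRDSeries-class].
#' @export
simulateLigandDispersion <- function(koff,
                                     saturations = seq(0, 0.12, by = 0.02),
                                     deltaOmegaH = 0.15, r2Free = 1.5,
                                     r2Bound = 20,
                                     schedule = ligandSchedule(),
                                     noiseSigma = 0.3, ligandConc = 2,
                                     proton = "H6", seed = 4004L) {
  if (koff <= 0) stop("koff must be positive")
  if (any(saturations < 0 | saturations >= 0.5))
    stop("saturation must lie in [0, 0.5) (two-site minor-state assumption)")
  field <- schedule@fields[1]
  nu <- scheduleFrequencies(schedule)
  samples <- data.frame(sample_id = seq_along(saturations),
                        protein_uM = saturations * ligandConc * 1000,
                        ligand_mM = ligandConc, saturation = saturations)
  rates <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_along(saturations), function(i) {
      p <- saturations[i]
      r <- if (p == 0) rep(r2Free, length(nu))
           else modelR2effNumeric(koff / (1 - p), p, deltaOmegaH, r2Free,
                                  r2Bound, field, "1H", schedule@nCycles,
                                  schedule@relaxTime)
      data.frame(sample_id = i, nu_cpmg_hz = nu,
                 r2_eff = r + rnorm(length(nu), 0, noiseSigma),
                 sigma = max(noiseSigma, 0.05))
    }))
  })
  new("LigandRDSeries", samples = samples, rates = rates, proton = proton,
      relaxTime = schedule@relaxTime, filterTime = 0.060,
      fieldMhz = field)
}
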