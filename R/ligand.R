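#' Residence time from an off-rate
#'
#' @param koff ligand release rate in 1/s.
#' @return residence time `1000 / koff` in milliseconds, to one decimal.
#' @examples
#' residenceTime(1600) # 0.6 ms
#' residenceTime(1300) # 0.8 ms
#' @export
residenceTime <- function(koff) {
  if (any(koff <= 0)) stop("koff must be positive")
  round(1000 / koff, 1)
}

#' Ligand saturation levels from sample compositions
#'
#' The bound fraction of the ligand at each protein concentration, either
#' by the stoichiometric convention (`P_total / L_total`, appropriate when
#' essentially all protein is complexed) or from the exact 1:1 binding
#' equilibrium at a given KD.
#'
#' @param proteinUm protein concentrations in µM (vectorized).
#' @param ligandMm ligand concentration in mM.
#' @param mode `"stoichiometric"` (default) or `"kd_based"`.
#' @param kd dissociation constant in mM (required for `"kd_based"`).
#' @return saturation fractions.
#' @examples
#' saturationLevels(240, 2) # 0.12
#' @export
saturationLevels <- function(proteinUm, ligandMm,
                             mode = c("stoichiometric", "kd_based"),
                             kd = NULL) {
  mode <- match.arg(mode)
  if (any(proteinUm < 0)) stop("protein concentrations must be >= 0")
  if (ligandMm <= 0) stop("ligand concentration must be positive")
  if (mode == "stoichiometric") {
    proteinUm / 1000 / ligandMm
  } else {
    if (is.null(kd)) stop("kd is required for kd_based mode")
    boundFraction(proteinUm / 1000, ligandMm, kd)$ligand
  }
}

## residuals of the global two-site ligand model; parameters on
## transformed scales to keep them in range
.ligandResiduals <- function(par, series) {
  koff <- exp(par[1])
  dw <- par[2]
  r2f <- par[3]
  dr2 <- exp(par[4])  # r2Bound - r2Free, positive
  unlist(lapply(seq_len(nrow(series@samples)), function(i) {
    sub <- series@rates[series@rates$sample_id ==
                        series@samples$sample_id[i], ]
    p <- series@samples$saturation[i]
    model <- if (p == 0) rep(r2f, nrow(sub)) else {
      n <- as.integer(round(sub$nu_cpmg_hz * series@relaxTime))
      .r2effExact(koff / (1 - p), p,
                  ppmToRadPerSec(abs(dw), series@fieldMhz, "1H"),
                  r2f, r2f + dr2, n, series@relaxTime)
    }
    (sub$r2_eff - model) / sub$sigma
  }))
}

#' Global off-rate fit for a ligand-observed dispersion series
#'
#' Fits all saturation levels of one ligand proton simultaneously to a
#' two-site free/bound exchange model sharing the off-rate, the free/bound
#' shift difference and the two intrinsic rates; the bound population of
#' each sample is fixed at its saturation level, so the per-sample exchange
#' rate is `koff / (1 - saturation)` and the forward rate
#' `koff * p / (1 - p)`. The zero-protein control contributes only to the
#' free intrinsic rate. Multi-start Levenberg-Marquardt; uncertainties by
#' parametric bootstrap as in the cluster fits.
#'
#' @param series a [LigandRDSeries-class] with at least 3 nonzero
#'   saturations plus the zero-protein control.
#' @param koffStarts,dwStarts multi-start grids for the off-rate (1/s) and
#'   shift difference (ppm).
#' @param nBoot Monte Carlo datasets for the uncertainty (default 100; 0
#'   skips it).
#' @param seed RNG seed for the bootstrap.
#' @return a [LigandKineticsFit-class].
#' @export
fitKoff <- function(series, koffStarts = c(400, 800, 1600, 3200),
                    dwStarts = c(0.05, 0.15, 0.4), nBoot = 100,
                    seed = 6006L) {
  stopifnot(is(series, "LigandRDSeries"))
  sat <- series@samples$saturation
  if (sum(sat > 0) < 3)
    stop("need at least 3 nonzero saturation levels")
  ## exchange information check: some sample must show real dispersion.
  ## Statistic: low-frequency-half mean minus high-frequency-half mean,
  ## compared with its own noise level.
  disp <- vapply(series@samples$sample_id, function(id) {
    sub <- series@rates[series@rates$sample_id == id, ]
    sub <- sub[order(sub$nu_cpmg_hz), ]
    h <- nrow(sub) %/% 2
    d <- mean(sub$r2_eff[seq_len(h)]) - mean(sub$r2_eff[(h + 1):nrow(sub)])
    d / (median(sub$sigma) * sqrt(2 / h))
  }, numeric(1))
  if (all(disp < 4))
    stop("insufficient dispersion: all profiles are flat within noise")
  r2fGuess <- {
    ctrl <- series@rates[series@rates$sample_id ==
      series@samples$sample_id[sat == 0][1], ]
    mean(ctrl$r2_eff)
  }
  starts <- expand.grid(koff = koffStarts, dw = dwStarts)
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(minpack.lm::nls.lm(
      par = c(log(starts$koff[i]), starts$dw[i], r2fGuess, log(10)),
      fn = .ligandResiduals, series = series,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no start converged")
  dev <- vapply(fits[ok], `[[`, numeric(1), "deviance")
  best <- fits[ok][[which.min(dev)]]
  par <- best$par
  nobs <- nrow(series@rates)
  npar <- 4L

  koffSig <- NA_real_
  mc <- list()
  if (nBoot >= 2) {
    ## parametric bootstrap: resimulate rates from the fitted model
    modelRates <- series@rates$r2_eff -
      .ligandResiduals(par, series) * series@rates$sigma
    kDraws <- withr::with_seed(seed, {
      vapply(seq_len(nBoot), function(b) {
        sb <- series
        sb@rates$r2_eff <- modelRates +
          rnorm(nobs, 0, series@rates$sigma)
        fb <- tryCatch(minpack.lm::nls.lm(
          par = par, fn = .ligandResiduals, series = sb,
          control = minpack.lm::nls.lm.control(maxiter = 120)),
          error = function(e) NULL)
        if (is.null(fb)) NA_real_ else exp(fb$par[1])
      }, numeric(1))
    })
    nFail <- sum(is.na(kDraws))
    if (nFail > 0.2 * nBoot)
      warning(nFail, " of ", nBoot, " bootstrap refits failed")
    koffSig <- sd(kDraws, na.rm = TRUE)
    mc <- list(n = nBoot, n_failed = nFail, seed = seed,
               koff_draws = kDraws[!is.na(kDraws)])
  }
  new("LigandKineticsFit", koff = exp(par[1]), koffSigma = koffSig,
      deltaOmegaPpm = abs(par[2]), r2Free = par[3],
      r2Bound = par[3] + exp(par[4]), chisq = best$deviance,
      nobs = as.integer(nobs), npar = npar, saturations = sat,
      convergence = list(n_starts = nrow(starts), n_ok = sum(ok),
                         deviances = dev),
      mc = mc)
}
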