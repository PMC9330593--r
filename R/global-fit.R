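#' Exchange timescale from a rate constant
#'
#' @param kex exchange rate constant in 1/s.
#' @return timescale `1000 / kex` in milliseconds, to one decimal.
#' @examples
#' exchangeTimescale(810)  # 1.2 ms
#' exchangeTimescale(1060) # 0.9 ms
#' @export
exchangeTimescale <- function(kex) {
  if (any(kex <= 0)) stop("kex must be positive")
  round(1000 / kex, 1)
}

## assemble per-field matrices for a cluster fit; curves must share the
## CPMG frequency grid within a field (the common grid is used, residues
## missing any common point are an error)
.clusterData <- function(set, cluster) {
  stopifnot(is(set, "DispersionSet"), is(cluster, "ClusterSpec"))
  r <- set@rates
  members <- sort(cluster@members)
  absent <- setdiff(members, unique(r$residue))
  if (length(absent))
    stop("cluster members without data: ", paste(absent, collapse = ", "))
  fields <- sort(unique(r$field_mhz))
  if (length(fields) < 2)
    warning("single-field data: exchange parameters are weakly constrained")
  lapply(fields, function(f) {
    sub <- r[r$field_mhz == f & r$residue %in% members, ]
    nuCommon <- sort(unique(sub$nu_cpmg_hz))
    nuCommon <- nuCommon[vapply(nuCommon, function(v)
      all(members %in% sub$residue[sub$nu_cpmg_hz == v]), logical(1))]
    if (length(nuCommon) < 4)
      stop("fewer than 4 shared CPMG frequencies at ", f, " MHz")
    sub <- sub[sub$nu_cpmg_hz %in% nuCommon, ]
    sub <- sub[order(sub$residue, sub$nu_cpmg_hz), ]
    D <- matrix(sub$r2_eff, nrow = length(members), byrow = TRUE,
                dimnames = list(members, NULL))
    sig <- vapply(members, function(m)
      sub$sigma[sub$residue == m][1], numeric(1))
    Dc <- D - rowMeans(D)
    list(field = f, nu = nuCommon,
         n = as.integer(round(nuCommon * set@relaxTime)),
         D = D, Dc = Dc, a = rowSums(Dc^2), w = 1 / sig^2, sigma = sig,
         relaxTime = set@relaxTime, nucleus = set@nucleus)
  })
}

## profiled objective: chi^2 minimized over per-residue delta (grid +
## parabolic interpolation) and per-curve intrinsic rate (analytic) at
## fixed shared (kex, pB)
.subglobalObjective <- function(kex, pB, fdata, deltaGrid) {
  nRes <- nrow(fdata[[1]]$D)
  nDelta <- length(deltaGrid)
  M <- matrix(0, nRes, nDelta)
  for (fd in fdata) {
    G <- .rexGrid(kex, pB, deltaGrid, fd$n, fd$relaxTime, fd$field,
                  fd$nucleus)
    Gc <- G - rowMeans(G)
    b <- rowSums(Gc^2)
    X <- tcrossprod(fd$Dc, Gc)             # nRes x nDelta
    M <- M + fd$w * (fd$a - 2 * X + rep(b, each = nRes))
  }
  delta <- numeric(nRes)
  chis <- numeric(nRes)
  for (r in seq_len(nRes)) {
    y <- M[r, ]
    j <- which.min(y)
    delta[r] <- deltaGrid[j]
    chis[r] <- max(y[j], 0)
    if (j > 1 && j < nDelta) {
      xm <- .parabolaMin(deltaGrid[(j - 1):(j + 1)], y[(j - 1):(j + 1)])
      if (!is.null(xm)) {
        ## exact chi^2 at the interpolated location, summed over fields
        cm <- sum(vapply(fdata, function(fd)
          fd$w[r] * .curveChisqAt(kex, pB, xm, fd$n, fd$relaxTime,
                                  fd$field, fd$nucleus, fd$D[r, ],
                                  rep(1, length(fd$n))), numeric(1)))
        if (cm < chis[r]) {
          delta[r] <- xm
          chis[r] <- cm
        }
      }
    }
  }
  list(chisq = sum(chis), delta = delta, perResidue = chis)
}

.thetaToPar <- function(th) c(kex = exp(th[1]), pB = 0.5 * stats::plogis(th[2]))
.parToTheta <- function(kex, pB)
  c(log(kex), stats::qlogis(pmin(pmax(pB / 0.5, 1e-6), 1 - 1e-6)))

## core optimizer shared by fitSubglobal and the Monte Carlo refits
.optimizeSubglobal <- function(fdata, deltaGrid, starts, maxit = 400) {
  obj <- function(th) {
    p <- .thetaToPar(th)
    if (!is.finite(p[1]) || p[1] > 5e4 || p[1] < 1) return(1e12)
    .subglobalObjective(p[1], p[2], fdata, deltaGrid)$chisq
  }
  fits <- lapply(starts, function(s)
    optim(.parToTheta(s[1], s[2]), obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-10)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  p <- .thetaToPar(best$par)
  sol <- .subglobalObjective(p[1], p[2], fdata, deltaGrid)
  list(kex = unname(p[1]), pB = unname(p[2]), delta = sol$delta,
       chisq = sol$chisq, codes = vapply(fits, `[[`, numeric(1),
                                         "convergence"),
       theta = best$par)
}

#' Subglobal two-site exchange fit for a residue cluster
#'
#' Jointly fits all dispersion curves of the cluster members across the
#' available fields to a two-site exchange model with a shared exchange
#' rate and minor population, residue-specific |shift differences| and a
#' free intrinsic rate per residue per field. The objective
#' `sum(((data - model) / sigma)^2)` is minimized by Nelder-Mead over
#' (kex, pB) with the remaining parameters profiled out (the shift
#' difference on a fine grid with parabolic interpolation, the intrinsic
#' rates analytically), multi-started from a fixed grid of
#' kex in {200, 500, 800, 1200, 2000, 4000} /s and pB in
#' {0.01, 0.03, 0.08, 0.15}.
#'
#' @param set a [DispersionSet-class] containing the cluster members
#'   (typically at 600 and 700 MHz; a single field gives a warning).
#' @param cluster a [ClusterSpec-class] with at least 2 members.
#' @param nStarts number of screened grid points refined by Nelder-Mead.
#' @param deltaMax upper bound of the shift-difference grid (ppm).
#' @param nDelta grid resolution for the profiled shift difference.
#' @param maxit Nelder-Mead iteration cap.
#' @return a [ClusterFitResult-class] (uncertainties `NA` until
#'   [monteCarloUncertainty()]).
#' @export
fitSubglobal <- function(set, cluster, nStarts = 3, deltaMax = 6,
                         nDelta = 161, maxit = 400) {
  if (length(cluster@members) < 2)
    stop("subglobal fits need at least 2 residues")
  fdata <- .clusterData(set, cluster)
  deltaGrid <- seq(0, deltaMax, length.out = nDelta)
  screen <- expand.grid(kex = c(200, 500, 800, 1200, 2000, 4000),
                        pB = c(0.01, 0.03, 0.08, 0.15))
  sv <- vapply(seq_len(nrow(screen)), function(i)
    .subglobalObjective(screen$kex[i], screen$pB[i], fdata,
                        deltaGrid)$chisq, numeric(1))
  ord <- order(sv, screen$kex)
  starts <- lapply(head(ord, nStarts), function(i)
    c(screen$kex[i], screen$pB[i]))
  fit <- .optimizeSubglobal(fdata, deltaGrid, starts, maxit = maxit)
  if (all(fit$codes != 0))
    stop("no multi-start converged for cluster '", cluster@name, "'")

  members <- sort(cluster@members)
  delta <- setNames(fit$delta, members)
  r20 <- do.call(rbind, lapply(fdata, function(fd) {
    data.frame(residue = members, field_mhz = fd$field,
               r2_0 = vapply(seq_along(members), function(i)
                 .profiledR20(fit$kex, fit$pB, delta[i], fd$n, fd$relaxTime,
                              fd$field, fd$nucleus, fd$D[i, ],
                              rep(1, length(fd$n))), numeric(1)))
  }))
  nobs <- sum(vapply(fdata, function(fd) length(fd$D), integer(1)))
  npar <- 2L + length(members) + length(members) * length(fdata)
  new("ClusterFitResult", kex = fit$kex, kexSigma = NA_real_, pB = fit$pB,
      pBSigma = NA_real_, deltaPpm = delta,
      deltaPpmSigma = setNames(rep(NA_real_, length(delta)), members),
      r20 = r20, chisq = fit$chisq, nobs = as.integer(nobs),
      npar = as.integer(npar), cluster = cluster,
      fields = vapply(fdata, `[[`, numeric(1), "field"),
      nucleus = fdata[[1]]$nucleus, relaxTime = fdata[[1]]$relaxTime,
      convergence = list(screen = data.frame(screen, chisq = sv),
                         codes = fit$codes, theta = fit$theta),
      mc = list())
}

#' Monte Carlo uncertainties for a subglobal fit
#'
#' Parametric bootstrap: `nDatasets` synthetic rate sets are generated from
#' the fitted exchange parameters plus Gaussian noise at the experimental
#' rate uncertainties, each is refitted (warm-started from the fit), and
#' the parameter uncertainties are the standard deviations of the refit
#' results. Refits that do not converge are excluded; a failure rate above
#' 20 percent triggers a warning.
#'
#' @param fit a converged [ClusterFitResult-class].
#' @param set the [DispersionSet-class] the fit was run on (provides the
#'   frequency grid and uncertainties).
#' @param nDatasets number of synthetic datasets (default 100).
#' @param seed RNG seed.
#' @param maxit Nelder-Mead iteration cap per refit.
#' @return the fit with `kexSigma`, `pBSigma`, `deltaPpmSigma` filled in and
#'   the bootstrap draws stored in the `mc` slot.
#' @export
monteCarloUncertainty <- function(fit, set, nDatasets = 100, seed = 5005L,
                                  maxit = 200) {
  stopifnot(is(fit, "ClusterFitResult"))
  if (nDatasets < 2) stop("nDatasets must be >= 2")
  fdata <- .clusterData(set, fit@cluster)
  deltaGrid <- seq(0, max(6, max(fit@deltaPpm) * 1.5),
                   length.out = 161)
  members <- sort(fit@cluster@members)
  ## noise-free model rates at the fitted parameters
  model <- lapply(fdata, function(fd) {
    r20f <- fit@r20[fit@r20$field_mhz == fd$field, ]
    t(vapply(seq_along(members), function(i) {
      .r2effExact(fit@kex, fit@pB,
                  ppmToRadPerSec(fit@deltaPpm[i], fd$field, fd$nucleus),
                  0, 0, fd$n, fd$relaxTime) +
        r20f$r2_0[match(members[i], r20f$residue)]
    }, numeric(length(fd$n))))
  })
  draws <- withr::with_seed(seed, {
    lapply(seq_len(nDatasets), function(b) {
      fdB <- fdata
      for (j in seq_along(fdB)) {
        noise <- matrix(rnorm(length(model[[j]]), 0,
                              rep(fdB[[j]]$sigma,
                                  times = ncol(model[[j]]))),
                        nrow = nrow(model[[j]]))
        D <- model[[j]] + noise
        fdB[[j]]$D <- D
        fdB[[j]]$Dc <- D - rowMeans(D)
        fdB[[j]]$a <- rowSums(fdB[[j]]$Dc^2)
      }
      r <- .optimizeSubglobal(fdB, deltaGrid,
                              list(c(fit@kex, fit@pB)), maxit = maxit)
      r$ok <- any(r$codes == 0)
      r
    })
  })
  ok <- vapply(draws, `[[`, logical(1), "ok")
  nFail <- sum(!ok)
  if (nFail > 0.2 * nDatasets)
    warning(nFail, " of ", nDatasets, " Monte Carlo refits failed")
  kexDraws <- vapply(draws[ok], `[[`, numeric(1), "kex")
  pBDraws <- vapply(draws[ok], `[[`, numeric(1), "pB")
  deltaDraws <- do.call(rbind, lapply(draws[ok], `[[`, "delta"))
  fit@kexSigma <- sd(kexDraws)
  fit@pBSigma <- sd(pBDraws)
  fit@deltaPpmSigma <- setNames(apply(deltaDraws, 2, sd), members)
  fit@mc <- list(n = nDatasets, n_failed = nFail, seed = seed,
                 kex_draws = kexDraws, pB_draws = pBDraws)
  fit
}

#' Compare one-process and two-process exchange models
#'
#' Fits a single shared exchange process to the pooled cluster and,
#' separately, one process per cluster, and compares them by AIC computed
#' from the weighted residual sum of squares (`chisq + 2 * npar`, valid for
#' known Gaussian errors). The two-process description is declared
#' preferred when it improves AIC by more than `aicThreshold`.
#'
#' @param set a [DispersionSet-class].
#' @param singleCluster a [ClusterSpec-class] pooling all residues.
#' @param twoClusters list of two [ClusterSpec-class] objects partitioning
#'   the same residues.
#' @param aicThreshold AIC improvement required (default 10).
#' @param ... passed to [fitSubglobal()].
#' @return list with per-model reduced chi-square, AIC, convergence rate,
#'   the fitted objects, `delta_aic` (one-process minus two-process) and
#'   `two_process_preferred`.
#' @export
compareModels <- function(set, singleCluster, twoClusters,
                          aicThreshold = 10, ...) {
  one <- fitSubglobal(set, singleCluster, ...)
  two <- lapply(twoClusters, function(cl) fitSubglobal(set, cl, ...))
  aic1 <- one@chisq + 2 * one@npar
  aic2 <- sum(vapply(two, function(f) f@chisq + 2 * f@npar, numeric(1)))
  convRate <- function(f) mean(f@convergence$codes == 0)
  list(one_process = list(red_chisq = reducedChisq(one), aic = aic1,
                          convergence_rate = convRate(one), fit = one),
       two_process = list(
         red_chisq = vapply(two, reducedChisq, numeric(1)),
         aic = aic2,
         convergence_rate = vapply(two, convRate, numeric(1)),
         fits = two),
       delta_aic = aic1 - aic2,
       two_process_preferred = (aic1 - aic2) > aicThreshold)
}

#' Compare fitted shift differences with unfolding expectations
#'
#' Diagnoses whether the fitted exchange shift differences look like local
#' unfolding: reports the Pearson correlation against a supplied unfolded
#' reference (|assigned minus random-coil shift| per residue), the fraction
#' of residues whose fitted value is smaller than the reference, and a flag
#' raised when that fraction exceeds 0.8.
#'
#' @param deltaEx named numeric, fitted |shift differences| (ppm).
#' @param unfoldedReference named numeric, expected unfolding shift changes
#'   (ppm); names are residue numbers.
#' @return list with `correlation`, `fraction_smaller`, `ratio` (named
#'   per-residue deltaEx / reference), `smaller_than_unfolding`.
#' @export
compareToUnfoldingShifts <- function(deltaEx, unfoldedReference) {
  shared <- intersect(names(deltaEx), names(unfoldedReference))
  if (length(shared) < 3)
    stop("need at least 3 shared residues")
  a <- deltaEx[shared]
  b <- unfoldedReference[shared]
  frac <- mean(a < b)
  list(correlation = cor(a, b),
       fraction_smaller = frac,
       ratio = a / b,
       smaller_than_unfolding = frac > 0.8)
}
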