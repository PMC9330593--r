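#' Classify a dispersion amplitude into flexibility bins
#'
#' Bins: `"<1"` (flat), `"[1,5)"`, `"[5,10)"`, `">=10"` in 1/s. `NA`
#' amplitudes stay `NA`.
#'
#' @param deltaR2eff dispersion amplitude(s) in 1/s.
#' @return character vector of bin labels.
#' @examples
#' classifyFlexibility(c(0.5, 7, 12))
#' @export
classifyFlexibility <- function(deltaR2eff) {
  as.character(cut(deltaR2eff, breaks = c(-Inf, 1, 5, 10, Inf),
                   labels = .FLEX_BINS, right = FALSE))
}

## weighted profile chi^2 over a delta grid for one curve at fixed
## (kex, pB); intrinsic rate is profiled out analytically (it is an exact
## additive offset of the model curve). Returns the parabolic-interpolated
## minimum and its location.
## exact chi^2 for one curve at (kex, pB, delta), intrinsic rate profiled;
## direct residual sum, free of the cancellation that plagues expanded
## quadratic forms near chi^2 = 0
.curveChisqAt <- function(kex, pB, delta, nCycles, relaxTime, fieldMhz,
                          nucleus, r2eff, w) {
  rex <- .r2effExact(kex, pB, ppmToRadPerSec(delta, fieldMhz, nucleus),
                     0, 0, nCycles, relaxTime)
  r <- r2eff - rex
  sum(w * (r - sum(w * r) / sum(w))^2)
}

## parabolic minimum location from three points (x must be increasing);
## NULL when the parabola is degenerate or the vertex falls outside
.parabolaMin <- function(x, y) {
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
        x[1] * (y[3] - y[2])) / denom
  if (!is.finite(a) || a <= 0) return(NULL)
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
        x[1]^2 * (y[2] - y[3])) / denom
  xm <- -b / (2 * a)
  if (xm <= x[1] || xm >= x[3]) return(NULL)
  xm
}

.curveChisqProfile <- function(kex, pB, deltaGrid, nCycles, relaxTime,
                               fieldMhz, nucleus, r2eff, w) {
  G <- .rexGrid(kex, pB, deltaGrid, nCycles, relaxTime, fieldMhz, nucleus)
  sw <- sum(w)
  dbar <- sum(w * r2eff) / sw
  gbar <- as.numeric(G %*% w) / sw
  Dc <- r2eff - dbar
  Gc <- G - gbar  # gbar recycles along rows: centers each delta row
  chisq <- as.numeric((Gc^2) %*% w) + sum(w * Dc^2) -
    2 * as.numeric(Gc %*% (w * Dc))
  j <- which.min(chisq)
  delta <- deltaGrid[j]
  best <- max(chisq[j], 0)
  ## parabolic interpolation locates the off-grid minimum; the value there
  ## is then computed exactly (the interpolated value can undershoot badly
  ## when the curvature is high relative to the grid spacing)
  if (j > 1 && j < length(deltaGrid)) {
    xm <- .parabolaMin(deltaGrid[(j - 1):(j + 1)], chisq[(j - 1):(j + 1)])
    if (!is.null(xm)) {
      cm <- .curveChisqAt(kex, pB, xm, nCycles, relaxTime, fieldMhz,
                          nucleus, r2eff, w)
      if (cm < best) {
        delta <- xm
        best <- cm
      }
    }
  }
  list(delta = delta, chisq = best, gridDelta = deltaGrid[j])
}

## profiled intrinsic rate for one curve at fixed (kex, pB, delta)
.profiledR20 <- function(kex, pB, delta, nCycles, relaxTime, fieldMhz,
                         nucleus, r2eff, w) {
  rex <- .r2effExact(kex, pB, ppmToRadPerSec(delta, fieldMhz, nucleus),
                     0, 0, nCycles, relaxTime)
  sum(w * (r2eff - rex)) / sum(w)
}

#' Per-residue dispersion amplitude by model fitting
#'
#' Fits the exact two-site model to one residue's dispersion curve with a
#' bounded multi-start (kex grid 200/500/1000/2000/4000 1/s crossed with pB
#' grid 0.01/0.05/0.15), the shift difference profiled on a grid and the
#' intrinsic rate profiled analytically, followed by a Nelder-Mead
#' refinement from the best start; ties on chi-square are broken towards
#' smaller kex. The reported quantity is the extrapolated amplitude
#' `R2eff(0) - R2eff(Inf)` of the fitted model -- single-curve exchange
#' parameters themselves are shallow and degenerate and are returned only
#' as diagnostics.
#'
#' @param curve a [DispersionCurve-class] with at least 6 points.
#' @param kexGrid,pBGrid multi-start grids.
#' @param deltaMax upper bound for the shift difference (ppm).
#' @param kexBounds box bounds on kex during refinement (1/s); the default
#'   matches the regime over which the model evaluation is validated and
#'   keeps the zero-frequency extrapolation of a single, weakly informative
#'   curve from running away.
#' @param refine run the Nelder-Mead refinement (default TRUE).
#' @return list with `delta_r2_eff` (1/s; exactly 0 when the flat model is
#'   selected, `NA` when the exchange fit did not converge), `kex`, `pB`,
#'   `delta_ppm`, `r2_0`, `chisq`, `red_chisq`, `converged`, and
#'   `exchange_detected` (AIC prefers exchange over the flat model).
#' @export
amplitudeDeltaR2eff <- function(curve,
                                kexGrid = c(200, 500, 1000, 2000, 4000),
                                pBGrid = c(0.01, 0.05, 0.15),
                                deltaMax = 6, kexBounds = c(100, 6000),
                                refine = TRUE) {
  stopifnot(is(curve, "DispersionCurve"))
  if (length(curve@nuCpmg) < 6)
    stop("at least 6 dispersion points are required")
  n <- as.integer(round(curve@nuCpmg * curve@relaxTime))
  w <- 1 / curve@sigma^2
  dg <- seq(0, deltaMax, length.out = 121)
  evalPoint <- function(kex, pB)
    .curveChisqProfile(kex, pB, dg, n, curve@relaxTime, curve@fieldMhz,
                       curve@nucleus, curve@r2eff, w)

  grid <- expand.grid(kex = kexGrid, pB = pBGrid)
  screens <- lapply(seq_len(nrow(grid)),
                    function(i) evalPoint(grid$kex[i], grid$pB[i]))
  chis <- vapply(screens, `[[`, numeric(1), "chisq")
  ## ties broken towards smaller kex (grid is ordered by kex within pB)
  ord <- order(chis, grid$kex)
  best <- ord[1]
  kexB <- grid$kex[best]; pBB <- grid$pB[best]
  chisqB <- chis[best]; deltaB <- screens[[best]]$delta
  converged <- TRUE
  if (refine) {
    obj <- function(th) {
      kx <- exp(th[1]); p <- 0.5 * stats::plogis(th[2])
      if (!is.finite(kx) || kx < kexBounds[1] || kx > kexBounds[2])
        return(1e12)
      evalPoint(kx, p)$chisq
    }
    ## Nelder-Mead from the two best grid starts, each restarted once from
    ## its own solution (a fresh simplex escapes premature stalls)
    runs <- lapply(unique(ord[1:2]), function(i) {
      th <- c(log(grid$kex[i]),
              stats::qlogis(min(grid$pB[i] / 0.5, 0.999)))
      o <- optim(th, obj, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
      ## restart with a fresh simplex until the value stops moving; a
      ## stalled simplex near the optimum otherwise reports non-convergence
      settled <- o$convergence == 0
      for (r in 1:4) {
        if (settled) break
        o2 <- optim(o$par, obj, method = "Nelder-Mead",
                    control = list(maxit = 300, reltol = 1e-10))
        settled <- o2$convergence == 0 ||
          (o$value - o2$value) < 1e-8 * (1 + abs(o2$value))
        o <- o2
      }
      o$settled <- settled
      o
    })
    opt <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    converged <- opt$settled
    if (opt$value <= chisqB) {
      kexB <- exp(opt$par[1]); pBB <- 0.5 * stats::plogis(opt$par[2])
      sol <- evalPoint(kexB, pBB)
      chisqB <- sol$chisq; deltaB <- sol$delta
    }
  }
  ## model selection against the no-exchange (flat) alternative: a single
  ## curve only supports an exchange amplitude when AIC improves over the
  ## constant model (exchange: 4 parameters, flat: 1)
  chisqFlat <- sum(w * (curve@r2eff - sum(w * curve@r2eff) / sum(w))^2)
  exchange <- (chisqFlat + 2) - (chisqB + 8) > 0
  r20 <- .profiledR20(kexB, pBB, deltaB, n, curve@relaxTime, curve@fieldMhz,
                      curve@nucleus, curve@r2eff, w)
  amp <- .modelAmplitude(kexB, pBB, deltaB, curve@fieldMhz, curve@nucleus)
  dof <- max(1L, length(n) - 4L)
  if (!exchange) {
    amp <- 0
    converged <- TRUE
  }
  list(delta_r2_eff = if (converged) amp else NA_real_,
       kex = kexB, pB = pBB, delta_ppm = deltaB, r2_0 = r20,
       chisq = chisqB, red_chisq = chisqB / dof, converged = converged,
       exchange_detected = exchange)
}

#' Amplitudes for every curve of a DispersionSet
#'
#' Runs [amplitudeDeltaR2eff()] for each (residue, field) curve.
#'
#' @param x a [DispersionSet-class].
#' @param fields restrict to these fields (MHz); default all.
#' @param ... passed to [amplitudeDeltaR2eff()].
#' @return data.frame with one row per curve: `residue`, `field_mhz`,
#'   `delta_r2_eff`, `sigma` (the curve's rate uncertainty), `kex`, `pB`,
#'   `delta_ppm`, `r2_0`, `red_chisq`, `converged`.
#' @export
dispersionAmplitudes <- function(x, fields = NULL, ...) {
  stopifnot(is(x, "DispersionSet"))
  if (is.null(fields)) fields <- fieldsMhz(x)
  combos <- unique(x@rates[x@rates$field_mhz %in% fields,
                           c("residue", "field_mhz")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cv <- dispersionCurve(x, combos$residue[i], combos$field_mhz[i])
    fit <- tryCatch(amplitudeDeltaR2eff(cv, ...), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(residue = combos$residue[i],
                        field_mhz = combos$field_mhz[i],
                        delta_r2_eff = NA_real_, sigma = NA_real_,
                        kex = NA_real_, pB = NA_real_, delta_ppm = NA_real_,
                        r2_0 = NA_real_, red_chisq = NA_real_,
                        converged = FALSE))
    data.frame(residue = combos$residue[i], field_mhz = combos$field_mhz[i],
               delta_r2_eff = fit$delta_r2_eff, sigma = cv@sigma[1],
               kex = fit$kex, pB = fit$pB, delta_ppm = fit$delta_ppm,
               r2_0 = fit$r2_0, red_chisq = fit$red_chisq,
               converged = fit$converged)
  }))
  rownames(out) <- NULL
  out
}

#' Build a per-residue flexibility profile
#'
#' Combines fitted amplitudes at one field with explicit missing-data
#' information into a full-sequence [FlexibilityProfile-class]. Positions
#' with neither an amplitude nor a declared reason are `"unassigned"`;
#' curves whose fit did not converge are `"not_fit"`.
#'
#' @param amplitudes data.frame from [dispersionAmplitudes()].
#' @param fieldMhz field to profile (default: highest present).
#' @param sequenceLength protein length (default: largest residue seen).
#' @param missing optional data.frame (`residue`, `reason`).
#' @param protein protein label.
#' @return a [FlexibilityProfile-class].
#' @export
flexibilityProfile <- function(amplitudes, fieldMhz = NULL,
                               sequenceLength = NULL, missing = NULL,
                               protein = "protein") {
  if (is.null(fieldMhz)) fieldMhz <- max(amplitudes$field_mhz)
  amp <- amplitudes[amplitudes$field_mhz == fieldMhz, ]
  if (is.null(sequenceLength))
    sequenceLength <- max(amp$residue, missing$residue)
  prof <- data.frame(residue = seq_len(sequenceLength),
                     delta_r2_eff = NA_real_,
                     missing_reason = NA_character_,
                     bin = NA_character_)
  m <- match(amp$residue, prof$residue)
  prof$delta_r2_eff[m] <- amp$delta_r2_eff
  prof$missing_reason[m][!amp$converged] <- "not_fit"
  if (!is.null(missing)) {
    mm <- match(as.integer(missing$residue), prof$residue)
    prof$missing_reason[mm] <- missing$reason
    prof$delta_r2_eff[mm] <- NA_real_
  }
  absent <- is.na(prof$delta_r2_eff) & is.na(prof$missing_reason)
  prof$missing_reason[absent] <- "unassigned"
  ok <- !is.na(prof$delta_r2_eff)
  prof$bin[ok] <- classifyFlexibility(prof$delta_r2_eff[ok])
  new("FlexibilityProfile", profile = prof, fieldMhz = fieldMhz,
      protein = protein)
}
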