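#' Combined amide chemical-shift perturbation
#'
#' `csp = sqrt(((dH)^2 + (dN/5)^2) / 2)`: the 15N change is scaled down by
#' 5 to place both nuclei on a comparable ppm scale before averaging.
#'
#' @param deltaH 1H shift change (ppm).
#' @param deltaN 15N shift change (ppm).
#' @return combined perturbation in ppm (vectorized, always >= 0).
#' @examples
#' combinedCsp(0.1, 0.5) # 0.1
#' @export
combinedCsp <- function(deltaH, deltaN) {
  sqrt((deltaH^2 + (deltaN / 5)^2) / 2)
}

#' Correct titration shifts for co-solvent drift
#'
#' Subtracts a linear co-solvent (DMSO) contribution from the 1H and 15N
#' shift changes separately before any perturbation is computed: at volume
#' fraction `v` the subtracted amount is `(v / maxFraction)` times the
#' reference shift change recorded at `maxFraction` co-solvent without
#' ligand. Residues without a reference are left uncorrected and flagged.
#'
#' @param x a [TitrationSeries-class].
#' @param reference data.frame (`residue`, `delta_h_ppm`, `delta_n_ppm`);
#'   defaults to the series' own DMSO reference.
#' @param maxFraction volume fraction of the reference experiment; defaults
#'   to the series' `maxDmsoFraction`.
#' @return the series with corrected shifts and a logical
#'   `dmso_corrected` column added.
#' @export
dmsoCorrect <- function(x, reference = NULL, maxFraction = NULL) {
  stopifnot(is(x, "TitrationSeries"))
  if (is.null(reference)) reference <- x@dmsoReference
  if (is.null(maxFraction)) maxFraction <- x@maxDmsoFraction
  if (!nrow(reference)) {
    x@shifts$dmso_corrected <- FALSE
    warning("no DMSO reference shifts: returning uncorrected series")
    return(x)
  }
  if (maxFraction <= 0) stop("maxFraction must be positive")
  if (any(x@points$dmso_fraction > maxFraction + 1e-12))
    stop("volume fractions exceed the reference maximum")
  sh <- x@shifts
  m <- match(sh$residue, reference$residue)
  vf <- x@points$dmso_fraction[match(sh$point_index, x@points$point_index)]
  scale <- vf / maxFraction
  corrected <- !is.na(m)
  if (any(!corrected))
    warning(length(unique(sh$residue[!corrected])),
            " residue(s) lack a DMSO reference; left uncorrected")
  sh$delta_h_ppm <- sh$delta_h_ppm -
    ifelse(corrected, scale * reference$delta_h_ppm[m], 0)
  sh$delta_n_ppm <- sh$delta_n_ppm -
    ifelse(corrected, scale * reference$delta_n_ppm[m], 0)
  sh$dmso_corrected <- corrected
  x@shifts <- sh
  x
}

#' Exact 1:1 binding equilibrium
#'
#' Solves the quadratic for the complex concentration,
#' `[PL] = ((P + L + KD) - sqrt((P + L + KD)^2 - 4 P L)) / 2`,
#' and returns the bound fractions of protein and ligand. The exact
#' solution accounts for ligand depletion, which matters whenever total
#' concentrations are comparable to KD.
#'
#' @param pTotal total protein concentration (mM), vectorized.
#' @param lTotal total ligand concentration (mM), vectorized.
#' @param kd dissociation constant (mM).
#' @return list with `complex` (mM), `protein` ([PL]/P), `ligand` ([PL]/L);
#'   fractions are 0 where the respective total is 0.
#' @examples
#' boundFraction(0.24, 2.0, 0.76)$complex # 0.1696 mM
#' @export
boundFraction <- function(pTotal, lTotal, kd) {
  if (any(pTotal < 0) || any(lTotal < 0)) stop("concentrations must be >= 0")
  if (any(kd <= 0)) stop("kd must be positive")
  s <- pTotal + lTotal + kd
  pl <- (s - sqrt(s^2 - 4 * pTotal * lTotal)) / 2
  pl <- pmin(pl, pTotal, lTotal)  # guard against rounding overshoot
  list(complex = pl,
       protein = ifelse(pTotal > 0, pl / pTotal, 0),
       ligand = ifelse(lTotal > 0, pl / lTotal, 0))
}

#' Per-residue combined perturbations of a titration
#'
#' @param x a [TitrationSeries-class] (correct with [dmsoCorrect()] first
#'   if a DMSO reference is available).
#' @return data.frame `residue`, `point_index`, `csp_ppm`.
#' @export
cspTable <- function(x) {
  stopifnot(is(x, "TitrationSeries"))
  data.frame(residue = x@shifts$residue, point_index = x@shifts$point_index,
             csp_ppm = combinedCsp(x@shifts$delta_h_ppm,
                                   x@shifts$delta_n_ppm))
}

#' Fit per-residue and mean dissociation constants
#'
#' For every residue whose maximum (drift-corrected) combined perturbation
#' exceeds `threshold`, fits `csp(point) = csp_max * fBound(point; KD)`
#' by Levenberg-Marquardt least squares, with the protein-bound fraction
#' from the exact 1:1 quadratic at each point's (diluted) concentrations.
#' The summary KD is the unweighted mean and standard deviation over the
#' qualifying residues; per-residue uncertainties come from the
#' least-squares covariance.
#'
#' @param x a [TitrationSeries-class].
#' @param threshold qualification threshold on the maximum perturbation
#'   (ppm, default 0.1).
#' @param correctDmso apply [dmsoCorrect()] first when a reference is
#'   present (default TRUE).
#' @return a [BindingFit-class].
#' @export
fitKd <- function(x, threshold = 0.1, correctDmso = TRUE) {
  stopifnot(is(x, "TitrationSeries"))
  if (nrow(x@points) < 5) stop("need at least 5 titration points")
  if (correctDmso && nrow(x@dmsoReference)) x <- dmsoCorrect(x)
  csp <- cspTable(x)
  pts <- x@points
  perRes <- do.call(rbind, lapply(split(csp, csp$residue), function(sub) {
    sub <- sub[order(match(sub$point_index, pts$point_index)), ]
    y <- sub$csp_ppm
    p <- pts$protein_mM[match(sub$point_index, pts$point_index)]
    l <- pts$ligand_mM[match(sub$point_index, pts$point_index)]
    maxCsp <- max(y)
    qualifies <- maxCsp > threshold
    resFun <- function(par) {
      fb <- boundFraction(p, l, exp(par[1]))$protein
      y - par[2] * fb
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(logkd = log(0.5), ddmax = maxCsp),
                         fn = resFun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(residue = sub$residue[1], kd_mM = NA_real_,
                        kd_sigma_mM = NA_real_, ddmax_ppm = NA_real_,
                        max_csp_ppm = maxCsp, qualifies = qualifies,
                        flagged_nonmonotone = FALSE))
    kd <- exp(coef(fit)[["logkd"]])
    ## delta method on log KD from the LM covariance
    kdSig <- tryCatch({
      s2 <- fit$deviance / max(1, length(y) - 2)
      covm <- s2 * solve(fit$hessian)
      kd * sqrt(covm[1, 1])
    }, error = function(e) NA_real_)
    monotone <- suppressWarnings(cor(y, l, method = "spearman"))
    data.frame(residue = sub$residue[1], kd_mM = kd, kd_sigma_mM = kdSig,
               ddmax_ppm = coef(fit)[["ddmax"]], max_csp_ppm = maxCsp,
               qualifies = qualifies,
               flagged_nonmonotone = qualifies && !is.na(monotone) &&
                 monotone < 0.8)
  }))
  rownames(perRes) <- NULL
  used <- perRes$residue[perRes$qualifies & !is.na(perRes$kd_mM)]
  if (!length(used))
    stop("no residues exceed the ", threshold, " ppm threshold")
  kds <- perRes$kd_mM[match(used, perRes$residue)]
  new("BindingFit", perResidue = perRes, meanKd = mean(kds),
      sdKd = if (length(kds) > 1) sd(kds) else NA_real_,
      threshold = threshold, residuesUsed = as.integer(used),
      nPoints = nrow(pts))
}
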