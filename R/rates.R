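#' Effective transverse relaxation rate from peak intensities
#'
#' `R2eff = -ln(I / I0) / Trelax`, where `I` is the peak intensity at a
#' given CPMG frequency and `I0` the reference intensity recorded without
#' the relaxation period. Intensities that have decayed to or below zero
#' cannot be converted; they return `NA` with a warning so that the position
#' can be flagged as unquantifiable rather than silently dropped.
#'
#' @param intensity peak intensity (vectorized).
#' @param referenceIntensity reference intensity, must be positive.
#' @param relaxTime relaxation period in seconds, must be positive.
#' @return effective rate(s) in 1/s; `NA` where `intensity <= 0`.
#' @examples
#' computeR2eff(50, 100, 0.060) # ln(2)/0.06 = 11.55 /s
#' @export
computeR2eff <- function(intensity, referenceIntensity, relaxTime) {
  if (any(referenceIntensity <= 0, na.rm = TRUE))
    stop("referenceIntensity must be positive")
  if (any(relaxTime <= 0)) stop("relaxTime must be positive")
  bad <- !is.na(intensity) & intensity <= 0
  if (any(bad)) {
    warning(sum(bad), " intensity value(s) <= 0: signal decayed below ",
            "noise; returning NA (unquantifiable)")
    intensity[bad] <- NA_real_
  }
  -log(intensity / referenceIntensity) / relaxTime
}

#' CPMG frequency of an echo train
#'
#' `nu_CPMG = nCycles / relaxTime` for a constant-time CPMG period
#' containing `nCycles` tau-180-tau echo cycles.
#'
#' @param nCycles integer number of cycles, >= 1.
#' @param relaxTime relaxation period in seconds.
#' @return frequency in Hz.
#' @examples
#' cpmgFrequency(4, 0.060) # 66.7 Hz
#' @export
cpmgFrequency <- function(nCycles, relaxTime) {
  if (any(nCycles < 1) || any(nCycles != round(nCycles)))
    stop("nCycles must be integers >= 1")
  if (any(relaxTime <= 0)) stop("relaxTime must be positive")
  nCycles / relaxTime
}

## long-format replicate-resolved rates for one experiment
.replicateRates <- function(x) {
  tab <- intensityTable(x)
  tt <- relaxTime(x)
  refs <- tab[tab$is_reference, ]
  ## reference intensity per (residue, field), averaged over replicates
  refKey <- paste(refs$residue, refs$field_mhz)
  refMean <- tapply(refs$intensity, refKey, mean)
  pts <- tab[!tab$is_reference, ]
  i0 <- as.numeric(refMean[paste(pts$residue, pts$field_mhz)])
  suppressWarnings(r2 <- computeR2eff(pts$intensity, i0, tt))
  data.frame(residue = pts$residue, field_mhz = pts$field_mhz,
             nu_cpmg_hz = pts$nu_cpmg_hz, replicate_id = pts$replicate_id,
             r2_eff = r2)
}

#' Rate uncertainties from repeat experiments
#'
#' The CPMG frequencies recorded twice give pairs of independently measured
#' rates. Each pair with rate difference d contributes `|d|/sqrt(2)` as a
#' one-point spread estimate; the per-residue uncertainty pools these as a
#' root mean square over all of that residue's pairs (across fields),
#' bounded below by `floor` so that no data point receives infinite weight.
#'
#' @param x a [CpmgExperiment-class].
#' @param floor lower bound on sigma in 1/s (default 0.05).
#' @param fallback sigma to use when an experiment contains no repeats
#'   (default `NULL`: no repeats is an error).
#' @return data.frame `residue`, `sigma`, `n_pairs`.
#' @export
sigmaFromRepeats <- function(x, floor = 0.05, fallback = NULL) {
  rr <- .replicateRates(x)
  key <- paste(rr$residue, rr$field_mhz, rr$nu_cpmg_hz)
  hasRep <- any(table(key) >= 2)
  resid <- sort(unique(rr$residue))
  if (!hasRep) {
    if (is.null(fallback))
      stop("no repeat experiments found and no fallback sigma given")
    return(data.frame(residue = resid, sigma = pmax(fallback, floor),
                      n_pairs = 0L, row.names = NULL))
  }
  out <- do.call(rbind, lapply(resid, function(res) {
    sub <- rr[rr$residue == res, ]
    sq <- unlist(lapply(split(sub$r2_eff,
                              paste(sub$field_mhz, sub$nu_cpmg_hz)),
                        function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NULL)
      ## variance of a pair difference: var(d) = 2 sigma^2
      diff(v[1:2])^2 / 2
    }))
    data.frame(residue = res,
               sigma = if (length(sq)) max(floor, sqrt(mean(sq))) else
                 max(floor, if (is.null(fallback)) floor else fallback),
               n_pairs = length(sq))
  }))
  rownames(out) <- NULL
  out
}

#' Convert an intensity experiment into dispersion curves
#'
#' Computes effective rates from intensities, averages replicate points,
#' attaches repeat-based uncertainties, and returns a tidy
#' [DispersionSet-class]. Points whose intensity could not be quantified are
#' dropped from the curves (the residue keeps its remaining points).
#'
#' @inheritParams sigmaFromRepeats
#' @param sigmaFloor lower bound for the repeat-based sigma (1/s).
#' @return a [DispersionSet-class].
#' @export
dispersionSet <- function(x, sigmaFloor = 0.05, fallback = NULL) {
  rr <- .replicateRates(x)
  rr <- rr[!is.na(rr$r2_eff), ]
  agg <- stats::aggregate(r2_eff ~ residue + field_mhz + nu_cpmg_hz,
                          data = rr, FUN = mean)
  sig <- sigmaFromRepeats(x, floor = sigmaFloor, fallback = fallback)
  agg$sigma <- sig$sigma[match(agg$residue, sig$residue)]
  agg <- agg[order(agg$residue, agg$field_mhz, agg$nu_cpmg_hz),
             c("residue", "field_mhz", "nu_cpmg_hz", "r2_eff", "sigma")]
  rownames(agg) <- NULL
  new("DispersionSet", rates = agg,
      relaxTime = relaxTime(x),
      nucleus = S4Vectors::metadata(x)$nucleus)
}

#' Extract one residue's curve from a DispersionSet
#'
#' @param x a [DispersionSet-class].
#' @param residue residue number.
#' @param fieldMhz spectrometer field in MHz.
#' @return a [DispersionCurve-class].
#' @export
dispersionCurve <- function(x, residue, fieldMhz) {
  stopifnot(is(x, "DispersionSet"))
  sub <- x@rates[x@rates$residue == residue & x@rates$field_mhz == fieldMhz, ]
  if (!nrow(sub)) stop("no data for residue ", residue, " at ", fieldMhz,
                       " MHz")
  sub <- sub[order(sub$nu_cpmg_hz), ]
  new("DispersionCurve", residue = as.integer(residue),
      fieldMhz = as.numeric(fieldMhz), nuCpmg = sub$nu_cpmg_hz,
      r2eff = sub$r2_eff, sigma = sub$sigma, relaxTime = x@relaxTime,
      nucleus = x@nucleus)
}
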