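#' Accessor generics
#'
#' Small accessor generics for the S4 classes in this package. These avoid
#' direct slot access in user code.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("fieldsMhz", function(x) standardGeneric("fieldsMhz"))
#' @rdname accessors
#' @export
setGeneric("kex", function(x) standardGeneric("kex"))
#' @rdname accessors
#' @export
setGeneric("kexSigma", function(x) standardGeneric("kexSigma"))
#' @rdname accessors
#' @export
setGeneric("pB", function(x) standardGeneric("pB"))
#' @rdname accessors
#' @export
setGeneric("pBSigma", function(x) standardGeneric("pBSigma"))
#' @rdname accessors
#' @export
setGeneric("deltaPpm", function(x) standardGeneric("deltaPpm"))
#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("relaxTime", function(x) standardGeneric("relaxTime"))
#' @rdname accessors
#' @export
setGeneric("reducedChisq", function(x) standardGeneric("reducedChisq"))
#' @rdname accessors
#' @export
setGeneric("koff", function(x) standardGeneric("koff"))
#' @rdname accessors
#' @export
setGeneric("koffSigma", function(x) standardGeneric("koffSigma"))
#' @rdname accessors
#' @export
setGeneric("meanKd", function(x) standardGeneric("meanKd"))
#' @rdname accessors
#' @export
setGeneric("sdKd", function(x) standardGeneric("sdKd"))
#' @rdname accessors
#' @export
setGeneric("perResidueKd", function(x) standardGeneric("perResidueKd"))
#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

## -- CpmgSchedule ----------------------------------------------------------

#' @rdname accessors
setMethod("relaxTime", "CpmgSchedule", function(x) x@relaxTime)
#' @rdname accessors
setMethod("fieldsMhz", "CpmgSchedule", function(x) x@fields)

#' CPMG frequencies of a schedule
#' @param x a [CpmgSchedule-class].
#' @return numeric vector of CPMG frequencies in Hz.
#' @export
scheduleFrequencies <- function(x) {
  stopifnot(is(x, "CpmgSchedule"))
  cpmgFrequency(x@nCycles, x@relaxTime)
}

## -- TwoSiteTruth ----------------------------------------------------------

#' @rdname accessors
setMethod("kex", "TwoSiteTruth", function(x) x@kex)
#' @rdname accessors
setMethod("pB", "TwoSiteTruth", function(x) x@pB)
#' @rdname accessors
setMethod("deltaPpm", "TwoSiteTruth", function(x) x@deltaPpm)
#' @rdname accessors
setMethod("residues", "TwoSiteTruth",
          function(x) as.integer(names(x@deltaPpm)))

## -- DispersionSet / DispersionCurve --------------------------------------

#' @rdname accessors
setMethod("rates", "DispersionSet", function(x) x@rates)
#' @rdname accessors
setMethod("relaxTime", "DispersionSet", function(x) x@relaxTime)
#' @rdname accessors
setMethod("residues", "DispersionSet",
          function(x) sort(unique(x@rates$residue)))
#' @rdname accessors
setMethod("fieldsMhz", "DispersionSet",
          function(x) sort(unique(x@rates$field_mhz)))

## -- ClusterFitResult ------------------------------------------------------

#' @rdname accessors
setMethod("kex", "ClusterFitResult", function(x) x@kex)
#' @rdname accessors
setMethod("kexSigma", "ClusterFitResult", function(x) x@kexSigma)
#' @rdname accessors
setMethod("pB", "ClusterFitResult", function(x) x@pB)
#' @rdname accessors
setMethod("pBSigma", "ClusterFitResult", function(x) x@pBSigma)
#' @rdname accessors
setMethod("deltaPpm", "ClusterFitResult", function(x) x@deltaPpm)
#' @rdname accessors
setMethod("residues", "ClusterFitResult", function(x) x@cluster@members)
#' @rdname accessors
setMethod("reducedChisq", "ClusterFitResult",
          function(x) x@chisq / max(1L, x@nobs - x@npar))

## -- BindingFit ------------------------------------------------------------

#' @rdname accessors
setMethod("meanKd", "BindingFit", function(x) x@meanKd)
#' @rdname accessors
setMethod("sdKd", "BindingFit", function(x) x@sdKd)
#' @rdname accessors
setMethod("perResidueKd", "BindingFit", function(x) x@perResidue)

## -- LigandKineticsFit -----------------------------------------------------

#' @rdname accessors
setMethod("koff", "LigandKineticsFit", function(x) x@koff)
#' @rdname accessors
setMethod("koffSigma", "LigandKineticsFit", function(x) x@koffSigma)
#' @rdname accessors
setMethod("reducedChisq", "LigandKineticsFit",
          function(x) x@chisq / max(1L, x@nobs - x@npar))

## -- FlexibilityProfile ----------------------------------------------------

#' @rdname accessors
setMethod("profileTable", "FlexibilityProfile", function(x) x@profile)
#' @rdname accessors
setMethod("residues", "FlexibilityProfile", function(x) x@profile$residue)

## -- show methods ----------------------------------------------------------

setMethod("show", "CpmgSchedule", function(object) {
  cat("CpmgSchedule:", length(object@nCycles), "cycle counts, T_relax =",
      object@relaxTime * 1000, "ms\n")
  cat("  fields (MHz):", paste(object@fields, collapse = ", "), "\n")
  cat("  nu_CPMG (Hz):",
      paste(sprintf("%.1f", scheduleFrequencies(object)), collapse = ", "), "\n")
  if (length(object@repeats))
    cat("  repeats at n =", paste(object@repeats, collapse = ", "), "\n")
})

setMethod("show", "TwoSiteTruth", function(object) {
  cat(sprintf("TwoSiteTruth: kex = %.4g /s, pB = %.4g (%s)\n",
              object@kex, object@pB, object@nucleus))
  cat(sprintf("  %d residues, |ddelta| %.2f-%.2f ppm, seed %d\n",
              length(object@deltaPpm), min(object@deltaPpm),
              max(object@deltaPpm), object@seed))
})

setMethod("show", "DispersionSet", function(object) {
  cat(sprintf("DispersionSet: %d residues x %d field(s), %d points (%s)\n",
              length(residues(object)), length(fieldsMhz(object)),
              nrow(object@rates), object@nucleus))
})

setMethod("show", "ClusterFitResult", function(object) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4g", v)
         else sprintf("%.4g +/- %.2g", v, s)
  cat(sprintf("ClusterFitResult '%s' (%d residues)\n",
              object@cluster@name, length(object@cluster@members)))
  cat("  kex  =", fmt(object@kex, object@kexSigma), "/s\n")
  cat("  pB   =", fmt(object@pB, object@pBSigma), "\n")
  cat(sprintf("  timescale = %.1f ms, reduced chi^2 = %.3g\n",
              exchangeTimescale(object@kex), reducedChisq(object)))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d points, %d residues, ratios %.3g-%.3g\n",
              nrow(object@points), length(unique(object@shifts$residue)),
              min(object@points$ratio), max(object@points$ratio)))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: mean KD = %.3g +/- %.3g mM over %d residues (CSP > %.3g ppm)\n",
              object@meanKd, object@sdKd, length(object@residuesUsed),
              object@threshold))
})

setMethod("show", "LigandRDSeries", function(object) {
  cat(sprintf("LigandRDSeries (%s): %d samples, saturation %.3g-%.3g\n",
              object@proton, nrow(object@samples),
              min(object@samples$saturation), max(object@samples$saturation)))
})

setMethod("show", "LigandKineticsFit", function(object) {
  s <- if (is.na(object@koffSigma)) "" else sprintf(" +/- %.3g", object@koffSigma)
  cat(sprintf("LigandKineticsFit: koff = %.4g%s /s (residence %.1f ms)\n",
              object@koff, s, residenceTime(object@koff)))
})

setMethod("show", "FlexibilityProfile", function(object) {
  p <- object@profile
  cat(sprintf("FlexibilityProfile '%s' at %g MHz: %d positions, %d evaluable\n",
              object@protein, object@fieldMhz, nrow(p),
              sum(!is.na(p$delta_r2_eff))))
})
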