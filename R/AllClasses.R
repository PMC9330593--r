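#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats coef cor mad median optimize quantile rnorm runif sd setNames uniroot var optim nlminb
#' @importFrom utils read.csv write.csv head
NULL

## ---------------------------------------------------------------------------
## CpmgSchedule: the timing of a CPMG experiment
## ---------------------------------------------------------------------------

#' CPMG experiment schedule
#'
#' Holds the constant-time relaxation period, the cycle counts of the echo
#' train, the spectrometer fields, and which cycle counts were measured in
#' duplicate for error estimation. The CPMG frequency of each point is
#' `nCycles / relaxTime`.
#'
#' @slot relaxTime total CPMG relaxation period in seconds.
#' @slot nCycles integer vector of echo-cycle counts (one tau-180-tau block
#'   per cycle).
#' @slot fields spectrometer 1H frequencies in MHz.
#' @slot repeats subset of `nCycles` recorded twice.
#' @export
setClass("CpmgSchedule",
  representation(relaxTime = "numeric", nCycles = "integer",
                 fields = "numeric", repeats = "integer"))

setValidity("CpmgSchedule", function(object) {
  msg <- character()
  if (length(object@relaxTime) != 1L || !is.finite(object@relaxTime) ||
      object@relaxTime <= 0)
    msg <- c(msg, "relaxTime must be a single positive number (seconds)")
  if (length(object@nCycles) < 1L || any(object@nCycles < 1L))
    msg <- c(msg, "nCycles must all be >= 1")
  if (anyDuplicated(object@nCycles))
    msg <- c(msg, "nCycles must be unique")
  if (is.unsorted(object@nCycles))
    msg <- c(msg, "nCycles must be increasing")
  if (!all(object@repeats %in% object@nCycles))
    msg <- c(msg, "repeats must be a subset of nCycles")
  if (length(object@fields) < 1L || any(object@fields <= 0))
    msg <- c(msg, "fields must be positive (MHz)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TwoSiteTruth: ground-truth exchange parameters for simulation
## ---------------------------------------------------------------------------

#' Ground-truth two-site exchange parameters
#'
#' Describes a single exchange process shared by a set of residues: a total
#' exchange rate constant kex (sum of forward and backward rates), a minor
#' state population pB, residue-specific absolute shift differences between
#' the two states, and residue/field-specific intrinsic transverse rates.
#'
#' @slot kex exchange rate constant in 1/s (kAB + kBA).
#' @slot pB minor-state population (fraction, major state is A).
#' @slot deltaPpm named numeric, per-residue |shift difference| in ppm; names
#'   are residue numbers.
#' @slot r20 numeric matrix of intrinsic rates in 1/s, rows = residues
#'   (rownames matching `names(deltaPpm)`), columns = fields in MHz.
#' @slot nucleus observed nucleus, `"15N"` or `"1H"`.
#' @slot seed integer RNG seed attached to the truth for reproducibility.
#' @export
setClass("TwoSiteTruth",
  representation(kex = "numeric", pB = "numeric", deltaPpm = "numeric",
                 r20 = "matrix", nucleus = "character", seed = "integer"))

setValidity("TwoSiteTruth", function(object) {
  msg <- character()
  if (length(object@kex) != 1L || !is.finite(object@kex) || object@kex <= 0)
    msg <- c(msg, "kex must be a single positive rate (1/s)")
  if (length(object@pB) != 1L || object@pB < 0 || object@pB > 0.5)
    msg <- c(msg, "pB must lie in [0, 0.5]")
  if (is.null(names(object@deltaPpm)))
    msg <- c(msg, "deltaPpm must be named by residue number")
  if (any(object@deltaPpm < 0))
    msg <- c(msg, "deltaPpm must be >= 0")
  if (!identical(rownames(object@r20), names(object@deltaPpm)))
    msg <- c(msg, "rownames(r20) must equal names(deltaPpm)")
  if (any(object@r20 <= 0))
    msg <- c(msg, "intrinsic rates r20 must be positive")
  if (!object@nucleus %in% names(.GAMMA_RATIO))
    msg <- c(msg, "nucleus must be one of '15N', '1H'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CpmgExperiment: intensity container (SummarizedExperiment)
## ---------------------------------------------------------------------------

#' CPMG peak-intensity experiment
#'
#' A `SummarizedExperiment` with one `"intensity"` assay whose rows are
#' residues and whose columns are measurement conditions: one reference
#' column per field (relaxation period absent) plus one column per
#' (field, CPMG frequency, replicate). Missing measurements (overlap,
#' proline, unassigned) are `NA` in the assay with the reason recorded in
#' `rowData(x)$missing_reason`. The relaxation time, nucleus, and (for
#' synthetic data) the generating truth and seed live in `metadata()`.
#'
#' @export
setClass("CpmgExperiment", contains = "SummarizedExperiment")

setValidity("CpmgExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("field_mhz", "nu_cpmg_hz", "is_reference", "replicate_id")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (all(need %in% colnames(cd))) {
    for (f in unique(cd$field_mhz))
      if (!any(cd$is_reference & cd$field_mhz == f))
        msg <- c(msg, sprintf("no reference column for field %s MHz", f))
    a <- SummarizedExperiment::assay(object, "intensity")
    ref <- a[, cd$is_reference, drop = FALSE]
    if (any(!is.na(ref) & ref <= 0))
      msg <- c(msg, "reference intensities must be positive")
  }
  if (is.null(S4Vectors::metadata(object)$relax_time))
    msg <- c(msg, "metadata()$relax_time is required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DispersionSet / curves
## ---------------------------------------------------------------------------

#' Set of relaxation-dispersion curves
#'
#' Tidy per-point effective rates: one row per (residue, field, CPMG
#' frequency) with the rate uncertainty. Replicate measurements have been
#' averaged; the uncertainty comes from repeat experiments (see
#' [sigmaFromRepeats()]).
#'
#' @slot rates data.frame with columns `residue`, `field_mhz`, `nu_cpmg_hz`,
#'   `r2_eff`, `sigma`.
#' @slot relaxTime CPMG relaxation period in seconds.
#' @slot nucleus observed nucleus.
#' @export
setClass("DispersionSet",
  representation(rates = "data.frame", relaxTime = "numeric",
                 nucleus = "character"))

setValidity("DispersionSet", function(object) {
  msg <- character()
  need <- c("residue", "field_mhz", "nu_cpmg_hz", "r2_eff", "sigma")
  if (!all(need %in% names(object@rates)))
    msg <- c(msg, paste("rates must contain columns:", paste(need, collapse = ", ")))
  else if (any(!is.na(object@rates$sigma) & object@rates$sigma <= 0))
    msg <- c(msg, "sigma must be positive")
  if (length(object@relaxTime) != 1L || object@relaxTime <= 0)
    msg <- c(msg, "relaxTime must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' One residue's dispersion curve at one field
#'
#' @slot residue residue number (native 1-based numbering).
#' @slot fieldMhz spectrometer 1H frequency in MHz.
#' @slot nuCpmg CPMG frequencies in Hz, strictly increasing.
#' @slot r2eff effective rates in 1/s.
#' @slot sigma rate uncertainties in 1/s.
#' @slot relaxTime relaxation period in seconds.
#' @slot nucleus observed nucleus.
#' @export
setClass("DispersionCurve",
  representation(residue = "integer", fieldMhz = "numeric", nuCpmg = "numeric",
                 r2eff = "numeric", sigma = "numeric", relaxTime = "numeric",
                 nucleus = "character"))

setValidity("DispersionCurve", function(object) {
  msg <- character()
  n <- length(object@nuCpmg)
  if (length(object@r2eff) != n || length(object@sigma) != n)
    msg <- c(msg, "nuCpmg, r2eff and sigma must have equal length")
  if (n > 1 && any(diff(object@nuCpmg) <= 0))
    msg <- c(msg, "nuCpmg must be strictly increasing")
  if (any(!is.na(object@sigma) & object@sigma <= 0))
    msg <- c(msg, "sigma must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Cluster fitting
## ---------------------------------------------------------------------------

#' Residue cluster for a subglobal exchange fit
#'
#' @slot name cluster label.
#' @slot members residue numbers in the cluster.
#' @slot threshold amplitude selection threshold in 1/s (membership rule:
#'   dispersion amplitude above this value at the highest field).
#' @export
setClass("ClusterSpec",
  representation(name = "character", members = "integer", threshold = "numeric"))

setValidity("ClusterSpec", function(object) {
  msg <- character()
  if (length(object@members) < 1L) msg <- c(msg, "cluster has no members")
  if (anyDuplicated(object@members)) msg <- c(msg, "duplicate members")
  if (length(msg)) msg else TRUE
})

#' Result of a subglobal two-site exchange fit
#'
#' Shared exchange rate and minor population across the cluster,
#' residue-specific shift differences, and per-curve intrinsic rates.
#' Uncertainties are `NA` until [monteCarloUncertainty()] fills them in.
#'
#' @slot kex,kexSigma exchange rate and its Monte Carlo uncertainty (1/s).
#' @slot pB,pBSigma minor-state population and uncertainty (fraction).
#' @slot deltaPpm,deltaPpmSigma named per-residue |shift difference| (ppm).
#' @slot r20 data.frame (`residue`, `field_mhz`, `r2_0`) of intrinsic rates.
#' @slot chisq weighted sum of squared residuals.
#' @slot nobs,npar numbers of data points and free parameters.
#' @slot cluster the [ClusterSpec-class] that was fitted.
#' @slot fields fields used (MHz); @slot nucleus observed nucleus.
#' @slot relaxTime relaxation period (s).
#' @slot convergence list of optimizer diagnostics (start grid, codes).
#' @slot mc list of Monte Carlo details (n, failures, draws).
#' @export
setClass("ClusterFitResult",
  representation(kex = "numeric", kexSigma = "numeric", pB = "numeric",
                 pBSigma = "numeric", deltaPpm = "numeric",
                 deltaPpmSigma = "numeric", r20 = "data.frame",
                 chisq = "numeric", nobs = "integer", npar = "integer",
                 cluster = "ClusterSpec", fields = "numeric",
                 nucleus = "character", relaxTime = "numeric",
                 convergence = "list", mc = "list"))

setValidity("ClusterFitResult", function(object) {
  msg <- character()
  if (object@kex <= 0) msg <- c(msg, "kex must be positive")
  if (object@pB < 0 || object@pB > 0.5) msg <- c(msg, "pB must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Titration / binding
## ---------------------------------------------------------------------------

#' Chemical-shift titration series
#'
#' Per-point sample composition and per-residue peak-position changes
#' relative to the ligand-free (apo) spectrum.
#'
#' @slot points data.frame with `point_index`, `ratio` (ligand:protein molar
#'   ratio), `protein_mM`, `ligand_mM`, `dmso_fraction` (v/v), ordered by
#'   increasing ligand.
#' @slot shifts data.frame with `residue`, `point_index`, `delta_h_ppm`,
#'   `delta_n_ppm` (changes from apo).
#' @slot dmsoReference data.frame with `residue`, `delta_h_ppm`,
#'   `delta_n_ppm`: shift changes at `maxDmsoFraction` co-solvent, no ligand.
#' @slot maxDmsoFraction co-solvent volume fraction of the DMSO-only
#'   reference experiment.
#' @export
setClass("TitrationSeries",
  representation(points = "data.frame", shifts = "data.frame",
                 dmsoReference = "data.frame", maxDmsoFraction = "numeric"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  pneed <- c("point_index", "ratio", "protein_mM", "ligand_mM", "dmso_fraction")
  if (!all(pneed %in% names(object@points)))
    msg <- c(msg, paste("points must contain:", paste(pneed, collapse = ", ")))
  else {
    if (any(object@points$protein_mM < 0) || any(object@points$ligand_mM < 0))
      msg <- c(msg, "concentrations must be >= 0")
    if (is.unsorted(object@points$ligand_mM))
      msg <- c(msg, "points must be ordered by increasing ligand")
  }
  sneed <- c("residue", "point_index", "delta_h_ppm", "delta_n_ppm")
  if (!all(sneed %in% names(object@shifts)))
    msg <- c(msg, paste("shifts must contain:", paste(sneed, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Dissociation-constant fit from a titration
#'
#' @slot perResidue data.frame: `residue`, `kd_mM`, `kd_sigma_mM`,
#'   `ddmax_ppm`, `max_csp_ppm`, `qualifies`, `flagged_nonmonotone`.
#' @slot meanKd,sdKd unweighted mean and sd of per-residue KD over residues
#'   passing the CSP threshold (mM).
#' @slot threshold CSP qualification threshold in ppm.
#' @slot residuesUsed residues entering the mean.
#' @slot nPoints titration points used.
#' @export
setClass("BindingFit",
  representation(perResidue = "data.frame", meanKd = "numeric", sdKd = "numeric",
                 threshold = "numeric", residuesUsed = "integer",
                 nPoints = "integer"))

setValidity("BindingFit", function(object) {
  if (length(object@meanKd) == 1L && is.finite(object@meanKd) &&
      object@meanKd <= 0) "meanKd must be positive" else TRUE
})

## ---------------------------------------------------------------------------
## Ligand-observed kinetics
## ---------------------------------------------------------------------------

#' Ligand-observed dispersion series
#'
#' 1H dispersion curves of one ligand proton at several protein
#' concentrations (saturation levels), including a zero-protein control.
#'
#' @slot samples data.frame: `sample_id`, `protein_uM`, `ligand_mM`,
#'   `saturation` (bound fraction of the ligand, in [0, 0.5)).
#' @slot rates data.frame: `sample_id`, `nu_cpmg_hz`, `r2_eff`, `sigma`.
#' @slot proton proton label (e.g. `"H6"`).
#' @slot relaxTime CPMG period (s); @slot filterTime relaxation filter (s).
#' @slot fieldMhz spectrometer 1H frequency (MHz).
#' @export
setClass("LigandRDSeries",
  representation(samples = "data.frame", rates = "data.frame",
                 proton = "character", relaxTime = "numeric",
                 filterTime = "numeric", fieldMhz = "numeric"))

setValidity("LigandRDSeries", function(object) {
  msg <- character()
  if (any(object@samples$saturation < 0 | object@samples$saturation >= 0.5))
    msg <- c(msg, "saturation must lie in [0, 0.5)")
  if (!any(object@samples$saturation == 0))
    msg <- c(msg, "a zero-protein control sample is required")
  if (!all(object@rates$sample_id %in% object@samples$sample_id))
    msg <- c(msg, "rates reference unknown sample_id")
  if (length(msg)) msg else TRUE
})

#' Ligand off-rate fit
#'
#' @slot koff,koffSigma ligand release rate and Monte Carlo uncertainty (1/s).
#' @slot deltaOmegaPpm shared free/bound 1H shift difference (ppm).
#' @slot r2Free,r2Bound intrinsic rates of free and bound ligand (1/s).
#' @slot chisq,nobs,npar fit statistics.
#' @slot saturations per-sample bound fractions used.
#' @slot convergence optimizer diagnostics; @slot mc Monte Carlo details.
#' @export
setClass("LigandKineticsFit",
  representation(koff = "numeric", koffSigma = "numeric",
                 deltaOmegaPpm = "numeric", r2Free = "numeric",
                 r2Bound = "numeric", chisq = "numeric", nobs = "integer",
                 npar = "integer", saturations = "numeric",
                 convergence = "list", mc = "list"))

setValidity("LigandKineticsFit", function(object) {
  if (object@koff <= 0) "koff must be positive" else TRUE
})

## ---------------------------------------------------------------------------
## Flexibility profile
## ---------------------------------------------------------------------------

#' Per-residue flexibility profile
#'
#' Dispersion amplitudes for every sequence position, with explicit
#' missing-data reasons and threshold bins.
#'
#' @slot profile data.frame: `residue`, `delta_r2_eff` (1/s or NA),
#'   `missing_reason` (`NA` if measured, else one of `"gap"`, `"overlap"`,
#'   `"proline"`, `"unassigned"`, `"not_fit"`), `bin` (`"<1"`, `"[1,5)"`,
#'   `"[5,10)"`, `">=10"` or NA).
#' @slot fieldMhz field the amplitudes refer to.
#' @slot protein protein label.
#' @export
setClass("FlexibilityProfile",
  representation(profile = "data.frame", fieldMhz = "numeric",
                 protein = "character"))

.MISSING_REASONS <- c("gap", "overlap", "proline", "unassigned", "not_fit")
.FLEX_BINS <- c("<1", "[1,5)", "[5,10)", ">=10")

setValidity("FlexibilityProfile", function(object) {
  msg <- character()
  need <- c("residue", "delta_r2_eff", "missing_reason", "bin")
  if (!all(need %in% names(object@profile)))
    msg <- c(msg, paste("profile must contain:", paste(need, collapse = ", ")))
  else {
    p <- object@profile
    bad <- !is.na(p$missing_reason) & !p$missing_reason %in% .MISSING_REASONS
    if (any(bad)) msg <- c(msg, "unknown missing_reason")
    if (any(is.na(p$delta_r2_eff) & is.na(p$missing_reason)))
      msg <- c(msg, "missing amplitudes must carry a reason")
    ok <- !is.na(p$delta_r2_eff)
    if (any(ok & is.na(p$bin)))
      msg <- c(msg, "measured amplitudes must be binned")
    if (any(ok) && !all(p$bin[ok] == classifyFlexibility(p$delta_r2_eff[ok])))
      msg <- c(msg, "bin inconsistent with delta_r2_eff")
  }
  if (length(msg)) msg else TRUE
})
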