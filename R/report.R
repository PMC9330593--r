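#' Summarize a flexibility profile
#'
#' Percentages of evaluable residues per amplitude bin (and the total above
#' 1/s), with missing positions counted separately by reason. Percentages
#' use evaluable residues as the denominator and are reported to one
#' decimal.
#'
#' @param profile a [FlexibilityProfile-class].
#' @return list with `protein`, `n_evaluable`, `n_missing`,
#'   `missing_by_reason`, `pct_nonflat` (amplitude > 1/s), and `pct_bins`
#'   (named by bin).
#' @export
summarizeProtein <- function(profile) {
  stopifnot(is(profile, "FlexibilityProfile"))
  p <- profile@profile
  ev <- p[!is.na(p$delta_r2_eff), ]
  if (!nrow(ev)) stop("profile has no evaluable residues")
  pct <- function(k) round(100 * k / nrow(ev), 1)
  bins <- table(factor(ev$bin, levels = .FLEX_BINS))
  list(protein = profile@protein,
       n_evaluable = nrow(ev),
       n_missing = sum(!is.na(p$missing_reason)),
       missing_by_reason = table(p$missing_reason),
       pct_nonflat = pct(sum(ev$delta_r2_eff > 1)),
       pct_bins = setNames(pct(as.numeric(bins)), names(bins)))
}

#' Assignment completeness percentage
#'
#' @param nAssigned number of assigned residues.
#' @param nAssignable number of assignable residues.
#' @return percentage to one decimal.
#' @examples
#' assignmentCompleteness(144, 146) # 98.6
#' @export
assignmentCompleteness <- function(nAssigned, nAssignable) {
  if (nAssignable <= 0) stop("nAssignable must be positive")
  if (nAssigned > nAssignable) stop("nAssigned exceeds nAssignable")
  round(100 * nAssigned / nAssignable, 1)
}

#' Amplitude heat-map matrix across proteins
#'
#' Arranges per-protein amplitude profiles into a protein-by-position
#' matrix with a parallel matrix of missing-reason codes; positions a
#' protein does not cover under the common numbering are `"gap"`. An
#' optional alignment table maps native residue numbers onto a common
#' numbering scheme; the default is the identity mapping. No values are
#' imputed.
#'
#' @param profiles named list of [FlexibilityProfile-class] objects.
#' @param residueMap optional data.frame (`protein`, `residue`, `position`)
#'   mapping native numbering to common positions; duplicate mapped
#'   positions within a protein are an error.
#' @return list with `amplitude` (numeric matrix, proteins x positions) and
#'   `reason` (character matrix of missing codes, `NA` where measured).
#' @export
heatmapMatrix <- function(profiles, residueMap = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    names(profiles) <- vapply(profiles, function(p) p@protein, character(1))
  mapFor <- function(name, prof) {
    if (is.null(residueMap))
      return(data.frame(residue = prof$residue, position = prof$residue))
    sub <- residueMap[residueMap$protein == name, c("residue", "position")]
    if (anyDuplicated(sub$position))
      stop("duplicate mapped positions for protein ", name)
    sub
  }
  maps <- lapply(names(profiles), function(nm)
    mapFor(nm, profiles[[nm]]@profile))
  npos <- max(vapply(maps, function(m) max(m$position), numeric(1)))
  amp <- matrix(NA_real_, nrow = length(profiles), ncol = npos,
                dimnames = list(names(profiles), seq_len(npos)))
  reason <- matrix("gap", nrow = length(profiles), ncol = npos,
                   dimnames = dimnames(amp))
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]@profile
    m <- maps[[i]]
    idx <- match(prof$residue, m$residue)
    pos <- m$position[idx]
    keep <- !is.na(pos)
    amp[i, pos[keep]] <- prof$delta_r2_eff[keep]
    reason[i, pos[keep]] <- prof$missing_reason[keep]
  }
  list(amplitude = amp, reason = reason)
}

#' Write / read a heat-map matrix as CSV (lossless)
#'
#' Amplitudes are serialized with full `%.17g` precision so that a write /
#' read cycle reproduces the matrix bit-exactly; the reason matrix is
#' stored alongside.
#'
#' @param hm output of [heatmapMatrix()].
#' @param path CSV path (reasons go to `<path>.reasons.csv`).
#' @return `path` invisibly; `readHeatmapCsv()` returns the list back.
#' @export
writeHeatmapCsv <- function(hm, path) {
  fmt <- apply(hm$amplitude, c(1, 2), function(v)
    if (is.na(v)) "" else sprintf("%.17g", v))
  df <- data.frame(protein = rownames(hm$amplitude), fmt,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  rdf <- data.frame(protein = rownames(hm$reason), hm$reason,
                    check.names = FALSE)
  write.csv(rdf, paste0(path, ".reasons.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeHeatmapCsv
#' @export
readHeatmapCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  amp <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), function(v)
    if (!nzchar(v)) NA_real_ else as.numeric(v))
  rownames(amp) <- df$protein
  rdf <- read.csv(paste0(path, ".reasons.csv"), check.names = FALSE,
                  colClasses = "character")
  reason <- as.matrix(rdf[, -1, drop = FALSE])
  rownames(reason) <- rdf$protein
  reason[reason == "NA" | reason == ""] <- NA_character_
  colnames(amp) <- colnames(reason) <- colnames(df)[-1]
  list(amplitude = amp, reason = reason)
}

#' Binding-site flexibility enrichment
#'
#' For each amplitude threshold, compares the percentage of binding-site
#' residues exceeding it with the percentage among all other evaluable
#' residues.
#'
#' @param profile a [FlexibilityProfile-class].
#' @param siteResidues residue numbers of the binding site.
#' @param thresholds amplitude thresholds in 1/s (default 5 and 10).
#' @return data.frame with one row per threshold: `threshold`,
#'   `site_pct`, `other_pct`, `site_n`, `other_n`, `site_exceed`,
#'   `other_exceed`, plus attribute `"missing_site_residues"`.
#' @export
siteEnrichment <- function(profile, siteResidues, thresholds = c(5, 10)) {
  stopifnot(is(profile, "FlexibilityProfile"))
  if (!length(siteResidues)) stop("empty site residue list")
  p <- profile@profile
  ev <- p[!is.na(p$delta_r2_eff), ]
  missingSite <- setdiff(siteResidues, ev$residue)
  inSite <- ev$residue %in% siteResidues
  out <- do.call(rbind, lapply(thresholds, function(th) {
    data.frame(threshold = th,
               site_pct = round(100 * mean(ev$delta_r2_eff[inSite] > th), 1),
               other_pct = round(100 * mean(ev$delta_r2_eff[!inSite] > th), 1),
               site_n = sum(inSite), other_n = sum(!inSite),
               site_exceed = sum(ev$delta_r2_eff[inSite] > th),
               other_exceed = sum(ev$delta_r2_eff[!inSite] > th))
  }))
  attr(out, "missing_site_residues") <- missingSite
  out
}
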