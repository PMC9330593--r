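#' Build a CpmgExperiment from a tidy intensity table
#'
#' The tidy schema has one row per measured intensity:
#' `residue`, `field_mhz`, `nu_cpmg_hz` (`NA` on reference rows),
#' `intensity`, `is_reference`, `replicate_id`. Rows are arranged into a
#' residue-by-condition `SummarizedExperiment` assay; residues without any
#' data may be declared in `missing` with a reason and appear as all-`NA`
#' rows.
#'
#' @param intensities tidy data.frame as described above.
#' @param relaxTime CPMG relaxation period in seconds.
#' @param nucleus observed nucleus, `"15N"` or `"1H"`.
#' @param truth optional [TwoSiteTruth-class] used to generate the data
#'   (stored in `metadata()` for provenance).
#' @param seed optional integer seed stored alongside.
#' @param missing optional data.frame (`residue`, `reason`) of positions
#'   without data; reasons as in [FlexibilityProfile-class].
#' @return a [CpmgExperiment-class].
#' @export
cpmgExperiment <- function(intensities, relaxTime, nucleus = "15N",
                           truth = NULL, seed = NA_integer_, missing = NULL) {
  need <- c("residue", "field_mhz", "nu_cpmg_hz", "intensity",
            "is_reference", "replicate_id")
  if (!all(need %in% names(intensities)))
    stop("intensities must contain columns: ", paste(need, collapse = ", "))
  nucleus <- match.arg(nucleus, names(.GAMMA_RATIO))
  df <- intensities
  df$residue <- as.integer(df$residue)
  if (any(is.na(df$residue) | df$residue < 1))
    stop("residue ids must be positive integers")
  key <- with(df, paste(residue, field_mhz, nu_cpmg_hz, is_reference,
                        replicate_id))
  if (anyDuplicated(key))
    stop("duplicate (residue, field, nu_cpmg, replicate): ",
         key[duplicated(key)][1])

  resids <- sort(unique(c(df$residue,
                          if (!is.null(missing)) as.integer(missing$residue))))
  cond <- unique(df[order(df$field_mhz, !df$is_reference, df$nu_cpmg_hz,
                          df$replicate_id),
                    c("field_mhz", "nu_cpmg_hz", "is_reference",
                      "replicate_id")])
  rownames(cond) <- NULL
  condKey <- with(cond, paste(field_mhz, nu_cpmg_hz, is_reference,
                              replicate_id))
  mat <- matrix(NA_real_, nrow = length(resids), ncol = nrow(cond),
                dimnames = list(resids, NULL))
  ri <- match(df$residue, resids)
  ci <- match(with(df, paste(field_mhz, nu_cpmg_hz, is_reference,
                             replicate_id)), condKey)
  mat[cbind(ri, ci)] <- df$intensity

  reason <- rep(NA_character_, length(resids))
  if (!is.null(missing)) {
    bad <- setdiff(missing$reason, .MISSING_REASONS)
    if (length(bad)) stop("unknown missing reason: ", bad[1])
    reason[match(as.integer(missing$residue), resids)] <- missing$reason
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    rowData = S4Vectors::DataFrame(residue = resids,
                                   missing_reason = reason),
    colData = S4Vectors::DataFrame(cond))
  S4Vectors::metadata(se) <- list(relax_time = as.numeric(relaxTime),
                                  nucleus = nucleus, truth = truth,
                                  seed = seed,
                                  schema_version = .SCHEMA_VERSION)
  new("CpmgExperiment", se)
}

#' @rdname accessors
setMethod("relaxTime", "CpmgExperiment",
          function(x) S4Vectors::metadata(x)$relax_time)
#' @rdname accessors
setMethod("residues", "CpmgExperiment",
          function(x) SummarizedExperiment::rowData(x)$residue)
#' @rdname accessors
setMethod("fieldsMhz", "CpmgExperiment",
          function(x) sort(unique(SummarizedExperiment::colData(x)$field_mhz)))

#' Tidy intensity table of a CpmgExperiment
#'
#' Inverse of [cpmgExperiment()]: returns the long-format intensity table
#' (measured entries only).
#'
#' @param x a [CpmgExperiment-class].
#' @return data.frame with columns `residue`, `field_mhz`, `nu_cpmg_hz`,
#'   `intensity`, `is_reference`, `replicate_id`.
#' @export
intensityTable <- function(x) {
  stopifnot(is(x, "CpmgExperiment"))
  a <- SummarizedExperiment::assay(x, "intensity")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  res <- SummarizedExperiment::rowData(x)$residue
  out <- do.call(rbind, lapply(seq_len(ncol(a)), function(j) {
    keep <- !is.na(a[, j])
    if (!any(keep)) return(NULL)
    data.frame(residue = res[keep], field_mhz = cd$field_mhz[j],
               nu_cpmg_hz = cd$nu_cpmg_hz[j], intensity = a[keep, j],
               is_reference = cd$is_reference[j],
               replicate_id = cd$replicate_id[j])
  }))
  rownames(out) <- NULL
  out[order(out$residue, out$field_mhz, !out$is_reference, out$nu_cpmg_hz,
            out$replicate_id), , drop = FALSE]
}

#' Write a tidy intensity CSV (with JSON provenance sidecar)
#'
#' Writes the long-format table of a [CpmgExperiment-class] to CSV and, for
#' synthetic data, a `<path>.json` sidecar holding the generating truth,
#' seed and schema version.
#'
#' @param x a [CpmgExperiment-class].
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
writeIntensityTable <- function(x, path, sidecar = TRUE) {
  tab <- intensityTable(x)
  write.csv(tab, path, row.names = FALSE)
  md <- S4Vectors::metadata(x)
  if (sidecar) {
    truth <- md$truth
    side <- list(schema_version = .SCHEMA_VERSION,
                 relax_time = md$relax_time, nucleus = md$nucleus,
                 seed = md$seed)
    if (!is.null(truth))
      side$truth <- list(kex = truth@kex, pB = truth@pB,
                         delta_ppm = as.list(truth@deltaPpm),
                         r2_0 = as.data.frame(truth@r20),
                         nucleus = truth@nucleus, seed = truth@seed)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
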