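#' Plot a dispersion curve with an optional fitted model
#'
#' @param curve a [DispersionCurve-class].
#' @param fit optional [ClusterFitResult-class] covering the residue; the
#'   fitted model curve is overlaid.
#' @return a ggplot object.
#' @export
plotDispersion <- function(curve, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(nu = curve@nuCpmg, r2 = curve@r2eff, sigma = curve@sigma)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = nu, y = r2)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = r2 - sigma,
                                        ymax = r2 + sigma), width = 0) +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * ",eff"] ~ (s^-1)),
                  title = sprintf("residue %d, %g MHz", curve@residue,
                                  curve@fieldMhz))
  if (!is.null(fit)) {
    rc <- as.character(curve@residue)
    r20 <- fit@r20$r2_0[fit@r20$residue == curve@residue &
                        fit@r20$field_mhz == curve@fieldMhz]
    nuGrid <- seq(min(curve@nuCpmg), max(curve@nuCpmg), length.out = 80)
    model <- modelR2effClosed(fit@kex, fit@pB, fit@deltaPpm[rc], r20,
                              curve@fieldMhz, fit@nucleus, nuGrid,
                              fit@relaxTime)
    p <- p + ggplot2::geom_line(
      data = data.frame(nu = nuGrid, r2 = model),
      ggplot2::aes(x = nu, y = r2), colour = "firebrick")
  }
  p
}

#' Stacked flexibility-bin percentages across proteins
#'
#' Mirrors the per-protein comparison of nonflat residues: one stacked bar
#' per protein, colored by amplitude bin.
#'
#' @param profiles named list of [FlexibilityProfile-class] objects.
#' @return a ggplot object.
#' @export
plotFlexibilityBins <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- do.call(rbind, lapply(names(profiles), function(nm) {
    s <- summarizeProtein(profiles[[nm]])
    data.frame(protein = nm, bin = factor(names(s$pct_bins),
                                          levels = rev(.FLEX_BINS)),
               pct = as.numeric(s$pct_bins))
  }))
  ggplot2::ggplot(df[df$bin != "<1", ],
                  ggplot2::aes(x = protein, y = pct, fill = bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "% residues", x = NULL,
                  fill = expression(Delta * R[2 * ",eff"] ~ (s^-1))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
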