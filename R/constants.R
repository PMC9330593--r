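#' Gyromagnetic ratios relative to the proton
#'
#' Single source of truth for converting chemical-shift differences in ppm
#' into angular frequencies. The ratio for 15N is the magnitude of
#' gamma(15N)/gamma(1H) = 0.101329; 1H is 1 by definition.
#'
#' @keywords internal
.GAMMA_RATIO <- c("15N" = 0.101329, "1H" = 1.0)

#' Larmor frequency of a nucleus at a given spectrometer field
#'
#' Spectrometer fields are quoted, as is conventional, by the proton
#' resonance frequency in MHz. The frequency of another nucleus is that
#' value scaled by its gyromagnetic ratio relative to 1H.
#'
#' @param nucleus `"15N"` or `"1H"`.
#' @param fieldMhz spectrometer 1H frequency in MHz (e.g. 600, 700).
#' @return Nucleus resonance frequency in MHz. One ppm of chemical shift for
#'   this nucleus corresponds to that many Hz.
#' @examples
#' nucleusFrequencyMHz("15N", 700) # ~70.9 MHz
#' @export
nucleusFrequencyMHz <- function(nucleus, fieldMhz) {
  nucleus <- match.arg(nucleus, names(.GAMMA_RATIO))
  stopifnot(is.numeric(fieldMhz), all(fieldMhz > 0))
  unname(.GAMMA_RATIO[[nucleus]]) * fieldMhz
}

#' Convert a chemical-shift difference in ppm to rad/s
#'
#' @inheritParams nucleusFrequencyMHz
#' @param deltaPpm shift difference in ppm.
#' @return Angular frequency difference in rad/s.
#' @export
ppmToRadPerSec <- function(deltaPpm, fieldMhz, nucleus) {
  2 * pi * deltaPpm * nucleusFrequencyMHz(nucleus, fieldMhz)
}

## Residue cluster membership for the Ara h 8.0101 subglobal fits:
## 26 beta-strand/loop residues and 20 alpha-helix residues (native
## 1-based numbering) whose 700 MHz dispersion amplitudes exceed 1/s.
.ARAH8_SHEET_RESIDUES <- as.integer(c(
  37, 38, 39, 41, 43, 47, 50, 53, 55, 56, 66, 67, 73, 74,
  84, 87, 88, 89, 97, 98, 99, 100, 101, 102, 115, 118
))
.ARAH8_HELIX_RESIDUES <- as.integer(c(
  16, 17, 20, 21, 22, 23, 24, 25, 27, 31, 33,
  123, 128, 134, 137, 138, 139, 145, 146, 156
))

## Schema version stamped into all file outputs.
.SCHEMA_VERSION <- "cpmgrd-1"
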