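#' Construct a CPMG schedule
#'
#' @param relaxTime total CPMG relaxation period in seconds.
#' @param nCycles integer echo-cycle counts; the CPMG frequencies are
#'   `nCycles / relaxTime`.
#' @param fields spectrometer 1H frequencies in MHz.
#' @param repeats subset of `nCycles` measured twice (for error estimation).
#' @return a [CpmgSchedule-class].
#' @examples
#' cpmgSchedule(0.030, c(1, 2, 4, 8), fields = 700, repeats = 2)
#' @export
cpmgSchedule <- function(relaxTime, nCycles, fields, repeats = integer()) {
  new("CpmgSchedule", relaxTime = as.numeric(relaxTime),
      nCycles = as.integer(nCycles), fields = as.numeric(fields),
      repeats = as.integer(repeats))
}

#' Standard backbone-amide 15N CPMG schedule
#'
#' Twelve CPMG frequencies between 33.3 and 933.3 Hz over a 30 ms constant
#' relaxation period, with repeat experiments at 66.7 and 600 Hz, recorded
#' at 600 and 700 MHz by default.
#'
#' @param fields spectrometer 1H frequencies in MHz.
#' @return a [CpmgSchedule-class].
#' @export
backboneSchedule <- function(fields = c(600, 700)) {
  cpmgSchedule(0.030, c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 14L, 18L, 22L, 28L),
               fields = fields, repeats = c(2L, 18L))
}

#' Ligand-observed 1H CPMG schedule
#'
#' Sixteen CPMG frequencies between 66.7 and 2000 Hz over a 60 ms CPMG
#' element, with repeats at 400, 933.3 and 1600 Hz, recorded at 600 MHz.
#'
#' @param fields spectrometer 1H frequency in MHz.
#' @return a [CpmgSchedule-class].
#' @export
ligandSchedule <- function(fields = 600) {
  cpmgSchedule(0.060,
               c(4L, 8L, 16L, 24L, 32L, 40L, 48L, 56L, 64L, 72L, 80L, 88L,
                 96L, 104L, 112L, 120L),
               fields = fields, repeats = c(24L, 56L, 96L))
}
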