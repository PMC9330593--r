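## shared fixture builders (everything is generated in code)

## small synthetic truth: n residues, shift differences spread over
## [0.5, 3] ppm, intrinsic rate 15 /s at both fields
smallTruth <- function(n = 6, kex = 900, pB = 0.05, seed = 21L,
                       fields = c(600, 700)) {
  delta <- setNames(seq(0.5, 3, length.out = n), seq_len(n))
  twoSiteTruth(kex, pB, delta, r20 = 15, fields = fields, seed = seed)
}

smallCluster <- function(n = 6, name = "small") {
  new("ClusterSpec", name = name, members = seq_len(as.integer(n)),
      threshold = 1)
}

## one flat noisy curve at 700 MHz on the backbone schedule
flatCurve <- function(sigma = 0.3, r20 = 15, seed = NULL) {
  nu <- scheduleFrequencies(backboneSchedule(700))
  if (!is.null(seed)) set.seed(seed)
  new("DispersionCurve", residue = 1L, fieldMhz = 700, nuCpmg = nu,
      r2eff = r20 + rnorm(length(nu), 0, sigma),
      sigma = rep(max(sigma, 0.05), length(nu)),
      relaxTime = 0.030, nucleus = "15N")
}

## noiseless model curve as a DispersionCurve
modelCurve <- function(kex, pB, delta, r20 = 15, field = 700,
                       sigma = 0.3) {
  nu <- scheduleFrequencies(backboneSchedule(field))
  new("DispersionCurve", residue = 1L, fieldMhz = field, nuCpmg = nu,
      r2eff = modelR2effClosed(kex, pB, delta, r20, field, "15N", nu, 0.030),
      sigma = rep(sigma, length(nu)), relaxTime = 0.030, nucleus = "15N")
}
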