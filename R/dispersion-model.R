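## Two-site exchange model for CPMG relaxation dispersion.
##
## The transverse magnetization of a spin exchanging between a major state A
## (population pA, offset 0) and a minor state B (population pB, offset
## dw rad/s) evolves under the 2x2 complex matrix
##
##   L = [ -(R2A + kAB)        kBA          ]
##       [   kAB          -(R2B + kBA) - i*dw ]
##
## with kAB = kex*pB, kBA = kex*pA. A CPMG element is tau - 180 - tau with
## tau = relaxTime/(2*nCycles); an ideal 180 pulse conjugates the complex
## magnetization. The effective rate is
## R2eff = -ln|MA(T) + MB(T)| / T with M(0) = (pA, pB).
##
## modelR2effClosed() evaluates this exactly by analytic eigendecomposition
## of the 2x2 matrices (the two-cycle propagator E Conj(E) Conj(E) E is
## complex-linear and is raised to the half cycle count in closed form).
## modelR2effNumeric() is the independent brute-force oracle: a
## scaling-and-squaring matrix exponential and an explicit pulse-by-pulse
## loop.

## vectorized exact evaluator; dwRad/nCycles/r2a/r2b recycled to a common
## length; r2a/r2b are the intrinsic rates of states A and B
.r2effExact <- function(kex, pB, dwRad, r2a, r2b, nCycles, relaxTime) {
  m <- max(length(dwRad), length(nCycles), length(r2a), length(r2b))
  dw <- rep_len(as.numeric(dwRad), m)
  n <- rep_len(as.integer(round(nCycles)), m)
  r2aV <- rep_len(r2a, m)
  r2bV <- rep_len(r2b, m)
  stopifnot(all(n >= 1L), relaxTime > 0, kex >= 0, pB >= 0, pB <= 0.5)
  pA <- 1 - pB
  ## no minor state: pure exponential decay of A at its intrinsic rate
  if (pB == 0) return(r2aV)
  kab <- kex * pB
  kba <- kex * pA
  tau <- relaxTime / (2 * n)

  a11 <- complex(real = -(r2aV + kab))
  a22 <- complex(real = -(r2bV + kba), imaginary = -dw)
  ## eigen of L
  s <- sqrt((a11 - a22)^2 + 4 * kab * kba)
  l1 <- (a11 + a22 + s) / 2
  l2 <- (a11 + a22 - s) / 2
  e1 <- exp(l1 * tau)
  e2 <- exp(l2 * tau)
  ## E = expm(L*tau) via spectral projectors
  e11 <- (e1 * (a11 - l2) - e2 * (a11 - l1)) / s
  e22 <- (e1 * (a22 - l2) - e2 * (a22 - l1)) / s
  eoff <- (e1 - e2) / s
  e12 <- eoff * kba
  e21 <- eoff * kab
  ## degenerate eigenvalues: first-order expansion of expm
  deg <- Mod(s) * tau < 1e-9
  if (any(deg)) {
    lm <- (a11[deg] + a22[deg]) / 2
    em <- exp(lm * tau[deg])
    e11[deg] <- em * (1 + (a11[deg] - lm) * tau[deg])
    e22[deg] <- em * (1 + (a22[deg] - lm) * tau[deg])
    e12[deg] <- em * kba * tau[deg]
    e21[deg] <- em * kab * tau[deg]
  }
  ## A = E %*% Conj(E); M2 = A %*% Conj(A) is the two-cycle propagator
  f11 <- Conj(e11); f12 <- Conj(e12); f21 <- Conj(e21); f22 <- Conj(e22)
  A11 <- e11 * f11 + e12 * f21
  A12 <- e11 * f12 + e12 * f22
  A21 <- e21 * f11 + e22 * f21
  A22 <- e21 * f12 + e22 * f22
  g11 <- Conj(A11); g12 <- Conj(A12); g21 <- Conj(A21); g22 <- Conj(A22)
  M11 <- A11 * g11 + A12 * g21
  M12 <- A11 * g12 + A12 * g22
  M21 <- A21 * g11 + A22 * g21
  M22 <- A21 * g12 + A22 * g22

  h <- n %/% 2L
  va <- complex(real = rep(pA, m))
  vb <- complex(real = rep(pB, m))
  ## v <- M2^h v  (analytic eigendecomposition of M2)
  trM <- M11 + M22
  sM <- sqrt(trM^2 - 4 * (M11 * M22 - M12 * M21))
  mu1 <- (trM + sM) / 2
  mu2 <- (trM - sM) / 2
  pos <- h > 0L
  if (any(pos)) {
    w1a <- ((M11 - mu2) * va + M12 * vb) / sM
    w1b <- (M21 * va + (M22 - mu2) * vb) / sM
    w2a <- va - w1a
    w2b <- vb - w1b
    p1 <- mu1^h
    p2 <- mu2^h
    nva <- p1 * w1a + p2 * w2a
    nvb <- p1 * w1b + p2 * w2b
    degM <- Mod(sM) < 1e-13 * Mod(trM)
    if (any(degM)) {
      ## defective/degenerate 2x2: M2^h = mu^h (I + h (M2 - mu I)/mu)
      mu <- trM[degM] / 2
      hd <- h[degM]
      na <- (M11[degM] - mu) * va[degM] + M12[degM] * vb[degM]
      nb <- M21[degM] * va[degM] + (M22[degM] - mu) * vb[degM]
      nva[degM] <- mu^hd * (va[degM] + hd * na / mu)
      nvb[degM] <- mu^hd * (vb[degM] + hd * nb / mu)
    }
    va[pos] <- nva[pos]
    vb[pos] <- nvb[pos]
  }
  odd <- n %% 2L == 1L
  if (any(odd)) {
    ## one remaining cycle: v -> E Conj(E v)
    ua <- Conj(e11[odd] * va[odd] + e12[odd] * vb[odd])
    ub <- Conj(e21[odd] * va[odd] + e22[odd] * vb[odd])
    va[odd] <- e11[odd] * ua + e12[odd] * ub
    vb[odd] <- e21[odd] * ua + e22[odd] * ub
  }
  -log(Mod(va + vb)) / relaxTime
}

## extrapolated zero-frequency rate: slowest-decaying eigenvalue of L
.r2effZero <- function(kex, pB, dwRad, r2a, r2b) {
  m <- max(length(dwRad), length(r2a), length(r2b))
  dw <- rep_len(as.numeric(dwRad), m)
  r2aV <- rep_len(r2a, m)
  r2bV <- rep_len(r2b, m)
  if (pB == 0 || kex == 0) return(r2aV)
  kab <- kex * pB
  kba <- kex * (1 - pB)
  a11 <- complex(real = -(r2aV + kab))
  a22 <- complex(real = -(r2bV + kba), imaginary = -dw)
  s <- sqrt((a11 - a22)^2 + 4 * kab * kba)
  -pmax(Re((a11 + a22 + s) / 2), Re((a11 + a22 - s) / 2))
}

.checkModelArgs <- function(kex, pB, deltaPpm, fieldMhz, nucleus) {
  if (any(kex < 0)) stop("kex must be >= 0")
  if (any(pB < 0 | pB > 0.5)) stop("pB must lie in [0, 0.5]")
  if (any(fieldMhz <= 0)) stop("fieldMhz must be positive")
  match.arg(nucleus, names(.GAMMA_RATIO))
}

#' Exact two-site exchange CPMG model (closed form)
#'
#' Effective transverse relaxation rate of a nucleus exchanging between two
#' sites, for a CPMG echo train of total length `relaxTime` at CPMG
#' frequency `nuCpmg = nCycles / relaxTime`. The evaluation is exact for
#' in-phase magnetization and ideal pulses: the 2x2 evolution matrices are
#' diagonalized analytically, so this agrees with the Bloch-McConnell
#' propagator [modelR2effNumeric()] to machine precision. Both intrinsic
#' rates are assumed equal (`r2_0`), which makes `r2_0` a pure additive
#' offset of the curve.
#'
#' `nuCpmg = 0` returns the extrapolated zero-frequency rate (the rate of
#' the slowest-decaying free-precession eigenmode) and `nuCpmg = Inf` the
#' fully refocused plateau `r2_0`; the dispersion amplitude is their
#' difference. Finite frequencies are mapped to the nearest integer cycle
#' count.
#'
#' @param kex exchange rate constant in 1/s.
#' @param pB minor-state population (0 to 0.5).
#' @param deltaPpm absolute shift difference between the states (ppm); only
#'   its magnitude enters the model.
#' @param r2_0 intrinsic transverse rate (1/s), shared by both states.
#' @param fieldMhz spectrometer 1H frequency (MHz).
#' @param nucleus `"15N"` or `"1H"`.
#' @param nuCpmg CPMG frequencies (Hz); may include 0 and `Inf`.
#' @param relaxTime CPMG period in seconds (default 0.030).
#' @return vector of effective rates (1/s), one per `nuCpmg`.
#' @seealso [modelR2effNumeric()], [dispersionAmplitude()]
#' @examples
#' nu <- c(33.3, 66.7, 133.3, 266.7, 533.3, 933.3)
#' modelR2effClosed(1000, 0.05, 2, 15, 700, "15N", nu)
#' @export
modelR2effClosed <- function(kex, pB, deltaPpm, r2_0, fieldMhz, nucleus,
                             nuCpmg, relaxTime = 0.030) {
  .checkModelArgs(kex, pB, deltaPpm, fieldMhz, nucleus)
  if (r2_0 <= 0) stop("r2_0 must be positive")
  dw <- ppmToRadPerSec(abs(deltaPpm), fieldMhz, nucleus)
  out <- numeric(length(nuCpmg))
  zero <- nuCpmg == 0
  inf <- is.infinite(nuCpmg)
  fin <- !zero & !inf
  if (any(zero)) out[zero] <- .r2effZero(kex, pB, dw, r2_0, r2_0)
  if (any(inf)) out[inf] <- r2_0  # population-average plateau, R2A = R2B
  if (any(fin)) {
    n <- pmax(1L, as.integer(round(nuCpmg[fin] * relaxTime)))
    out[fin] <- .r2effExact(kex, pB, dw, r2_0, r2_0, n, relaxTime)
  }
  out
}

## 2x2 complex matrix exponential, scaling-and-squaring with Taylor series
.expm2c <- function(M) {
  nrm <- max(abs(M))
  k <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0
  A <- M / 2^k
  E <- diag(2) + 0i
  term <- diag(2) + 0i
  for (j in 1:40) {
    term <- (term %*% A) / j
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(k)) E <- E %*% E
  E
}

#' Numerical Bloch-McConnell CPMG oracle
#'
#' Brute-force reference for [modelR2effClosed()]: propagates the two-state
#' transverse magnetization through the explicit tau-180-tau echo sequence,
#' cycle by cycle, using a scaling-and-squaring matrix exponential of the
#' 2x2 complex evolution matrix. Intrinsic rates may differ between the
#' states.
#'
#' @inheritParams modelR2effClosed
#' @param r2_0A,r2_0B intrinsic rates of states A and B (1/s).
#' @param nCycles integer vector of echo-cycle counts.
#' @return vector of effective rates (1/s), one per `nCycles`.
#' @export
modelR2effNumeric <- function(kex, pB, deltaPpm, r2_0A, r2_0B, fieldMhz,
                              nucleus, nCycles, relaxTime = 0.030) {
  .checkModelArgs(kex, pB, deltaPpm, fieldMhz, nucleus)
  nCycles <- as.integer(nCycles)
  if (any(nCycles < 1L)) stop("nCycles must be >= 1")
  if (relaxTime <= 0) stop("relaxTime must be positive")
  dw <- ppmToRadPerSec(abs(deltaPpm), fieldMhz, nucleus)
  pA <- 1 - pB
  kab <- kex * pB
  kba <- kex * pA
  L <- matrix(c(complex(real = -(r2_0A + kab)), complex(real = kab),
                complex(real = kba),
                complex(real = -(r2_0B + kba), imaginary = -dw)),
              nrow = 2)
  vapply(nCycles, function(n) {
    tau <- relaxTime / (2 * n)
    E <- .expm2c(L * tau)
    v <- c(complex(real = pA), complex(real = pB))
    for (i in seq_len(n)) v <- E %*% Conj(E %*% v)
    -log(Mod(sum(v))) / relaxTime
  }, numeric(1))
}

## Exchange contribution grid used by the fitting code: matrix of
## Rex(deltaPpm, nCycles) at zero intrinsic rate. Rows = deltaGrid entries.
.rexGrid <- function(kex, pB, deltaGridPpm, nCycles, relaxTime, fieldMhz,
                     nucleus) {
  dw <- ppmToRadPerSec(deltaGridPpm, fieldMhz, nucleus)
  nd <- length(dw)
  nn <- length(nCycles)
  r <- .r2effExact(kex, pB, rep(dw, times = nn), 0, 0,
                   rep(nCycles, each = nd), relaxTime)
  matrix(r, nrow = nd, ncol = nn)
}

## Dispersion amplitude R2eff(0) - R2eff(Inf) implied by model parameters
## (independent of r2_0 when both states share the intrinsic rate).
.modelAmplitude <- function(kex, pB, deltaPpm, fieldMhz, nucleus) {
  dw <- ppmToRadPerSec(abs(deltaPpm), fieldMhz, nucleus)
  .r2effZero(kex, pB, dw, 0, 0)
}
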