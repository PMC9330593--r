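---
title: "Quantifying millisecond protein dynamics and ligand exchange by CPMG relaxation dispersion"
author: "cpmgrd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying millisecond protein dynamics and ligand exchange by CPMG relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgrd)
```

## Scope

`cpmgrd` analyses Carr-Purcell-Meiboom-Gill (CPMG) relaxation-dispersion
NMR data of the kind used to map millisecond-timescale conformational
exchange in PR-10 food allergens and to characterize weak ligand binding
to their internal cavity. The pipeline covers four experiments:

1. **Backbone-amide ^15^N dispersion** at one or two magnetic fields:
   peak intensities are converted to effective rates, per-residue
   dispersion amplitudes are extracted, and clusters of residues are
   fitted jointly to a two-site exchange model with Monte Carlo
   uncertainties.
2. **Model comparison** between one shared exchange process and two
   secondary-structure-specific processes.
3. **Chemical-shift titrations** for per-residue and mean 1:1
   dissociation constants, with co-solvent drift correction.
4. **Ligand-observed ^1^H dispersion** at increasing protein saturation
   for the ligand off-rate and residence time.

Because raw spectra for such studies are typically not deposited, the
package ships a synthetic-data generator built on the same exchange
physics; every downstream stage is exercised end to end on generated
inputs with known ground truth.

## The two-site exchange model

A nucleus exchanging between a major state A (population $p_A$) and a
sparsely populated state B ($p_B = 1 - p_A$) with total rate constant
$k_{ex} = k_{AB} + k_{BA}$ and chemical-shift difference $\Delta\omega$
(rad/s) evolves, in the rotating frame, under

$$
\frac{d}{dt}
\begin{pmatrix} M_A \\ M_B \end{pmatrix} =
\begin{pmatrix}
-R_{2A}^0 - k_{AB} & k_{BA} \\
k_{AB} & -R_{2B}^0 - k_{BA} - i\,\Delta\omega
\end{pmatrix}
\begin{pmatrix} M_A \\ M_B \end{pmatrix},
$$

with $k_{AB} = p_B\,k_{ex}$ and $k_{BA} = p_A\,k_{ex}$. During a CPMG
element the magnetization passes through $n$ repetitions of
$\tau\text{--}180^\circ\text{--}\tau$ with $\tau = T_{relax}/(2n)$; an
ideal $180^\circ$ pulse conjugates the complex magnetization. The
effective rate reported by the experiment is

$$
R_{2,\mathrm{eff}} = -\frac{1}{T_{relax}}
  \ln\frac{I(\nu_{CPMG})}{I_0},
\qquad \nu_{CPMG} = \frac{n}{T_{relax}},
$$

which the model mirrors as $-\ln |M_A(T) + M_B(T)| / T_{relax}$ with
$M(0) = (p_A, p_B)$.

`modelR2effClosed()` evaluates this **exactly**: the $2\times 2$ complex
matrix exponential is written in terms of its analytic eigendecomposition,
the two-cycle propagator $E\,\bar E\,\bar E\,E$ (which, unlike a single
conjugation step, is complex-linear) is raised to the half cycle count in
closed form, and odd cycle counts receive one explicit extra cycle. The
independent oracle `modelR2effNumeric()` obtains the same quantity by a
scaling-and-squaring matrix exponential and an explicit pulse-by-pulse
loop; the test suite demands agreement to 1% over
$k_{ex} \in [100, 6000]$ /s, $p_B \in [0.005, 0.2]$,
$|\Delta\delta| \in [0.2, 4]$ ppm at 600 and 700 MHz (the two routes in
fact agree to machine precision).

Shift differences are supplied in ppm and converted with
$\Delta\omega = 2\pi\,\Delta\delta \cdot \Xi\, B_0^{1H}$, where
$\Xi$ is the gyromagnetic ratio relative to ^1^H (0.101329 for ^15^N, 1
for ^1^H) and $B_0^{1H}$ the spectrometer frequency in MHz. This constant
lives in one place (`nucleusFrequencyMHz()`).

Two limits close the model: $\nu_{CPMG} \to \infty$ refocuses all
exchange dephasing, leaving the population-average intrinsic rate; the
extrapolated $\nu_{CPMG} = 0$ value is the decay rate of the
slowest-decaying free-precession eigenmode. Their difference is the
dispersion amplitude $\Delta R_{2,\mathrm{eff}}$.

One numerical caveat is documented and tested rather than hidden: with
magnitude detection and discrete cycle counts, exact curves in the deep
slow-exchange corner ($k_{ex} \ll \Delta\omega$) show small even/odd-cycle
ripples and are not strictly monotone in $\nu_{CPMG}$; in the
exchange-dominated regime ($k_{ex} \ge \Delta\omega$) curves are strictly
non-increasing. The ripple is bounded in the tests by a quarter of the
dispersion amplitude and is irrelevant at the fitted parameters of the
study system.

## From intensities to rates and uncertainties

Intensities live in a `CpmgExperiment` (a `SummarizedExperiment` with
residues as rows and measurement conditions as columns), built from tidy
CSV or nmrPipe-style peak tables. `computeR2eff()` applies the log-ratio
formula; non-positive intensities are flagged `NA` with a warning, never
silently dropped or zero-filled.

Rate uncertainties come from the repeat experiments: each twice-measured
CPMG frequency yields a rate difference $d$, contributing $|d|/\sqrt 2$;
`sigmaFromRepeats()` pools these per residue (across fields) as a root
mean square, with a floor (default 0.05 /s) so no point gets infinite
weight. With only a handful of repeat pairs per residue this estimate is
itself noisy; pooling across fields rather than per curve noticeably
stabilizes the weights of the global fits.

## Per-residue amplitudes

`amplitudeDeltaR2eff()` fits the full closed form to one curve, with a
bounded multi-start ($k_{ex}$ grid 200/500/1000/2000/4000 /s crossed with
$p_B$ 0.01/0.05/0.15; ties broken toward smaller $k_{ex}$). Two nuisance
dimensions are profiled out: the intrinsic rate analytically (it is an
exact additive offset when both states share it) and $|\Delta\delta|$ on
a fine grid. Single-curve exchange parameters are degenerate -- many
$(k_{ex}, p_B, \Delta\delta)$ triples reproduce twelve in-window points
essentially exactly while their zero-frequency extrapolations differ by a
few percent -- so the *amplitude* is the reported quantity and the
parameters are diagnostics only. Two safeguards keep the extrapolation
honest:

* $k_{ex}$ is bounded to [100, 6000] /s during refinement, the regime in
  which the evaluation is validated;
* the exchange model must beat the constant (no-exchange) model by AIC,
  otherwise the amplitude is exactly 0. This mirrors standard
  model-selection practice in dispersion analysis and calibrates the
  false-positive rate: at the default rate noise of 0.3 /s, fewer than 5%
  of truly flat curves exceed the 1 /s "nonflat" threshold.

Amplitudes are binned (<1, [1,5), [5,10), >=10 /s) into
`FlexibilityProfile` objects; missing positions always carry a reason
(gap, overlap, proline, unassigned, or not_fit for non-convergent
curves). Summaries report percentages over evaluable residues only, to
one decimal -- positions without data are counted separately, never in
the denominator.

## Subglobal cluster fits

`fitSubglobal()` fits all curves of a residue cluster at both fields
jointly: shared $k_{ex}$ and $p_B$, residue-specific $|\Delta\delta|$,
and a free intrinsic rate per residue per field (intrinsic rates differ
across residues and fields; sharing them would bias the exchange terms).
The objective $\sum \left[(y - \hat y)/\sigma\right]^2$ is minimized over
$(\log k_{ex}, \mathrm{logit}\, 2 p_B)$ by Nelder-Mead, multi-started
from a fixed grid ($k_{ex}$ in {200, 500, 800, 1200, 2000, 4000},
$p_B$ in {0.01, 0.03, 0.08, 0.15}); everything else is profiled. The
shift-difference profile is evaluated on a 161-point grid with parabolic
interpolation of the minimum *location*, followed by an exact evaluation
of the objective at that location -- interpolating the *value* can
undershoot badly near sharp minima and was the dominant numerical error
before this refinement. Adding starts can only improve the objective;
this is asserted as a property test.

The cluster memberships of the study system ship as packaged constants
(`araH8Clusters()`): 26 beta-strand/loop residues and 20 helix residues
whose 700 MHz amplitudes exceed 1 /s. On noiseless synthetic data the
fit recovers the generating $(k_{ex}, p_B, \Delta\delta)$ to well below
1%, which also documents that the well-known shallow
$p_B$--$\Delta\delta$ valley at low minor population does not prevent
exact recovery when the data are exact.

`compareModels()` fits one shared process to the pooled residues and one
process per cluster, comparing $\chi^2 + 2k$ (AIC with known Gaussian
errors). The two-process description is declared preferred when AIC
improves by more than 10 -- a deliberately conservative, documented
stand-in for a qualitative "the fits improved significantly" judgement.

### Monte Carlo uncertainties

`monteCarloUncertainty()` implements a parametric bootstrap: 100
synthetic rate sets (default) are drawn from the fitted model plus
Gaussian noise at the experimental $\sigma$, each is refitted
(warm-started from the fit), and parameter uncertainties are standard
deviations over the refits. Refits that fail are excluded; more than 20%
failures triggers a warning. Two caveats are worth knowing:

* the bootstrap is centred on the fitted values, so it quantifies
  noise-driven spread but cannot see estimator *bias*. The shared-rate
  estimator carries a small positive incidental-parameter bias (one
  nuisance shift difference per residue, one offset per curve); at the
  default noise level it is of the order of the Monte Carlo sigma itself,
  so 1-sigma intervals undercover. The same limitation applies to any
  pipeline using this error model;
* uncertainty in the repeat-derived weights is likewise not propagated.

As noise goes to zero the Monte Carlo sigmas vanish; this limit is
tested.

## Titration analysis

The combined amide perturbation is
$\Delta\delta_{obs} = \sqrt{(\Delta\delta_H^2 +
(\Delta\delta_N/5)^2)/2}$, computed after (not before) the co-solvent
correction, which subtracts a linear-in-volume-fraction DMSO contribution
from ^1^H and ^15^N separately, referenced to a DMSO-only spectrum at the
maximum added volume. All trajectories are referenced to the ligand-free
(apo) spectrum; the 2:1 protein:ligand point is an ordinary data point.

Binding is modelled as 1:1 with the exact quadratic solution for the
complex concentration. At 0.2 mM protein and $K_D$ near 0.76 mM, ligand
depletion is substantial at the low-ratio points, and the hyperbolic
(no-depletion) approximation would bias $K_D$; the quadratic costs
nothing and is used throughout. Concentrations at each point track the
stepwise addition from a 90 mM stock into 450 µL (dilution included; at
the top ratio of 30:1, 30 µL of stock has been added, fixing the maximum
DMSO fraction).

`fitKd()` fits $\Delta\delta_{obs} = \Delta\delta_{max}\cdot
f_{bound}(K_D)$ per residue by Levenberg-Marquardt for residues whose
maximum corrected perturbation exceeds 0.1 ppm, and reports the
unweighted mean $\pm$ sd over those residues, mirroring how a
mean-and-spread summary of per-residue constants is usually quoted.
Non-monotone trajectories (Spearman correlation against ligand below
0.8) are kept but flagged.

## Ligand-observed kinetics

The ligand's aromatic protons report on binding through ^1^H dispersion
at 600 MHz (16 frequencies, 60 ms CPMG element). The ligand is a
two-site free/bound exchanger whose bound population equals the
saturation level, so the per-sample exchange rate is
$k_{ex} = k_{off}/(1 - p)$ and the forward rate $k_{off}\,p/(1-p)$.
`fitKoff()` fits all saturations simultaneously, sharing $k_{off}$, the
free/bound shift difference and the two intrinsic rates; per-sample
bound fractions are fixed from `saturationLevels()`. The zero-protein
control enters the fit with $p = 0$ and therefore only constrains the
free-ligand rate -- exactly the role it plays experimentally, where its
flatness also demonstrates that the small scalar coupling between the
two protons does not interfere. The transverse relaxation filter ahead
of the CPMG element scales all intensities of a sample equally and
cancels in $I/I_0$, so it does not enter the model.

Saturation defaults to the stoichiometric convention $P_{tot}/L_{tot}$
(240 µM protein in 2 mM ligand = 12%, matching the stated 0--12% range);
a $K_D$-based convention using the exact isotherm is available as an
option. Uncertainties come from the same parametric bootstrap as the
cluster fits. The residence time is $1000/k_{off}$ ms, reported to one
decimal.

## The synthetic-data generator

`simulateDispersionDataset()` generates intensity tables from a
`TwoSiteTruth` via the numerical propagator, then perturbs on the *rate*
scale: $R_{noisy} = R_{model} + N(0, \sigma^2)$ and
$I = I_0 e^{-R_{noisy} T}$ (equivalently multiplicative log-normal noise
on intensities). Rate-scale noise is the natural choice because
experimental uncertainties are quoted on rates; recomputed rates then
carry exactly the injected Gaussian noise, which the suite verifies
(pooled sd within 10% over >1000 draws). Repeat points receive
independent noise. Defaults:

* noise sigma 0.3 /s -- not a reported experimental value (none is
  stated for these experiments) but a documented choice that makes the
  1 /s nonflat threshold operate at a realistic false-positive rate;
* per-residue $|\Delta\delta|$ drawn uniformly from 0.3--3.5 ppm,
  matching the span of fitted shift differences in the study system;
* intrinsic rates uniform in 12--18 /s, typical backbone ^15^N $R_2^0$
  values for a ~17 kDa protein at 25 °C;
* reference intensities arbitrary (they cancel).

`truthPresets()` returns the published subglobal fit results as ground
truth: helix cluster $k_{ex} = 1060$ /s, $p_B = 0.079$, 20 residues;
sheet/loop cluster $k_{ex} = 810$ /s, $p_B = 0.013$, 26 residues.
`simulateTitrationSeries()` and `simulateLigandDispersion()` provide the
matching titration (17 ratios from 0.5 to 30, dilution tracked, DMSO
drift, ^15^N noise five times the ^1^H noise to mirror the relative
shift scales) and ligand series (saturations 0--12%, default
$\Delta\omega_H$ 0.15 ppm, free/bound rates 1.5 and 20 /s -- chosen to
give dispersion amplitudes of a few to ~15 /s, the magnitude at which
such experiments are practical).

What the generator does **not** emulate: spectral lineshapes, peak
overlap and picking errors, off-resonance and pulse-imperfection
effects, anti-phase coherence and relaxation interference (the
experiments use ^1^H decoupling that justifies the in-phase model),
three-site exchange, temperature or field miscalibration. Passing tests
therefore demonstrate the correctness and calibration of the *analysis*
given the stated error model -- not robustness to every artefact of real
spectra.

All randomness flows from explicit integer seeds; identical seeds give
bit-identical tables, and the pipeline derives per-stage seeds from one
master seed with fixed offsets.

## Problem sizes and tolerances

The shipped tests and the acceptance script use: 10 stochastic datasets
per cluster for parameter recovery (noise 0.3 /s, both fields), Monte
Carlo sizes of 100 in the acceptance script and 12--60 inside the test
suite, 17-point titrations at 0.005 ppm noise, 7-saturation ligand
series, and a 120-combination grid for the closed-form/propagator
cross-check. These sizes were chosen so that each stochastic check sits
comfortably inside its tolerance (e.g. recovered mean $k_{ex}$ within
two Monte Carlo sigmas; $K_D$ within 10%; $k_{off}$ within 15%) while
the whole suite stays quick enough to run routinely.

## Known limitations

* The exact evaluator and its oracle assume ideal, infinitely short
  180° pulses and in-phase magnetization.
* Monte Carlo intervals undercover in the presence of estimator bias
  (see above); quoted uncertainties are noise-driven spreads, as is
  conventional.
* Single-curve exchange parameters are not interpretable; only the
  amplitude is.
* The $K_D$ fit assumes a single binding site and fast exchange on the
  chemical-shift timescale; intermediate-exchange lineshape effects are
  outside scope.
* Random-coil reference shifts for the unfolding comparison are an
  input, not computed here.
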