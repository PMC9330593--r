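# cpmgrd

Analysis of Carr–Purcell–Meiboom–Gill (CPMG) relaxation-dispersion NMR
data: millisecond-timescale conformational exchange in proteins and the
kinetics of weak ligand binding. The package was built around the kind of
study that maps backbone flexibility of PR-10 food allergens (a
seven-stranded β-sheet plus three helices enclosing a ligand cavity) and
probes flavonoid binding to the peanut allergen Ara h 8 — but every stage
is generic for two-site exchange CPMG data.

It is aimed at NMR spectroscopists and structural biologists who have
peak-intensity tables from constant-time CPMG experiments (and, for
binding work, titration peak positions and ligand-observed dispersion
series) and want per-residue flexibility metrics, cluster-level exchange
parameters with honest uncertainties, dissociation constants, and ligand
off-rates from a scripted, reproducible pipeline.

## The model

A nucleus exchanging between a major state A and a minor state B
(populations p_A, p_B; total rate k_ex = k_AB + k_BA; shift difference
Δω) evolves under the 2×2 Bloch–McConnell matrix

    L = [ −R2A − k_AB        k_BA          ]
        [   k_AB        −R2B − k_BA − iΔω  ]

through n repetitions of τ–180°–τ (τ = T_relax/2n, ν_CPMG = n/T_relax),
with ideal 180° pulses acting as complex conjugation. The package
evaluates

    R2,eff(ν_CPMG) = −ln |M_A(T) + M_B(T)| / T_relax

**exactly** by analytic eigendecomposition of the 2×2 propagators
(`modelR2effClosed()`), cross-checked against an independent
matrix-exponential propagation oracle (`modelR2effNumeric()`). On top of
that sit:

* `computeR2eff()` / `sigmaFromRepeats()` — rates from intensities
  (R2,eff = −ln(I/I₀)/T_relax) and uncertainties from repeat experiments;
* `amplitudeDeltaR2eff()` — per-residue dispersion amplitudes
  ΔR2,eff = R2,eff(0) − R2,eff(∞) with an AIC guard against noise-driven
  false positives, binned into flexibility classes (<1, 1–5, 5–10,
  ≥10 s⁻¹);
* `fitSubglobal()` / `monteCarloUncertainty()` / `compareModels()` —
  joint two-field cluster fits with shared (k_ex, p_B), residue-specific
  |Δδ_ex|, per-curve intrinsic rates, parametric-bootstrap errors, and
  one- vs two-process model comparison;
* `fitKd()` — per-residue and mean K_D from combined chemical-shift
  perturbations (Δδ_obs = √((Δδ_H² + (Δδ_N/5)²)/2)), DMSO-drift
  corrected, using the exact 1:1 quadratic isotherm with dilution
  tracking;
* `fitKoff()` — global two-site fit of ligand-observed ¹H dispersion
  across saturation levels for k_off and the residence time 1000/k_off;
* `simulateDispersionDataset()` and friends — a deterministic
  synthetic-data generator on the same physics, with presets carrying the
  published exchange parameters of the two Ara h 8 subglobal clusters;
* `runPipeline()` — YAML-configured orchestration with logging, derived
  seeds, and JSON/CSV outputs.

See the methods vignette (`vignettes/cpmg-dispersion-analysis.Rmd`) for
the full model description, parameter conventions, and design decisions.

## Worked example

Simulate the helix cluster of Ara h 8 at its published exchange
parameters, refit it, and run the two binding branches:

```r
library(cpmgrd)

truth <- truthPresets("arah8_helix")   # kex 1060 /s, pB 0.079, 20 residues
x  <- simulateDispersionDataset(truth, backboneSchedule(), noiseSigma = 0.3, seed = 7)
ds <- dispersionSet(x)
fit <- fitSubglobal(ds, araH8Clusters()$helix)
fit <- monteCarloUncertainty(fit, ds, nDatasets = 100, seed = 8)
fit
#> ClusterFitResult 'arah8_helix' (20 residues)
#>   kex  = 1059 +/- 6.8 /s
#>   pB   = 0.07929 +/- 0.00012
#>   timescale = 0.9 ms, reduced chi^2 = 2.63

fitKd(simulateTitrationSeries(0.76, noisePpm = 0.005, seed = 9))
#> BindingFit: mean KD = 0.76 +/- 0.0296 mM over 12 residues (CSP > 0.1 ppm)

fitKoff(simulateLigandDispersion(1600, noiseSigma = 0.3, seed = 10),
        nBoot = 100, seed = 11)
#> LigandKineticsFit: koff = 1612 +/- 42.9 /s (residence 0.6 ms)
```

Reading the numbers: the joint fit of 480 rate measurements (20 residues
× 2 fields × 12 CPMG frequencies) recovers the generating exchange rate
(1059 vs 1060 s⁻¹) and minor-state population (7.93% vs 7.9%); the Monte
Carlo uncertainties are the standard deviations over 100 refits of
parametrically resimulated data. The exchange timescale 1/k_ex is 0.9 ms.
The 17-point titration returns the generating dissociation constant
(0.76 mM, averaged over the 12 residues whose corrected perturbation
exceeds 0.1 ppm), and the ligand-observed fit across saturations 0–12%
returns the generating off-rate within its bootstrap error, i.e. a
sub-millisecond residence time of the bound ligand.

The complete configured pipeline (both clusters, amplitudes, reports,
both binding branches) runs with:

```r
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml", package = "cpmgrd"))
runPipeline(cfg)
```

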