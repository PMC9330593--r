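# Demonstration pipeline configuration: simulates backbone 15N dispersion
# data for the two Ara h 8.0101 subglobal clusters at 600/700 MHz, fits
# them, estimates Monte Carlo uncertainties, and runs the independent
# titration and ligand-observed branches.
stages:
  - simulate
  - rates
  - amplitudes
  - cluster_fit
  - monte_carlo
  - report
  - titration
  - ligand_rd
seed: 42
outdir: results/demo
simulate:
  presets: [arah8_helix, arah8_sheet]
  fields: [600, 700]
  noise_sigma: 0.3          # rate noise, 1/s
monte_carlo:
  n_datasets: 100
titration:
  kd: 0.76                  # mM
  noise_ppm: 0.005
ligand_rd:
  koff: 1600                # 1/s
  noise_sigma: 0.3
  n_boot: 100
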