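# membrafluor

Steady-state fluorescence analysis of lipid membranes: order, phase
transitions, raft-like domains, and peroxidation protection.

## Who this is for

Membrane biophysicists running cuvette or plate-reader fluorescence
assays on model vesicles (LUVs) or live cells, who need the standard
derived quantities — DPH anisotropy melting parameters, Laurdan GP,
TEMPO-quench raft fractions, cis-parinaric-acid oxidation endpoints —
computed reproducibly from delimited-text exports, with replicate
statistics and seeded synthetic data for validating the whole chain by
parameter recovery.

## The quantities

* **Fluorescence anisotropy** `r = (I_vv − G·I_vh)/(I_vv + 2G·I_vh)`
  with grating factor `G = I_hv/I_hh`: acyl-chain order from DPH
  depolarization.
* **Melting analysis (two-stage)**: a descending Boltzmann sigmoid
  `r(T) = r_fluid + (r_gel − r_fluid)/(1 + exp((T − T_½)/w))` is fitted
  to the melting curve; its analytic first derivative is fitted with a
  Lorentzian peak `y = y₀ + (2A/π)·Γ/(4(T − T_m)² + Γ²)`, giving the
  main transition temperature `T_m` (center) and the Lorentzian peak
  width LPW (`Γ`, an index of transition heterogeneity).
* **Laurdan generalized polarization**
  `GP = (I_440 − I_490)/(I_440 + I_490)`: lipid order at the
  hydrophilic–hydrophobic interface.
* **Raft fraction from TEMPO quenching**: `Q = F/F₀`, inverted through
  `F/F₀ = f_lo + (1 − f_lo)(1 − E)` for the liquid-ordered fraction
  `f_lo` at quenching efficiency `E`.
* **Peroxidation**: fraction oxidized `ox = 1 − F(t_end)/F(0)`,
  endpoint protection factor `p = ox_control/ox_treated`, and a
  first-order decay fit `F(t) = F₀((1 − B)e^{−kt} + B)` with the rate
  ratio as a kinetic diagnostic.
* **Statistics**: replicate mean ± SD, paired t, Tukey HSD with
  `"*"`/`"ns"` coding at α = 0.05.

See `vignettes/membrane-fluorescence-methods.Rmd` for models,
assumptions, parameter defaults and numerical choices.

## Worked example

Simulate a 3-replicate melting scan at a known truth (T_½ = 39.3 °C,
sigmoid width calibrated so the noiseless Lorentzian width is 4.4 °C,
multiplicative intensity noise SD 0.005), then recover the transition:

```r
library(membrafluor)

sim <- simulate_polarized_melt(t_half = 39.3,
                               slope_width = slope_width_for_lpw(4.4),
                               noise_sd = 0.005, n_replicates = 3, seed = 1)
curves <- lapply(split(sim$readings, sim$readings$replicate),
                 anisotropy_curve_from_readings)
melting_analysis(curves)
#> Two-stage melting analysis
#>   T_m  = 39.28 C (Lorentzian center)
#>   LPW  = 4.43 C (Lorentzian FWHM)
#>   per-replicate T_m = 39.28 +/- 0.02 C (n = 3, across-replicate SD)
#>   per-replicate LPW = 4.44 +/- 0.40 C
```

The recovered T_m (39.28 °C) and LPW (4.43 °C) match the simulated truth
within the replicate scatter. The other modalities round-trip the same
way:

```r
spec <- simulate_laurdan_spectrum(gp_target = 0.037)   # ordered-cell regime
generalized_polarization(spec$spectrum)
#> [1] 0.037

ox <- simulate_oxidation(protection = 2.0, noise_sd = 0.01, seed = 1)
fraction_oxidized(ox$control)                 #> 0.776
protection_factor(ox$control, ox$treated)     #> 2.08
```

A protection factor of ~2 means the antioxidant-treated vesicles lost
half as much probe fluorescence (≈ oxidized lipid) as the control by the
endpoint.

## Command line

```sh
Rscript inst/cli/membrafluor simulate melt --seed 1 --out runs/demo
Rscript inst/cli/membrafluor melt --input runs/demo/simulated_melt.csv --out runs/demo
Rscript inst/cli/membrafluor --help
```

Subcommands: `simulate {melt,spectrum,quench,oxidation}`, `melt`, `gp`,
`quench`, `oxidation`, `compare`; common flags `--config`, `--input`,
`--seed`, `--out`, `--verbose`. All outputs are delimited text with a
commented provenance header (version, seed, config hash) plus a JSON run
record; reruns with the same config and seed are byte-identical.

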