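---
title: "Methods: membrane order, phase transitions and peroxidation from steady-state fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane order, phase transitions and peroxidation from steady-state fluorescence}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membrafluor)
```

membrafluor analyzes the four steady-state fluorescence modalities most
often used to characterize lipid-bilayer organization: polarized DPH
emission (acyl-chain order and melting), Laurdan emission spectra
(interfacial polarity / lipid order), DPH quenching by the water-soluble
nitroxide TEMPO (liquid-ordered domain fraction), and cis-parinaric acid
decay under an oxidizing reaction mixture (lipid peroxidation and
antioxidant protection). This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generators emulate, and the limits of what a passing test establishes.

## Fluorescence anisotropy and the melting analysis

DPH partitions into the hydrophobic bilayer core; restriction of its
rotation during the excited-state lifetime polarizes the emission. The
steady-state anisotropy is

r = (I_vv − G I_vh) / (I_vv + 2 G I_vh),   G = I_hv / I_hh,

where the first subscript is the excitation polarizer orientation and the
second the emission analyzer. `anisotropy()` enforces the mathematical
range [−0.5, 1]; the much narrower empirical envelope for DPH in
membranes, about −0.2 to +0.4, is treated as a plausibility band that
warns without failing, because plate-reader noise legitimately produces
excursions. All intensities are assumed blank-corrected; a constant
background subtraction (default 0) is available in
`anisotropy_curve_from_readings()` because blank handling varies between
instruments. Replicate handling computes r per replicate and aggregates
afterwards (mean, SD, n), so the reported SD is the replicate scatter of
the derived quantity, not of raw intensities.

A gel-to-fluid melting scan of r versus temperature is analyzed in two
stages, mirroring the common peak-analysis workflow of commercial fitting
software:

1. `fit_boltzmann()` fits the descending logistic
   r(T) = r_fluid + (r_gel − r_fluid) / (1 + exp((T − t_half)/w)).
   The sigmoid family is a deliberate choice — the data place the probe
   between two plateaus with a cooperative transition, and the logistic is
   the standard analytic form that can be differentiated exactly.
2. `derivative_profile()` evaluates the analytic |dr/dT| on a fine grid
   (default 0.1 °C) over the data window. Finite differencing of 15 raw
   points spaced 2–3 °C would be far too unstable to support a peak fit.
3. `fit_lorentzian()` fits
   y(T) = offset + (2 area/π) · fwhm / (4(T − center)² + fwhm²);
   `center` is reported as the main transition temperature T_m and `fwhm`
   as the Lorentzian peak width (LPW), an index of transition width /
   phase heterogeneity.

`melting_analysis()` chains the three stages, propagates convergence
flags, and raises a structured error naming the failing stage (a flat,
transition-free curve fails at the sigmoid stage). With replicate curves
the headline T_m/LPW come from the replicate-mean curve and the
per-replicate fits supply an across-replicate SD; because it is ambiguous
whether published SDs are replicate SDs or fit standard errors, both
routes exist and the output labels the replicate SD explicitly.

Numerical choices: starts are data-driven (plateaus from the three
lowest/highest-temperature points, midpoint from the nearest
half-crossing with ties to the lowest temperature, w = 1 °C); the
optimizer is `nls` (port algorithm, bounded, `scaleOffset = 1` so exact
noiseless fits converge) with a BFGS polish as fallback; tolerances are
at the optimizer defaults with a 10,000-evaluation cap and all fits are
deterministic given the data.

### The width mapping

For a logistic with steepness w the derivative's analytic FWHM is
4·ln(1+√2)·w ≈ 3.5255·w. A Lorentzian, however, has heavier tails than
the logistic derivative (a sech² shape), so the least-squares FWHM also
depends mildly on the fitting window — empirically 3.0–3.4 · w over
realistic windows. `slope_width_for_lpw()` therefore offers the analytic
`"closed_form"` mapping and a `"calibrated"` inverse (default) that
solves w by root-finding against the actual two-stage pipeline on the
stated window, making the noiseless pipeline return exactly the requested
LPW. The calibrated route is what the synthetic generator uses to target
a published peak width.

Non-goals: one transition only (no two-peak deconvolution, no
pretransition), no calorimetry import.

## Laurdan generalized polarization

Laurdan sits at the hydrophilic–hydrophobic interface; solvent dipolar
relaxation red-shifts its emission in fluid membranes. With the ordered
band near 440 nm and the disordered band near 490 nm,

GP = (I440 − I490) / (I440 + I490).

How I440/I490 are read from a spectrum is rarely stated in publications;
`generalized_polarization()` takes the nearest grid wavelength and, on
grids coarser than 5 nm, averages over a ±5 nm window. GP is bounded in
[−1, 1] and antisymmetric under band exchange; the empirical envelope
0.6 to −0.2 again warns rather than fails.

## TEMPO quenching and the raft fraction

TEMPO is water-soluble and quenches DPH only in the liquid-disordered
phase, so the surviving fraction Q = F/F0 reports the ordered-domain
fraction. Treating the proportionality explicitly via a quenching
efficiency E in (0, 1],

F/F0 = f_lo + (1 − f_lo)(1 − E)  ⇒  f_lo = (Q − (1 − E)) / E,

with E = 1 recovering f_lo ≡ Q. E is not identifiable from a single pair
and defaults to 1; estimates outside [0, 1] are clipped with a warning,
and Q > 1 (apparent enhancement) warns but is retained, since noise
produces it routinely.

## cis-parinaric acid peroxidation

cis-PnA's conjugated tetraene fluorescence is destroyed by peroxidation.
The headline statistic is endpoint-based: fraction oxidized
ox = 1 − F(t_end)/F(0) (linear interpolation between samples, invariant
under trace rescaling) and protection factor
p = ox(control)/ox(treated) at a shared endpoint, defaulting to the last
common time point. A first-order decay with plateau,
F(t) = F0((1 − B)e^(−kt) + B), is fitted by `fit_decay()`, and
k_control/k_treated gives a kinetics-based protection estimate reported
as a diagnostic alongside the endpoint number; the two agree only while
the control is far from saturation. Published endpoint reductions are
quoted inconsistently between results and discussion sections of typical
reports of this assay (2-fold versus 4-fold phrasings refer to different
baselines); this package fixes the endpoint definition above as the
contract and leaves such discrepancies to the reader. No photobleaching
correction is applied by default; a no-reaction-mixture reference trace
can be subtracted externally.

## Synthetic data: the stated world

Every modality has a seeded forward simulator returning the data plus a
ground-truth manifest, so each analysis is tested by parameter recovery
with no external data:

* `simulate_polarized_melt()` — Boltzmann r(T) on the standard 15-point
  acquisition grid (20, 23, 26, 29, then 31–51 °C by 2); intensities
  constructed by fixing I_vv and solving
  I_vh = I_vv(1 − r)/(G(1 + 2r)), with I_hv/I_hh = G, so noiseless
  readings invert exactly. Defaults: control-like truth r_gel = 0.30,
  r_fluid = 0.07, t_half = 39.3 °C, w = 1.2 °C; G = 1.1; noise SD 0.005;
  3 replicates. Noise is multiplicative Gaussian per intensity
  (photomultiplier-like).
* `simulate_laurdan_spectrum()` — two Gaussian bands (440/490 nm, SD
  18 nm) on a 390–600 nm, 1 nm grid. The ordered-band weight is solved
  numerically so the grid intensities at 440/490 nm give exactly the
  requested GP; band overlap makes the naive w = (1+GP)/2 wrong by a few
  percent, which the root-finder absorbs. Real Laurdan bands are
  asymmetric; only the two band intensities matter to GP, so Gaussian
  shapes are a pragmatic simplification. Spectrum noise is additive.
* `simulate_quenching()` — the two-phase quench model above with
  multiplicative noise on F and F0.
* `simulate_oxidation()` — control and treated decays over 60 min at
  1-min cadence (the assay cadence is rarely published; these defaults
  are explicit config), plateau B = 0.2, k_control = 0.05/min. The
  treated rate is solved so that the noiseless endpoint protection factor
  equals the requested fold-protection exactly ("endpoint" calibration,
  recorded in the manifest); the naive k/p scaling is available as
  `calibration = "rate"` but undershoots the endpoint factor once the
  control saturates. Noise is additive with SD expressed as a fraction
  of F0.
* Raw intensity magnitudes (1000 a.u. scales) are arbitrary and
  documented as such; no published magnitudes exist to emulate.

A single seed fans out to fixed per-replicate substreams, so adding
replicates never reshuffles earlier ones and everything is
bit-reproducible given (parameters, seed).

What a green recovery test does establish: the estimators invert the
generator's forward model without bias at realistic noise, and the
two-stage T_m detour does not displace the center (< 0.05 °C noiseless).
What it does not establish: robustness to instrument drift, scattering,
inner-filter effects, asymmetric spectra, photobleaching, or model
misspecification of the sigmoid/decay families — none of which the
generators emulate.

## Statistics

`aggregate_replicates()` is the mean ± SD (n − 1) summary;
`paired_t_test()` is the closed-form two-sided paired t with an explicit
degenerate-input error for zero-variance differences (identical series or
a constant shift would otherwise give an infinite statistic);
`tukey_hsd()` wraps `stats::aov` + `stats::TukeyHSD` (Tukey–Kramer for
unbalanced groups) and encodes pairs as `"*"`/`"ns"` at α = 0.05, the
annotation scheme used in figure panels for this kind of assay. Source
reports are often ambiguous about which test applies where; both are
exposed and the pipeline records which was used. Exact p-values accompany
every flag; no correction beyond Tukey is applied.

## Known limitations

* One sigmoid, one Lorentzian peak: multi-component transitions are out
  of scope.
* The quenching efficiency E is a user parameter, not estimated.
* The Lorentzian width calibration is window-dependent by construction;
  compare LPWs only across fits with the same window.
* The CLI covers the analysis and simulation surface but not plotting.
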