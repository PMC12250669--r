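# Seeded forward simulators for every input modality, each returning the
# simulated data together with a ground-truth manifest, so every analysis
# stage can be tested by parameter recovery without any external data.
#
# Reproducibility contract: a single global seed fans out to fixed
# per-replicate substreams, so adding replicates never reshuffles earlier
# ones, and every generator is bit-reproducible given (params, seed).

derive_seed <- function(seed, stream) {
  # deterministic substream derivation; stays below 2^31 - 1
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1299721) %% 2147483647)
}

#' Default melting-experiment temperature grid
#'
#' 15 points: 3-degree increments from 20 to 29 C, then 2-degree increments
#' from 31 to 51 C -- the acquisition grid of a typical anisotropy melting
#' scan bracketing a sphingomyelin transition.
#'
#' @return Numeric vector of temperatures in degrees C.
#' @export
default_temperature_grid <- function() {
  c(20, 23, 26, 29, seq(31, 51, by = 2))
}

#' Simulate a polarized-intensity melting experiment
#'
#' Forward model of a DPH anisotropy melting scan. The target anisotropy
#' follows the descending Boltzmann law at each grid temperature; polarized
#' intensities are constructed by fixing `i_vv` and solving
#' `i_vh = i_vv (1 - r) / (g_true (1 + 2 r))`, which makes the noiseless
#' readings invert exactly to `r(T)`. `i_hv / i_hh` is fixed at `g_true`.
#' Multiplicative Gaussian noise of standard deviation `noise_sd` is applied
#' to every intensity independently (photomultiplier-like noise).
#'
#' @param r_gel,r_fluid Plateau anisotropies of the gel and fluid phase.
#' @param t_half Sigmoid midpoint (degrees C).
#' @param slope_width Sigmoid steepness (degrees C, > 0); see
#'   [slope_width_for_lpw()] to target a Lorentzian peak width.
#' @param g_true True instrument grating factor (> 0).
#' @param noise_sd Relative (multiplicative) noise SD per intensity.
#' @param n_replicates Number of independent replicate scans.
#' @param temperature_grid Measurement temperatures (degrees C).
#' @param i_vv_scale Base intensity of the parallel channel (arbitrary
#'   units; real magnitudes are instrument-specific).
#' @param seed Integer seed; replicate `i` uses a substream derived from it.
#' @return List with `readings` (long data frame: `temperature_C`, `i_vv`,
#'   `i_vh`, `i_hv`, `i_hh`, `replicate`) and `truth` (all parameters plus
#'   the noiseless `r` at each grid temperature).
#' @export
simulate_polarized_melt <- function(r_gel = 0.30, r_fluid = 0.07,
                                    t_half = 39.3, slope_width = 1.2,
                                    g_true = 1.1, noise_sd = 0.005,
                                    n_replicates = 3,
                                    temperature_grid = default_temperature_grid(),
                                    i_vv_scale = 1000, seed = 1) {
  check_numeric(slope_width, "slope_width", positive = TRUE, scalar = TRUE)
  check_numeric(g_true, "g_true", positive = TRUE, scalar = TRUE)
  check_numeric(noise_sd, "noise_sd", non_negative = TRUE, scalar = TRUE)
  r_true <- boltzmann_model(temperature_grid, r_gel, r_fluid, t_half, slope_width)
  if (any(r_true <= -0.5 | r_true >= 1)) {
    mf_stop("target anisotropy outside (-0.5, 1) on the grid; adjust plateaus")
  }
  nt <- length(temperature_grid)
  reps <- lapply(seq_len(n_replicates), function(i) {
    withr::with_seed(derive_seed(seed, i), {
      i_vv <- rep(i_vv_scale, nt)
      i_vh <- i_vv * (1 - r_true) / (g_true * (1 + 2 * r_true))
      i_hh <- rep(i_vv_scale, nt)
      i_hv <- g_true * i_hh
      noisy <- function(x) x * (1 + stats::rnorm(length(x), 0, noise_sd))
      data.frame(temperature_C = temperature_grid,
                 i_vv = noisy(i_vv), i_vh = noisy(i_vh),
                 i_hv = noisy(i_hv), i_hh = noisy(i_hh),
                 replicate = i)
    })
  })
  readings <- do.call(rbind, reps)
  if (any(readings[c("i_vv", "i_vh", "i_hv", "i_hh")] < 0)) {
    mf_stop("noise level produced negative intensities; lower 'noise_sd'")
  }
  list(readings = readings,
       truth = list(r_gel = r_gel, r_fluid = r_fluid, t_half = t_half,
                    slope_width = slope_width, g_true = g_true,
                    noise_sd = noise_sd, n_replicates = n_replicates,
                    temperature_grid = temperature_grid,
                    i_vv_scale = i_vv_scale, seed = seed, r_true = r_true))
}

#' Simulate a Laurdan emission spectrum with a target GP
#'
#' Builds a bimodal spectrum as a weighted sum of two Gaussian bands
#' (ordered band near 440 nm, disordered band near 490 nm) and solves the
#' ordered-band weight `w` numerically so that the intensities realized at
#' the grid points nearest 440/490 nm yield exactly `gp_target`. Band
#' overlap makes `w != (1 + gp)/2`; the root-finder accounts for it.
#' Optional additive Gaussian noise (spectrometer baseline noise).
#'
#' @param gp_target Target GP in the attainable open interval (reported in
#'   the error message if exceeded).
#' @param band_centers Band centers in nm (default `c(440, 490)`).
#' @param band_sd Common Gaussian band SD in nm (default 18).
#' @param total_intensity Peak intensity scale (arbitrary units).
#' @param wavelength_grid Emission wavelengths in nm.
#' @param noise_sd Additive noise SD (same units as intensity).
#' @param excitation_nm Excitation wavelength metadata.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List with `spectrum` (an [emission_spectrum()]) and `truth`
#'   (parameters plus the solved weight `w`).
#' @export
simulate_laurdan_spectrum <- function(gp_target, band_centers = c(440, 490),
                                      band_sd = 18, total_intensity = 1000,
                                      wavelength_grid = seq(390, 600, by = 1),
                                      noise_sd = 0, excitation_nm = 355,
                                      seed = 1) {
  check_numeric(gp_target, "gp_target", scalar = TRUE)
  check_numeric(band_sd, "band_sd", positive = TRUE, scalar = TRUE)
  if (any(band_centers < min(wavelength_grid) | band_centers > max(wavelength_grid))) {
    mf_stop("band centers must lie inside the wavelength grid")
  }
  shape1 <- exp(-(wavelength_grid - band_centers[1])^2 / (2 * band_sd^2))
  shape2 <- exp(-(wavelength_grid - band_centers[2])^2 / (2 * band_sd^2))
  # GP realized at the extraction wavelengths for ordered-band weight w
  i1 <- which.min(abs(wavelength_grid - 440))
  i2 <- which.min(abs(wavelength_grid - 490))
  gp_of_w <- function(w) {
    s <- w * shape1 + (1 - w) * shape2
    (s[i1] - s[i2]) / (s[i1] + s[i2])
  }
  lo <- gp_of_w(0)
  hi <- gp_of_w(1)
  if (gp_target <= lo || gp_target >= hi) {
    mf_stop(sprintf(
      "gp_target %.4g unreachable for these band shapes; attainable range (%.4g, %.4g)",
      gp_target, lo, hi))
  }
  w <- stats::uniroot(function(w) gp_of_w(w) - gp_target, c(0, 1),
                      tol = .Machine$double.eps^0.75)$root
  intensity <- (w * shape1 + (1 - w) * shape2) * total_intensity
  if (noise_sd > 0) {
    intensity <- withr::with_seed(derive_seed(seed, 1L), {
      pmax(intensity + stats::rnorm(length(intensity), 0, noise_sd), 0)
    })
  }
  list(spectrum = emission_spectrum(wavelength_grid, intensity,
                                    excitation_nm = excitation_nm),
       truth = list(gp_target = gp_target, w = w, band_centers = band_centers,
                    band_sd = band_sd, total_intensity = total_intensity,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate TEMPO quenching replicates
#'
#' Forward model of the two-phase quenching experiment:
#' `F = F0 (f_lo + (1 - f_lo)(1 - E))`, with multiplicative Gaussian noise
#' on both intensities. The noiseless pair inverts exactly through
#' [quench_ratio()] and [raft_fraction()] back to `f_lo`.
#'
#' @param f_lo True liquid-ordered (raft) fraction in `[0, 1]`.
#' @param quench_efficiency `E` in `(0, 1]`.
#' @param f0_mean Mean unquenched intensity.
#' @param noise_sd Relative noise SD per intensity.
#' @param n_replicates Number of replicate pairs.
#' @param seed Integer seed.
#' @return List with `pairs` (data frame `f`, `f0`, `replicate`) and
#'   `truth`.
#' @export
simulate_quenching <- function(f_lo, quench_efficiency = 0.9, f0_mean = 1000,
                               noise_sd = 0, n_replicates = 3, seed = 1) {
  check_numeric(f_lo, "f_lo", scalar = TRUE)
  if (f_lo < 0 || f_lo > 1) mf_stop("'f_lo' must be in [0, 1]")
  if (quench_efficiency <= 0 || quench_efficiency > 1) {
    mf_stop("'quench_efficiency' must be in (0, 1]")
  }
  q_true <- f_lo + (1 - f_lo) * (1 - quench_efficiency)
  pairs <- do.call(rbind, lapply(seq_len(n_replicates), function(i) {
    withr::with_seed(derive_seed(seed, i), {
      f0 <- f0_mean * (1 + stats::rnorm(1, 0, noise_sd))
      f <- f0_mean * q_true * (1 + stats::rnorm(1, 0, noise_sd))
      data.frame(f = f, f0 = f0, replicate = i)
    })
  }))
  list(pairs = pairs,
       truth = list(f_lo = f_lo, quench_efficiency = quench_efficiency,
                    q_true = q_true, f0_mean = f0_mean, noise_sd = noise_sd,
                    n_replicates = n_replicates, seed = seed))
}

#' Simulate a lipid-peroxidation protection experiment
#'
#' Generates a control and an antioxidant-treated fluorescence decay trace:
#' `F(t) = F0 ((1 - B) exp(-k t) + B)` with control rate `k_control`.
#' With `calibration = "endpoint"` (default) the treated rate is solved so
#' that the noiseless endpoint protection factor at `t_end = duration`
#' equals `protection` exactly (the calibration is part of the generator
#' contract and is recorded in the manifest); `calibration = "rate"` uses
#' the naive `k_control / protection`, whose endpoint factor is smaller
#' once the control saturates. Additive Gaussian noise with SD
#' `noise_sd * f0`.
#'
#' @param protection Target fold-protection (>= 1).
#' @param k_control Control decay rate per minute (>= 0); 0 gives the
#'   no-reaction-mixture scenario where nothing oxidizes.
#' @param plateau_fraction Residual fluorescence fraction `B` in `[0, 1)`.
#' @param f0 Initial intensity.
#' @param duration Trace length in minutes.
#' @param cadence Sampling interval in minutes.
#' @param noise_sd Noise SD as a fraction of `f0`.
#' @param seed Integer seed.
#' @param calibration `"endpoint"` or `"rate"`.
#' @return List with `control`, `treated` (both [oxidation_series()]) and
#'   `truth` (including the solved `k_treated`).
#' @export
simulate_oxidation <- function(protection = 2.0, k_control = 0.05,
                               plateau_fraction = 0.2, f0 = 1000,
                               duration = 60, cadence = 1, noise_sd = 0,
                               seed = 1, calibration = c("endpoint", "rate")) {
  calibration <- match.arg(calibration)
  check_numeric(protection, "protection", scalar = TRUE)
  if (protection < 1) mf_stop("'protection' must be >= 1")
  check_numeric(k_control, "k_control", non_negative = TRUE, scalar = TRUE)
  if (plateau_fraction < 0 || plateau_fraction >= 1) {
    mf_stop("'plateau_fraction' must be in [0, 1)")
  }
  times <- seq(0, duration, by = cadence)
  b <- plateau_fraction
  ox_control <- (1 - b) * (1 - exp(-k_control * duration))
  k_treated <- if (k_control == 0 || protection == 1) {
    k_control
  } else if (calibration == "endpoint") {
    # solve (1-b)(1-exp(-k_t T)) = ox_control / protection
    -log(1 - ox_control / protection / (1 - b)) / duration
  } else {
    k_control / protection
  }
  trace <- function(k, stream) {
    f <- f0 * ((1 - b) * exp(-k * times) + b)
    if (noise_sd > 0) {
      f <- withr::with_seed(derive_seed(seed, stream), {
        pmax(f + stats::rnorm(length(f), 0, noise_sd * f0), 0)
      })
      f[1] <- max(f[1], f0 * 1e-6)  # keep the F(0) > 0 invariant under noise
    }
    f
  }
  list(control = oxidation_series(times, trace(k_control, 1L), "control"),
       treated = oxidation_series(times, trace(k_treated, 2L), "treated"),
       truth = list(protection = protection, k_control = k_control,
                    k_treated = k_treated, plateau_fraction = b, f0 = f0,
                    duration = duration, cadence = cadence,
                    noise_sd = noise_sd, seed = seed,
                    calibration = calibration,
                    ox_control_noiseless = ox_control))
}
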