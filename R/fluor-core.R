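# Closed-form steady-state fluorescence observables.

#' Instrument grating factor
#'
#' Polarization correction factor `G = I_hv / I_hh` accounting for the
#' different sensitivity of the detection channel towards vertically and
#' horizontally polarized light. Measured with horizontally polarized
#' excitation, where the two emission components should be equal on an ideal
#' instrument.
#'
#' @param i_hv Emission intensity, horizontal excitation / vertical analyzer
#'   (arbitrary units, >= 0).
#' @param i_hh Emission intensity, horizontal excitation / horizontal
#'   analyzer (> 0).
#' @return `G`, dimensionless, same length as the inputs. `i_hv == 0`
#'   (fully polarized emission) is flagged with a degenerate-input warning.
#' @examples
#' grating_factor(0.8, 1.0)
#' @seealso [anisotropy()]
#' @export
grating_factor <- function(i_hv, i_hh) {
  check_numeric(i_hv, "i_hv", non_negative = TRUE)
  if (!is.numeric(i_hh) || anyNA(i_hh) || any(i_hh <= 0)) {
    mf_stop("'i_hh' must be strictly positive to compute a grating factor")
  }
  if (any(i_hv == 0)) {
    mf_warn("i_hv = 0: emission fully polarized, grating factor degenerate (G = 0)",
            class = "membrafluor_plausibility")
  }
  i_hv / i_hh
}

#' Steady-state fluorescence anisotropy
#'
#' `r = (I_vv - G I_vh) / (I_vv + 2 G I_vh)` from the two polarized emission
#' components under vertically polarized excitation, with the grating factor
#' `G` correcting detector polarization bias. High `r` reports a rigid probe
#' environment (restricted rotation), low `r` a fluid one.
#'
#' The mathematically attainable range is `[-0.5, 1]`. DPH in membranes
#' empirically spans roughly `-0.2` to `+0.4`; values outside that envelope
#' are physically implausible and raise a plausibility warning (not an
#' error).
#'
#' @param i_vv,i_vh Polarized emission intensities (>= 0), vertical
#'   excitation with vertical / horizontal analyzer.
#' @param g Grating factor (> 0), see [grating_factor()]. Default 1 (ideal
#'   detection).
#' @param envelope Empirical plausibility band; set to `NULL` to disable the
#'   warning.
#' @return Anisotropy `r`, dimensionless, in `[-0.5, 1]`.
#' @examples
#' anisotropy(1.55, 0.72, g = 1.1)
#' @export
anisotropy <- function(i_vv, i_vh, g = 1, envelope = c(-0.2, 0.4)) {
  check_numeric(i_vv, "i_vv", non_negative = TRUE)
  check_numeric(i_vh, "i_vh", non_negative = TRUE)
  check_numeric(g, "g", positive = TRUE)
  denom <- i_vv + 2 * g * i_vh
  if (any(denom <= 0)) {
    mf_stop("total intensity i_vv + 2*g*i_vh must be positive")
  }
  r <- (i_vv - g * i_vh) / denom
  if (!is.null(envelope) && any(r < envelope[1] | r > envelope[2])) {
    mf_warn(sprintf(
      "anisotropy outside the empirical envelope [%g, %g] (min %.4g, max %.4g)",
      envelope[1], envelope[2], min(r), max(r)), class = "membrafluor_plausibility")
  }
  r
}

#' Emission spectrum container
#'
#' A wavelength-indexed emission spectrum with excitation metadata. Input to
#' [generalized_polarization()].
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param intensity Emission intensities (arbitrary units, >= 0), same
#'   length.
#' @param excitation_nm Excitation wavelength in nm (metadata).
#' @param temperature Sample temperature in degrees C (metadata).
#' @return A data frame of class `emission_spectrum` with columns
#'   `wavelength_nm` and `intensity`.
#' @export
emission_spectrum <- function(wavelength, intensity, excitation_nm = NA_real_,
                              temperature = NA_real_) {
  check_numeric(wavelength, "wavelength")
  check_numeric(intensity, "intensity", non_negative = TRUE)
  if (length(wavelength) != length(intensity)) {
    mf_stop("'wavelength' and 'intensity' must have the same length")
  }
  if (any(diff(wavelength) <= 0)) {
    mf_stop("'wavelength' must be strictly increasing")
  }
  structure(
    data.frame(wavelength_nm = wavelength, intensity = intensity),
    excitation_nm = excitation_nm, temperature = temperature,
    class = c("emission_spectrum", "data.frame")
  )
}

# Intensity at a target wavelength: nearest grid point, or the mean over a
# +/- window when the grid is coarser than the window (the band position is
# then poorly sampled by a single point).
band_intensity <- function(spectrum, target_nm, window_nm = 5) {
  wl <- spectrum$wavelength_nm
  if (target_nm < min(wl) || target_nm > max(wl)) {
    mf_stop(sprintf("spectrum (%g-%g nm) does not cover the %g nm band",
                    min(wl), max(wl), target_nm))
  }
  spacing <- stats::median(diff(wl))
  if (spacing > window_nm) {
    sel <- abs(wl - target_nm) <= window_nm
    if (!any(sel)) sel <- which.min(abs(wl - target_nm))
    return(mean(spectrum$intensity[sel]))
  }
  spectrum$intensity[which.min(abs(wl - target_nm))]
}

#' Laurdan generalized polarization
#'
#' `GP = (I_440 - I_490) / (I_440 + I_490)` where the two intensities are the
#' emission at the ordered-phase (~440 nm) and disordered-phase (~490 nm)
#' band maxima. High positive GP indicates an ordered bilayer, negative GP a
#' fluid one. Band intensities are read at the grid wavelength nearest each
#' target; on grids coarser than `window_nm` they are averaged over a
#' `+/- window_nm` window.
#'
#' The mathematical range is `[-1, 1]`; membrane measurements typically fall
#' in about `[-0.2, 0.6]`, and values outside that envelope warn but do not
#' fail.
#'
#' @param spectrum An [emission_spectrum()].
#' @param bands Target wavelengths in nm for the ordered and disordered
#'   bands; default `c(440, 490)`.
#' @param window_nm Averaging half-window for coarse grids (nm).
#' @param envelope Empirical plausibility band, or `NULL` to disable.
#' @return GP, dimensionless, in `[-1, 1]`.
#' @examples
#' s <- emission_spectrum(seq(390, 600, 5), dnorm(seq(390, 600, 5), 455, 30))
#' generalized_polarization(s)
#' @export
generalized_polarization <- function(spectrum, bands = c(440, 490),
                                     window_nm = 5, envelope = c(-0.2, 0.6)) {
  if (!inherits(spectrum, "emission_spectrum")) {
    if (is.data.frame(spectrum) &&
        all(c("wavelength_nm", "intensity") %in% names(spectrum))) {
      spectrum <- emission_spectrum(spectrum$wavelength_nm, spectrum$intensity)
    } else {
      mf_stop("'spectrum' must be an emission_spectrum (wavelength_nm, intensity)")
    }
  }
  i440 <- band_intensity(spectrum, bands[1], window_nm)
  i490 <- band_intensity(spectrum, bands[2], window_nm)
  if (i440 + i490 <= 0) {
    mf_stop("both band intensities are zero; GP undefined")
  }
  gp <- (i440 - i490) / (i440 + i490)
  if (!is.null(envelope) && (gp < envelope[1] || gp > envelope[2])) {
    mf_warn(sprintf("GP = %.4g outside the empirical envelope [%g, %g]",
                    gp, envelope[1], envelope[2]),
            class = "membrafluor_plausibility")
  }
  gp
}

#' Quench ratio
#'
#' `Q = F / F0`, the fraction of probe fluorescence surviving an
#' aqueous-phase quencher (TEMPO). Because the quencher only reaches the
#' disordered phase, `Q` is proportional to the fraction of fluorophore
#' residing in ordered (raft-like) domains.
#'
#' @param f Intensity with quencher (>= 0). May also be a data frame with
#'   columns `f` and `f0` (a quench-pair table), in which case `f0` is taken
#'   from it.
#' @param f0 Intensity without quencher (> 0).
#' @return `Q >= 0`; `Q > 1` (apparent enhancement) raises an anomaly
#'   warning but is returned unchanged.
#' @export
quench_ratio <- function(f, f0 = NULL) {
  if (is.data.frame(f)) {
    if (!all(c("f", "f0") %in% names(f))) {
      mf_stop("quench-pair table must have columns 'f' and 'f0'")
    }
    f0 <- f$f0
    f <- f$f
  }
  check_numeric(f, "f", non_negative = TRUE)
  if (!is.numeric(f0) || anyNA(f0) || any(f0 <= 0)) {
    mf_stop("'f0' must be strictly positive")
  }
  q <- f / f0
  if (any(q > 1)) {
    mf_warn(sprintf("Q > 1 in %d reading(s): apparent fluorescence enhancement",
                    sum(q > 1)))
  }
  q
}

#' Liquid-ordered (raft) fraction from a quench ratio
#'
#' Inverts the two-phase quenching model `F/F0 = f_lo + (1 - f_lo)(1 - E)`,
#' where `E` is the quenching efficiency in the disordered phase:
#' `f_lo = (Q - (1 - E)) / E`. With an ideal quencher (`E = 1`) the raft
#' fraction equals `Q` itself.
#'
#' @param q Quench ratio, see [quench_ratio()]. Values slightly above 1
#'   (noise) warn; negative values error.
#' @param quench_efficiency `E` in `(0, 1]`, fraction of disordered-phase
#'   fluorescence removed by the quencher.
#' @return Raft fraction in `[0, 1]`; out-of-range estimates are clipped
#'   with a warning.
#' @export
raft_fraction <- function(q, quench_efficiency = 1) {
  check_numeric(q, "q", non_negative = TRUE)
  check_numeric(quench_efficiency, "quench_efficiency", scalar = TRUE)
  if (quench_efficiency <= 0 || quench_efficiency > 1) {
    mf_stop("'quench_efficiency' must be in (0, 1]")
  }
  if (any(q > 1)) {
    mf_warn(sprintf("q > 1 in %d value(s); raft fraction will be clipped",
                    sum(q > 1)))
  }
  f_lo <- (q - (1 - quench_efficiency)) / quench_efficiency
  tol <- 1e-9  # rounding slop is clipped silently, real excursions warn
  if (any(f_lo < -tol | f_lo > 1 + tol)) {
    mf_warn("raft fraction outside [0, 1]; clipped", class = "membrafluor_clipped")
  }
  pmin(pmax(f_lo, 0), 1)
}

#' Anisotropy temperature curve container
#'
#' Ordered `(temperature, r, sd, n)` series consumed by all melting and
#' linear fits.
#'
#' @param temperature Temperatures in degrees C, strictly increasing.
#' @param r Anisotropy values in `[-0.5, 1]`.
#' @param sd Replicate standard deviation of `r` (NA when `n < 2`).
#' @param n Replicate count (>= 1).
#' @return A data frame of class `anisotropy_curve`.
#' @export
anisotropy_curve <- function(temperature, r, sd = NA_real_, n = 1L) {
  check_numeric(temperature, "temperature")
  check_numeric(r, "r")
  if (length(temperature) != length(r)) {
    mf_stop("'temperature' and 'r' must have the same length")
  }
  if (any(diff(temperature) <= 0)) {
    mf_stop("'temperature' must be strictly increasing")
  }
  if (any(r < -0.5 | r > 1)) {
    mf_stop("anisotropy 'r' outside the attainable range [-0.5, 1]")
  }
  if (any(!is.na(n) & n < 1)) mf_stop("replicate count 'n' must be >= 1")
  structure(
    data.frame(temperature_C = temperature, r = r,
               sd = rep_len(as.numeric(sd), length(r)),
               n = rep_len(as.integer(n), length(r))),
    class = c("anisotropy_curve", "data.frame")
  )
}

#' Polarized-intensity table to anisotropy curve
#'
#' Converts a long table of polarized readings (columns `temperature_C`,
#' `i_vv`, `i_vh`, `i_hv`, `i_hh`, optional `replicate`) into an
#' [anisotropy_curve()]. The anisotropy is computed per replicate (each with
#' its own grating factor from `i_hv/i_hh`) and then aggregated across
#' replicates per temperature (mean, SD, n) -- replicate-wise computation
#' preserves the replicate scatter of the derived quantity.
#'
#' @param readings Data frame of polarized readings.
#' @param background Constant background subtracted from every intensity
#'   before any ratio is formed (default 0; inputs are assumed
#'   blank-corrected).
#' @param envelope Passed to [anisotropy()].
#' @return An [anisotropy_curve()].
#' @export
anisotropy_curve_from_readings <- function(readings, background = 0,
                                           envelope = c(-0.2, 0.4)) {
  need <- c("temperature_C", "i_vv", "i_vh", "i_hv", "i_hh")
  if (!all(need %in% names(readings))) {
    mf_stop(sprintf("readings must have columns: %s", paste(need, collapse = ", ")))
  }
  if (is.null(readings$replicate)) readings$replicate <- 1L
  for (col in c("i_vv", "i_vh", "i_hv", "i_hh")) {
    readings[[col]] <- readings[[col]] - background
    if (any(readings[[col]] < 0)) {
      mf_stop(sprintf("negative %s after background subtraction", col))
    }
  }
  g <- grating_factor(readings$i_hv, readings$i_hh)
  r <- anisotropy(readings$i_vv, readings$i_vh, g, envelope = envelope)
  agg <- lapply(split(data.frame(t = readings$temperature_C, r = r),
                      readings$temperature_C), function(d) {
    s <- aggregate_replicates(d$r, warn = FALSE)
    data.frame(temperature_C = d$t[1], r = s$mean, sd = s$sd, n = s$n)
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$temperature_C), ]
  anisotropy_curve(agg$temperature_C, agg$r, agg$sd, agg$n)
}
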