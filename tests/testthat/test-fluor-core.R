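# Closed-form fluorescence observables: worked examples, error contracts,
# and the algebraic properties that must hold for any input.

test_that("grating factor is I_hv/I_hh with guarded degenerate cases", {
  expect_equal(grating_factor(1.0, 1.0), 1.0)
  expect_equal(grating_factor(0.8, 1.0), 0.8)
  expect_warning(g0 <- grating_factor(0.0, 1.0), class = "membrafluor_plausibility")
  expect_equal(g0, 0.0)
  expect_error(grating_factor(1.0, 0.0), "i_hh", class = "membrafluor_invalid")
  expect_error(grating_factor(-0.1, 1.0), class = "membrafluor_invalid")
})

test_that("anisotropy matches its defining limits", {
  expect_equal(suppressWarnings(anisotropy(1, 1, 1)), 0.0)
  expect_equal(suppressWarnings(anisotropy(1, 0, 1)), 1.0)
  expect_equal(suppressWarnings(anisotropy(0, 1, 1)), -0.5)
  # r = 0 iff i_vv = g * i_vh
  expect_equal(anisotropy(0.66, 0.6, 1.1), 0.0)
  expect_error(anisotropy(0, 0, 1), class = "membrafluor_invalid")
  expect_error(anisotropy(1, 1, -2), class = "membrafluor_invalid")
})

test_that("anisotropy stays in [-0.5, 1] for any admissible intensities", {
  withr::with_seed(11, {
    for (i in 1:500) {
      r <- suppressWarnings(
        anisotropy(runif(1, 0, 100), runif(1, 0, 100), runif(1, 0.5, 2)))
      expect_gte(r, -0.5)
      expect_lte(r, 1)
    }
  })
})

test_that("out-of-envelope anisotropy warns but is returned", {
  expect_warning(r <- anisotropy(1, 0, 1), class = "membrafluor_plausibility")
  expect_equal(r, 1)
  expect_silent(anisotropy(1, 0, 1, envelope = NULL))
})

gauss_spectrum <- function(i440, i490, sd = 14) {
  # two narrow bands so the grid values at 440/490 nm are the band weights
  wl <- seq(390, 600, by = 1)
  emission_spectrum(wl, i440 * exp(-(wl - 440)^2 / (2 * sd^2)) +
                          i490 * exp(-(wl - 490)^2 / (2 * sd^2)))
}

test_that("generalized polarization reproduces its worked examples", {
  wl <- seq(390, 600, by = 1)
  flat <- emission_spectrum(wl, rep(1, length(wl)))
  expect_equal(generalized_polarization(flat), 0.0)
  only440 <- emission_spectrum(c(440, 490), c(3, 0))
  expect_warning(gp1 <- generalized_polarization(only440),
                 class = "membrafluor_plausibility")
  expect_equal(gp1, 1.0)
  two_to_one <- emission_spectrum(c(440, 490), c(2, 1))
  expect_equal(generalized_polarization(two_to_one), 1 / 3)
})

test_that("GP is antisymmetric under band swap", {
  withr::with_seed(21, {
    for (i in 1:50) {
      a <- runif(1, 0.1, 5)
      b <- runif(1, 0.1, 5)
      gp_ab <- suppressWarnings(generalized_polarization(gauss_spectrum(a, b)))
      gp_ba <- suppressWarnings(generalized_polarization(gauss_spectrum(b, a)))
      expect_equal(gp_ab, -gp_ba, tolerance = 1e-12)
      expect_lte(abs(gp_ab), 1)
    }
  })
})

test_that("GP errors on coverage gaps and all-zero bands", {
  short <- emission_spectrum(seq(500, 600, 5), rep(1, 21))
  expect_error(generalized_polarization(short), "440", class = "membrafluor_invalid")
  wl <- seq(390, 600, by = 1)
  dark <- emission_spectrum(wl, ifelse(wl > 560, 1, 0))
  expect_error(generalized_polarization(dark), class = "membrafluor_invalid")
})

test_that("GP band extraction averages over +/-5 nm on coarse grids", {
  wl <- seq(390, 600, by = 10)   # coarser than the 5 nm window
  intens <- approx(c(390, 440, 490, 600), c(0, 4, 2, 0), xout = wl)$y
  gp <- generalized_polarization(emission_spectrum(wl, intens))
  # window mean over {435, 445} and {485, 495} of the piecewise shape
  i440 <- mean(intens[wl %in% c(435, 440, 445)])
  i490 <- mean(intens[wl %in% c(485, 490, 495)])
  expect_equal(gp, (i440 - i490) / (i440 + i490))
})

test_that("quench ratio follows Q = F/F0 and flags enhancement", {
  expect_equal(quench_ratio(1.2, 1.2), 1.0)
  expect_equal(quench_ratio(0, 1), 0.0)
  expect_equal(quench_ratio(0.6, 1.2), 0.5)
  expect_warning(q <- quench_ratio(1.3, 1.0), class = "membrafluor_anomaly")
  expect_equal(q, 1.3)
  expect_error(quench_ratio(1, 0), class = "membrafluor_invalid")
  # data-frame (quench pair) input
  expect_equal(quench_ratio(data.frame(f = c(0.5, 0.6), f0 = c(1, 2))),
               c(0.5, 0.3))
})

test_that("raft fraction inverts the two-phase quenching model", {
  expect_equal(raft_fraction(0.4, 1), 0.4)
  expect_equal(raft_fraction(1, 0.3), 1.0)
  # derived by hand from F/F0 = f_lo + (1 - f_lo)(1 - E)
  expect_equal(raft_fraction(0.7, 0.5), 0.4)
  expect_error(raft_fraction(0.5, 0), class = "membrafluor_invalid")
  expect_warning(f <- raft_fraction(0.02, 0.95), class = "membrafluor_clipped")
  expect_equal(f, 0)
})

test_that("raft_fraction at E = 1 is the identity on [0, 1]", {
  q <- seq(0, 1, by = 0.01)
  expect_equal(raft_fraction(q, 1), q)
})

test_that("anisotropy_curve enforces its invariants", {
  expect_error(anisotropy_curve(c(20, 20, 25), c(0.1, 0.2, 0.3)),
               "increasing", class = "membrafluor_invalid")
  expect_error(anisotropy_curve(c(20, 25), c(0.1, 1.2)),
               class = "membrafluor_invalid")
  cv <- anisotropy_curve(c(20, 25, 30), c(0.3, 0.2, 0.1), sd = 0.01, n = 3)
  expect_s3_class(cv, "anisotropy_curve")
  expect_equal(cv$n, rep(3L, 3))
})

test_that("polarized readings convert replicate-wise to an anisotropy curve", {
  sim <- simulate_polarized_melt(noise_sd = 0, n_replicates = 3, seed = 4)
  cv <- anisotropy_curve_from_readings(sim$readings)
  expect_equal(cv$r, sim$truth$r_true, tolerance = 1e-12)
  expect_equal(cv$n, rep(3L, nrow(cv)))
  # per-replicate r then aggregate: the SD must equal the replicate scatter
  noisy <- simulate_polarized_melt(noise_sd = 0.01, n_replicates = 3, seed = 5)
  cvn <- suppressWarnings(anisotropy_curve_from_readings(noisy$readings))
  g <- noisy$readings$i_hv / noisy$readings$i_hh
  r_all <- suppressWarnings(
    anisotropy(noisy$readings$i_vv, noisy$readings$i_vh, g))
  manual_sd <- tapply(r_all, noisy$readings$temperature_C, sd)
  expect_equal(cvn$sd, as.vector(manual_sd[as.character(cvn$temperature_C)]),
               tolerance = 1e-12)
  # constant background subtraction undoes an added offset
  shifted <- noisy$readings
  for (col in c("i_vv", "i_vh", "i_hv", "i_hh")) shifted[[col]] <- shifted[[col]] + 50
  cvb <- suppressWarnings(anisotropy_curve_from_readings(shifted, background = 50))
  expect_equal(cvb$r, cvn$r, tolerance = 1e-12)
})
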