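# Melting-curve inference: noiseless generator-inversion recovery, oracle
# agreement, and the structural properties of the two-stage T_m pipeline.

control_truth <- list(r_gel = 0.30, r_fluid = 0.07, t_half = 39.3,
                      slope_width = 1.2)

noiseless_curve <- function(truth = control_truth) {
  temp <- default_temperature_grid()
  r <- truth$r_fluid + (truth$r_gel - truth$r_fluid) /
    (1 + exp((temp - truth$t_half) / truth$slope_width))
  anisotropy_curve(temp, r)
}

test_that("fit_boltzmann recovers noiseless truth to 1e-6", {
  fit <- fit_boltzmann(noiseless_curve())
  expect_true(fit$converged)
  expect_equal(fit$r_gel, 0.30, tolerance = 1e-6)
  expect_equal(fit$r_fluid, 0.07, tolerance = 1e-6)
  expect_equal(fit$t_half, 39.3, tolerance = 1e-6)
  expect_equal(fit$slope_width, 1.2, tolerance = 1e-6)
})

test_that("a flat curve yields converged = FALSE, never a silent number", {
  flat <- anisotropy_curve(default_temperature_grid(),
                           rep(0.2, 15))
  fit <- fit_boltzmann(flat)
  expect_false(fit$converged)
  expect_match(fit$diagnostics, "transition")
  expect_error(fit_boltzmann(anisotropy_curve(c(20, 25, 30), c(0.3, 0.2, 0.1))),
               "6", class = "membrafluor_invalid")
})

test_that("noisy t_half lands in the basin a grid-search oracle finds", {
  sim <- simulate_polarized_melt(noise_sd = 0.005, n_replicates = 1, seed = 7)
  curve <- suppressWarnings(anisotropy_curve_from_readings(sim$readings))
  fit <- fit_boltzmann(curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$t_half - 39.3), 0.3)
  oracle <- boltzmann_grid_oracle(curve$temperature_C, curve$r,
                                  t_half_grid = seq(37, 42, by = 0.05),
                                  width_grid = seq(0.5, 2.5, by = 0.05))
  expect_lt(abs(fit$t_half - oracle$t_half), 0.05 + 1e-9)
  expect_lt(abs(fit$slope_width - oracle$slope_width), 0.05 + 1e-9)
})

test_that("derivative profile peaks at t_half with the closed-form height", {
  fit <- fit_boltzmann(noiseless_curve())
  prof <- derivative_profile(fit, 20, 51, step = 0.1)
  peak_at <- prof$temperature_C[which.max(prof$dr_dT)]
  expect_lt(abs(peak_at - fit$t_half), 0.1 + 1e-9)
  expect_equal(max(prof$dr_dT),
               abs(fit$r_gel - fit$r_fluid) / (4 * fit$slope_width),
               tolerance = 1e-4)
  # equal plateaus: identically zero profile
  flat_fit <- structure(list(r_gel = 0.2, r_fluid = 0.2, t_half = 39,
                             slope_width = 1, converged = TRUE),
                        class = "melting_fit")
  expect_equal(derivative_profile(flat_fit, 20, 51)$dr_dT,
               rep(0, length(seq(20, 51, 0.1))))
  # unconverged fits cannot be differentiated
  bad <- structure(list(converged = FALSE), class = "melting_fit")
  expect_error(derivative_profile(bad, 20, 51), class = "membrafluor_degenerate")
})

test_that("fit_lorentzian recovers an exact Lorentzian to 1e-8", {
  temp <- seq(20, 60, by = 0.1)
  y <- 0 + (2 * 1 / pi) * 5 / (4 * (temp - 40)^2 + 5^2)
  fit <- fit_lorentzian(data.frame(temp, y))
  expect_true(fit$converged)
  expect_equal(fit$center, 40, tolerance = 1e-8)
  expect_equal(fit$fwhm, 5, tolerance = 1e-8)
  expect_equal(fit$area, 1, tolerance = 1e-8)
  expect_equal(fit$offset, 0, tolerance = 1e-8)
})

test_that("Lorentzian center matches the symmetric logistic-derivative midpoint", {
  fit <- fit_boltzmann(noiseless_curve())
  lfit <- fit_lorentzian(derivative_profile(fit, 27.6, 51, step = 0.1))
  # window symmetric about t_half: symmetry forces the center
  expect_lt(abs(lfit$center - fit$t_half), 0.05)
})

test_that("melting_analysis chains the stages and reports replicate spread", {
  sim <- simulate_polarized_melt(noise_sd = 0.005, n_replicates = 3, seed = 1)
  ma <- suppressWarnings(melting_analysis(replicate_curves(sim)))
  expect_s3_class(ma, "melting_analysis")
  expect_lt(abs(ma$t_m - 39.3), 0.6)
  expect_length(ma$replicate_t_m, 3)
  expect_equal(ma$t_m_sd, sd(ma$replicate_t_m))
  # shifted truth: recovered T_m tracks the shift
  sim_pa <- simulate_polarized_melt(t_half = 41.3, noise_sd = 0.005,
                                    n_replicates = 1, seed = 2)
  ma_pa <- suppressWarnings(
    melting_analysis(anisotropy_curve_from_readings(sim_pa$readings)))
  expect_lt(abs(ma_pa$t_m - 41.3), 0.6)
  # widened truth: LPW strictly larger
  sim_w <- simulate_polarized_melt(slope_width = 1.2 * 1.5, noise_sd = 0,
                                   n_replicates = 1)
  ma_w <- melting_analysis(anisotropy_curve_from_readings(sim_w$readings))
  sim_0 <- simulate_polarized_melt(noise_sd = 0, n_replicates = 1)
  ma_0 <- melting_analysis(anisotropy_curve_from_readings(sim_0$readings))
  expect_gt(ma_w$lpw, ma_0$lpw)
})

test_that("melting_analysis failure names the failing stage", {
  flat <- anisotropy_curve(default_temperature_grid(), rep(0.2, 15))
  err <- tryCatch(melting_analysis(flat), error = identity)
  expect_s3_class(err, "membrafluor_stage_error")
  expect_equal(err$stage, "fit_boltzmann")
})

test_that("LPW and T_m are invariant to vertical scaling and shifts of r", {
  base <- noiseless_curve()
  ma <- melting_analysis(base)
  scaled <- anisotropy_curve(base$temperature_C, base$r * 0.5)
  shifted <- anisotropy_curve(base$temperature_C, base$r + 0.1)
  ma_s <- melting_analysis(scaled)
  ma_h <- melting_analysis(shifted)
  expect_equal(ma_s$lpw, ma$lpw, tolerance = 1e-6)
  expect_equal(ma_h$lpw, ma$lpw, tolerance = 1e-6)
  expect_equal(ma_s$t_m, ma$t_m, tolerance = 1e-6)
  expect_equal(ma_h$t_m, ma$t_m, tolerance = 1e-6)
})

test_that("fit_linear equals the closed-form normal-equations oracle", {
  # exact line
  temp <- seq(20, 50, by = 3)
  exact <- fit_linear(anisotropy_curve(temp, 0.4 - 0.002 * temp))
  expect_equal(exact$slope, -0.002, tolerance = 1e-10)
  expect_equal(exact$intercept, 0.4, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)
  # random instances against the oracle
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(3:20, 1)
      x <- sort(runif(n, 20, 50)) + seq_len(n) * 1e-6
      y <- runif(1, 0.05, 0.2) + runif(1, -0.003, 0.003) * x + rnorm(n, 0, 0.01)
      got <- fit_linear(anisotropy_curve(x, y))
      want <- ols_oracle(x, y)
      expect_equal(got$slope, want$slope, tolerance = 1e-10)
      expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
      expect_equal(got$adjusted_r_squared, want$adjusted_r_squared,
                   tolerance = 1e-10)
    }
  })
  # no-signal case: adjusted R^2 at or below zero, slope near zero
  withr::with_seed(32, {
    noise <- fit_linear(anisotropy_curve(temp, 0.25 + rnorm(length(temp), 0, 0.004)))
  })
  expect_lte(noise$adjusted_r_squared, noise$r_squared)
  expect_lt(abs(noise$slope), 1e-3)
  expect_error(fit_linear(anisotropy_curve(c(20, 25), c(0.1, 0.1))),
               class = "membrafluor_invalid")
})

test_that("T_m recovery over 200 noisy simulations is unbiased and tight", {
  w <- slope_width_for_lpw(4.4)
  tm <- vapply(1:200, function(i) {
    sim <- simulate_polarized_melt(slope_width = w, noise_sd = 0.005,
                                   n_replicates = 1, seed = 5000 + i)
    ma <- suppressWarnings(
      melting_analysis(anisotropy_curve_from_readings(sim$readings)))
    ma$t_m
  }, numeric(1))
  expect_lt(abs(mean(tm) - 39.3), 0.1)
  expect_lt(sd(tm), 0.6)
})

test_that("slope_width_for_lpw inverts the two-stage width mapping", {
  # closed form: analytic FWHM of the logistic derivative
  expect_equal(slope_width_for_lpw(4.4, method = "closed_form"),
               4.4 / (4 * log(1 + sqrt(2))), tolerance = 1e-12)
  # calibrated: the noiseless pipeline returns exactly the requested LPW
  for (lpw in c(2.3, 4.4)) {
    w <- slope_width_for_lpw(lpw)
    sim <- simulate_polarized_melt(slope_width = w, noise_sd = 0, n_replicates = 1)
    ma <- melting_analysis(anisotropy_curve_from_readings(sim$readings))
    expect_equal(ma$lpw, lpw, tolerance = 1e-5)
  }
})
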