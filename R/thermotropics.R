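# Melting-curve inference: Boltzmann sigmoid fit of r(T), Lorentzian fit of
# its first derivative (T_m and peak width), and linear r(T) regression for
# non-melting (liquid-ordered) samples.

# Descending Boltzmann sigmoid: gel plateau r_gel at low T, fluid plateau
# r_fluid at high T, midpoint t_half, steepness slope_width (degC).
boltzmann_model <- function(temperature, r_gel, r_fluid, t_half, slope_width) {
  r_fluid + (r_gel - r_fluid) / (1 + exp((temperature - t_half) / slope_width))
}

# FWHM-parameterized Lorentzian peak (area/offset/center/fwhm), the peak
# convention of standard peak-fitting software.
lorentzian_model <- function(temperature, offset, area, fwhm, center) {
  offset + (2 * area / pi) * fwhm / (4 * (temperature - center)^2 + fwhm^2)
}

# Shared least-squares backend: nls (port, bounded, scaleOffset so exact
# zero-residual fits converge) with a BFGS polish fallback. Returns
# list(par, residual_rms, converged, message).
ls_fit <- function(x, y, fn, start, lower = NULL) {
  par_names <- names(start)
  upper <- rep(Inf, length(start))
  if (is.null(lower)) lower <- rep(-Inf, length(start))
  env <- new.env(parent = baseenv())
  assign("..fn", fn, envir = env)
  form <- stats::as.formula(
    paste0("..y ~ ..fn(..x, ", paste(par_names, collapse = ", "), ")"),
    env = env)
  fit <- try(stats::nls(
    form, data = list(..x = x, ..y = y),
    start = start, algorithm = "port", lower = lower, upper = upper,
    control = stats::nls.control(maxiter = 10000, scaleOffset = 1,
                                 warnOnly = FALSE)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    par <- stats::coef(fit)
    res <- y - do.call(fn, c(list(x), as.list(par)))
    return(list(par = par, residual_rms = sqrt(mean(res^2)),
                converged = fit$convInfo$isConv, message = "nls/port"))
  }
  nls_msg <- attr(fit, "condition")$message
  # polish from the start values with a bounded quasi-Newton pass
  sse <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    sum((y - do.call(fn, c(list(x), as.list(p))))^2)
  }
  o <- try(stats::optim(unlist(start), sse, method = "BFGS",
                        control = list(maxit = 10000, reltol = 1e-14)),
           silent = TRUE)
  if (inherits(o, "try-error")) {
    return(list(par = unlist(start), residual_rms = NA_real_,
                converged = FALSE,
                message = paste("nls:", nls_msg, "| optim:",
                                attr(o, "condition")$message)))
  }
  par <- stats::setNames(pmin(pmax(o$par, lower), upper), par_names)
  res <- y - do.call(fn, c(list(x), as.list(par)))
  list(par = par, residual_rms = sqrt(mean(res^2)),
       converged = o$convergence == 0,
       message = paste("optim fallback after nls:", nls_msg))
}

#' Boltzmann sigmoid fit of an anisotropy melting curve
#'
#' Fits `r(T) = r_fluid + (r_gel - r_fluid) / (1 + exp((T - t_half) /
#' slope_width))`: a descending sigmoid from the gel-phase plateau `r_gel`
#' to the fluid-phase plateau `r_fluid` with midpoint `t_half` and
#' steepness parameter `slope_width` (degrees C).
#'
#' Default initialization: plateaus from the means of the three lowest /
#' highest temperature points, `t_half` from the temperature whose `r` is
#' closest to the plateau midpoint (ties broken towards the lowest
#' temperature), `slope_width = 1`.
#'
#' @param curve An [anisotropy_curve()] with at least 6 points spanning
#'   both plateaus.
#' @param init Optional named list overriding any of the four start values.
#' @return A `melting_fit`: `r_gel`, `r_fluid`, `t_half`, `slope_width`,
#'   `residual_rms`, `converged`, `diagnostics`. A flat (no-transition)
#'   curve yields `converged = FALSE`, never a silent number.
#' @export
fit_boltzmann <- function(curve, init = NULL) {
  curve <- as_anisotropy_curve(curve)
  if (nrow(curve) < 6) {
    mf_stop("at least 6 temperature points are required for a sigmoid fit")
  }
  temp <- curve$temperature_C
  r <- curve$r
  lo3 <- mean(r[order(temp)[1:3]])
  hi3 <- mean(r[order(temp, decreasing = TRUE)[1:3]])
  mid <- (lo3 + hi3) / 2
  start <- list(r_gel = lo3, r_fluid = hi3,
                t_half = temp[which.min(abs(r - mid))],  # lowest-T tie wins
                slope_width = 1)
  if (!is.null(init)) start[names(init)] <- init
  if (diff(range(r)) < 1e-12) {
    return(structure(list(
      r_gel = r[1], r_fluid = r[1], t_half = NA_real_, slope_width = NA_real_,
      residual_rms = 0, converged = FALSE,
      diagnostics = "flat curve: no transition to fit"),
      class = "melting_fit"))
  }
  fit <- ls_fit(temp, r, boltzmann_model, start,
                lower = c(-0.5, -0.5, min(temp) - 20, 1e-4))
  converged <- fit$converged && abs(fit$par["r_gel"] - fit$par["r_fluid"]) > 1e-6
  structure(list(
    r_gel = unname(fit$par["r_gel"]), r_fluid = unname(fit$par["r_fluid"]),
    t_half = unname(fit$par["t_half"]),
    slope_width = unname(fit$par["slope_width"]),
    residual_rms = fit$residual_rms, converged = converged,
    diagnostics = fit$message), class = "melting_fit")
}

#' Analytic first-derivative profile of a fitted sigmoid
#'
#' Evaluates `|dr/dT|` of a converged Boltzmann fit on a fine temperature
#' grid. For the logistic sigmoid the derivative is a single symmetric peak
#' centred at `t_half` with height `|r_gel - r_fluid| / (4 slope_width)`.
#' The analytic derivative is used instead of finite differences of the raw
#' 2-3 degree-spaced data, which would be unstable.
#'
#' @param fit A converged `melting_fit`.
#' @param t_min,t_max Profile window in degrees C.
#' @param step Grid step in degrees C (default 0.1).
#' @return Data frame (`temperature_C`, `dr_dT`) of class
#'   `derivative_profile`.
#' @export
derivative_profile <- function(fit, t_min, t_max, step = 0.1) {
  if (!inherits(fit, "melting_fit")) mf_stop("'fit' must be a melting_fit")
  if (!isTRUE(fit$converged)) {
    mf_stop("cannot differentiate an unconverged melting fit",
            class = "membrafluor_degenerate")
  }
  check_numeric(step, "step", positive = TRUE, scalar = TRUE)
  temp <- seq(t_min, t_max, by = step)
  p <- stats::plogis((temp - fit$t_half) / fit$slope_width)
  d <- abs(fit$r_gel - fit$r_fluid) / fit$slope_width * p * (1 - p)
  structure(data.frame(temperature_C = temp, dr_dT = d),
            class = c("derivative_profile", "data.frame"))
}

#' Lorentzian peak fit
#'
#' Least-squares fit of `y(T) = offset + (2 area / pi) * fwhm /
#' (4 (T - center)^2 + fwhm^2)` to a single-peaked profile. On melting-curve
#' derivatives the fitted `center` is reported as the main transition
#' temperature T_m and `fwhm` as the Lorentzian peak width (LPW), a proxy
#' for the width / cooperativity of the transition.
#'
#' @param profile A `derivative_profile` or any data frame with a
#'   temperature column and one value column (first two columns are used).
#' @return A `lorentzian_fit`: `center`, `fwhm`, `area`, `offset`,
#'   `residual_rms`, `converged`, `diagnostics`.
#' @export
fit_lorentzian <- function(profile) {
  x <- profile[[1]]
  y <- profile[[2]]
  check_numeric(x, "temperature")
  check_numeric(y, "profile values")
  if (length(x) < 5) mf_stop("profile too short for a 4-parameter peak fit")
  off0 <- min(y)
  h <- max(y) - off0
  if (h <= 0) {
    return(structure(list(center = NA_real_, fwhm = NA_real_, area = NA_real_,
                          offset = off0, residual_rms = 0, converged = FALSE,
                          diagnostics = "flat profile: no peak"),
                     class = "lorentzian_fit"))
  }
  c0 <- x[which.max(y)]  # ties: which.max takes the first = lowest temperature
  above <- x[y >= off0 + h / 2]
  fw0 <- max(diff(range(above)), mean(diff(x)))
  start <- list(offset = off0, area = h * pi * fw0 / 2, fwhm = fw0, center = c0)
  fit <- ls_fit(x, y, lorentzian_model, start,
                lower = c(-Inf, 0, 1e-9, -Inf))
  conv <- fit$converged && fit$par["fwhm"] > 0
  if (conv && (fit$par["center"] < min(x) || fit$par["center"] > max(x))) {
    mf_warn("Lorentzian center outside the fitted temperature window",
            class = "membrafluor_plausibility")
  }
  structure(list(center = unname(fit$par["center"]),
                 fwhm = unname(fit$par["fwhm"]),
                 area = unname(fit$par["area"]),
                 offset = unname(fit$par["offset"]),
                 residual_rms = fit$residual_rms, converged = conv,
                 diagnostics = fit$message), class = "lorentzian_fit")
}

#' Two-stage melting analysis: T_m and Lorentzian peak width
#'
#' Chains [fit_boltzmann()] -> [derivative_profile()] -> [fit_lorentzian()]:
#' a sigmoid is fitted to the anisotropy melting curve, its analytic first
#' derivative is evaluated on a fine grid over the data window, and a
#' Lorentzian peak is fitted to the derivative. The Lorentzian `center` is
#' reported as T_m and its FWHM as the Lorentzian peak width (LPW).
#'
#' When a list of replicate curves is supplied, the headline numbers come
#' from the fit to the replicate-mean curve and the per-replicate fits
#' provide the T_m / LPW spread (mean +/- SD across independent
#' measurements). Both are reported; SDs from per-replicate fits are labeled
#' as such and are distinct from fit standard errors.
#'
#' @param curve An [anisotropy_curve()], a polarized-readings data frame
#'   (routed through [anisotropy_curve_from_readings()]), or a list of
#'   replicate curves on a common temperature grid.
#' @param step Derivative grid step in degrees C.
#' @return A `melting_analysis` list: `boltzmann`, `lorentzian`, `t_m`,
#'   `lpw`, and (with replicates) `replicate_t_m`, `replicate_lpw`,
#'   `t_m_sd`, `lpw_sd`. Any stage failure raises a structured error naming
#'   the stage.
#' @export
melting_analysis <- function(curve, step = 0.1) {
  replicate_fits <- NULL
  if (is.list(curve) && !is.data.frame(curve)) {
    curves <- lapply(curve, as_anisotropy_curve)
    temps <- curves[[1]]$temperature_C
    for (cv in curves[-1]) {
      if (!isTRUE(all.equal(cv$temperature_C, temps))) {
        mf_stop("replicate curves must share a common temperature grid")
      }
    }
    rmat <- vapply(curves, function(cv) cv$r, numeric(length(temps)))
    mean_curve <- anisotropy_curve(
      temps, rowMeans(rmat),
      sd = apply(rmat, 1, stats::sd), n = length(curves))
    replicate_fits <- lapply(curves, function(cv) {
      try(melting_analysis(cv, step = step), silent = TRUE)
    })
    curve <- mean_curve
  }
  curve <- as_anisotropy_curve(curve)

  bfit <- tryCatch(fit_boltzmann(curve),
                   error = function(e) mf_stage_stop("fit_boltzmann", conditionMessage(e)))
  if (!isTRUE(bfit$converged)) {
    mf_stage_stop("fit_boltzmann",
                  paste("sigmoid fit did not converge:", bfit$diagnostics))
  }
  profile <- tryCatch(
    derivative_profile(bfit, min(curve$temperature_C), max(curve$temperature_C),
                       step = step),
    error = function(e) mf_stage_stop("derivative_profile", conditionMessage(e)))
  lfit <- tryCatch(fit_lorentzian(profile),
                   error = function(e) mf_stage_stop("fit_lorentzian", conditionMessage(e)))
  if (!isTRUE(lfit$converged)) {
    mf_stage_stop("fit_lorentzian",
                  paste("peak fit did not converge:", lfit$diagnostics))
  }
  out <- list(boltzmann = bfit, lorentzian = lfit,
              t_m = lfit$center, lpw = lfit$fwhm)
  if (!is.null(replicate_fits)) {
    ok <- !vapply(replicate_fits, inherits, logical(1), "try-error")
    out$replicate_t_m <- vapply(replicate_fits[ok], `[[`, numeric(1), "t_m")
    out$replicate_lpw <- vapply(replicate_fits[ok], `[[`, numeric(1), "lpw")
    out$t_m_sd <- stats::sd(out$replicate_t_m)   # across-replicate SD
    out$lpw_sd <- stats::sd(out$replicate_lpw)
    out$n_replicates <- sum(ok)
  }
  structure(out, class = "melting_analysis")
}

#' Linear regression of anisotropy on temperature
#'
#' Ordinary least squares of `r` on `T` for samples without a transition
#' (e.g. the cholesterol-rich liquid-ordered phase). Reports R-squared and
#' the adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - 2)`; a negative
#' adjusted R-squared is permitted and meaningful -- it is the signature of
#' a flat, temperature-insensitive response.
#'
#' @param curve An [anisotropy_curve()] with >= 3 points.
#' @return A `linear_fit`: `slope` (per degree C), `intercept`,
#'   `r_squared`, `adjusted_r_squared`, `n_points`, `residual_rms`.
#' @export
fit_linear <- function(curve) {
  curve <- as_anisotropy_curve(curve)
  if (nrow(curve) < 3) mf_stop("at least 3 points are required")
  if (diff(range(curve$temperature_C)) == 0) {
    mf_stop("all temperatures identical: slope undefined")
  }
  fit <- stats::lm(r ~ temperature_C, data = curve)
  n <- nrow(curve)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((curve$r - mean(curve$r))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
    n_points = n,
    residual_rms = sqrt(ssr / n)), class = "linear_fit")
}

#' Sigmoid steepness for a target Lorentzian peak width
#'
#' The two-stage analysis maps the sigmoid steepness `slope_width` to a
#' fitted Lorentzian FWHM (LPW). The analytic FWHM of the logistic
#' derivative is `4 log(1 + sqrt(2)) * slope_width ~= 3.5255 slope_width`
#' (`method = "closed_form"`), but because a Lorentzian is not the exact
#' shape of the logistic derivative the least-squares FWHM also depends
#' mildly on the fitting window. `method = "calibrated"` (default) solves
#' `slope_width` numerically so that the noiseless two-stage pipeline on
#' the stated window returns exactly `lpw`; this is the inverse mapping the
#' synthetic generator uses.
#'
#' @param lpw Target Lorentzian peak width (degrees C, > 0).
#' @param center Sigmoid midpoint used during calibration (degrees C).
#' @param t_min,t_max,step Derivative window matching the analysis.
#' @param method `"calibrated"` or `"closed_form"`.
#' @return `slope_width` in degrees C.
#' @export
slope_width_for_lpw <- function(lpw, center = 39.3, t_min = 20, t_max = 51,
                                step = 0.1, method = c("calibrated", "closed_form")) {
  check_numeric(lpw, "lpw", positive = TRUE, scalar = TRUE)
  method <- match.arg(method)
  closed <- lpw / (4 * log(1 + sqrt(2)))
  if (method == "closed_form") return(closed)
  fitted_lpw <- function(w) {
    fit <- structure(list(r_gel = 0.3, r_fluid = 0.07, t_half = center,
                          slope_width = w, converged = TRUE),
                     class = "melting_fit")
    lf <- fit_lorentzian(derivative_profile(fit, t_min, t_max, step = step))
    lf$fwhm
  }
  stats::uniroot(function(w) fitted_lpw(w) - lpw,
                 lower = closed / 2, upper = closed * 2, tol = 1e-8)$root
}

as_anisotropy_curve <- function(x) {
  if (inherits(x, "anisotropy_curve")) return(x)
  if (is.data.frame(x) && all(c("i_vv", "i_vh") %in% names(x))) {
    return(anisotropy_curve_from_readings(x))
  }
  if (is.data.frame(x) && all(c("temperature_C", "r") %in% names(x))) {
    return(anisotropy_curve(x$temperature_C, x$r,
                            if (is.null(x$sd)) NA_real_ else x$sd,
                            if (is.null(x$n)) 1L else x$n))
  }
  mf_stop("cannot interpret input as an anisotropy curve")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat("Boltzmann sigmoid fit\n")
  cat(sprintf("  r_gel = %.4f  r_fluid = %.4f\n", x$r_gel, x$r_fluid))
  cat(sprintf("  t_half = %.2f C  slope_width = %.3f C\n", x$t_half, x$slope_width))
  cat(sprintf("  residual RMS = %.3g  converged = %s\n", x$residual_rms, x$converged))
  invisible(x)
}

#' @export
print.melting_analysis <- function(x, ...) {
  cat("Two-stage melting analysis\n")
  cat(sprintf("  T_m  = %.2f C (Lorentzian center)\n", x$t_m))
  cat(sprintf("  LPW  = %.2f C (Lorentzian FWHM)\n", x$lpw))
  if (!is.null(x$replicate_t_m)) {
    cat(sprintf("  per-replicate T_m = %.2f +/- %.2f C (n = %d, across-replicate SD)\n",
                mean(x$replicate_t_m), x$t_m_sd, x$n_replicates))
    cat(sprintf("  per-replicate LPW = %.2f +/- %.2f C\n",
                mean(x$replicate_lpw), x$lpw_sd))
  }
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: slope = %.4g /C, intercept = %.4g\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f (n = %d)\n",
              x$r_squared, x$adjusted_r_squared, x$n_points))
  invisible(x)
}
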