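#' @title Rate estimates from linear fits
#' @description All time-series rates in the package are ordinary
#'   least-squares slopes with an intercept (blanks at time zero need not be
#'   zero), reported with the standard error of the slope. `rate_estimate`
#'   objects support [tidy()] and `print()`.
#' @name rate_estimate
NULL

new_rate_estimate <- function(estimate, std_error, n_points, units,
                              intercept = NA_real_, flag = NA_character_,
                              fit = NULL) {
  structure(
    list(
      estimate = estimate, std_error = std_error, n_points = n_points,
      units = units, intercept = intercept, flag = flag, fit = fit
    ),
    class = "rate_estimate"
  )
}

# OLS slope with intercept; exact fits give zero standard error.
ols_slope <- function(x, y) {
  fit <- lm(y ~ x)
  # exact fits legitimately give zero residuals; keep summary() quiet
  s <- suppressWarnings(summary(fit))$coefficients
  list(
    slope = unname(coef(fit)[2]),
    se = unname(s["x", "Std. Error"]),
    intercept = unname(coef(fit)[1]),
    fit = fit
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %.6g +/- %.3g %s (n = %d)\n",
    x$estimate, x$std_error, x$units, x$n_points
  ))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @rdname rate_estimate
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(
    estimate = x$estimate,
    std_error = x$std_error,
    intercept = x$intercept,
    n_points = x$n_points,
    units = x$units,
    flag = x$flag
  )
}

#' Gross photosynthesis from a light-dark-shift oxygen series
#'
#' Immediately after darkening, photosynthetic oxygen production stops while
#' consumption and transport continue unchanged, so the initial rate of
#' oxygen decline at a depth equals the gross photosynthesis rate there. The
#' estimator fits an OLS line to concentration versus time inside the
#' analysis window and sign-flips the slope so a decline yields a positive
#' rate. The window must stay within the few seconds before diffusion
#' re-equilibrates the field (at most `cap_s`).
#'
#' @param series A data frame with `time_s` (seconds from light-off,
#'   increasing) and `conc_umol_per_L`.
#' @param window_s Two-element analysis window in seconds; default the first
#'   5 s.
#' @param cap_s Upper limit for the window end; the dark shift is only
#'   interpretable over the first 5-10 s.
#' @return A [rate_estimate] in µmol L\eqn{^{-1}} s\eqn{^{-1}}. An
#'   increasing oxygen trace returns a negative rate flagged
#'   `"oxygen_increasing"` with a warning, not an error.
#' @export
gross_photosynthesis <- function(series, window_s = c(0, 5), cap_s = 10) {
  series <- as_tibble(series)
  for (col in c("time_s", "conc_umol_per_L")) {
    if (!col %in% names(series)) {
      abort(sprintf("dark-shift series is missing column '%s'", col))
    }
  }
  if (is.unsorted(series$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing")
  }
  if (length(window_s) != 2 || window_s[1] >= window_s[2]) {
    abort("`window_s` must be an increasing pair of times")
  }
  if (window_s[2] > cap_s) {
    abort(sprintf(
      "window end %g s exceeds the %g s dark-shift cap; diffusion has re-equilibrated",
      window_s[2], cap_s
    ))
  }
  sel <- series$time_s >= window_s[1] & series$time_s <= window_s[2]
  if (sum(sel) < 3) {
    abort(sprintf("only %d point(s) in the window; at least 3 required", sum(sel)))
  }
  f <- ols_slope(series$time_s[sel], series$conc_umol_per_L[sel])
  rate <- -f$slope
  flag <- NA_character_
  if (rate < 0) {
    flag <- "oxygen_increasing"
    warn("oxygen increased after darkening; returning a negative photosynthesis rate")
  }
  new_rate_estimate(rate, f$se, sum(sel), "umol L^-1 s^-1",
    intercept = f$intercept, flag = flag, fit = f$fit
  )
}

#' Total excess 15N from labelled dinitrogen
#'
#' Total excess \eqn{^{15}}N = excess \eqn{^{29}N_2 + 2 \times} excess
#' \eqn{^{30}N_2}: a \eqn{^{29}}N\eqn{_2} molecule carries one labelled atom
#' and a \eqn{^{30}}N\eqn{_2} molecule two.
#'
#' @param excess29,excess30 Non-negative excess amounts (nmol of
#'   N\eqn{_2} molecules above natural abundance).
#' @return Total excess \eqn{^{15}}N in nmol N.
#' @examples
#' excess_15n_total(10, 5) # 20
#' @export
excess_15n_total <- function(excess29, excess30) {
  if (any(excess29 < 0, na.rm = TRUE) || any(excess30 < 0, na.rm = TRUE)) {
    abort("excess N2 amounts must be non-negative")
  }
  excess29 + 2 * excess30
}

check_isotope_series <- function(series, need_nox = FALSE) {
  series <- as_tibble(series)
  needed <- c("time_h", "excess29_nmol", "excess30_nmol")
  if (need_nox) needed <- c(needed, "nox_nmol")
  for (col in needed) {
    if (!col %in% names(series)) {
      abort(sprintf("isotope series is missing column '%s'", col))
    }
  }
  if (any(series$time_h < 0) || is.unsorted(series$time_h, strictly = TRUE)) {
    abort("`time_h` must be non-negative and strictly increasing")
  }
  if (nrow(series) < 3) {
    abort("at least 3 timepoints are required for a slope estimate")
  }
  amounts <- unlist(series[intersect(
    c("excess29_nmol", "excess30_nmol", "nox_nmol"), names(series)
  )])
  if (any(amounts < 0, na.rm = TRUE)) {
    abort("isotope amounts must be non-negative")
  }
  series
}

#' Denitrification rate from a closed-vial 15N time series
#'
#' Denitrification is the OLS slope of total excess \eqn{^{15}}N
#' ([excess_15n_total()]) versus incubation time; the standard error of the
#' slope is the reported uncertainty.
#'
#' @param series A data frame with `time_h`, `excess29_nmol`,
#'   `excess30_nmol` (and optionally `nox_nmol`); the first timepoint is the
#'   blank.
#' @return A [rate_estimate] in nmol \eqn{^{15}}N h\eqn{^{-1}}.
#' @export
denitrification_rate <- function(series) {
  series <- check_isotope_series(series)
  total <- excess_15n_total(series$excess29_nmol, series$excess30_nmol)
  f <- ols_slope(series$time_h, total)
  new_rate_estimate(f$slope, f$se, nrow(series), "nmol 15N h^-1",
    intercept = f$intercept, fit = f$fit
  )
}

#' Nitrification rate from a closed-vial 15N time series
#'
#' Nitrification is the OLS slope of (total excess \eqn{^{15}}N +
#' NO\eqn{_x}) versus time: the production of extracellular nitrate and
#' nitrite plus the \eqn{^{15}}N-N\eqn{_2} already denitrified from it.
#' Tracking the sum makes the estimate insensitive to how much of the
#' produced NO\eqn{_x} has been passed on to denitrification.
#'
#' @param series A data frame with `time_h`, `excess29_nmol`,
#'   `excess30_nmol` and `nox_nmol` (vial amounts; see [nox_amount()]).
#' @return A [rate_estimate] in nmol N h\eqn{^{-1}}.
#' @export
nitrification_rate <- function(series) {
  series <- check_isotope_series(series, need_nox = TRUE)
  total <- excess_15n_total(series$excess29_nmol, series$excess30_nmol) +
    series$nox_nmol
  f <- ols_slope(series$time_h, total)
  new_rate_estimate(f$slope, f$se, nrow(series), "nmol N h^-1",
    intercept = f$intercept, fit = f$fit
  )
}

#' Convert a NOx concentration to a vial amount
#'
#' Closed-vial incubations measure NO\eqn{_x} (nitrate + nitrite) as a
#' concentration; the rate estimators work on amounts, so the concentration
#' is multiplied by the liquid volume (vial minus headspace). Conveniently,
#' µmol L\eqn{^{-1}} × mL = nmol.
#'
#' @param conc_umol_per_L NO\eqn{_x} concentration in µmol L\eqn{^{-1}}.
#' @param vial_volume_ml Total vial volume in mL (required; not hard-coded).
#' @param headspace_ml Headspace volume in mL, default 0.
#' @return Amount in nmol.
#' @export
nox_amount <- function(conc_umol_per_L, vial_volume_ml, headspace_ml = 0) {
  if (missing(vial_volume_ml) || !is.numeric(vial_volume_ml) ||
      any(vial_volume_ml <= headspace_ml)) {
    abort("`vial_volume_ml` must be supplied and exceed the headspace")
  }
  conc_umol_per_L * (vial_volume_ml - headspace_ml)
}

#' Calibrate a microsensor against standards
#'
#' Two modes: `"linear"` for amperometric sensors (e.g. Clark-type oxygen,
#' two-point calibrated in air-saturated water and an oxygen-free ascorbate
#' baseline) and `"log_linear"` for potentiometric ion-exchange (LIX)
#' sensors whose signal is Nernstian in log10 activity, calibrated in a
#' dilution series. A two-point linear calibration passes exactly through
#' both standards.
#'
#' @param signal Sensor readings at the standards.
#' @param concentration Standard concentrations (µmol L\eqn{^{-1}});
#'   strictly positive for `"log_linear"`.
#' @param mode `"linear"` (≥ 2 standards) or `"log_linear"` (≥ 3 standards).
#' @return A `sensor_calibration` object; use [predict()] to map signals to
#'   concentrations.
#' @examples
#' cal <- calibrate_sensor(c(0.2, 2.2), c(0, 250))
#' predict(cal, 1.2) # 125
#' @export
calibrate_sensor <- function(signal, concentration,
                             mode = c("linear", "log_linear")) {
  mode <- match.arg(mode)
  if (length(signal) != length(concentration)) {
    abort("`signal` and `concentration` must have the same length")
  }
  o <- order(concentration)
  signal <- signal[o]
  concentration <- concentration[o]
  mono <- function(v) all(diff(v) > 0) || all(diff(v) < 0)
  if (!mono(concentration) || !mono(signal)) {
    abort("standards must be strictly monotone in both signal and concentration")
  }
  if (mode == "linear") {
    if (length(signal) < 2) abort("linear calibration needs at least 2 standards")
    fit <- lm(concentration ~ signal)
    coefs <- coef(fit)
  } else {
    if (length(signal) < 3) abort("log-linear calibration needs at least 3 standards")
    if (any(concentration <= 0)) {
      abort("log-linear calibration requires strictly positive concentrations")
    }
    fit <- lm(signal ~ log10(concentration))
    coefs <- coef(fit) # signal = E0 + S * log10(conc)
  }
  structure(
    list(mode = mode, coefficients = coefs, fit = fit, n = length(signal)),
    class = "sensor_calibration"
  )
}

#' @rdname calibrate_sensor
#' @param object A `sensor_calibration`.
#' @param new_signal Signals to convert to concentrations.
#' @param ... Unused.
#' @export
predict.sensor_calibration <- function(object, new_signal, ...) {
  cf <- object$coefficients
  if (object$mode == "linear") {
    unname(cf[1] + cf[2] * new_signal)
  } else {
    unname(10^((new_signal - cf[1]) / cf[2]))
  }
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf(
    "<sensor_calibration> %s, %d standards; slope %.6g\n",
    x$mode, x$n, x$coefficients[2]
  ))
  invisible(x)
}

#' Light attenuation from a spectral scalar-irradiance profile
#'
#' Fits the band-averaged relative scalar irradiance to an exponential decay
#' \eqn{I(z) = e^{-kz}} by log-linear OLS and reports the attenuation
#' coefficient `k` and the depth `z_p` at which a fraction `p` of surface
#' light remains (\eqn{z_p = -\ln p / k}). Wavelengths whose relative
#' irradiance rises above the surface value at depth — caused by
#' photopigment fluorescence or strong scattering with weak absorption,
#' typically in the 700-800 nm band — are excluded from the fit and reported
#' separately. Each wavelength is first renormalized to its own surface
#' value.
#'
#' @param irradiance Long-format data frame with `depth_um`,
#'   `wavelength_nm`, `rel_irradiance` (fraction of the surface value).
#' @param band_nm Two-element wavelength band over which to average.
#' @param p Remaining-light fraction defining `z_p`; default 0.1 (the depth
#'   by which 90% of surface light is absorbed).
#' @return A `light_attenuation` object with `k_per_um`, `k_std_error`,
#'   `z_p_um`, the excluded `excess` wavelengths, and the band-mean
#'   profile; supports [glance()] and [autoplot()].
#' @export
light_attenuation <- function(irradiance, band_nm = c(400, 700), p = 0.1) {
  irradiance <- as_tibble(irradiance)
  for (col in c("depth_um", "wavelength_nm", "rel_irradiance")) {
    if (!col %in% names(irradiance)) {
      abort(sprintf("irradiance profile is missing column '%s'", col))
    }
  }
  band <- irradiance[
    irradiance$wavelength_nm >= band_nm[1] &
      irradiance$wavelength_nm <= band_nm[2], ,
    drop = FALSE
  ]
  if (nrow(band) == 0) abort("no wavelengths inside `band_nm`")
  surface_depth <- min(band$depth_um)

  # renormalize each wavelength to its surface value
  band <- dplyr::group_by(band, .data$wavelength_nm)
  band <- dplyr::mutate(
    band,
    surface = .data$rel_irradiance[.data$depth_um == surface_depth][1],
    rel_irradiance = ifelse(.data$surface > 0,
      .data$rel_irradiance / .data$surface, .data$rel_irradiance
    )
  )
  band <- dplyr::ungroup(band)

  excess_tbl <- dplyr::summarise(
    dplyr::group_by(band, .data$wavelength_nm),
    max_rel_irradiance = max(.data$rel_irradiance[.data$depth_um > surface_depth]),
    .groups = "drop"
  )
  excess_tbl <- excess_tbl[excess_tbl$max_rel_irradiance > 1 + 1e-9, , drop = FALSE]
  clean <- band[!band$wavelength_nm %in% excess_tbl$wavelength_nm, , drop = FALSE]
  if (nrow(clean) == 0) {
    abort("all wavelengths in the band show above-surface (excess) irradiance")
  }

  mean_profile <- dplyr::summarise(
    dplyr::group_by(clean, .data$depth_um),
    mean_rel_irradiance = mean(.data$rel_irradiance),
    .groups = "drop"
  )
  usable <- mean_profile[mean_profile$mean_rel_irradiance > 0, , drop = FALSE]
  if (nrow(usable) < 3) {
    abort(sprintf(
      "only %d depth(s) with positive band-mean irradiance; at least 3 required",
      nrow(usable)
    ))
  }
  f <- ols_slope(usable$depth_um, log(usable$mean_rel_irradiance))
  k <- -f$slope
  flag <- NA_character_
  z_p <- if (k > 0) -log(p) / k else NA_real_
  if (k <= 0) flag <- "no_attenuation"

  structure(
    list(
      k_per_um = k, k_std_error = f$se, z_p_um = z_p, p = p,
      band_nm = band_nm, excess = excess_tbl, n_depths = nrow(usable),
      profile = mean_profile, flag = flag, fit = f$fit
    ),
    class = "light_attenuation"
  )
}

#' @export
print.light_attenuation <- function(x, ...) {
  cat(sprintf(
    "<light_attenuation> band %g-%g nm: k = %.4g um^-1, z_%g%% = %.4g um\n",
    x$band_nm[1], x$band_nm[2], x$k_per_um, 100 * x$p, x$z_p_um
  ))
  if (nrow(x$excess) > 0) {
    cat(sprintf(
      "  %d wavelength(s) with above-surface irradiance excluded from the fit\n",
      nrow(x$excess)
    ))
  }
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @rdname light_attenuation
#' @param x A `light_attenuation`.
#' @param ... Unused.
#' @export
glance.light_attenuation <- function(x, ...) {
  tibble(
    k_per_um = x$k_per_um, k_std_error = x$k_std_error,
    z_p_um = x$z_p_um, p = x$p,
    band_lo_nm = x$band_nm[1], band_hi_nm = x$band_nm[2],
    n_depths = x$n_depths, n_excess_wavelengths = nrow(x$excess),
    flag = x$flag
  )
}

#' @rdname light_attenuation
#' @param object A `light_attenuation`.
#' @export
autoplot.light_attenuation <- function(object, ...) {
  prof <- object$profile
  ggplot2::ggplot(
    prof,
    ggplot2::aes(x = .data$mean_rel_irradiance, y = .data$depth_um)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(i) -log(i) / object$k_per_um,
      linetype = "dashed"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "band-mean relative irradiance",
      y = expression(paste("depth (", mu, "m)")),
      title = sprintf(
        "k = %.4g per um, z_%g%% = %.0f um",
        object$k_per_um, 100 * object$p, object$z_p_um
      )
    )
}

#' Volumetric carbon-fixation rate from a microradiograph summary
#'
#' Converts detector counts over a section region into a volumetric fixation
#' rate: counts are made absolute with a user-supplied conversion factor,
#' normalized per mm\eqn{^2} of imaged area, divided by the section
#' thickness to reach mm\eqn{^3}, and divided by the incubation time. When a
#' blank (killed-control) summary is supplied its rate is subtracted.
#'
#' @param counts Detector counts in the region (≥ 0).
#' @param area_mm2 Imaged region area in mm\eqn{^2}.
#' @param thickness_um Section thickness in µm.
#' @param duration_h Incubation duration in hours.
#' @param conversion_nmol_per_count nmol of fixed carbon per count. Required:
#'   the specific activity of the tracer is instrument- and batch-specific,
#'   so counts cannot be made absolute without it.
#' @param blank Optional list or one-row data frame with the same fields
#'   (`counts`, `area_mm2`, `thickness_um`, `duration_h`, optionally its own
#'   `conversion_nmol_per_count`) describing a killed control.
#' @return Rate in nmol C mm\eqn{^{-3}} h\eqn{^{-1}}.
#' @examples
#' radiograph_volumetric_rate(1000, 2, 20, 6, 0.01) # 41.67
#' @export
radiograph_volumetric_rate <- function(counts, area_mm2, thickness_um,
                                       duration_h, conversion_nmol_per_count,
                                       blank = NULL) {
  if (missing(conversion_nmol_per_count) ||
      is.null(conversion_nmol_per_count) ||
      any(is.na(conversion_nmol_per_count))) {
    abort(paste(
      "`conversion_nmol_per_count` is required:",
      "detector counts cannot be made absolute without a count-to-mol conversion"
    ))
  }
  if (any(counts < 0)) abort("`counts` must be non-negative")
  if (any(area_mm2 <= 0) || any(thickness_um <= 0) || any(duration_h <= 0)) {
    abort("area, thickness and duration must be positive")
  }
  rate <- counts * conversion_nmol_per_count /
    (area_mm2 * (thickness_um / 1000) * duration_h)
  if (!is.null(blank)) {
    blank <- as.list(blank)
    conv_b <- blank$conversion_nmol_per_count %||% conversion_nmol_per_count
    rate <- rate - radiograph_volumetric_rate(
      blank$counts, blank$area_mm2, blank$thickness_um, blank$duration_h,
      conv_b
    )
  }
  rate
}

#' Scale a per-granule rate to a reactor volumetric rate
#'
#' Multiplies a per-granule rate by the granule number density and converts
#' nmol h\eqn{^{-1}} L\eqn{^{-1}} to mmol L\eqn{^{-1}} d\eqn{^{-1}}
#' (× 24 / 10\eqn{^6}). A deliberately simple scaling helper: it assumes
#' every granule converts at the supplied rate.
#'
#' @param per_granule_rate_nmol_per_h Rate per granule in nmol h\eqn{^{-1}}.
#' @param granules_per_litre Granule number density in L\eqn{^{-1}}.
#' @return Reactor rate in mmol L\eqn{^{-1}} d\eqn{^{-1}}.
#' @export
reactor_scale_rate <- function(per_granule_rate_nmol_per_h,
                               granules_per_litre) {
  if (any(granules_per_litre < 0)) abort("`granules_per_litre` must be >= 0")
  per_granule_rate_nmol_per_h * granules_per_litre * 24 / 1e6
}
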