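#' Define a synthetic granule scenario
#'
#' A scenario is the ground truth behind every synthetic data set: a granule
#' radius, concentric layers with zero-order (concentration-independent)
#' volumetric rates, a bulk concentration fixed at the surface (profiles are
#' measured into the granule from stirred bulk), optional boundary-layer
#' mass transfer, simple exponential optics, a noise level and a seed.
#' Zero-order kinetics admit closed-form reference solutions; wherever
#' consumption would drive the concentration below zero the solver switches
#' it off, producing an anoxic core with zero concentration and zero
#' gradient at the front.
#'
#' @param radius_um Granule radius in µm.
#' @param layers Tibble with columns `r_inner_um`, `r_outer_um`,
#'   `rate_umol_per_L_s` (signed net base rate: positive = production) and
#'   optionally `photo_umol_per_L_s` (gross photosynthesis, ≥ 0, active only
#'   in the light). Layers must tile `[0, radius_um]`. See
#'   [layers_from_depths()].
#' @param bulk_umol_per_L Bulk concentration at the granule surface.
#' @param analyte,diffusion_um2_s Analyte label and optional diffusion
#'   coefficient override (defaults: oxygen 2000, nitrate 1700 µm\eqn{^2}
#'   s\eqn{^{-1}}).
#' @param boundary_layer_um_per_s Optional mass-transfer coefficient; when
#'   given, the surface condition becomes flux matching across a diffusive
#'   boundary layer instead of a fixed bulk concentration.
#' @param attenuation_per_um Scalar-irradiance attenuation coefficient;
#'   default ln(10)/600 µm\eqn{^{-1}} (90% of surface light absorbed within
#'   600 µm).
#' @param surface_irradiance_umol_m2_s Surface scalar irradiance.
#' @param noise_sd_umol_per_L Additive Gaussian noise applied by
#'   [sample_profile()].
#' @param seed Integer seed governing all stochastic draws in the scenario.
#' @return A `granule_scenario` object.
#' @export
granule_scenario <- function(radius_um, layers, bulk_umol_per_L = 250,
                             analyte = "oxygen", diffusion_um2_s = NULL,
                             boundary_layer_um_per_s = NULL,
                             attenuation_per_um = log(10) / 600,
                             surface_irradiance_umol_m2_s = 250,
                             noise_sd_umol_per_L = 0, seed = NULL) {
  if (radius_um <= 0) abort("`radius_um` must be positive")
  layers <- as_tibble(layers)
  for (col in c("r_inner_um", "r_outer_um", "rate_umol_per_L_s")) {
    if (!col %in% names(layers)) {
      abort(sprintf("`layers` is missing required column '%s'", col))
    }
  }
  if (!"photo_umol_per_L_s" %in% names(layers)) {
    layers$photo_umol_per_L_s <- 0
  }
  if (any(layers$photo_umol_per_L_s < 0)) {
    abort("gross photosynthesis (`photo_umol_per_L_s`) must be >= 0")
  }
  layers <- dplyr::arrange(layers, .data$r_inner_um)
  tol <- 1e-6 * radius_um
  if (abs(layers$r_inner_um[1]) > tol ||
      abs(layers$r_outer_um[nrow(layers)] - radius_um) > tol ||
      any(abs(layers$r_outer_um[-nrow(layers)] -
                layers$r_inner_um[-1]) > tol) ||
      any(layers$r_outer_um <= layers$r_inner_um)) {
    abort("`layers` must tile [0, radius_um] without gaps or overlap")
  }
  if (noise_sd_umol_per_L < 0) abort("`noise_sd_umol_per_L` must be >= 0")
  if (bulk_umol_per_L < 0) abort("`bulk_umol_per_L` must be >= 0")
  structure(
    list(
      radius_um = radius_um, layers = layers,
      bulk_umol_per_L = bulk_umol_per_L,
      analyte = analyte,
      diffusion_um2_s = resolve_diffusion(analyte, diffusion_um2_s),
      boundary_layer_um_per_s = boundary_layer_um_per_s,
      attenuation_per_um = attenuation_per_um,
      surface_irradiance_umol_m2_s = surface_irradiance_umol_m2_s,
      noise_sd_umol_per_L = noise_sd_umol_per_L,
      seed = seed
    ),
    class = "granule_scenario"
  )
}

#' @export
print.granule_scenario <- function(x, ...) {
  cat(sprintf(
    "<granule_scenario> R = %g um, %s (D = %g um^2/s), bulk %g umol/L, %d layer(s)\n",
    x$radius_um, x$analyte, x$diffusion_um2_s, x$bulk_umol_per_L,
    nrow(x$layers)
  ))
  print(x$layers, ...)
  invisible(x)
}

#' Build scenario layers from depth bands
#'
#' Microsensor work describes stratification in depth from the surface;
#' the solver works in radius. This helper converts contiguous depth bands
#' (e.g. production in the outer 0-500 µm) into radius layers tiling
#' `[0, R]`.
#'
#' @param radius_um Granule radius in µm.
#' @param depth_breaks_um Increasing depth band boundaries starting at 0 and
#'   ending at `radius_um` (the centre).
#' @param rate_umol_per_L_s Signed base rate per band (length
#'   `length(depth_breaks_um) - 1`), positive = production.
#' @param photo_umol_per_L_s Gross photosynthesis per band (recycled).
#' @return A layers tibble for [granule_scenario()].
#' @export
layers_from_depths <- function(radius_um, depth_breaks_um,
                               rate_umol_per_L_s, photo_umol_per_L_s = 0) {
  nb <- length(depth_breaks_um)
  if (nb < 2 || is.unsorted(depth_breaks_um, strictly = TRUE) ||
      depth_breaks_um[1] != 0 || depth_breaks_um[nb] != radius_um) {
    abort("`depth_breaks_um` must increase from 0 to `radius_um`")
  }
  if (length(rate_umol_per_L_s) != nb - 1) {
    abort("need one rate per depth band")
  }
  photo <- rep_len(photo_umol_per_L_s, nb - 1)
  tibble(
    r_inner_um = radius_um - depth_breaks_um[-1],
    r_outer_um = radius_um - depth_breaks_um[-nb],
    rate_umol_per_L_s = rate_umol_per_L_s,
    photo_umol_per_L_s = photo
  )
}

# Volume-weighted (r^3 measure) average of a per-layer value over [a, b].
layer_shell_average <- function(r_inner, r_outer, value, a, b) {
  lo <- pmax(r_inner, a)
  hi <- pmin(r_outer, b)
  w <- pmax(0, hi^3 - lo^3)
  sum(value * w) / (b^3 - a^3)
}

# Point lookup of a per-layer value at radius r (surface belongs to the
# outermost layer, the centre to the innermost).
layer_value_at <- function(layers, col, r) {
  vapply(r, function(ri) {
    hit <- which(ri >= layers$r_inner_um & ri <= layers$r_outer_um)
    layers[[col]][hit[length(hit)]]
  }, numeric(1))
}

# Finite-volume steady state on a uniform radial grid. Returns the grid,
# the concentration field, the realized (front-gated) volumetric rate per
# cell and bookkeeping used by the transient solver.
steady_field <- function(scenario, grid_um = 5, light = TRUE) {
  R <- scenario$radius_um
  D <- scenario$diffusion_um2_s
  n_cells <- max(3L, as.integer(round(R / grid_um)))
  h <- R / n_cells
  r <- seq(0, R, by = h) # nodes, length n_cells + 1
  m <- length(r)
  face_r <- (r[-m] + r[-1]) / 2 # faces between adjacent nodes
  f2 <- face_r^2
  cell_lo <- c(0, face_r)
  cell_hi <- c(face_r, R)
  vc <- (cell_hi^3 - cell_lo^3) / 3 # cell volume / (4 pi)

  ly <- scenario$layers
  q_total <- ly$rate_umol_per_L_s + if (light) ly$photo_umol_per_L_s else 0
  qpos_l <- pmax(q_total, 0)
  qneg_l <- pmin(q_total, 0)
  qpos <- vapply(seq_len(m), function(i) {
    layer_shell_average(ly$r_inner_um, ly$r_outer_um, qpos_l,
      cell_lo[i], cell_hi[i])
  }, numeric(1))
  qneg <- vapply(seq_len(m), function(i) {
    layer_shell_average(ly$r_inner_um, ly$r_outer_um, qneg_l,
      cell_lo[i], cell_hi[i])
  }, numeric(1))

  km <- scenario$boundary_layer_um_per_s
  bulk <- scenario$bulk_umol_per_L
  dh <- D / h

  solve_once <- function(active) {
    q <- qpos + qneg * active
    A <- matrix(0, m, m)
    mid <- 2:(m - 1)
    A[cbind(mid, mid - 1)] <- dh * f2[mid - 1]
    A[cbind(mid, mid)] <- -dh * (f2[mid - 1] + f2[mid])
    A[cbind(mid, mid + 1)] <- dh * f2[mid]
    b <- -q * vc
    A[1, 1] <- -dh * f2[1]
    A[1, 2] <- dh * f2[1]
    if (is.null(km)) {
      A[m, m] <- 1
      b[m] <- bulk
    } else {
      A[m, m - 1] <- dh * f2[m - 1]
      A[m, m] <- -dh * f2[m - 1] - km * R^2
      b[m] <- -q[m] * vc[m] - km * R^2 * bulk
    }
    solve(A, b)
  }

  # Zero-order consumption cannot run where C would fall below 0. The
  # resulting complementarity problem is solved by locating the oxic-anoxic
  # front: with consumption switched off in the k innermost cells the core
  # concentration increases monotonically with k, so the smallest k that
  # keeps the centre non-negative brackets the front to one grid cell.
  active <- rep(TRUE, m)
  conc <- solve_once(active)
  if (min(conc) < 0) {
    with_core_off <- function(k) {
      act <- rep(TRUE, m)
      if (k > 0) act[seq_len(k)] <- FALSE
      act
    }
    lo <- 0
    hi <- m - 1
    c_hi <- solve_once(with_core_off(hi))
    if (c_hi[1] < 0) {
      abort(sprintf(
        "anoxic-front iteration did not converge; last bracket r = [%g, %g] µm",
        r[lo + 1], r[hi + 1]
      ))
    }
    while (hi - lo > 1) {
      k <- (lo + hi) %/% 2
      if (solve_once(with_core_off(k))[1] >= 0) hi <- k else lo <- k
    }
    active <- with_core_off(hi)
    conc <- solve_once(active)
    if (any(conc < -1e-9 * max(bulk, 1))) {
      bad <- r[conc < -1e-9 * max(bulk, 1)]
      abort(sprintf(
        "concentration fell below zero outside the anoxic core (r = %g-%g µm); scenario not supported by a single centred front",
        min(bad), max(bad)
      ))
    }
  }
  conc <- pmax(conc, 0)
  q_realized <- qpos + qneg * active

  # diagnostics: one-sided second-order surface gradient vs volume integral
  dcdr_R <- (3 * conc[m] - 4 * conc[m - 1] + conc[m - 2]) / (2 * h)
  surface_flux <- fick_flux_nmol_h(D, dcdr_R, R) # outward positive
  q_integral <- sum(q_realized * vc) * 4 * pi * UMOL_L_PER_NMOL_UM3 *
    SECONDS_PER_HOUR
  front <- if (any(!active)) max(r[!active]) else NA_real_

  list(
    r = r, conc = conc, h = h, f2 = f2, vc = vc,
    cell_lo = cell_lo, cell_hi = cell_hi,
    qpos = qpos, qneg = qneg, q_realized = q_realized,
    surface_flux_nmol_per_h = surface_flux,
    q_integral_nmol_per_h = q_integral,
    front_radius_um = front, light = light, grid_um = h
  )
}

#' Solve the steady-state spherical reaction-diffusion problem
#'
#' Solves \eqn{\frac{D}{r^2}\frac{d}{dr}\!\left(r^2 \frac{dC}{dr}\right) =
#' -Q(r)} with zero gradient at the centre and either a fixed bulk
#' concentration or boundary-layer flux matching at the surface, on a
#' conservative finite-volume grid. Zero-order consumption is switched off
#' wherever it would drive the concentration below zero (active-set
#' iteration), so strong consumption produces an anoxic core with `C = 0`
#' and zero gradient at the front; the front is located to within one grid
#' cell. Because the scheme is conservative and exact for quadratics, a
#' uniform-consumption scenario reproduces the closed form
#' \eqn{C(r) = C_R - q(R^2 - r^2)/(6D)} to machine precision.
#'
#' @param scenario A [granule_scenario()].
#' @param grid_um Radial grid spacing in µm (≤ 10 µm recommended for
#'   verification-grade runs).
#' @param light If `TRUE`, gross photosynthesis layers are active.
#' @return A `granule_field`: a tibble with `r_um`, `depth_um` and
#'   `conc_umol_per_L`, with attributes `front_radius_um`,
#'   `surface_flux_nmol_per_h`, `q_integral_nmol_per_h` (both outward
#'   positive; equal at steady state), `realized_q` (the front-gated
#'   volumetric rate field) and the scenario.
#' @export
solve_steady_state <- function(scenario, grid_um = 5, light = TRUE) {
  stopifnot(inherits(scenario, "granule_scenario"))
  fs <- steady_field(scenario, grid_um = grid_um, light = light)
  out <- tibble(
    r_um = fs$r,
    depth_um = scenario$radius_um - fs$r,
    conc_umol_per_L = fs$conc
  )
  attr(out, "scenario") <- scenario
  attr(out, "grid_um") <- fs$grid_um
  attr(out, "light") <- light
  attr(out, "front_radius_um") <- fs$front_radius_um
  attr(out, "surface_flux_nmol_per_h") <- fs$surface_flux_nmol_per_h
  attr(out, "q_integral_nmol_per_h") <- fs$q_integral_nmol_per_h
  attr(out, "realized_q") <- list(
    cell_lo = fs$cell_lo, cell_hi = fs$cell_hi,
    q_umol_per_L_s = fs$q_realized
  )
  class(out) <- c("granule_field", class(out))
  out
}

#' Simulate a light-dark-shift transient
#'
#' Starts from the illuminated steady state, switches gross photosynthesis
#' off at `t = 0`, and integrates the transient diffusion-reaction equation
#' by the method of lines (`deSolve::lsoda`, banded Jacobian). At each depth
#' the initial rate of concentration change equals minus the local gross
#' photosynthesis before diffusion relaxes the field — the premise of the
#' dark-shift method.
#'
#' @param scenario A [granule_scenario()] whose layers carry
#'   `photo_umol_per_L_s`.
#' @param depths_um Probe depths (µm from the surface) at which traces are
#'   returned.
#' @param duration_s Length of the simulated dark period.
#' @param sample_hz Output sampling rate (≥ 1 Hz).
#' @param grid_um Radial grid spacing of the method-of-lines grid.
#' @param keep_field If `TRUE`, the full space-time field is attached as
#'   attribute `field` (a times × radii matrix) for mass-balance checks.
#' @return A tibble with `depth_um`, `time_s`, `conc_umol_per_L`; the
#'   imposed gross photosynthesis at each probe depth is attached as
#'   attribute `p_gross_umol_per_L_s`.
#' @export
solve_dark_shift <- function(scenario, depths_um, duration_s = 20,
                             sample_hz = 1, grid_um = 5,
                             keep_field = FALSE) {
  stopifnot(inherits(scenario, "granule_scenario"))
  R <- scenario$radius_um
  if (any(depths_um < 0 | depths_um > R)) {
    abort("probe depths must lie within [0, radius_um]")
  }
  fs <- steady_field(scenario, grid_um = grid_um, light = TRUE)

  # dark source field: base rates only, photosynthesis off
  ly <- scenario$layers
  m <- length(fs$r)
  qpos_d <- vapply(seq_len(m), function(i) {
    layer_shell_average(ly$r_inner_um, ly$r_outer_um,
      pmax(ly$rate_umol_per_L_s, 0), fs$cell_lo[i], fs$cell_hi[i])
  }, numeric(1))
  qneg_d <- vapply(seq_len(m), function(i) {
    layer_shell_average(ly$r_inner_um, ly$r_outer_um,
      pmin(ly$rate_umol_per_L_s, 0), fs$cell_lo[i], fs$cell_hi[i])
  }, numeric(1))

  D <- scenario$diffusion_um2_s
  km <- scenario$boundary_layer_um_per_s
  bulk <- scenario$bulk_umol_per_L
  h <- fs$h
  f2 <- fs$f2
  vc <- fs$vc
  dh <- D / h

  rhs <- function(t, conc, parms) {
    face_flux <- dh * f2 * diff(conc) # per face, / (4 pi)
    q <- qpos_d + qneg_d * (conc > 0)
    dc <- numeric(m)
    dc[1] <- face_flux[1] / vc[1] + q[1]
    mid <- 2:(m - 1)
    dc[mid] <- (face_flux[mid] - face_flux[mid - 1]) / vc[mid] + q[mid]
    if (is.null(km)) {
      dc[m] <- 0
    } else {
      dc[m] <- (-face_flux[m - 1] + km * R^2 * (bulk - conc[m])) / vc[m] + q[m]
    }
    list(dc)
  }

  times <- seq(0, duration_s, by = 1 / sample_hz)
  sol <- deSolve::ode(
    y = fs$conc, times = times, func = rhs, parms = NULL,
    method = "lsoda", jactype = "bandint", bandup = 1, banddown = 1,
    rtol = 1e-8, atol = 1e-8
  )
  field <- sol[, -1, drop = FALSE]

  r_probe <- R - depths_um
  traces <- lapply(seq_along(depths_um), function(i) {
    conc_t <- apply(field, 1, function(row) {
      approx(fs$r, row, xout = r_probe[i])$y
    })
    tibble(
      depth_um = depths_um[i],
      time_s = times,
      conc_umol_per_L = conc_t
    )
  })
  out <- dplyr::bind_rows(traces)
  attr(out, "p_gross_umol_per_L_s") <- setNames(
    layer_value_at(ly, "photo_umol_per_L_s", r_probe),
    as.character(depths_um)
  )
  attr(out, "scenario") <- scenario
  if (keep_field) {
    attr(out, "field") <- field
    attr(out, "r_um") <- fs$r
    attr(out, "vc_um3") <- fs$vc * 4 * pi
    attr(out, "q_dark_umol_per_L_s") <- list(qpos = qpos_d, qneg = qneg_d)
    attr(out, "times_s") <- times
  }
  out
}

#' Sample a simulated concentration field at measurement depths
#'
#' Interpolates a fine-grid steady-state field at microsensor measurement
#' depths, adds seeded Gaussian noise, clips at zero, and attaches the
#' ground-truth shell rates — the realized (front-gated) volumetric rates
#' volume-averaged over the shell grid that [invert_profile()] will build
#' from the same depths. This closes the forward-inverse loop: the inversion
#' of a sampled profile can be compared shell by shell against truth.
#'
#' @param field A `granule_field` from [solve_steady_state()].
#' @param depths_um Measurement depths in µm, within `[0, R]`.
#' @param noise_sd Gaussian noise standard deviation in µmol L\eqn{^{-1}};
#'   defaults to the scenario's `noise_sd_umol_per_L`.
#' @param seed Seed for the noise draws; defaults to the scenario seed. The
#'   same seed reproduces the same profile exactly.
#' @return A `simulated_profile`: a profile tibble (`depth_um`,
#'   `conc_umol_per_L`) with attribute `ground_truth`, a tibble of per-shell
#'   true volumetric and net rates.
#' @export
sample_profile <- function(field, depths_um, noise_sd = NULL, seed = NULL) {
  scenario <- attr(field, "scenario")
  if (is.null(scenario)) {
    abort("`field` must come from solve_steady_state()")
  }
  R <- scenario$radius_um
  if (any(depths_um < 0 | depths_um > R)) {
    abort("sampling depths must lie within [0, radius_um]")
  }
  noise_sd <- noise_sd %||% scenario$noise_sd_umol_per_L
  seed <- seed %||% scenario$seed

  r_target <- R - depths_um
  conc <- approx(field$r_um, field$conc_umol_per_L, xout = r_target)$y
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    conc <- conc + rnorm(length(conc), sd = noise_sd)
  }
  conc <- pmax(conc, 0)

  rq <- attr(field, "realized_q")
  grid <- shell_grid(depths_um, R)
  truth_q <- vapply(seq_len(nrow(grid)), function(i) {
    layer_shell_average(
      rq$cell_lo, rq$cell_hi, rq$q_umol_per_L_s,
      grid$r_inner_um[i], grid$r_outer_um[i]
    )
  }, numeric(1))
  truth <- tibble(
    shell = grid$shell,
    depth_um = grid$depth_um,
    truth_volumetric_rate_nmol_per_mm3_per_h = umol_l_s_to_nmol_mm3_h(truth_q),
    truth_net_rate_nmol_per_h = umol_l_s_to_nmol_mm3_h(truth_q) *
      grid$volume_um3 / 1e9
  )

  out <- tibble(depth_um = depths_um, conc_umol_per_L = conc)
  attr(out, "ground_truth") <- truth
  attr(out, "radius_um") <- R
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("simulated_profile", class(out))
  out
}

#' Generate a closed-vial 15N isotope time series with known rates
#'
#' Labelled N\eqn{_2} accumulates linearly at `denitrification ×
#' labelled_fraction` and is split between \eqn{^{29}}N\eqn{_2} and
#' \eqn{^{30}}N\eqn{_2} by random isotope pairing, \eqn{2F(1-F) : F^2} (an
#' assumption of the generator, stated, not a measured split). NO\eqn{_x}
#' accumulates at `nitrification - denitrification` on top of an optional
#' background amount. Gaussian noise is added per observable and amounts are
#' floored at zero; the first timepoint is the blank.
#'
#' @param nitrification_nmol_per_h,denitrification_nmol_per_h True rates.
#' @param labelled_fraction Fraction `F` of the substrate pool that is
#'   \eqn{^{15}}N-labelled, in (0, 1].
#' @param times_h Sampling times in hours (vial kill times).
#' @param noise_sd Gaussian noise SD in nmol; a scalar or a length-3 vector
#'   for (excess29, excess30, nox).
#' @param seed Seed for the noise draws.
#' @param nox0_nmol Background NO\eqn{_x} amount in the vial at time zero.
#' @param label,light,acetate Metadata columns carried through.
#' @return An isotope series tibble (`time_h`, `excess29_nmol`,
#'   `excess30_nmol`, `nox_nmol`, metadata) ready for
#'   [denitrification_rate()] and [nitrification_rate()].
#' @export
generate_isotope_series <- function(nitrification_nmol_per_h,
                                    denitrification_nmol_per_h,
                                    labelled_fraction = 1,
                                    times_h = c(0, 2, 4.5, 5.5),
                                    noise_sd = 0, seed = NULL,
                                    nox0_nmol = 0,
                                    label = "ammonium", light = NA,
                                    acetate = NA) {
  f <- labelled_fraction
  if (length(f) != 1 || f <= 0 || f > 1) {
    abort("`labelled_fraction` must lie in (0, 1]")
  }
  if (any(times_h < 0) || is.unsorted(times_h, strictly = TRUE)) {
    abort("`times_h` must be non-negative and strictly increasing")
  }
  sd3 <- rep_len(noise_sd, 3)
  if (any(sd3 < 0)) abort("`noise_sd` must be >= 0")

  n2_n <- denitrification_nmol_per_h * times_h # nmol N2-N produced
  excess30 <- n2_n * f^2 / 2 # molecules carry 2 N
  excess29 <- n2_n * f * (1 - f)
  nox <- nox0_nmol +
    (nitrification_nmol_per_h - denitrification_nmol_per_h) * times_h

  if (any(sd3 > 0)) {
    if (!is.null(seed)) withr::local_seed(seed)
    k <- length(times_h)
    excess29 <- excess29 + rnorm(k, sd = sd3[1])
    excess30 <- excess30 + rnorm(k, sd = sd3[2])
    nox <- nox + rnorm(k, sd = sd3[3])
  }

  tibble(
    time_h = times_h,
    excess29_nmol = pmax(excess29, 0),
    excess30_nmol = pmax(excess30, 0),
    nox_nmol = pmax(nox, 0),
    label = label, light = light, acetate = acetate
  )
}

#' Generate a spectral scalar-irradiance depth profile
#'
#' Exponential attenuation \eqn{I(z,\lambda) = e^{-k_\lambda z}} relative to
#' the surface, optionally with an above-surface "excess" feature in a
#' near-infrared band peaking a short distance below the surface, emulating
#' photopigment fluorescence or scattering with weak absorption. The surface
#' row is identically 1.
#'
#' @param k_per_um Attenuation coefficient(s): a scalar or one value per
#'   wavelength.
#' @param depths_um Depths at which the profile is evaluated.
#' @param wavelengths_nm Wavelength grid.
#' @param excess_band_nm Optional two-element band in which the excess
#'   feature is added (e.g. `c(700, 800)`); `NULL` for none.
#' @param excess_amplitude,excess_peak_um,excess_width_um Amplitude (added
#'   relative irradiance), peak depth and Gaussian width of the excess
#'   feature.
#' @return A long-format tibble `depth_um`, `wavelength_nm`,
#'   `rel_irradiance` for [light_attenuation()].
#' @export
generate_light_profile <- function(k_per_um, depths_um = seq(0, 600, by = 100),
                                   wavelengths_nm = seq(400, 900, by = 20),
                                   excess_band_nm = NULL,
                                   excess_amplitude = 0.5,
                                   excess_peak_um = 150,
                                   excess_width_um = 75) {
  if (any(k_per_um < 0)) abort("`k_per_um` must be >= 0")
  k <- rep_len(k_per_um, length(wavelengths_nm))
  out <- tidyr::expand_grid(
    wavelength_nm = wavelengths_nm,
    depth_um = depths_um
  )
  out$rel_irradiance <- exp(
    -k[match(out$wavelength_nm, wavelengths_nm)] * out$depth_um
  )
  if (!is.null(excess_band_nm)) {
    in_band <- out$wavelength_nm >= excess_band_nm[1] &
      out$wavelength_nm <= excess_band_nm[2]
    bump <- excess_amplitude *
      exp(-(out$depth_um - excess_peak_um)^2 / (2 * excess_width_um^2)) *
      (out$depth_um > 0)
    out$rel_irradiance[in_band] <- out$rel_irradiance[in_band] +
      bump[in_band]
  }
  out[, c("depth_um", "wavelength_nm", "rel_irradiance")]
}
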