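test_that("steady state matches the uniform-consumption closed form", {
  sc <- granule_scenario(1800, layers_from_depths(1800, c(0, 1800), -0.5),
                         bulk_umol_per_L = 250)
  fld <- solve_steady_state(sc, grid_um = 5)
  exact <- 250 - 0.5 * (1800^2 - fld$r_um^2) / (6 * 2000)
  expect_lt(max(abs(fld$conc_umol_per_L - exact) / exact), 1e-3)
  expect_true(is.na(attr(fld, "front_radius_um")))
})

test_that("a source-free granule equilibrates to the bulk concentration", {
  sc <- granule_scenario(1500, layers_from_depths(1500, c(0, 1500), 0),
                         bulk_umol_per_L = 123)
  fld <- solve_steady_state(sc, grid_um = 10)
  expect_equal(fld$conc_umol_per_L, rep(123, nrow(fld)), tolerance = 1e-12)
})

test_that("strong consumption produces an anoxic core at the analytic front", {
  sc <- anoxic_scenario() # q R^2 / 6D = 270 > bulk 250
  fld <- solve_steady_state(sc, grid_um = 5)
  front <- attr(fld, "front_radius_um")
  expect_false(is.na(front))
  expect_lt(abs(front - analytic_front_radius(1.0, 2000, 1800, 250)), 10)
  core <- fld$conc_umol_per_L[fld$r_um < front]
  expect_lt(max(core), 0.005 * 250) # core is anoxic
  # zero gradient at the front: core concentrations are flat
  expect_lt(max(core) - min(core), 1e-9)
})

test_that("surface flux balances the volume-integrated realized source", {
  for (sc in list(three_layer_scenario(), anoxic_scenario())) {
    fld <- solve_steady_state(sc, grid_um = 5)
    sf <- attr(fld, "surface_flux_nmol_per_h")
    qi <- attr(fld, "q_integral_nmol_per_h")
    expect_lt(abs(sf - qi) / abs(qi), 0.005)
  }
})

test_that("halving the grid changes the field by less than 0.1%", {
  sc <- three_layer_scenario()
  f5 <- solve_steady_state(sc, grid_um = 5)
  f25 <- solve_steady_state(sc, grid_um = 2.5)
  on_coarse <- approx(f25$r_um, f25$conc_umol_per_L, xout = f5$r_um)$y
  expect_lt(
    max(abs(f5$conc_umol_per_L - on_coarse)) / max(f5$conc_umol_per_L),
    1e-3
  )
})

test_that("a large mass-transfer coefficient approaches the fixed-bulk limit", {
  ly <- layers_from_depths(1200, c(0, 1200), -0.2)
  dirichlet <- solve_steady_state(
    granule_scenario(1200, ly, bulk_umol_per_L = 200), grid_um = 10
  )
  robin <- solve_steady_state(
    granule_scenario(1200, ly, bulk_umol_per_L = 200,
                     boundary_layer_um_per_s = 1e5),
    grid_um = 10
  )
  expect_lt(
    max(abs(dirichlet$conc_umol_per_L - robin$conc_umol_per_L)), 0.5
  )
  # a finite boundary layer depresses the surface concentration
  robin2 <- solve_steady_state(
    granule_scenario(1200, ly, bulk_umol_per_L = 200,
                     boundary_layer_um_per_s = 20),
    grid_um = 10
  )
  expect_lt(max(robin2$conc_umol_per_L), 200)
})

test_that("dark-shift traces are flat without photosynthesis", {
  sc <- granule_scenario(1800, layers_from_depths(1800, c(0, 1800), 0),
                         bulk_umol_per_L = 250)
  ds <- solve_dark_shift(sc, depths_um = c(100, 500), duration_s = 10)
  expect_lt(max(abs(ds$conc_umol_per_L - 250)), 1e-6)
})

test_that("the initial dark slope equals the imposed gross photosynthesis", {
  sc <- photic_scenario()
  ds <- solve_dark_shift(sc, depths_um = c(275, 1500), duration_s = 2,
                         sample_hz = 10)
  inside <- ds[ds$depth_um == 275, ]
  est <- gross_photosynthesis(inside, window_s = c(0, 1))
  expect_lt(abs(est$estimate - 0.5) / 0.5, 0.02)

  # far outside the photic layer the initial slope is ~0 (locality at t->0+)
  outside <- ds[ds$depth_um == 1500, ]
  slope_out <- unname(coef(lm(conc_umol_per_L ~ time_s,
                              outside[outside$time_s <= 1, ]))[2])
  expect_lt(abs(slope_out), 0.01 * 0.5)
  expect_equal(
    unname(attr(ds, "p_gross_umol_per_L_s")), c(0.5, 0)
  )
})

test_that("the transient conserves mass at every output step", {
  sc <- photic_scenario()
  ds <- solve_dark_shift(sc, depths_um = 275, duration_s = 60,
                         sample_hz = 1, keep_field = TRUE)
  fld <- attr(ds, "field")
  vc <- attr(ds, "vc_um3")
  r <- attr(ds, "r_um")
  qd <- attr(ds, "q_dark_umol_per_L_s")
  h <- r[2] - r[1]
  m <- length(r)
  total <- as.numeric(fld %*% vc) * 1e-12 # nmol
  rhs <- vapply(seq_len(nrow(fld)), function(i) {
    conc <- fld[i, ]
    src <- sum((qd$qpos + qd$qneg * (conc > 0)) * vc) * 1e-12
    outward <- -2000 * ((3 * conc[m] - 4 * conc[m - 1] + conc[m - 2]) /
                          (2 * h)) * 1e-12 * 4 * pi * r[m]^2
    src - outward
  }, numeric(1))
  step <- diff(total)
  pred <- (rhs[-1] + rhs[-length(rhs)]) / 2
  # every step balances sources minus surface flux; cumulative drift < 1%
  expect_lt(max(abs(step - pred)) / max(abs(step)), 0.05)
  expect_lt(abs(sum(step - pred)) / abs(total[1]), 0.01)
})

test_that("sampling a field is exact without noise and deterministic with it", {
  sc <- three_layer_scenario()
  fld <- solve_steady_state(sc, grid_um = 5)
  depths <- seq(0, 1800, 50)
  clean <- sample_profile(fld, depths, noise_sd = 0)
  expect_equal(
    clean$conc_umol_per_L,
    approx(fld$r_um, fld$conc_umol_per_L, xout = 1800 - depths)$y
  )
  p1 <- sample_profile(fld, depths, noise_sd = 1, seed = 11)
  p2 <- sample_profile(fld, depths, noise_sd = 1, seed = 11)
  expect_identical(p1$conc_umol_per_L, p2$conc_umol_per_L)
  p3 <- sample_profile(fld, depths, noise_sd = 1, seed = 12)
  expect_false(identical(p1$conc_umol_per_L, p3$conc_umol_per_L))
  expect_true(all(p1$conc_umol_per_L >= 0))
  expect_error(sample_profile(fld, c(0, 2000)), "within")
})

test_that("noisy sampling is unbiased (CLT bound at one depth)", {
  sc <- granule_scenario(1000, layers_from_depths(1000, c(0, 1000), -0.1),
                         bulk_umol_per_L = 250)
  fld <- solve_steady_state(sc, grid_um = 5)
  truth <- approx(fld$r_um, fld$conc_umol_per_L, xout = 1000 - 300)$y
  draws <- vapply(seq_len(1e4), function(i) {
    sample_profile(fld, 300, noise_sd = 1, seed = 40000 + i)$conc_umol_per_L
  }, numeric(1))
  expect_lt(abs(mean(draws) - truth), 3 * 1 / sqrt(1e4))
})

test_that("sampled profiles carry volume-weighted ground-truth shell rates", {
  sc <- three_layer_scenario()
  fld <- solve_steady_state(sc, grid_um = 5)
  prof <- sample_profile(fld, seq(0, 1800, 50))
  truth <- attr(prof, "ground_truth")
  g <- shell_grid(seq(0, 1800, 50), 1800)
  # shells fully inside the outer production layer carry its rate exactly
  in_outer <- g$r_inner_um >= 1300
  expect_equal(
    truth$truth_volumetric_rate_nmol_per_mm3_per_h[in_outer],
    rep(0.4 * 3.6, sum(in_outer))
  )
  # net rates are volumetric rates times shell volumes
  expect_equal(
    truth$truth_net_rate_nmol_per_h,
    truth$truth_volumetric_rate_nmol_per_mm3_per_h * g$volume_um3 / 1e9
  )
})

test_that("isotope generator obeys the pairing split and rate arithmetic", {
  # F = 1: all excess in 30N2, totals = denitrification x t
  s1 <- generate_isotope_series(30, 10, 1, times_h = c(0, 2, 4.5, 5.5))
  expect_true(all(s1$excess29_nmol == 0))
  expect_equal(excess_15n_total(s1$excess29_nmol, s1$excess30_nmol),
               10 * c(0, 2, 4.5, 5.5))
  expect_equal(s1$nox_nmol, (30 - 10) * c(0, 2, 4.5, 5.5))
  expect_equal(s1$nox_nmol[2], 40) # 2 h timepoint
  expect_equal(2 * s1$excess30_nmol[2], 20)

  # F = 0.5: 29N2 : 30N2 = 2F(1-F) : F^2 = 2 : 1
  s2 <- generate_isotope_series(30, 10, 0.5, times_h = c(0, 1, 2, 3))
  expect_equal(s2$excess29_nmol[-1] / s2$excess30_nmol[-1], rep(2, 3))

  expect_error(generate_isotope_series(30, 10, 0), "0, 1")
  expect_error(generate_isotope_series(30, 10, 1.5), "0, 1")

  # same seed, same draws; amounts never negative
  a <- generate_isotope_series(30, 10, 1, noise_sd = 5, seed = 99)
  b <- generate_isotope_series(30, 10, 1, noise_sd = 5, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$excess29_nmol >= 0 & a$nox_nmol >= 0))
})

test_that("light generator reproduces the 90%-absorbed-within-600-um field", {
  prof <- generate_light_profile(log(10) / 600,
                                 depths_um = c(0, 300, 600))
  at600 <- prof$rel_irradiance[prof$depth_um == 600]
  expect_equal(at600, rep(0.1, length(at600)), tolerance = 1e-12)
  flat <- generate_light_profile(0, depths_um = c(0, 300, 600))
  expect_true(all(flat$rel_irradiance == 1))
  # surface row is identically 1 even with an excess band
  ex <- generate_light_profile(log(10) / 600, depths_um = c(0, 100, 200, 400),
                               excess_band_nm = c(700, 800))
  expect_true(all(ex$rel_irradiance[ex$depth_um == 0] == 1))
  expect_gt(max(ex$rel_irradiance), 1)
})

test_that("scenario layers must tile the granule", {
  expect_error(
    granule_scenario(1000, tibble::tibble(
      r_inner_um = c(0, 600), r_outer_um = c(500, 1000),
      rate_umol_per_L_s = c(0, 0)
    )),
    "tile"
  )
  expect_error(
    layers_from_depths(1000, c(0, 500), c(1, 2)),
    "increase from 0"
  )
  expect_error(
    granule_scenario(1000, layers_from_depths(1000, c(0, 1000), 0,
                                              photo_umol_per_L_s = -1)),
    ">= 0"
  )
})
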