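# Closed-form reference solutions and standard scenarios shared by tests.

# Steady-state profile for uniform zero-order consumption q (µmol L^-1 s^-1)
# in a sphere of radius R with bulk concentration at the surface:
# C(r) = C_R - q (R^2 - r^2) / (6 D)
uniform_consumption_profile <- function(depths_um, radius_um = 1800,
                                        q = 0.5, d_um2_s = 2000,
                                        bulk = 250) {
  r <- radius_um - depths_um
  tibble::tibble(
    depth_um = depths_um,
    conc_umol_per_L = bulk - q * (radius_um^2 - r^2) / (6 * d_um2_s)
  )
}

# Front radius of the zero-order anoxic-core solution: C(r_f) = 0 and
# C'(r_f) = 0 with consumption q only outside r_f requires
# bulk = (q / 3D) [ (R^2 - r_f^2)/2 + r_f^3/R - r_f^2 ].
analytic_front_radius <- function(q, d_um2_s, radius_um, bulk) {
  stats::uniroot(
    function(rf) {
      (q / (3 * d_um2_s)) *
        ((radius_um^2 - rf^2) / 2 + rf^3 / radius_um - rf^2) - bulk
    },
    c(1e-6, radius_um * (1 - 1e-9))
  )$root
}

# Photic-layer scenario: gross photosynthesis 0.5 µmol L^-1 s^-1 in the
# outer 500 µm (where light and phototroph density peak), weak background
# respiration everywhere.
photic_scenario <- function() {
  granule_scenario(
    radius_um = 1800,
    layers = layers_from_depths(
      1800, c(0, 500, 1800),
      rate_umol_per_L_s = c(-0.05, -0.05),
      photo_umol_per_L_s = c(0.5, 0)
    ),
    bulk_umol_per_L = 250
  )
}

# Stratified scenario: production in the outer 500 µm, an inert middle, and
# a weakly consuming core.
three_layer_scenario <- function() {
  granule_scenario(
    radius_um = 1800,
    layers = layers_from_depths(
      1800, c(0, 500, 1200, 1800),
      rate_umol_per_L_s = c(0.4, 0, -0.1)
    ),
    bulk_umol_per_L = 250
  )
}

# Strong uniform consumption exceeding the diffusive supply
# (q R^2 / 6D > bulk), producing an anoxic core.
anoxic_scenario <- function() {
  granule_scenario(
    radius_um = 1800,
    layers = layers_from_depths(1800, c(0, 1800), -1.0),
    bulk_umol_per_L = 250
  )
}

volumetric_truth <- function(profile) {
  attr(profile, "ground_truth")$truth_volumetric_rate_nmol_per_mm3_per_h
}
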