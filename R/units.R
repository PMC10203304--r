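# Internal canonical units: µm, s, nmol. 1 litre = 1e15 µm³ and
# 1 µmol = 1e3 nmol, so 1 µmol L⁻¹ = 1e-12 nmol µm⁻³.
UMOL_L_PER_NMOL_UM3 <- 1e-12
SECONDS_PER_HOUR <- 3600

#' Convert a concentration gradient to internal units
#'
#' Microsensor gradients are naturally expressed in µmol L\eqn{^{-1}}
#' µm\eqn{^{-1}}; flux arithmetic on the shell grid uses nmol µm\eqn{^{-4}}
#' (amount per volume per length). Since 1 µmol L\eqn{^{-1}} =
#' 10\eqn{^{-12}} nmol µm\eqn{^{-3}}, the conversion is a factor of
#' 10\eqn{^{-12}}.
#'
#' @param gradient_umol_per_l_per_um Numeric vector of concentration
#'   gradients in µmol L\eqn{^{-1}} µm\eqn{^{-1}}.
#' @return The gradients in nmol µm\eqn{^{-4}}.
#' @examples
#' convert_conc_gradient(1)   # 1e-12
#' convert_conc_gradient(2.5) # 2.5e-12
#' @export
convert_conc_gradient <- function(gradient_umol_per_l_per_um) {
  if (!is.numeric(gradient_umol_per_l_per_um) ||
      any(!is.finite(gradient_umol_per_l_per_um))) {
    abort("concentration gradients must be finite numbers")
  }
  gradient_umol_per_l_per_um * UMOL_L_PER_NMOL_UM3
}

#' Convert a point volumetric rate to nmol mm^-3 h^-1
#'
#' Dark-shift photosynthesis rates come out in µmol L\eqn{^{-1}}
#' s\eqn{^{-1}}; depth integration over the shell grid and comparison with
#' inverted profiles use nmol mm\eqn{^{-3}} h\eqn{^{-1}}. The factor is
#' 3.6 (10\eqn{^{-3}} nmol mm\eqn{^{-3}} per µmol L\eqn{^{-1}}, times
#' 3600 s h\eqn{^{-1}}).
#'
#' @param rate_umol_per_l_per_s Numeric vector of volumetric rates in
#'   µmol L\eqn{^{-1}} s\eqn{^{-1}}.
#' @return Rates in nmol mm\eqn{^{-3}} h\eqn{^{-1}}.
#' @export
umol_l_s_to_nmol_mm3_h <- function(rate_umol_per_l_per_s) {
  rate_umol_per_l_per_s * 3.6
}

#' Diffusion coefficients for microsensor analytes
#'
#' Free-solution diffusion coefficients used by the shell inversion:
#' 2000 µm\eqn{^2} s\eqn{^{-1}} for oxygen and 1700 µm\eqn{^2}
#' s\eqn{^{-1}} for nitrate.
#'
#' @param analyte `"oxygen"` or `"nitrate"`.
#' @return The diffusion coefficient in µm\eqn{^2} s\eqn{^{-1}}.
#' @export
diffusion_coefficient <- function(analyte = c("oxygen", "nitrate")) {
  analyte <- match.arg(analyte)
  c(oxygen = 2000, nitrate = 1700)[[analyte]]
}

# Resolve the coefficient to use: an explicit override wins, otherwise the
# analyte default. Other analytes require an explicit value.
resolve_diffusion <- function(analyte, diffusion_um2_s = NULL) {
  if (!is.null(diffusion_um2_s)) {
    if (!is.numeric(diffusion_um2_s) || length(diffusion_um2_s) != 1 ||
        !is.finite(diffusion_um2_s) || diffusion_um2_s <= 0) {
      abort("`diffusion_um2_s` must be a single positive number")
    }
    return(diffusion_um2_s)
  }
  if (!analyte %in% c("oxygen", "nitrate")) {
    abort(sprintf(
      "no default diffusion coefficient for analyte '%s'; supply `diffusion_um2_s`",
      analyte
    ))
  }
  diffusion_coefficient(analyte)
}

# Diffusive flux through a spherical interface, nmol h^-1, positive outward.
# dcdr is dC/dr in µmol L^-1 µm^-1 at radius r_um.
fick_flux_nmol_h <- function(diffusion_um2_s, dcdr_umol_l_um, r_um) {
  -diffusion_um2_s * dcdr_umol_l_um * UMOL_L_PER_NMOL_UM3 *
    4 * pi * r_um^2 * SECONDS_PER_HOUR
}

sphere_volume_um3 <- function(r_um) 4 / 3 * pi * r_um^3
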