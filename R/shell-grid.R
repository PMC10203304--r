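#' Build the concentric-shell grid for a spherical aggregate
#'
#' Segments a granule of radius `radius_um` into concentric spherical shells,
#' one per measurement depth, each shell as wide as the spacing between
#' measurements. Shells are centred on the measurement radii `r = R - z` with
#' interfaces at the midpoints between adjacent radii (a staggered grid: the
#' two-point finite difference between adjacent measurements is exactly the
#' derivative at the midpoint for locally quadratic profiles). The outermost
#' interface sits at the granule surface `R` and the innermost at the centre
#' `r = 0`, so the shells always tile the full sphere; when the profile stops
#' short of the centre the innermost shell contains an unmeasured core, which
#' downstream inversion treats as a zero-flux symmetry region.
#'
#' @param depths_um Strictly increasing measurement depths in µm from the
#'   aggregate surface (depth 0 = surface). All depths must lie in
#'   `[0, radius_um]` unless `truncate = TRUE`.
#' @param radius_um Granule radius in µm.
#' @param truncate If `TRUE`, depths beyond the radius are dropped with a
#'   warning instead of raising an error. Truncation is never silent.
#' @return A tibble with one row per shell: `shell`, `depth_um`, `r_um`
#'   (measurement radius), `r_outer_um`, `r_inner_um`, `volume_um3`
#'   (\eqn{\frac{4}{3}\pi(r_{out}^3 - r_{in}^3)}) and `area_outer_um2`
#'   (\eqn{4\pi r_{out}^2}). The granule radius is attached as attribute
#'   `radius_um`.
#' @examples
#' shell_grid(c(0, 600, 1200, 1800), radius_um = 1800)
#' @export
shell_grid <- function(depths_um, radius_um, truncate = FALSE) {
  if (!is.numeric(radius_um) || length(radius_um) != 1 ||
      !is.finite(radius_um) || radius_um <= 0) {
    abort("`radius_um` must be a single positive number")
  }
  if (!is.numeric(depths_um) || length(depths_um) < 1 ||
      any(!is.finite(depths_um))) {
    abort("`depths_um` must be a non-empty vector of finite depths")
  }
  if (is.unsorted(depths_um, strictly = TRUE)) {
    abort("`depths_um` must be strictly increasing (duplicate or unsorted depths)")
  }
  if (any(depths_um < 0)) {
    abort(paste0(
      "depth ", min(depths_um), " µm is above the surface; ",
      "boundary-layer points must be excluded before grid construction"
    ))
  }
  beyond <- depths_um > radius_um
  if (any(beyond)) {
    if (!truncate) {
      abort(sprintf(
        "depth %g µm exceeds the granule radius (%g µm); remove it or call with `truncate = TRUE`",
        depths_um[which(beyond)[1]], radius_um
      ))
    }
    warn(sprintf(
      "dropping %d depth(s) beyond the granule radius (%g µm)",
      sum(beyond), radius_um
    ))
    depths_um <- depths_um[!beyond]
    if (length(depths_um) < 1) abort("no depths remain inside the granule")
  }

  n <- length(depths_um)
  r <- radius_um - depths_um
  midpoints <- if (n > 1) (r[-n] + r[-1]) / 2 else numeric(0)
  interfaces <- c(radius_um, midpoints, 0)

  grid <- tibble(
    shell = seq_len(n),
    depth_um = depths_um,
    r_um = r,
    r_outer_um = interfaces[seq_len(n)],
    r_inner_um = interfaces[seq_len(n) + 1]
  )
  grid$volume_um3 <- sphere_volume_um3(grid$r_outer_um) -
    sphere_volume_um3(grid$r_inner_um)
  grid$area_outer_um2 <- 4 * pi * grid$r_outer_um^2
  attr(grid, "radius_um") <- radius_um
  grid
}
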