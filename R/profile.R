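#' Assemble and validate a microsensor depth profile
#'
#' A depth profile is a tibble with at least `depth_um` (µm from the
#' aggregate surface, increasing into the granule; negative depths are points
#' recorded in the diffusive boundary layer above the surface) and
#' `conc_umol_per_L` (concentration in µmol L\eqn{^{-1}}). `as_profile()`
#' validates the columns, sorts by depth, flags boundary-layer points and
#' attaches optional metadata. Boundary-layer rows are kept for plotting but
#' excluded from inversion.
#'
#' @param data A data frame with columns `depth_um` and `conc_umol_per_L`.
#' @param analyte Optional analyte label (e.g. `"oxygen"`, `"nitrate"`).
#' @param condition Optional free-text incubation condition.
#' @param replicate_id Optional replicate identifier.
#' @return A tibble with columns `depth_um`, `conc_umol_per_L`,
#'   `boundary_layer` (logical) and any metadata columns.
#' @export
as_profile <- function(data, analyte = NULL, condition = NULL,
                       replicate_id = NULL) {
  data <- as_tibble(data)
  for (col in c("depth_um", "conc_umol_per_L")) {
    if (!col %in% names(data)) {
      abort(sprintf("profile is missing required column '%s'", col))
    }
    if (!is.numeric(data[[col]])) {
      abort(sprintf("profile column '%s' must be numeric", col))
    }
    if (any(!is.finite(data[[col]]))) {
      abort(sprintf(
        "profile column '%s' has non-finite values at row(s) %s",
        col, paste(which(!is.finite(data[[col]])), collapse = ", ")
      ))
    }
  }
  if (anyDuplicated(data$depth_um)) {
    dup <- unique(data$depth_um[duplicated(data$depth_um)])
    abort(sprintf(
      "duplicate measurement depth(s): %s µm",
      paste(dup, collapse = ", ")
    ))
  }
  if (any(data$conc_umol_per_L < 0)) {
    abort("concentrations must be non-negative")
  }
  data <- dplyr::arrange(data, .data$depth_um)
  data$boundary_layer <- data$depth_um < 0
  if (!is.null(analyte)) data$analyte <- analyte
  if (!is.null(condition)) data$condition <- condition
  if (!is.null(replicate_id)) data$replicate <- replicate_id
  data
}

# In-granule part of a profile, validated against the geometry. Used by the
# inversion; requires >= min_points points inside the granule.
prepare_profile <- function(profile, radius_um, min_points = 3) {
  profile <- as_profile(profile)
  inside <- profile[!profile$boundary_layer, , drop = FALSE]
  beyond <- inside$depth_um > radius_um
  if (any(beyond)) {
    abort(sprintf(
      "depth %g µm exceeds the granule radius (%g µm)",
      inside$depth_um[which(beyond)[1]], radius_um
    ))
  }
  if (nrow(inside) < min_points) {
    abort(sprintf(
      "profile has %d point(s) inside the granule; at least %d are required",
      nrow(inside), min_points
    ))
  }
  inside
}

#' Plot a concentration depth profile
#'
#' Conventional microsensor orientation: concentration on the x axis, depth
#' on a reversed y axis so the aggregate surface is at the top. Boundary-layer
#' points (negative depth) are drawn hollow.
#'
#' @param profile A profile accepted by [as_profile()].
#' @param radius_um Optional granule radius; when given, a dashed line marks
#'   the granule centre.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, radius_um = NULL) {
  profile <- as_profile(profile)
  p <- ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$conc_umol_per_L, y = .data$depth_um)
  ) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$boundary_layer)) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1), guide = "none"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = expression(paste("concentration (", mu, "mol ", L^-1, ")")),
      y = expression(paste("depth (", mu, "m)"))
    )
  if (!is.null(radius_um)) {
    p <- p + ggplot2::geom_hline(yintercept = radius_um, linetype = "dashed")
  }
  p
}
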