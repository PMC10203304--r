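# Delimited-text I/O. Microsensor exports are vendor-heterogeneous text, so
# the readers accept comma or tab delimiters, require a header with a small
# set of mandatory columns, and report malformed cells by file line.

read_delim_checked <- function(path, required, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "'%s' is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in required) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "'%s': non-numeric value in column '%s' at line(s) %s",
        path, col, paste(bad + 1, collapse = ", ") # +1 for the header
      ))
    }
    raw[[col]] <- vals
  }
  raw
}

#' Read a microsensor depth profile from delimited text
#'
#' Reads CSV or TSV (delimiter guessed, or forced via `delim`) with
#' mandatory columns `depth_um` and `conc_umol_per_L` and optional
#' `analyte`, `replicate`, `condition`. Rows with negative depths are
#' retained and flagged as diffusive-boundary-layer points; duplicate depths
#' are rejected with their file lines.
#'
#' @param path Path to the file.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return A validated profile tibble (see [as_profile()]).
#' @export
read_profile <- function(path, delim = NULL) {
  raw <- read_delim_checked(path, c("depth_um", "conc_umol_per_L"), delim)
  if (anyDuplicated(raw$depth_um)) {
    lines <- which(duplicated(raw$depth_um) |
                     duplicated(raw$depth_um, fromLast = TRUE)) + 1
    abort(sprintf(
      "'%s': duplicate depths at line(s) %s",
      path, paste(lines, collapse = ", ")
    ))
  }
  as_profile(raw)
}

#' Read a closed-vial isotope time series
#'
#' Mandatory columns: `time_h`, `excess29_nmol`, `excess30_nmol`; optional
#' `nox_nmol` (required by [nitrification_rate()]) and metadata columns.
#'
#' @inheritParams read_profile
#' @return A tibble.
#' @export
read_isotope_series <- function(path, delim = NULL) {
  raw <- read_delim_checked(
    path, c("time_h", "excess29_nmol", "excess30_nmol"), delim
  )
  if ("nox_nmol" %in% names(raw)) {
    raw$nox_nmol <- suppressWarnings(as.numeric(raw$nox_nmol))
  }
  raw
}

#' Read a dark-shift oxygen time series
#'
#' Mandatory columns: `time_s`, `conc_umol_per_L`; optional `depth_um`.
#'
#' @inheritParams read_profile
#' @return A tibble.
#' @export
read_darkshift_series <- function(path, delim = NULL) {
  raw <- read_delim_checked(path, c("time_s", "conc_umol_per_L"), delim)
  if ("depth_um" %in% names(raw)) {
    raw$depth_um <- suppressWarnings(as.numeric(raw$depth_um))
  }
  raw
}

#' Read a long-format spectral irradiance profile
#'
#' Mandatory columns: `depth_um`, `wavelength_nm`, `rel_irradiance`.
#'
#' @inheritParams read_profile
#' @return A tibble for [light_attenuation()].
#' @export
read_light_profile <- function(path, delim = NULL) {
  read_delim_checked(
    path, c("depth_um", "wavelength_nm", "rel_irradiance"), delim
  )
}

#' Read a granule scenario from a YAML file
#'
#' The file maps directly onto [granule_scenario()]: top-level keys
#' `radius_um`, `bulk_umol_per_L`, `analyte`, optional `diffusion_um2_s`,
#' `boundary_layer_um_per_s`, `attenuation_per_um`, `noise_sd_umol_per_L`,
#' `seed`, and a `layers` list whose entries carry `r_inner_um`,
#' `r_outer_um`, `rate_umol_per_L_s` and optional `photo_umol_per_L_s`.
#'
#' @param path Path to a YAML scenario file.
#' @return A [granule_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers)) abort(sprintf("'%s' has no `layers` section", path))
  layers <- dplyr::bind_rows(lapply(cfg$layers, as_tibble))
  granule_scenario(
    radius_um = cfg$radius_um,
    layers = layers,
    bulk_umol_per_L = cfg$bulk_umol_per_L %||% 250,
    analyte = cfg$analyte %||% "oxygen",
    diffusion_um2_s = cfg$diffusion_um2_s,
    boundary_layer_um_per_s = cfg$boundary_layer_um_per_s,
    attenuation_per_um = cfg$attenuation_per_um %||% (log(10) / 600),
    noise_sd_umol_per_L = cfg$noise_sd_umol_per_L %||% 0,
    seed = cfg$seed
  )
}

#' Write a rate profile to CSV
#'
#' Writes the per-shell rate table (`shell_index`, `r_inner_um`,
#' `r_outer_um`, `net_rate_nmol_per_h`,
#' `volumetric_rate_nmol_per_mm3_per_h`) and a one-row summary
#' (total rate, surface flux, analyte, D, R) to a companion
#' `*_summary.csv`. Values round-trip through [readr::read_csv()] at full
#' double precision.
#'
#' @param rate_profile A `rate_profile` from [invert_profile()].
#' @param path Output CSV path for the shell table.
#' @param summary_path Output path for the summary row; defaults to
#'   `*_summary.csv` next to `path`.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rate_profile, path, summary_path = NULL) {
  stopifnot(inherits(rate_profile, "rate_profile"))
  shells <- tidy(rate_profile)
  out <- tibble(
    shell_index = shells$shell,
    depth_um = shells$depth_um,
    r_inner_um = shells$r_inner_um,
    r_outer_um = shells$r_outer_um,
    net_rate_nmol_per_h = shells$net_rate_nmol_per_h,
    volumetric_rate_nmol_per_mm3_per_h =
      shells$volumetric_rate_nmol_per_mm3_per_h
  )
  readr::write_csv(out, path)
  if (is.null(summary_path)) {
    summary_path <- sub("(\\.[^.]+)?$", "_summary.csv", path)
  }
  readr::write_csv(glance(rate_profile), summary_path)
  invisible(path)
}

#' Write a depth profile to CSV
#'
#' Counterpart of [read_profile()]; values round-trip at full double
#' precision.
#'
#' @param profile A profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  profile <- as_profile(profile)
  keep <- intersect(
    c("depth_um", "conc_umol_per_L", "analyte", "replicate", "condition"),
    names(profile)
  )
  readr::write_csv(profile[, keep], path)
  invisible(path)
}
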