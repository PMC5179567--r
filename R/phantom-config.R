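#' Configure a synthetic longitudinal retina phantom
#'
#' Parameterizes a simulated longitudinal two-photon imaging experiment of the
#' mouse retina: acquisition geometry (field of view, pixel grid, z-stack),
#' session schedule (days post-immunization), the static anatomy (optic nerve
#' head shadow, radial vessels), the infiltrating-cell kinetics (per-day cell
#' counts and radial seeding spread, drift and random motility), and the
#' neuronal calcium field sensed by the FRET channels.
#'
#' Defaults reproduce the acquisition geometry of the longitudinal retinal
#' imaging protocol this package models: a 1400 um x 1400 um field of view,
#' 300 um z-stacks acquired once per minute over a 20-minute session
#' (21 stacks), with sessions at days 7, 11, 14, 21 and 28 after
#' immunization, and a ~100 nM baseline neuronal calcium concentration.
#'
#' @param field_of_view_um Lateral field of view in micrometres (square).
#' @param n_pixels Lateral grid size in pixels (square).
#' @param z_depth_um Axial stack depth in micrometres.
#' @param n_z Number of z slices (z step = `z_depth_um / n_z`).
#' @param frame_interval_min Minutes between consecutive stacks.
#' @param n_frames Number of stacks per session (>= 2).
#' @param session_days Strictly increasing integer days post-immunization.
#' @param onh_center_um x-y position of the optic nerve head centre (um).
#' @param onh_radius_um Radius of the non-fluorescent optic nerve head disc.
#' @param vessel_count Number of radial vessels shadowing the field.
#' @param vessel_width_um Vessel stripe width (um).
#' @param vessel_angles Optional explicit vessel directions (radians); when
#'   `NULL` they are drawn reproducibly from `rng_seed`.
#' @param cells_per_day Named numeric vector mapping day to seeded cell count.
#' @param radial_scale_per_day Named numeric vector mapping day to the scale
#'   (um) of the gamma-distributed radial seeding distance from the ONH.
#' @param motile_fraction Probability that a seeded cell is motile.
#' @param drift_rate_um_min Signed radial drift of motile cells (um/min;
#'   positive = centrifugal, away from the ONH).
#' @param step_sigma Random-walk step scale (um per sqrt-minute), applied to
#'   every cell, motile or sessile.
#' @param cell_radius_um Lateral Gaussian blob sigma of a rendered cell (um).
#' @param axial_sigma_um Axial blob sigma (um); defaults to the ~15 um
#'   axial point-spread extent of the long-working-distance optics, which
#'   dominates the apparent axial size of a cell.
#' @param min_separation_um Minimum planar distance between seeded cells
#'   (um); the phantom guarantees separable cells so that detection does
#'   not need to split touching objects.
#' @param cell_peak_intensity Peak rendered cell intensity (arbitrary units).
#' @param background_level Autofluorescent background intensity (RPE layer).
#' @param sensor_level Total corrected FRET-sensor intensity in the
#'   ganglion-cell layer (donor + acceptor, arbitrary units).
#' @param vessel_label_intensity Intensity of the vessel-label channel.
#' @param photon_scale Photons per intensity unit for Poisson noise;
#'   `Inf` disables noise.
#' @param acceptor_split Fraction of acceptor emission detected in the
#'   525 nm channel (remainder in 593 nm).
#' @param n_neuronal_slices Number of top z slices forming the ganglion-cell
#'   (sensor-expressing) layer.
#' @param n_rpe_slices Number of bottom z slices carrying the autofluorescent
#'   retinal pigment epithelium background.
#' @param calcium_baseline_M Baseline neuronal calcium concentration (molar).
#' @param calcium_lesions List of lesions, each
#'   `list(center_um = c(x, y), radius_um, concentration_M)`, overriding the
#'   baseline inside a disc of the ganglion-cell layer.
#' @param ionomycin If `TRUE`, the whole-field ionomycin scenario: neuronal
#'   calcium is set to 3 uM everywhere (the positive-control condition).
#' @param channel_cal A [channel_calibration()] used when rendering raw
#'   detector channels (gains are inverted at render time so that the
#'   downstream correction chain recovers the intended signal). The phantom
#'   renders no optical blur, so its default correction chain uses
#'   `smoothing_sigma = 0`.
#' @param rng_seed Integer seed governing all phantom randomness.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [small_phantom_config()], [simulate_experiment()]
#' @export
phantom_config <- function(field_of_view_um = 1400,
                           n_pixels = 994L,
                           z_depth_um = 300,
                           n_z = 20L,
                           frame_interval_min = 1,
                           n_frames = 21L,
                           session_days = c(7L, 11L, 14L, 21L, 28L),
                           onh_center_um = c(700, 700),
                           onh_radius_um = 100,
                           vessel_count = 6L,
                           vessel_width_um = 20,
                           vessel_angles = NULL,
                           cells_per_day = c(`7` = 2, `11` = 4, `14` = 12,
                                             `21` = 20, `28` = 26),
                           radial_scale_per_day = c(`7` = 100, `11` = 100,
                                                    `14` = 120, `21` = 180,
                                                    `28` = 250),
                           motile_fraction = 0.3,
                           drift_rate_um_min = 1,
                           step_sigma = 0.5,
                           cell_radius_um = 6,
                           axial_sigma_um = 15,
                           min_separation_um = 40,
                           cell_peak_intensity = 100,
                           background_level = 20,
                           sensor_level = 60,
                           vessel_label_intensity = 80,
                           photon_scale = Inf,
                           acceptor_split = 0.6,
                           n_neuronal_slices = 3L,
                           n_rpe_slices = 3L,
                           calcium_baseline_M = 100e-9,
                           calcium_lesions = list(),
                           ionomycin = FALSE,
                           channel_cal = channel_calibration(smoothing_sigma = 0),
                           rng_seed = 1L) {
  cfg <- list(
    field_of_view_um = field_of_view_um, n_pixels = as.integer(n_pixels),
    z_depth_um = z_depth_um, n_z = as.integer(n_z),
    frame_interval_min = frame_interval_min, n_frames = as.integer(n_frames),
    session_days = as.integer(session_days),
    onh_center_um = onh_center_um, onh_radius_um = onh_radius_um,
    vessel_count = as.integer(vessel_count),
    vessel_width_um = vessel_width_um, vessel_angles = vessel_angles,
    cells_per_day = cells_per_day,
    radial_scale_per_day = radial_scale_per_day,
    motile_fraction = motile_fraction,
    drift_rate_um_min = drift_rate_um_min, step_sigma = step_sigma,
    cell_radius_um = cell_radius_um,
    axial_sigma_um = axial_sigma_um,
    min_separation_um = min_separation_um,
    cell_peak_intensity = cell_peak_intensity,
    background_level = background_level, sensor_level = sensor_level,
    vessel_label_intensity = vessel_label_intensity,
    photon_scale = photon_scale, acceptor_split = acceptor_split,
    n_neuronal_slices = as.integer(n_neuronal_slices),
    n_rpe_slices = as.integer(n_rpe_slices),
    calcium_baseline_M = calcium_baseline_M,
    calcium_lesions = calcium_lesions, ionomycin = ionomycin,
    channel_cal = channel_cal, rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  lengths_pos <- c("field_of_view_um", "z_depth_um", "onh_radius_um",
                   "vessel_width_um", "cell_radius_um")
  for (fld in lengths_pos) {
    if (!is.numeric(cfg[[fld]]) || any(cfg[[fld]] <= 0)) {
      stop_config(sprintf("`%s` must be positive", fld))
    }
  }
  if (cfg$n_pixels < 2L || cfg$n_z < 1L) {
    stop_config("pixel grid must have at least 2x2x1 voxels")
  }
  if (cfg$n_frames < 2L) {
    stop_config("`n_frames` must be at least 2")
  }
  if (cfg$motile_fraction < 0 || cfg$motile_fraction > 1) {
    stop_config("`motile_fraction` must lie in [0, 1]")
  }
  if (any(diff(cfg$session_days) <= 0)) {
    stop_config("`session_days` must be strictly increasing")
  }
  if (cfg$onh_radius_um > cfg$field_of_view_um / 2) {
    stop_config("`onh_radius_um` exceeds half the field of view")
  }
  if (cfg$calcium_baseline_M < 0) {
    stop_config("`calcium_baseline_M` must be non-negative")
  }
  for (les in cfg$calcium_lesions) {
    if (is.null(les$concentration_M) || les$concentration_M < 0) {
      stop_config("lesion concentrations must be non-negative")
    }
    if (is.null(les$radius_um) || les$radius_um < 0) {
      stop_config("lesion radii must be non-negative")
    }
  }
  missing_days <- setdiff(as.character(cfg$session_days),
                          names(cfg$cells_per_day))
  if (length(missing_days) > 0) {
    stop_config(sprintf("`cells_per_day` lacks entries for day(s) %s",
                        paste(missing_days, collapse = ", ")))
  }
  missing_scale <- setdiff(as.character(cfg$session_days),
                           names(cfg$radial_scale_per_day))
  if (length(missing_scale) > 0) {
    stop_config(sprintf("`radial_scale_per_day` lacks entries for day(s) %s",
                        paste(missing_scale, collapse = ", ")))
  }
  if (cfg$n_neuronal_slices + cfg$n_rpe_slices > cfg$n_z) {
    stop_config("neuronal + RPE slices exceed the stack depth")
  }
  invisible(cfg)
}

#' Small phantom preset
#'
#' The default test-scale phantom: 256 x 256 x 10 voxels over the full
#' 1400 um x 1400 um x 300 um acquisition volume, 21 one-minute frames.
#' The full-resolution 994 x 994 geometry remains reachable through
#' [phantom_config()].
#'
#' @param ... Overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
small_phantom_config <- function(...) {
  args <- list(...)
  defaults <- list(n_pixels = 256L, n_z = 10L, n_neuronal_slices = 2L,
                   n_rpe_slices = 2L)
  do.call(phantom_config, utils::modifyList(defaults, args))
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %d x %d px (%g um), %d z-slices (%g um), %d frames @ %g min\n",
    x$n_pixels, x$n_pixels, x$field_of_view_um, x$n_z, x$z_depth_um,
    x$n_frames, x$frame_interval_min))
  cat(sprintf("  sessions at days %s; ONH at (%g, %g) um, radius %g um\n",
              paste(x$session_days, collapse = ", "),
              x$onh_center_um[1], x$onh_center_um[2], x$onh_radius_um))
  cat(sprintf("  drift %+g um/min, step sigma %g um/sqrt(min), motile fraction %g\n",
              x$drift_rate_um_min, x$step_sigma, x$motile_fraction))
  invisible(x)
}
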