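# Synthetic retina phantom: static anatomy, cell tracks, calcium field,
# and rendering into raw detector channels with known ground truth.

#' Generate the static phantom background
#'
#' Builds the static anatomy of the phantom: an autofluorescent background
#' layer (retinal pigment epithelium) with a zero-intensity disc at the optic
#' nerve head and zero-intensity vessel stripes radiating from it, plus a
#' vessel-label channel that is bright exactly where vessels run (emulating
#' dextrane/rhodamine labeling of the vasculature).
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_background`: a list with the 2D
#'   logical masks `shadow_mask` (TRUE where tissue is *not* shadowed),
#'   `vessel_mask`, `onh_mask`, the vessel directions used, and the pixel
#'   coordinate vectors (um).
#' @export
generate_background <- function(config) {
  validate_phantom_config(config)
  n <- config$n_pixels
  xs <- pixel_centers(n, config$field_of_view_um)
  ys <- xs
  cx <- config$onh_center_um[1]
  cy <- config$onh_center_um[2]
  dxm <- matrix(xs, n, n, byrow = TRUE) - cx    # (y, x) layout
  dym <- matrix(ys, n, n) - cy
  r2 <- dxm^2 + dym^2
  onh_mask <- r2 <= config$onh_radius_um^2

  angles <- config$vessel_angles
  if (is.null(angles) && config$vessel_count > 0) {
    angles <- with_seed(config$rng_seed, {
      base <- seq(0, 2 * pi, length.out = config$vessel_count + 1L)[-1]
      base + runif(config$vessel_count, -pi / config$vessel_count,
                   pi / config$vessel_count)
    })
  }
  vessel_mask <- matrix(FALSE, n, n)
  for (th in angles) {
    along <- cos(th) * dxm + sin(th) * dym
    perp <- -sin(th) * dxm + cos(th) * dym
    vessel_mask <- vessel_mask |
      (along >= 0 & abs(perp) <= config$vessel_width_um / 2)
  }
  structure(
    list(shadow_mask = !(onh_mask | vessel_mask),
         vessel_mask = vessel_mask,
         onh_mask = onh_mask,
         vessel_angles = angles %||% numeric(0),
         xs_um = xs, ys_um = ys,
         config = config),
    class = "phantom_background"
  )
}

#' Simulate ground-truth cell tracks
#'
#' Seeds cells for each session day at gamma-distributed radial distances
#' from the optic nerve head (shape 2, per-day scale), then propagates them
#' frame by frame (seeds are re-drawn until all pairwise planar distances
#' exceed `min_separation_um`, so rendered cells are separable): motile
#' cells drift radially by
#' `drift_rate_um_min * dt` along the current radial unit vector, and every
#' cell receives isotropic Gaussian x-y noise of scale
#' `step_sigma * sqrt(dt)`. Positions are clipped at the field boundary and
#' flagged `exited`. Cell identity is not preserved across days: each session
#' is an independent cohort (within-session motion only).
#'
#' @param config A [phantom_config()].
#' @return A tibble of ground-truth positions: `day`, `cell_id`, `frame`
#'   (1-based), `x_um`, `y_um`, `z_um`, `motile`, `exited`.
#' @export
simulate_tracks <- function(config) {
  validate_phantom_config(config)
  fov <- config$field_of_view_um
  dt <- config$frame_interval_min
  cx <- config$onh_center_um[1]
  cy <- config$onh_center_um[2]
  out <- with_seed(config$rng_seed + 1L, {
    purrr::map(config$session_days, function(day) {
      n_cells <- round(config$cells_per_day[[as.character(day)]])
      if (n_cells == 0) {
        return(NULL)
      }
      scale_d <- config$radial_scale_per_day[[as.character(day)]]
      x <- numeric(n_cells)
      y <- numeric(n_cells)
      for (ci in seq_len(n_cells)) {
        for (attempt in seq_len(200L)) {
          r0 <- rgamma(1, shape = 2, scale = scale_d)
          th0 <- runif(1, 0, 2 * pi)
          xc <- cx + r0 * cos(th0)
          yc <- cy + r0 * sin(th0)
          sep_ok <- ci == 1L || all(
            (xc - x[seq_len(ci - 1L)])^2 + (yc - y[seq_len(ci - 1L)])^2 >=
              config$min_separation_um^2)
          if (sep_ok) break
        }
        x[ci] <- xc
        y[ci] <- yc
      }
      z <- runif(n_cells, 0, config$z_depth_um)
      motile <- runif(n_cells) < config$motile_fraction
      exited <- x < 0 | x > fov | y < 0 | y > fov
      x <- pmin(pmax(x, 0), fov)
      y <- pmin(pmax(y, 0), fov)
      pos <- vector("list", config$n_frames)
      pos[[1]] <- list(x = x, y = y, exited = exited)
      for (t in 2:config$n_frames) {
        rx <- x - cx
        ry <- y - cy
        r <- sqrt(rx^2 + ry^2)
        # at the ONH centre the radial direction is undefined; pick one
        zero <- r == 0
        if (any(zero)) {
          phi <- runif(sum(zero), 0, 2 * pi)
          rx[zero] <- cos(phi); ry[zero] <- sin(phi); r[zero] <- 1
        }
        drift <- ifelse(motile, config$drift_rate_um_min * dt, 0)
        x <- x + drift * rx / r + rnorm(n_cells, 0, config$step_sigma * sqrt(dt))
        y <- y + drift * ry / r + rnorm(n_cells, 0, config$step_sigma * sqrt(dt))
        exited <- x < 0 | x > fov | y < 0 | y > fov
        x <- pmin(pmax(x, 0), fov)
        y <- pmin(pmax(y, 0), fov)
        pos[[t]] <- list(x = x, y = y, exited = exited)
      }
      tibble::tibble(
        day = day,
        cell_id = rep(seq_len(n_cells), times = config$n_frames),
        frame = rep(seq_len(config$n_frames), each = n_cells),
        x_um = unlist(purrr::map(pos, "x")),
        y_um = unlist(purrr::map(pos, "y")),
        z_um = rep(z, times = config$n_frames),
        motile = rep(motile, times = config$n_frames),
        exited = unlist(purrr::map(pos, "exited"))
      )
    })
  })
  empty <- tibble::tibble(
    day = integer(), cell_id = integer(), frame = integer(),
    x_um = numeric(), y_um = numeric(), z_um = numeric(),
    motile = logical(), exited = logical())
  dplyr::bind_rows(c(list(empty), out))
}

#' Simulate the neuronal calcium field
#'
#' Returns the ganglion-cell-layer free-calcium concentration as a 2D grid
#' (molar): uniform baseline, overwritten inside each configured lesion disc
#' by the lesion concentration. The ionomycin scenario (`ionomycin = TRUE`
#' in the config) sets the whole field to 3 uM, the positive-control
#' concentration at which the sensor saturates toward a 70% FRET ratio.
#'
#' @param config A [phantom_config()].
#' @return A numeric matrix (y, x) of concentrations in molar.
#' @export
simulate_calcium <- function(config) {
  validate_phantom_config(config)
  n <- config$n_pixels
  if (isTRUE(config$ionomycin)) {
    return(matrix(3e-6, n, n))
  }
  ca <- matrix(config$calcium_baseline_M, n, n)
  if (length(config$calcium_lesions) == 0) {
    return(ca)
  }
  xs <- pixel_centers(n, config$field_of_view_um)
  xm <- matrix(xs, n, n, byrow = TRUE)
  ym <- matrix(xs, n, n)
  for (les in config$calcium_lesions) {
    inside <- (xm - les$center_um[1])^2 + (ym - les$center_um[2])^2 <=
      les$radius_um^2
    ca[inside] <- les$concentration_M
  }
  ca
}

#' Render one imaging session from phantom components
#'
#' Renders raw detector channels for one session day. Cells are 3D Gaussian
#' blobs (sigma = `cell_radius_um`) in the `cell` channel; the vessel-label
#' channel is bright along vessels; the autofluorescent background occupies
#' the bottom (RPE) z slices of the 525 nm channel; the ganglion-cell-layer
#' slices carry the FRET sensor signal, split between donor (466 nm) and
#' acceptor (525 + 593 nm) channels according to the FRET ratio implied by
#' the calcium field through `calibration`. Per-channel raw intensities
#' invert the correction chain (gain `eta/alpha`, additive background `I_B`)
#' so that [correct_channel()] with the same [channel_calibration()] recovers
#' the intended signal; Poisson noise is applied at `photon_scale`.
#'
#' @param background A [generate_background()] result.
#' @param tracks Ground-truth track tibble from [simulate_tracks()].
#' @param calcium Calcium grid from [simulate_calcium()] (molar).
#' @param calibration A [calcium_calibration] mapping concentration to ratio.
#' @param config The shared [phantom_config()].
#' @param day Which session day to render (must appear in `tracks$day`
#'   unless the day seeded zero cells).
#' @return An [image_session] with channels `466`, `525`, `593`, `vessel`
#'   and `cell`.
#' @export
render_session <- function(background, tracks, calcium, calibration, config,
                           day) {
  validate_phantom_config(config)
  if (calibration$r_min < 0 || calibration$r_max > 1) {
    stop_config("calibration ratio range must lie within [0, 1]")
  }
  n <- config$n_pixels
  nz <- config$n_z
  nt <- config$n_frames
  cal <- config$channel_cal
  xs <- background$xs_um
  zs <- pixel_centers(nz, config$z_depth_um)
  shadow <- background$shadow_mask * 1

  ratio <- calcium_to_ratio(calcium, calibration)
  s_total <- config$sensor_level * shadow
  donor <- s_total * (1 - ratio)
  acceptor <- s_total * ratio
  f <- config$acceptor_split
  gain <- function(ch) cal$sensitivity[[ch]] / cal$overlap[[ch]]

  neuronal <- seq_len(config$n_neuronal_slices)
  rpe <- if (config$n_rpe_slices > 0) (nz - config$n_rpe_slices + 1L):nz else integer(0)

  channels <- c("466", "525", "593", "vessel", "cell")
  arr <- array(0, dim = c(n, n, nz, length(channels), nt))
  # static expected planes per channel and z
  plane466 <- gain("466") * donor + cal$background[["466"]]
  plane525n <- gain("525") * (f * acceptor) + cal$background[["525"]]
  plane593n <- gain("593") * ((1 - f) * acceptor) + cal$background[["593"]]
  plane525r <- gain("525") * (config$background_level * shadow) +
    cal$background[["525"]]
  flat <- function(ch) matrix(cal$background[[ch]], n, n)
  vessel_plane <- config$vessel_label_intensity * (background$vessel_mask * 1)

  day_tracks <- tracks[tracks$day == day, , drop = FALSE]
  sigma <- config$cell_radius_um
  sigma_z <- config$axial_sigma_um

  for (t in seq_len(nt)) {
    for (k in seq_len(nz)) {
      arr[, , k, 1L, t] <- if (k %in% neuronal) plane466 else flat("466")
      arr[, , k, 2L, t] <- if (k %in% neuronal) plane525n
        else if (k %in% rpe) plane525r else flat("525")
      arr[, , k, 3L, t] <- if (k %in% neuronal) plane593n else flat("593")
      arr[, , k, 4L, t] <- vessel_plane
    }
    ft <- day_tracks[day_tracks$frame == t, , drop = FALSE]
    if (nrow(ft) > 0) {
      cell_stack <- array(0, dim = c(n, n, nz))
      for (i in seq_len(nrow(ft))) {
        jr <- which(abs(xs - ft$x_um[i]) <= 3 * sigma)
        ir <- which(abs(xs - ft$y_um[i]) <= 3 * sigma)
        kr <- which(abs(zs - ft$z_um[i]) <= 3 * sigma_z)
        if (!length(jr) || !length(ir) || !length(kr)) next
        gx <- exp(-(xs[jr] - ft$x_um[i])^2 / (2 * sigma^2))
        gy <- exp(-(xs[ir] - ft$y_um[i])^2 / (2 * sigma^2))
        gz <- exp(-(zs[kr] - ft$z_um[i])^2 / (2 * sigma_z^2))
        blob2d <- config$cell_peak_intensity * outer(gy, gx)
        for (kk in seq_along(kr)) {
          cell_stack[ir, jr, kr[kk]] <- cell_stack[ir, jr, kr[kk]] +
            blob2d * gz[kk]
        }
      }
      arr[, , , 5L, t] <- cell_stack
    }
  }

  if (is.finite(config$photon_scale)) {
    arr <- with_seed(config$rng_seed + 1000L + day, {
      noisy <- rpois(length(arr), lambda = as.vector(arr) * config$photon_scale)
      array(noisy / config$photon_scale, dim = dim(arr))
    })
  }

  image_session(
    intensity = arr,
    channel_names = channels,
    voxel_size_um = c(config$field_of_view_um / n,
                      config$field_of_view_um / n,
                      config$z_depth_um / nz),
    frame_interval_min = config$frame_interval_min,
    day = day,
    onh_center_um = NULL
  )
}

#' Simulate a full longitudinal phantom experiment
#'
#' Convenience wrapper: generates the shared background, ground-truth tracks
#' and calcium field, fits the default anchored calcium calibration (unless
#' one is supplied), and renders one [image_session] per requested day.
#'
#' @param config A [phantom_config()].
#' @param days Session days to render (default all configured days).
#' @param calibration Optional [calcium_calibration]; default
#'   [fit_calibration()] with its anchor defaults.
#' @return A list of class `phantom_experiment` with elements `sessions`
#'   (named by day), and `ground_truth` (tracks tibble, calcium grid, zone
#'   counts at the default zone radii, per-day true global radial
#'   displacement of motile cells, background masks, calibration, config).
#' @export
simulate_experiment <- function(config, days = config$session_days,
                                calibration = fit_calibration()) {
  validate_phantom_config(config)
  bg <- generate_background(config)
  tracks <- simulate_tracks(config)
  ca <- simulate_calcium(config)
  sessions <- purrr::map(days, function(d) {
    render_session(bg, tracks, ca, calibration, config, d)
  })
  names(sessions) <- as.character(days)

  zones <- zone_config(onh_center_um = config$onh_center_um)
  seeds <- tracks[tracks$frame == 1L, , drop = FALSE]
  true_zone <- zone_counts(assign_zone(seeds, zones), zones)
  # true global radial displacement: motile, never-exited cells, end - start
  true_global <- tracks |>
    dplyr::filter(.data$motile) |>
    dplyr::group_by(.data$day, .data$cell_id) |>
    dplyr::filter(!any(.data$exited)) |>
    dplyr::summarise(
      radial_um = sqrt((.data$x_um[dplyr::n()] - config$onh_center_um[1])^2 +
                       (.data$y_um[dplyr::n()] - config$onh_center_um[2])^2) -
                  sqrt((.data$x_um[1] - config$onh_center_um[1])^2 +
                       (.data$y_um[1] - config$onh_center_um[2])^2),
      .groups = "drop_last") |>
    dplyr::summarise(global_radial_um = sum(.data$radial_um), .groups = "drop")

  structure(
    list(sessions = sessions,
         ground_truth = list(
           tracks = tracks,
           calcium = ca,
           zone_counts = true_zone,
           global_radial = true_global,
           background = bg,
           calibration = calibration,
           config = config)),
    class = "phantom_experiment"
  )
}
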