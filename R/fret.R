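# Ratiometric FRET signal, anchored Hill calibration, and the
# neuronal-dysfunction threshold.

#' Compute the relative acceptor FRET ratio
#'
#' From corrected channels (see [correct_channel()]), the relative acceptor
#' FRET signal is the acceptor emission over total emission per voxel:
#' `ratio = (c525 + c593) / (c525 + c593 + c466)`. Voxels whose denominator
#' falls below `denom_floor_frac` times the denominator maximum (dark
#' voxels: vessel shadows, the optic nerve head) are marked undefined (`NA`)
#' rather than zero-filled. The ratio is invariant to multiplying all three
#' channels by a positive constant and increases monotonically with
#' intracellular calcium for the troponin-based sensor.
#'
#' @param c466,c525,c593 Corrected channel arrays of identical shape
#'   (donor 466 nm; acceptor 525 and 593 nm).
#' @param denom_floor_frac Undefined-voxel floor as a fraction of the
#'   maximum denominator (default 1e-6).
#' @param mask Optional logical array (first two dims, y-x) restricting the
#'   voxels of interest; default: all defined voxels.
#' @param voxel_size_um,frame_interval_min Optional metadata carried on the
#'   result for downstream ROI/zone analyses.
#' @return An object of class `fret_map`: list with `ratio` (same shape as
#'   input, `NA` where undefined), `mask`, and the metadata.
#' @export
compute_fret_ratio <- function(c466, c525, c593, denom_floor_frac = 1e-6,
                               mask = NULL, voxel_size_um = NULL,
                               frame_interval_min = NULL) {
  if (!identical(dim(c466) %||% length(c466), dim(c525) %||% length(c525)) ||
      !identical(dim(c466) %||% length(c466), dim(c593) %||% length(c593))) {
    abort("channel shapes differ", class = "retinaivm_shape_error")
  }
  acceptor <- c525 + c593
  denom <- acceptor + c466
  floor_val <- denom_floor_frac * max(denom, 0)
  ratio <- acceptor / denom
  ratio[denom <= floor_val] <- NA_real_
  if (!is.null(dim(c466))) dim(ratio) <- dim(c466)
  structure(
    list(ratio = ratio,
         mask = mask,
         voxel_size_um = voxel_size_um,
         frame_interval_min = frame_interval_min),
    class = "fret_map"
  )
}

#' Anchored Hill calibration between FRET ratio and calcium
#'
#' Fits the Hill form
#' `R(C) = R_min + (R_max - R_min) * C^n / (K_d^n + C^n)` exactly through
#' two (ratio, concentration) anchor points. The default anchors are the
#' sensor's characteristic points: a 47% FRET ratio at 1 uM calcium (the
#' neuronal-dysfunction boundary) and a 70% ratio at 3 uM (the
#' ionomycin-saturated positive control). Two anchors under-determine a
#' four-parameter sigmoid, so the asymptotes `R_min`/`R_max` are fixed
#' configuration values (defaults 0.25 / 0.85) and `(K_d, n)` are solved in
#' closed form.
#'
#' @param anchors Two-row data frame or list of `(ratio, concentration_M)`
#'   pairs, ratios strictly inside `(r_min, r_max)` and increasing with
#'   concentration.
#' @param r_min,r_max Ratio asymptotes, `0 <= r_min < r_max <= 1`.
#' @param dysfunction_threshold_M Sustained-calcium threshold operationally
#'   defining neuronal dysfunction (default 1 uM).
#' @return An object of class `calcium_calibration` with elements `r_min`,
#'   `r_max`, `kd_M`, `hill_n`, `anchors`, `dysfunction_threshold_M`.
#' @export
fit_calibration <- function(anchors = tibble::tibble(
                              ratio = c(0.47, 0.70),
                              concentration_M = c(1e-6, 3e-6)),
                            r_min = 0.25, r_max = 0.85,
                            dysfunction_threshold_M = 1e-6) {
  anchors <- tibble::as_tibble(anchors)
  if (nrow(anchors) != 2L) {
    abort("exactly two anchors are required", class = "retinaivm_calibration_error")
  }
  if (!(r_min >= 0 && r_min < r_max && r_max <= 1)) {
    abort("need 0 <= r_min < r_max <= 1", class = "retinaivm_calibration_error")
  }
  r <- anchors$ratio
  cc <- anchors$concentration_M
  if (any(r <= r_min) || any(r >= r_max)) {
    abort("anchor ratios must lie strictly inside (r_min, r_max)",
          class = "retinaivm_calibration_error")
  }
  if (cc[1] == cc[2] || r[1] == r[2]) {
    abort("anchors must have distinct ratios and concentrations",
          class = "retinaivm_calibration_error")
  }
  if (sign(diff(r)) != sign(diff(cc))) {
    abort("anchors must be increasing: ratio must grow with concentration",
          class = "retinaivm_calibration_error")
  }
  # (r - r_min) / (r_max - r) = (C / K_d)^n, solved through both anchors
  y <- (r - r_min) / (r_max - r)
  n <- (log(y[2]) - log(y[1])) / (log(cc[2]) - log(cc[1]))
  kd <- cc[1] / y[1]^(1 / n)
  structure(
    list(r_min = r_min, r_max = r_max, kd_M = kd, hill_n = n,
         anchors = anchors,
         dysfunction_threshold_M = dysfunction_threshold_M),
    class = "calcium_calibration"
  )
}

#' @export
print.calcium_calibration <- function(x, ...) {
  cat(sprintf(
    "<calcium_calibration> Hill: R(C) = %.3g + %.3g * C^%.4g / (K_d^%.4g + C^%.4g)\n",
    x$r_min, x$r_max - x$r_min, x$hill_n, x$hill_n, x$hill_n))
  cat(sprintf("  K_d = %.4g uM; dysfunction threshold %.3g uM\n",
              x$kd_M * 1e6, x$dysfunction_threshold_M * 1e6))
  invisible(x)
}

#' Convert between FRET ratio and calcium concentration
#'
#' Exact algebraic inverse pair of the anchored Hill calibration. Ratios at
#' or below `r_min` map to concentration 0 (floored); ratios at or above
#' `r_max` map to `Inf` (saturated). The flags are available as attribute
#' `"flag"` (`"ok"`, `"floor"`, `"saturated"`).
#'
#' @param ratio Numeric vector/array of FRET ratios.
#' @param concentration_M Numeric vector/array of concentrations (molar).
#' @param cal A [fit_calibration()] result.
#' @return Numeric of the same shape.
#' @export
ratio_to_calcium <- function(ratio, cal) {
  stopifnot(inherits(cal, "calcium_calibration"))
  y <- (ratio - cal$r_min) / (cal$r_max - ratio)
  out <- cal$kd_M * y^(1 / cal$hill_n)
  flag <- rep("ok", length(ratio))
  floor_sel <- !is.na(ratio) & ratio <= cal$r_min
  sat_sel <- !is.na(ratio) & ratio >= cal$r_max
  out[floor_sel] <- 0
  out[sat_sel] <- Inf
  flag[floor_sel] <- "floor"
  flag[sat_sel] <- "saturated"
  if (!is.null(dim(ratio))) dim(out) <- dim(ratio)
  attr(out, "flag") <- flag
  out
}

#' @rdname ratio_to_calcium
#' @export
calcium_to_ratio <- function(concentration_M, cal) {
  stopifnot(inherits(cal, "calcium_calibration"))
  attr(concentration_M, "flag") <- NULL
  cn <- concentration_M^cal$hill_n
  out <- cal$r_min + (cal$r_max - cal$r_min) * cn / (cal$kd_M^cal$hill_n + cn)
  out[is.infinite(concentration_M)] <- cal$r_max
  if (!is.null(dim(concentration_M))) dim(out) <- dim(concentration_M)
  out
}

#' Neuronal mask from corrected channels
#'
#' Default mask of sensor-expressing tissue: voxels whose time-averaged
#' summed corrected intensity (donor + acceptor) exceeds an Otsu threshold.
#' This restricts FRET statistics to the ganglion-cell layer neurons that
#' express the biosensor, excluding shadows and non-expressing tissue.
#'
#' @param c466,c525,c593 Corrected channel arrays `(y, x[, t])`.
#' @return Logical matrix (y, x).
#' @export
neuronal_mask <- function(c466, c525, c593) {
  total <- c466 + c525 + c593
  if (length(dim(total)) > 2L) {
    total <- apply(total, c(1, 2), mean)
  }
  thr <- otsu_threshold(total)
  total > thr
}

#' Session-level FRET map
#'
#' Convenience wrapper for a rendered/acquired session: corrects the three
#' acquisition channels, averages the ganglion-cell-layer z slices, computes
#' the per-frame FRET ratio and an Otsu neuronal mask, and attaches the
#' session metadata needed by [roi_time_course()], [zone_fret()] and
#' [dysfunction_fraction()].
#'
#' @param session An [image_session] with channels `466`, `525`, `593`.
#' @param cal A [channel_calibration()].
#' @param neuronal_slices Indices of the z slices forming the neuronal
#'   (sensor-expressing) layer; default the topmost slice.
#' @param denom_floor_frac Passed to [compute_fret_ratio()].
#' @return A `fret_map` with `ratio` of shape (y, x, t).
#' @export
session_fret <- function(session, cal = channel_calibration(),
                         neuronal_slices = 1L, denom_floor_frac = 1e-6) {
  layer_mean <- function(channel) {
    g <- session_channel(session, channel) # (y, x, z, t)
    d <- dim(g)
    sub <- g[, , neuronal_slices, , drop = FALSE]
    out <- apply(sub, c(1, 2, 4), mean)
    array(out, dim = c(d[1], d[2], d[4]))
  }
  c466 <- correct_channel(layer_mean("466"), cal, "466")
  c525 <- correct_channel(layer_mean("525"), cal, "525")
  c593 <- correct_channel(layer_mean("593"), cal, "593")
  fm <- compute_fret_ratio(c466, c525, c593,
                           denom_floor_frac = denom_floor_frac,
                           voxel_size_um = session$voxel_size_um,
                           frame_interval_min = session$frame_interval_min)
  fm$mask <- neuronal_mask(c466, c525, c593) &
    apply(!is.na(fm$ratio), c(1, 2), all)
  fm
}

# Shared helper: mean defined ratio inside a 2D pixel selection, per frame.
frame_means <- function(fret, sel) {
  d <- dim(fret$ratio)
  nt <- if (length(d) == 3L) d[3] else 1L
  purrr::map_dbl(seq_len(nt), function(t) {
    r <- if (length(d) == 3L) fret$ratio[, , t] else fret$ratio
    vals <- r[sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  })
}

fret_pixel_grid <- function(fret) {
  if (is.null(fret$voxel_size_um)) {
    stop_config("fret map lacks `voxel_size_um` metadata")
  }
  d <- dim(fret$ratio)
  list(xs = pixel_centers(d[2], d[2] * fret$voxel_size_um[1]),
       ys = pixel_centers(d[1], d[1] * fret$voxel_size_um[2]))
}

#' ROI time courses of the FRET ratio
#'
#' Mean defined FRET ratio per region of interest per frame, mirroring the
#' per-ROI time-course panels of a 20-min imaging session. ROIs with no
#' defined voxel in a frame are reported as missing (`NA`), not an error.
#'
#' @param fret A `fret_map` (see [session_fret()]).
#' @param rois Tibble of disc ROIs: `roi`, `x_um`, `y_um`, `radius_um`.
#' @return Tibble `roi`, `frame`, `t_min`, `mean_ratio`.
#' @export
roi_time_course <- function(fret, rois) {
  grid <- fret_pixel_grid(fret)
  dt <- fret$frame_interval_min %||% 1
  purrr::pmap(rois, function(roi, x_um, y_um, radius_um, ...) {
    sel <- outer(grid$ys - y_um, grid$xs - x_um,
                 function(dy, dx) dy^2 + dx^2) <= radius_um^2
    m <- frame_means(fret, sel)
    tibble::tibble(roi = roi, frame = seq_along(m),
                   t_min = (seq_along(m) - 1) * dt, mean_ratio = m)
  }) |>
    dplyr::bind_rows()
}

#' Zonal and whole-field FRET means
#'
#' Mean defined FRET ratio per concentric zone per frame (the zonal FRET
#' quantification around the optic nerve head) plus a whole-mask grand mean.
#'
#' @param fret A `fret_map`.
#' @param zones A [zone_config()].
#' @return Tibble `zone` (`NA` = whole mask), `frame`, `mean_ratio`.
#' @export
zone_fret <- function(fret, zones) {
  grid <- fret_pixel_grid(fret)
  d2 <- outer(grid$ys - zones$onh_center_um[2], grid$xs - zones$onh_center_um[1],
              function(dy, dx) dy^2 + dx^2)
  mask <- fret$mask %||% array(TRUE, dim(d2))
  radii <- c(0, zones$radii)
  rows <- purrr::map(seq_along(zones$radii), function(k) {
    sel <- d2 >= radii[k]^2 & d2 < radii[k + 1]^2 & mask
    m <- frame_means(fret, sel)
    tibble::tibble(zone = k, frame = seq_along(m), mean_ratio = m)
  })
  gm <- frame_means(fret, mask)
  grand <- tibble::tibble(zone = NA_integer_, frame = seq_along(gm),
                          mean_ratio = gm)
  dplyr::bind_rows(c(rows, list(grand)))
}

#' Fraction of the neuronal mask above the dysfunction threshold
#'
#' The area of calcium-associated neuronal dysfunction is operationalized as
#' the fraction of masked voxels whose inferred calcium stays at or above
#' the calibration's dysfunction threshold (default 1 uM) for at least
#' `persistence_frames` consecutive frames — by default the whole session,
#' i.e. sustained elevation throughout the 20-min imaging window.
#'
#' @param fret A `fret_map` with a non-empty `mask`.
#' @param cal A [fit_calibration()] result.
#' @param persistence_frames Required consecutive-frame run length
#'   (default: all frames).
#' @return A single fraction in `[0, 1]`.
#' @export
dysfunction_fraction <- function(fret, cal, persistence_frames = NULL) {
  mask <- fret$mask
  if (is.null(mask) || !any(mask)) {
    abort("empty neuronal mask", class = "retinaivm_mask_error")
  }
  d <- dim(fret$ratio)
  nt <- if (length(d) == 3L) d[3] else 1L
  persistence_frames <- persistence_frames %||% nt
  if (persistence_frames < 1) {
    stop_config("`persistence_frames` must be >= 1")
  }
  idx <- which(mask)
  above <- matrix(FALSE, length(idx), nt)
  for (t in seq_len(nt)) {
    r <- if (length(d) == 3L) fret$ratio[, , t] else fret$ratio
    ca <- ratio_to_calcium(r[idx], cal)
    above[, t] <- !is.na(ca) & ca >= cal$dysfunction_threshold_M
  }
  run_ok <- apply(above, 1, function(v) {
    r <- rle(v)
    any(r$values & r$lengths >= persistence_frames)
  })
  mean(run_ok)
}
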