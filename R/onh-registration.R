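# Optic-nerve-head localization and vasculature-based session registration.

#' Localize the optic nerve head
#'
#' The optic nerve head does not fluoresce and appears as a shadow in the
#' autofluorescence channel. The localizer takes the time-averaged z-mean
#' projection of that channel, marks pixels below a low intensity quantile
#' as dark, erodes the dark mask to detach radial vessel shadows (which are
#' thin) from the ONH disc (which is wide), and returns the centroid of the
#' largest remaining dark connected region in micrometres.
#'
#' @param session An [image_session].
#' @param channel Autofluorescence channel name (default `"525"`, the
#'   retinol autofluorescence band).
#' @param dark_quantile Pixels at or below this intensity quantile count as
#'   dark (default 0.05).
#' @param min_area_um2 Minimum area of the (eroded) dark region; smaller
#'   regions raise a localization-failed error prompting manual input.
#'   Default: one disc of 50 um radius.
#' @param erode_um Erosion half-width in micrometres used to strip vessel
#'   shadows off the dark mask.
#' @param override Manual x-y position (um); returned verbatim when given.
#' @return Numeric `c(x, y)` in micrometres.
#' @export
localize_onh <- function(session, channel = "525", dark_quantile = 0.05,
                         min_area_um2 = pi * 50^2, erode_um = 15,
                         override = NULL) {
  if (!is.null(override)) {
    return(as.numeric(override))
  }
  g <- session_channel(session, channel)
  proj <- apply(g, c(1, 2), mean)
  # a shadow must be genuinely dark, not merely in the lowest quantile of a
  # flat image: cap the threshold at half the median intensity
  thr <- min(quantile(proj, dark_quantile), 0.5 * stats::median(proj))
  dark <- proj <= thr
  px <- session$voxel_size_um[1]
  dark <- binary_erode(dark, r = max(0L, round(erode_um / px)))
  labels <- label_components(dark)
  if (max(labels) == 0L) {
    abort("no dark region found; supply `override` with a manual ONH position",
          class = "retinaivm_localization_error")
  }
  sizes <- tabulate(labels[labels > 0])
  best <- which.max(sizes)
  area <- sizes[best] * px * session$voxel_size_um[2]
  if (area < min_area_um2) {
    abort(sprintf(
      "largest dark region (%.0f um^2) is below `min_area_um2`; supply `override`",
      area), class = "retinaivm_localization_error")
  }
  idx <- which(labels == best, arr.ind = TRUE)
  xs <- pixel_centers(dim(proj)[2], dim(proj)[2] * px)
  ys <- pixel_centers(dim(proj)[1], dim(proj)[1] * session$voxel_size_um[2])
  c(mean(xs[idx[, 2]]), mean(ys[idx[, 1]]))
}

#' Register repeated sessions using the vasculature
#'
#' Estimates the rigid x-y translation between two imaging visits of the
#' same eye by maximizing the cross-correlation of the time-averaged,
#' z-projected vessel-label channels, then applies it to the moving session.
#' Repositioning between sessions is translational to a good approximation;
#' rotation is not estimated.
#'
#' @param reference,moving [image_session]s sharing a vessel channel and
#'   voxel size.
#' @param channel Vessel-label channel name.
#' @param confidence_ratio Warn (`retinaivm_registration_warning`) when the
#'   correlation peak is less than this multiple of the next-highest peak
#'   outside its immediate neighbourhood (default 1.2).
#' @return A list with `offset_um` (x, y translation applied to the moving
#'   session to align it onto the reference), `offset_px`, `confidence`,
#'   and `aligned` (the shifted moving session).
#' @export
register_sessions <- function(reference, moving, channel = "vessel",
                              confidence_ratio = 1.2) {
  if (any(abs(reference$voxel_size_um - moving$voxel_size_um) > 1e-9)) {
    stop_config("sessions must share a voxel size")
  }
  a <- apply(session_channel(reference, channel), c(1, 2), mean)
  b <- apply(session_channel(moving, channel), c(1, 2), mean)
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE)) / length(a0)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(cc)
  # wrap circular lags into the centred range
  lag <- function(i, len) ifelse(i - 1 > len / 2, i - 1 - len, i - 1)
  dy <- unname(lag(peak[1], n[1]))
  dx <- unname(lag(peak[2], n[2]))
  # confidence: peak against the best correlation outside a 5x5 neighbourhood
  nb_i <- ((peak[1] + (-2:2) - 1) %% n[1]) + 1
  nb_j <- ((peak[2] + (-2:2) - 1) %% n[2]) + 1
  masked <- cc
  masked[nb_i, nb_j] <- -Inf
  second <- max(masked)
  confidence <- if (second > 0) max(cc) / second else Inf
  if (max(cc) <= 0 || confidence < confidence_ratio) {
    warn("registration peak is weak; offset may be unreliable",
         class = "retinaivm_registration_warning")
  }
  offset_px <- c(dx, dy)
  offset_um <- offset_px * moving$voxel_size_um[1:2]
  aligned <- shift_session(moving, offset_um[1], offset_um[2])
  list(offset_um = offset_um, offset_px = offset_px,
       confidence = confidence, aligned = aligned)
}

#' Translate a session in the x-y plane
#'
#' Shifts every plane of the session by an integer number of pixels (the
#' nearest pixel to the requested micrometre shift), filling vacated pixels
#' with zero.
#'
#' @param session An [image_session].
#' @param dx_um,dy_um Translation in micrometres (+x right, +y down).
#' @return The shifted [image_session].
#' @export
shift_session <- function(session, dx_um, dy_um) {
  px <- session$voxel_size_um[1:2]
  sj <- round(dx_um / px[1])
  si <- round(dy_um / px[2])
  d <- dim(session$intensity)
  out <- array(0, dim = d)
  src_i <- seq_len(d[1]) - si
  src_j <- seq_len(d[2]) - sj
  ok_i <- src_i >= 1 & src_i <= d[1]
  ok_j <- src_j >= 1 & src_j <= d[2]
  out[which(ok_i), which(ok_j), , , ] <-
    session$intensity[src_i[ok_i], src_j[ok_j], , , , drop = FALSE]
  session$intensity <- out
  session
}
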