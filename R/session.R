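# Imaging-session container and TIFF round trip.

#' Construct an imaging session
#'
#' Container for one imaging visit: a 5-axis intensity grid plus physical and
#' acquisition metadata. The intensity array uses dimension order
#' `(y, x, z, channel, time)`; physical coordinates are micrometres with the
#' origin at the image corner and pixel centres at `(index - 0.5) * pixel`.
#'
#' @param intensity Non-negative numeric array `(y, x, z, channel, time)`.
#'   Arrays of fewer dimensions are promoted with singleton axes.
#' @param channel_names Unique channel names, one per channel axis entry.
#'   The detection bands of the acquisition protocol are named
#'   `"466"`, `"525"` and `"593"` (nm); other names are carried as auxiliary
#'   channels.
#' @param voxel_size_um Voxel size `(x, y, z)` in micrometres.
#' @param frame_interval_min Minutes between frames.
#' @param day Integer day post-immunization.
#' @param onh_center_um Optional x-y position (um) of the optic nerve head;
#'   `NULL` before localization.
#' @return An object of class `image_session`.
#' @export
image_session <- function(intensity, channel_names, voxel_size_um,
                          frame_interval_min = 1, day = NA_integer_,
                          onh_center_um = NULL) {
  d <- dim(intensity) %||% length(intensity)
  if (length(d) < 5L) {
    dim(intensity) <- c(d, rep(1L, 5L - length(d)))
  }
  d <- dim(intensity)
  if (length(channel_names) != d[4]) {
    stop_config("`channel_names` length must match the channel axis")
  }
  if (anyDuplicated(channel_names)) {
    stop_config("channel names must be unique")
  }
  if (any(voxel_size_um <= 0) || length(voxel_size_um) != 3L) {
    stop_config("`voxel_size_um` must be three positive values (x, y, z)")
  }
  if (d[5] < 1L) {
    stop_config("the time axis must have length >= 1")
  }
  structure(
    list(intensity = intensity,
         channel_names = as.character(channel_names),
         voxel_size_um = as.numeric(voxel_size_um),
         frame_interval_min = frame_interval_min,
         day = as.integer(day),
         onh_center_um = onh_center_um),
    class = "image_session"
  )
}

#' @export
print.image_session <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<image_session> day %s: %d x %d x %d voxels, %d channel(s) [%s], %d frame(s)\n",
    ifelse(is.na(x$day), "?", x$day), d[2], d[1], d[3], d[4],
    paste(x$channel_names, collapse = ", "), d[5]))
  cat(sprintf("  voxel %g x %g x %g um, frame interval %g min\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              x$frame_interval_min))
  invisible(x)
}

#' Extract one channel of a session
#'
#' @param session An [image_session].
#' @param channel Channel name.
#' @return A numeric `(y, x, z, t)` array.
#' @export
session_channel <- function(session, channel) {
  idx <- match(as.character(channel), session$channel_names)
  if (is.na(idx)) {
    abort(sprintf("channel '%s' not present in session", channel),
          class = "retinaivm_format_error")
  }
  d <- dim(session$intensity)
  array(session$intensity[, , , idx, ], dim = d[c(1, 2, 3, 5)])
}

stop_format <- function(msg) {
  abort(msg, class = "retinaivm_format_error")
}

#' Write / read an imaging session
#'
#' Sessions are stored as multi-page 32-bit float TIFF (axis order TZCYX:
#' pages cycle channel fastest, then z, then time) next to a JSON metadata
#' sidecar `<path>.json` that carries channel names, voxel size, frame
#' interval, imaging day and the intensity scale used to map data into the
#' [0, 1] storage range. The round trip preserves intensities to 32-bit
#' float precision and metadata exactly.
#'
#' @param session An [image_session].
#' @param path Output TIFF path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   an [image_session].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "image_session"))
  d <- dim(session$intensity)
  scale <- max(session$intensity, 1e-12)
  pages <- vector("list", d[3] * d[4] * d[5])
  p <- 0L
  for (t in seq_len(d[5])) {
    for (z in seq_len(d[3])) {
      for (ch in seq_len(d[4])) {
        p <- p + 1L
        pages[[p]] <- session$intensity[, , z, ch, t] / scale
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    axes = "TZCYX",
    shape = list(t = d[5], z = d[3], c = d[4], y = d[1], x = d[2]),
    channel_names = session$channel_names,
    voxel_size_um = session$voxel_size_um,
    frame_interval_min = session$frame_interval_min,
    day = session$day,
    onh_center_um = session$onh_center_um,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param known_channels Channel names treated as acquisition bands; any
#'   other name in the file is loaded and flagged as an auxiliary channel
#'   (attribute `auxiliary_channels`).
#' @rdname write_session
#' @export
read_session <- function(path,
                         known_channels = c("466", "525", "593", "vessel",
                                            "cell")) {
  if (!file.exists(path)) {
    stop_format(sprintf("session file '%s' does not exist", path))
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop_format("missing metadata sidecar: voxel size and channel metadata unavailable")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (fld in c("shape", "channel_names", "voxel_size_um",
                "frame_interval_min", "intensity_scale")) {
    if (is.null(meta[[fld]])) {
      stop_format(sprintf("metadata sidecar lacks required field '%s'", fld))
    }
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop_format(sprintf("unreadable TIFF: %s", conditionMessage(e))),
    warning = function(w) stop_format(sprintf("unreadable TIFF: %s", conditionMessage(w)))
  )
  sh <- meta$shape
  expected <- sh$t * sh$z * sh$c
  if (length(pages) != expected) {
    stop_format(sprintf(
      "truncated or inconsistent TIFF: expected %d pages, found %d",
      expected, length(pages)))
  }
  arr <- array(0, dim = c(sh$y, sh$x, sh$z, sh$c, sh$t))
  p <- 0L
  for (t in seq_len(sh$t)) {
    for (z in seq_len(sh$z)) {
      for (ch in seq_len(sh$c)) {
        p <- p + 1L
        arr[, , z, ch, t] <- pages[[p]] * meta$intensity_scale
      }
    }
  }
  day <- suppressWarnings(as.integer(meta$day))
  sess <- image_session(
    intensity = arr,
    channel_names = meta$channel_names,
    voxel_size_um = meta$voxel_size_um,
    frame_interval_min = meta$frame_interval_min,
    day = if (length(day) == 1L) day else NA_integer_,
    onh_center_um = meta$onh_center_um
  )
  aux <- setdiff(meta$channel_names, known_channels)
  attr(sess, "auxiliary_channels") <- aux
  sess
}
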