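# Track linking (global nearest-neighbour assignment) and motility metrics.

# Minimal-cost square assignment via shortest augmenting paths with dual
# potentials (O(n^3)). Returns, for each row, the assigned column.
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) {
    return(integer(0))
  }
  stopifnot(ncol(cost) == n)
  vc <- n + 1L # virtual column
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j]: row matched to column j (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[vc] <- i
    j0 <- vc
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      jf <- which(!used[seq_len(n)])
      cur <- cost[i0, jf] - u[i0] - v[jf]
      upd <- cur < minv[jf]
      if (any(upd)) {
        minv[jf[upd]] <- cur[upd]
        way[jf[upd]] <- j0
      }
      j1 <- jf[which.min(minv[jf])]
      delta <- minv[j1]
      ju <- which(used)
      u[p[ju]] <- u[p[ju]] + delta
      v[ju] <- v[ju] - delta
      jn <- which(!used[seq_len(n)])
      minv[jn] <- minv[jn] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == vc) break
    }
  }
  assignment <- integer(n)
  assignment[p[seq_len(n)]] <- seq_len(n)
  assignment
}

# One-to-one frame-to-frame linking between two point sets, minimizing total
# squared distance with links beyond `max_dist` forbidden; every unlinked
# point (track termination or birth) incurs a max_dist^2 penalty, so an
# allowed link is always preferred to leaving both ends unlinked. Returns an
# integer vector over rows of `pos1`: the matched row of `pos2` or NA.
link_frame_pair <- function(pos1, pos2, max_dist) {
  n1 <- nrow(pos1)
  n2 <- nrow(pos2)
  if (n1 == 0L || n2 == 0L) {
    return(rep(NA_integer_, n1))
  }
  d2 <- outer(pos1[, 1], pos2[, 1], `-`)^2 + outer(pos1[, 2], pos2[, 2], `-`)^2
  D2 <- max_dist^2
  big <- (n1 + n2) * D2 + 1
  n <- n1 + n2
  cost <- matrix(big, n, n)
  link <- d2
  link[link > D2] <- big
  cost[seq_len(n1), seq_len(n2)] <- link
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- D2    # termination
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- D2    # birth
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0       # dummy-dummy
  a <- solve_lap(cost)
  match12 <- a[seq_len(n1)]
  match12[match12 > n2] <- NA_integer_
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    if (!is.na(match12[i]) && d2[i, match12[i]] <= D2) {
      out[i] <- match12[i]
    }
  }
  out
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame, globally optimal one-to-one assignment minimizing total
#' squared planar distance; links longer than `max_link_distance` are
#' forbidden. Unmatched detections start new tracks; a missed detection
#' terminates a track (no gap closing). Tracks spanning fewer than
#' `min_length` frames are discarded.
#'
#' @param detections Tibble with `frame`, `x_um`, `y_um` (and optionally
#'   `z_um` and other columns, which are carried along).
#' @param max_link_distance Maximum per-frame link distance (um, > 0).
#' @param min_length Minimum track length in frames (default 5).
#' @return A tibble of track points: `cell_id` (track identifier), `frame`,
#'   `x_um`, `y_um`, plus carried columns, ordered by track then frame.
#' @export
link_tracks <- function(detections, max_link_distance, min_length = 5L) {
  if (max_link_distance <= 0) {
    stop_config("`max_link_distance` must be > 0")
  }
  if (nrow(detections) == 0) {
    return(dplyr::mutate(detections, cell_id = integer(0)))
  }
  detections <- dplyr::arrange(detections, .data$frame)
  frames <- sort(unique(detections$frame))
  per_frame <- split(detections, detections$frame)
  next_track <- 0L
  new_ids <- function(k) {
    ids <- next_track + seq_len(k)
    next_track <<- next_track + k
    ids
  }
  f1 <- per_frame[[as.character(frames[1])]]
  f1$cell_id <- new_ids(nrow(f1))
  linked <- list(f1)
  prev <- f1
  for (fi in seq_along(frames)[-1]) {
    cur <- per_frame[[as.character(frames[fi])]]
    if (frames[fi] - frames[fi - 1] == 1 && nrow(prev) > 0) {
      m <- link_frame_pair(cbind(prev$x_um, prev$y_um),
                           cbind(cur$x_um, cur$y_um), max_link_distance)
    } else {
      m <- rep(NA_integer_, nrow(prev)) # non-consecutive frames: no links
    }
    cur$cell_id <- NA_integer_
    ok <- !is.na(m)
    cur$cell_id[m[ok]] <- prev$cell_id[ok]
    fresh <- is.na(cur$cell_id)
    cur$cell_id[fresh] <- new_ids(sum(fresh))
    linked[[fi]] <- cur
    prev <- cur
  }
  out <- dplyr::bind_rows(linked)
  keep <- out |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n >= min_length) |>
    dplyr::pull(.data$cell_id)
  out |>
    dplyr::filter(.data$cell_id %in% keep) |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::relocate("cell_id")
}

#' Per-track motility metrics
#'
#' Computes, per track, the straight-line net displacement between start and
#' end point, the traversed path length, the displacement rate
#' (net displacement / duration) and, when the ONH position is known, the
#' signed radial displacement. All metrics are planar (x-y, um): axial
#' sampling is far coarser than lateral sampling, so z is excluded.
#' Track frames flagged `exited` (clipped at the phantom boundary) and all
#' later frames of that track are excluded. Single-point tracks get zero
#' metrics and `degenerate = TRUE`.
#'
#' @param track_points Tibble with `cell_id`, `frame`, `x_um`, `y_um`
#'   (optional `exited`, `motile` ground-truth flags carried as
#'   `motile_truth`).
#' @param frame_interval_min Minutes per frame step.
#' @param onh_center_um Optional ONH position for [radial_displacement()].
#' @return One row per track: `cell_id`, `n_frames`, `duration_min`,
#'   `net_displacement_um`, `path_length_um`, `displacement_rate_um_min`,
#'   `radial_displacement_um` (if ONH given), `degenerate`.
#' @export
summarize_tracks <- function(track_points, frame_interval_min = 1,
                             onh_center_um = NULL) {
  track_points |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$frame)
      if ("exited" %in% names(df) && any(df$exited)) {
        first_exit <- which(df$exited)[1]
        df <- df[seq_len(first_exit - 1L), , drop = FALSE]
      }
      n <- nrow(df)
      if (n < 2L) {
        return(tibble::tibble(
          n_frames = n, duration_min = 0, net_displacement_um = 0,
          path_length_um = 0, displacement_rate_um_min = 0,
          radial_displacement_um = if (is.null(onh_center_um)) NULL else 0,
          motile_truth = if ("motile" %in% names(df) && n > 0) df$motile[1]
            else NA,
          degenerate = TRUE))
      }
      dx <- diff(df$x_um)
      dy <- diff(df$y_um)
      path <- sum(sqrt(dx^2 + dy^2))
      net <- sqrt((df$x_um[n] - df$x_um[1])^2 + (df$y_um[n] - df$y_um[1])^2)
      dur <- (df$frame[n] - df$frame[1]) * frame_interval_min
      tibble::tibble(
        n_frames = n,
        duration_min = dur,
        net_displacement_um = net,
        path_length_um = path,
        displacement_rate_um_min = net / dur,
        radial_displacement_um = if (is.null(onh_center_um)) NULL else {
          radial_displacement(df, onh_center_um)
        },
        motile_truth = if ("motile" %in% names(df)) df$motile[1] else NA,
        degenerate = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Classify tracks as motile or sessile
#'
#' A track is motile iff its net displacement strictly exceeds the
#' threshold. The default threshold of 10 um per 20-min session matches the
#' criterion used to single out the significantly displacing cell
#' population; a 20 um threshold is the convention for trajectory overlay
#' plots.
#'
#' @param track_summary Output of [summarize_tracks()].
#' @param displacement_threshold_um Threshold (um, >= 0).
#' @return `track_summary` with an added logical `motile` column.
#' @export
classify_motile <- function(track_summary, displacement_threshold_um = 10) {
  if (displacement_threshold_um < 0) {
    stop_config("`displacement_threshold_um` must be >= 0")
  }
  dplyr::mutate(track_summary,
                motile = .data$net_displacement_um > displacement_threshold_um)
}

#' Signed radial displacement of one track
#'
#' The difference between the end-point and start-point distances to the
#' optic nerve head, in the x-y plane:
#' `||end - onh|| - ||start - onh||` (um). Positive values are centrifugal
#' (motion away from the ONH), negative centripetal. This planar radial
#' difference reproduces the sign semantics of projecting the ONH-to-start
#' and ONH-to-end vectors onto the radial direction, and is invariant under
#' rotations about the ONH.
#'
#' @param track Tibble of one track's points (`frame`, `x_um`, `y_um`).
#' @param onh_center_um x-y ONH position (um).
#' @return Signed displacement in micrometres.
#' @export
radial_displacement <- function(track, onh_center_um) {
  track <- dplyr::arrange(track, .data$frame)
  n <- nrow(track)
  r <- function(i) sqrt((track$x_um[i] - onh_center_um[1])^2 +
                        (track$y_um[i] - onh_center_um[2])^2)
  r(n) - r(1)
}

#' Global displacement vector
#'
#' Sums the signed radial displacements of the selected tracks of one
#' condition or session (motile tracks only by default). Positive totals
#' indicate net centrifugal migration away from the optic nerve head,
#' negative totals net centripetal migration toward it.
#'
#' @param track_summary Output of [summarize_tracks()], with a `motile`
#'   column when `motile_only = TRUE` (add one via [classify_motile()]).
#' @param motile_only Restrict the sum to motile tracks (default `TRUE`).
#' @return Signed micrometres; `0` with a warning for an empty selection.
#' @export
global_displacement_vector <- function(track_summary, motile_only = TRUE) {
  if (motile_only) {
    if (!"motile" %in% names(track_summary)) {
      stop_config("`track_summary` lacks a `motile` column; run classify_motile()")
    }
    track_summary <- track_summary[track_summary$motile, , drop = FALSE]
  }
  if (nrow(track_summary) == 0) {
    warn("no tracks selected; global displacement vector is 0",
         class = "retinaivm_empty_selection_warning")
    return(0)
  }
  sum(track_summary$radial_displacement_um)
}
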