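# Shared fixtures and independent oracles for the test suite.

# A fast phantom: full field of view on a coarse grid, short session.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_pixels = 96L, n_z = 4L, n_frames = 6L,
    n_neuronal_slices = 1L, n_rpe_slices = 1L,
    session_days = c(14L, 21L),
    cells_per_day = c(`14` = 5, `21` = 8),
    radial_scale_per_day = c(`14` = 120, `21` = 180),
    channel_cal = channel_calibration(smoothing_sigma = 0)
  )
  do.call(phantom_config, utils::modifyList(defaults, args))
}

# Brute-force minimal-cost partial matching between two planar point sets:
# enumerates every injective assignment with links gated at `max_dist`,
# charging max_dist^2 per unmatched point on either side. Independent of the
# package's assignment solver.
oracle_matching_cost <- function(pos1, pos2, max_dist) {
  n1 <- nrow(pos1)
  n2 <- nrow(pos2)
  D2 <- max_dist^2
  if (n1 == 0 || n2 == 0) {
    return((n1 + n2) * D2)
  }
  d2 <- outer(pos1[, 1], pos2[, 1], `-`)^2 + outer(pos1[, 2], pos2[, 2], `-`)^2
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) {
      return(invisible())
    }
    if (i > n1) {
      best <<- min(best, acc + D2 * sum(!used))
      return(invisible())
    }
    for (j in which(!used)) {
      if (d2[i, j] <= D2) {
        used2 <- used
        used2[j] <- TRUE
        rec(i + 1L, used2, acc + d2[i, j])
      }
    }
    rec(i + 1L, used, acc + D2)
  }
  rec(1L, rep(FALSE, n2), 0)
  best
}

# Cost of the package's frame-pair linking under the same objective.
linker_matching_cost <- function(pos1, pos2, max_dist) {
  m <- retinaivm:::link_frame_pair(pos1, pos2, max_dist)
  D2 <- max_dist^2
  cost <- 0
  for (i in seq_along(m)) {
    if (is.na(m[i])) {
      cost <- cost + D2
    } else {
      cost <- cost + sum((pos1[i, ] - pos2[m[i], ])^2)
    }
  }
  cost + D2 * (nrow(pos2) - sum(!is.na(m)))
}

# Separately coded random-walk oracle for the drift update rule: returns the
# signed radial displacement (end radius minus start radius) of `n_cells`
# motile cells after `n_steps` of drift plus isotropic noise.
rw_oracle_radial <- function(n_cells, n_steps, drift, sigma, dt = 1,
                             start_radius = 300) {
  sapply(seq_len(n_cells), function(i) {
    th <- runif(1, 0, 2 * pi)
    p <- start_radius * c(cos(th), sin(th))
    r0 <- sqrt(sum(p^2))
    for (s in seq_len(n_steps)) {
      rhat <- p / sqrt(sum(p^2))
      p <- p + drift * dt * rhat + rnorm(2, 0, sigma * sqrt(dt))
    }
    sqrt(sum(p^2)) - r0
  })
}

# Rotate planar points by 90 degrees counter-clockwise about a centre.
rotate90 <- function(x, y, cx, cy) {
  list(x = cx - (y - cy), y = cy + (x - cx))
}

# Rotate a (y, x) matrix by 90 degrees about the grid centre (square grids):
# the pixel at (i, j) maps to the pixel holding the rotated physical point.
rotate90_matrix <- function(m) {
  n <- nrow(m)
  out <- matrix(m[1], n, n)
  # physical rotation (x, y) -> (cx - (y - cy), cy + (x - cx)) with the
  # centre at (n/2 + 0.5 - 0.5) pixels maps column j -> row j, row i -> col n + 1 - i
  for (i in seq_len(n)) {
    out[, n + 1L - i] <- m[i, ]
  }
  out
}
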