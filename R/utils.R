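# Internal numerical primitives shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(msg) {
  abort(msg, class = "retinaivm_config_error")
}

# Otsu's threshold on a 256-bin histogram; returns a value separating the two
# intensity classes (voxels strictly above are foreground).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) {
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b) + 1L]
}

# 1D Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian convolution of a 2D matrix with replicate padding.
gaussian_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  smooth_1d <- function(mat) {
    # convolve each column of `mat` with k, replicate padding
    n <- nrow(mat)
    pad_top <- mat[rep(1L, r), , drop = FALSE]
    pad_bot <- mat[rep(n, r), , drop = FALSE]
    padded <- rbind(pad_top, mat, pad_bot)
    out <- matrix(0, n, ncol(mat))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  m <- smooth_1d(m)          # along y
  t(smooth_1d(t(m)))         # along x
}

# Apply 2D x-y Gaussian smoothing to every z/t plane of an array whose first
# two dims are (y, x); no smoothing along z (anisotropic voxels).
gaussian_smooth_planes <- function(a, sigma) {
  if (sigma <= 0) {
    return(a)
  }
  d <- dim(a)
  if (is.null(d) || length(d) == 2L) {
    return(gaussian_smooth_matrix(as.matrix(a), sigma))
  }
  planes <- prod(d[-(1:2)])
  m <- array(a, dim = c(d[1], d[2], planes))
  for (p in seq_len(planes)) {
    m[, , p] <- gaussian_smooth_matrix(m[, , p], sigma)
  }
  array(m, dim = d)
}

# Connected components of a 3D logical mask (26-connectivity by default).
# Returns an integer array of labels (0 = background). Pass a 2D mask with
# dim (y, x, 1) for 8-connectivity 2D labeling.
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    d <- c(d, 1L)
    mask <- array(mask, dim = d)
  }
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) {
    return(labels)
  }
  # 26-neighbour offsets in (dy, dx, dz)
  nb <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  current <- 0L
  for (v in fg) {
    if (labels[v] != 0L) next
    current <- current + 1L
    queue <- v
    labels[v] <- current
    while (length(queue) > 0L) {
      idx <- queue
      queue <- integer(0)
      i0 <- ((idx - 1L) %% ny) + 1L
      j0 <- (((idx - 1L) %/% ny) %% nx) + 1L
      k0 <- ((idx - 1L) %/% (ny * nx)) + 1L
      for (q in seq_len(nrow(nb))) {
        i <- i0 + nb[q, 1L]; j <- j0 + nb[q, 2L]; k <- k0 + nb[q, 3L]
        ok <- i >= 1L & i <= ny & j >= 1L & j <= nx & k >= 1L & k <= nz
        if (!any(ok)) next
        lin <- (k[ok] - 1L) * ny * nx + (j[ok] - 1L) * ny + i[ok]
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin) > 0L) {
          labels[lin] <- current
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

# Binary erosion of a 2D logical mask with a square structuring element of
# half-width `r` pixels, via separable running windows on the complement.
binary_erode <- function(mask, r) {
  if (r <= 0) {
    return(mask)
  }
  m <- mask * 1
  box_sum_cols <- function(mat, r) {
    n <- nrow(mat)
    cs <- rbind(0, apply(mat, 2, cumsum))
    lo <- pmax(seq_len(n) - r, 1L)
    hi <- pmin(seq_len(n) + r, n)
    cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  win_rows <- pmin(seq_len(nrow(m)) + r, nrow(m)) - pmax(seq_len(nrow(m)) - r, 1L) + 1L
  win_cols <- pmin(seq_len(ncol(m)) + r, ncol(m)) - pmax(seq_len(ncol(m)) - r, 1L) + 1L
  s <- box_sum_cols(m, r)
  full_rows <- s == win_rows                      # all TRUE in the column window
  s2 <- t(box_sum_cols(t(full_rows * 1), r))
  s2 == matrix(win_cols, nrow(m), ncol(m), byrow = TRUE)
}

# Pixel-centre physical coordinates (micrometres) along one axis.
pixel_centers <- function(n, extent_um) {
  (seq_len(n) - 0.5) * (extent_um / n)
}
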