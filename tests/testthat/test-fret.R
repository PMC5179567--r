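# Ratiometric FRET signal, anchored Hill calibration, and the
# dysfunction-threshold statistics.

test_that("the FRET ratio reproduces the corrected-channel arithmetic", {
  cal525 <- channel_calibration(background = c(`525` = 10, `593` = 10, `466` = 10),
                                sensitivity = c(`525` = 0.8, `593` = 1, `466` = 0.8),
                                overlap = c(`525` = 0.9, `593` = 1, `466` = 1),
                                smoothing_sigma = 0)
  g <- function(v) matrix(v, 4, 4)
  c525 <- correct_channel(g(210), cal525, "525") # (0.9/0.8) * 200 = 225
  c593 <- correct_channel(g(110), cal525, "593") # 100
  c466 <- correct_channel(g(90), cal525, "466")  # (1/0.8) * 80 = 100
  fm <- compute_fret_ratio(c466, c525, c593)
  expect_equal(as.vector(fm$ratio), rep(325 / 425, 16), tolerance = 1e-9)
})

test_that("FRET ratio limit cases and invariances hold", {
  z <- matrix(0, 3, 3)
  a <- matrix(5, 3, 3)
  # no donor signal: ratio exactly 1
  expect_equal(as.vector(compute_fret_ratio(z, a, a)$ratio), rep(1, 9))
  # acceptor sum equal to donor: exactly 0.5
  expect_equal(as.vector(compute_fret_ratio(a + a, a, a)$ratio), rep(0.5, 9))
  # invariance under positive rescaling of all channels
  set.seed(5)
  x <- matrix(runif(9, 1, 2), 3, 3)
  y <- matrix(runif(9, 1, 2), 3, 3)
  w <- matrix(runif(9, 1, 2), 3, 3)
  r1 <- compute_fret_ratio(x, y, w)$ratio
  r2 <- compute_fret_ratio(7.3 * x, 7.3 * y, 7.3 * w)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
  # ratios always within [0, 1]
  expect_true(all(r1 >= 0 & r1 <= 1))
  # dark voxels are undefined, not zero
  dark <- compute_fret_ratio(z, z, z)$ratio
  expect_true(all(is.na(dark)))
  expect_error(compute_fret_ratio(matrix(1, 2, 2), matrix(1, 3, 3),
                                  matrix(1, 2, 2)),
               class = "retinaivm_shape_error")
})

test_that("the anchored calibration passes through both anchor points", {
  cal <- fit_calibration()
  expect_equal(calcium_to_ratio(1e-6, cal), 0.47, tolerance = 1e-9)
  expect_equal(calcium_to_ratio(3e-6, cal), 0.70, tolerance = 1e-9)
  expect_equal(as.numeric(ratio_to_calcium(0.47, cal)), 1e-6,
               tolerance = 1e-9)
  expect_equal(as.numeric(ratio_to_calcium(0.70, cal)), 3e-6,
               tolerance = 1e-9)
})

test_that("a known Hill curve is recovered from two samples", {
  # sample a chosen curve (r_min 0, r_max 1, K_d 2 M, n 1) at C = 1, 3
  truth <- function(C) C / (2 + C)
  cal <- fit_calibration(
    anchors = tibble::tibble(ratio = truth(c(1, 3)),
                             concentration_M = c(1, 3)),
    r_min = 0, r_max = 1)
  expect_equal(cal$kd_M, 2, tolerance = 1e-12)
  expect_equal(cal$hill_n, 1, tolerance = 1e-12)
})

test_that("invalid anchors are rejected", {
  expect_error(fit_calibration(anchors = tibble::tibble(
    ratio = c(0.70, 0.47), concentration_M = c(1e-6, 3e-6))),
    class = "retinaivm_calibration_error")
  expect_error(fit_calibration(anchors = tibble::tibble(
    ratio = c(0.1, 0.7), concentration_M = c(1e-6, 3e-6)),
    r_min = 0.25, r_max = 0.85),
    class = "retinaivm_calibration_error")
  expect_error(fit_calibration(r_min = 0.9, r_max = 0.5),
               class = "retinaivm_calibration_error")
})

test_that("ratio-calcium conversion round-trips and stays monotone", {
  cal <- fit_calibration()
  for (r in c(0.3, 0.5, 0.8)) {
    expect_equal(calcium_to_ratio(ratio_to_calcium(r, cal), cal), r,
                 tolerance = 1e-9)
  }
  grid <- seq(cal$r_min + 1e-4, cal$r_max - 1e-4, length.out = 200)
  back <- calcium_to_ratio(ratio_to_calcium(grid, cal), cal)
  expect_equal(back, grid, tolerance = 1e-9)
  conc <- as.numeric(ratio_to_calcium(grid, cal))
  expect_true(all(diff(conc) > 0))
  # flags at the asymptotes
  lo <- ratio_to_calcium(cal$r_min - 0.01, cal)
  hi <- ratio_to_calcium(cal$r_max + 0.01, cal)
  expect_equal(as.numeric(lo), 0)
  expect_equal(as.numeric(hi), Inf)
  expect_identical(attr(lo, "flag"), "floor")
  expect_identical(attr(hi, "flag"), "saturated")
})

test_that("ROI time courses report per-ROI means and tolerate empty ROIs", {
  cfg <- tiny_config(calcium_lesions = list(
    list(center_um = c(350, 350), radius_um = 120, concentration_M = 2e-6)))
  s <- render_session(generate_background(cfg), simulate_tracks(cfg),
                      simulate_calcium(cfg), fit_calibration(), cfg, 14L)
  fm <- session_fret(s, cfg$channel_cal)
  rois <- tibble::tibble(roi = c(1, 2, 3),
                         x_um = c(350, 1050, -500), y_um = c(350, 1050, -500),
                         radius_um = c(100, 100, 100))
  tc <- roi_time_course(fm, rois)
  expect_equal(nrow(tc), 3 * cfg$n_frames)
  m1 <- mean(tc$mean_ratio[tc$roi == 1])
  m2 <- mean(tc$mean_ratio[tc$roi == 2])
  expect_gt(m1, m2) # the lesion ROI runs hot
  expect_true(all(is.na(tc$mean_ratio[tc$roi == 3]))) # off-field ROI missing
  # uniform field: every ROI mean equals the field ratio
  cfg0 <- tiny_config()
  s0 <- render_session(generate_background(cfg0), simulate_tracks(cfg0),
                       simulate_calcium(cfg0), fit_calibration(), cfg0, 14L)
  fm0 <- session_fret(s0, cfg0$channel_cal)
  tc0 <- roi_time_course(fm0, rois[1:2, ])
  expect_equal(tc0$mean_ratio,
               rep(calcium_to_ratio(100e-9, fit_calibration()),
                   nrow(tc0)), tolerance = 1e-6)
})

test_that("zonal FRET means are flat on a uniform calcium field", {
  cfg <- tiny_config()
  s <- render_session(generate_background(cfg), simulate_tracks(cfg),
                      simulate_calcium(cfg), fit_calibration(), cfg, 14L)
  fm <- session_fret(s, cfg$channel_cal)
  zf <- zone_fret(fm, zone_config(onh_center_um = cfg$onh_center_um))
  expect_equal(zf$mean_ratio,
               rep(calcium_to_ratio(100e-9, fit_calibration()), nrow(zf)),
               tolerance = 1e-6)
})

test_that("dysfunction fraction separates baseline, lesion and ionomycin", {
  cal <- fit_calibration()
  run <- function(cfg) {
    s <- render_session(generate_background(cfg), simulate_tracks(cfg),
                        simulate_calcium(cfg), cal, cfg, 14L)
    fm <- session_fret(s, cfg$channel_cal)
    list(f = dysfunction_fraction(fm, cal), fm = fm, cfg = cfg)
  }
  expect_equal(run(tiny_config(vessel_count = 0L))$f, 0)
  expect_equal(run(tiny_config(vessel_count = 0L, ionomycin = TRUE))$f, 1)
  # a lesion sized to 10% of the mask
  les_r <- sqrt(0.1 * (1400^2 - pi * 100^2) / pi)
  res <- run(tiny_config(vessel_count = 0L, calcium_lesions = list(
    list(center_um = c(350, 350), radius_um = les_r, concentration_M = 2e-6))))
  truth_frac <- {
    ca <- simulate_calcium(res$cfg)
    mean(ca[res$fm$mask] >= 1e-6)
  }
  expect_equal(res$f, truth_frac)
  expect_lt(abs(res$f - 0.10), 0.02) # voxelization error only
  # monotone in the threshold
  cal_hi <- fit_calibration(dysfunction_threshold_M = 2.5e-6)
  expect_lte(dysfunction_fraction(res$fm, cal_hi), res$f)
  # empty mask errors
  fm_bad <- res$fm
  fm_bad$mask <- fm_bad$mask & FALSE
  expect_error(dysfunction_fraction(fm_bad, cal),
               class = "retinaivm_mask_error")
})

test_that("noise-off phantom calcium is recovered voxelwise within 1%", {
  cal <- fit_calibration()
  cfg <- tiny_config(n_pixels = 128L, vessel_count = 0L,
                     calcium_lesions = list(
                       list(center_um = c(400, 400), radius_um = 180,
                            concentration_M = 0.5e-6)))
  s <- render_session(generate_background(cfg), simulate_tracks(cfg),
                      simulate_calcium(cfg), cal, cfg, 14L)
  fm <- session_fret(s, cfg$channel_cal)
  inferred <- ratio_to_calcium(fm$ratio[, , 1], cal)
  truth <- simulate_calcium(cfg)
  sel <- fm$mask & !is.na(fm$ratio[, , 1])
  rel <- abs(inferred[sel] - truth[sel]) / truth[sel]
  expect_lt(max(rel), 0.01)
})
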