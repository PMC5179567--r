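# Synthetic retina phantom: background anatomy, track simulation, calcium
# field, and rendering with a known ground truth.

test_that("background carries a dark ONH disc and dark vessels over an autofluorescent field", {
  cfg <- tiny_config()
  bg <- generate_background(cfg)
  s <- render_session(bg, simulate_tracks(cfg), simulate_calcium(cfg),
                      fit_calibration(), cfg, 14L)
  rpe <- session_channel(s, "525")[, , cfg$n_z, 1] # bottom slice, frame 1
  expect_equal(mean(rpe[bg$onh_mask]), 0)
  outside <- rpe[bg$shadow_mask]
  expect_equal(mean(outside), cfg$background_level)
  expect_true(all(rpe[bg$vessel_mask] == 0))
  # vessel-label channel is bright exactly along vessels
  ves <- session_channel(s, "vessel")[, , 1, 1]
  expect_true(all(ves[bg$vessel_mask] == cfg$vessel_label_intensity))
  expect_true(all(ves[!bg$vessel_mask] == 0))
})

test_that("a vessel-free background has only the ONH shadow", {
  bg <- generate_background(tiny_config(vessel_count = 0L))
  expect_false(any(bg$vessel_mask))
  expect_identical(bg$shadow_mask, !bg$onh_mask)
})

test_that("background generation is deterministic in the seed", {
  cfg <- tiny_config(rng_seed = 42L)
  expect_identical(generate_background(cfg), generate_background(cfg))
})

test_that("an oversized ONH is rejected", {
  expect_error(tiny_config(onh_radius_um = 800), class = "retinaivm_config_error")
})

test_that("rotating the vessel layout by 90 degrees rotates the background", {
  base_angles <- c(0.3, 1.1, 2.8)
  cfg1 <- tiny_config(vessel_angles = base_angles)
  cfg2 <- tiny_config(vessel_angles = base_angles + pi / 2)
  m1 <- generate_background(cfg1)$vessel_mask
  m2 <- generate_background(cfg2)$vessel_mask
  expect_identical(rotate90_matrix(m1), m2)
})

test_that("noise-free tracks follow the drift law exactly", {
  # no drift, no noise: every track is one repeated point
  cfg <- tiny_config(drift_rate_um_min = 0, step_sigma = 0)
  tr <- simulate_tracks(cfg)
  spans <- tr |>
    dplyr::group_by(day, cell_id) |>
    dplyr::summarise(sx = diff(range(x_um)), sy = diff(range(y_um)),
                     .groups = "drop")
  expect_true(all(spans$sx == 0 & spans$sy == 0))

  # pure drift: every motile cell's radial distance grows by drift * time
  cfg <- tiny_config(drift_rate_um_min = 2, step_sigma = 0,
                     motile_fraction = 1, n_frames = 21L,
                     session_days = 21L, cells_per_day = c(`21` = 10),
                     radial_scale_per_day = c(`21` = 120))
  tr <- simulate_tracks(cfg)
  radial <- tr |>
    dplyr::mutate(r = sqrt((x_um - 700)^2 + (y_um - 700)^2)) |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(growth = r[frame == 21] - r[frame == 1],
                     clipped = any(exited), .groups = "drop")
  expect_equal(radial$growth[!radial$clipped],
               rep(40, sum(!radial$clipped)), tolerance = 1e-10)
})

test_that("mean signed radial displacement agrees with an independent random-walk oracle", {
  cfg <- tiny_config(drift_rate_um_min = 2, step_sigma = 1,
                     motile_fraction = 1, n_frames = 21L,
                     session_days = 21L, cells_per_day = c(`21` = 50),
                     radial_scale_per_day = c(`21` = 150),
                     rng_seed = 11L)
  tr <- simulate_tracks(cfg)
  radial <- tr |>
    dplyr::group_by(cell_id) |>
    dplyr::filter(!any(exited)) |>
    dplyr::summarise(
      dr = sqrt((x_um[21] - 700)^2 + (y_um[21] - 700)^2) -
           sqrt((x_um[1] - 700)^2 + (y_um[1] - 700)^2))
  set.seed(11)
  oracle <- rw_oracle_radial(50, 20, drift = 2, sigma = 1)
  se <- sd(oracle) / sqrt(length(oracle))
  # both the simulator and the oracle must sit within 3 SE of the 40 um drift
  expect_lt(abs(mean(radial$dr) - 40), 3 * se + 3 * sd(radial$dr) / sqrt(50))
  expect_lt(abs(mean(oracle) - 40), 3 * se)
  expect_lt(abs(mean(radial$dr) - mean(oracle)),
            3 * sqrt(se^2 + var(radial$dr) / 50))
})

test_that("seeded cells honour the minimum separation", {
  cfg <- tiny_config(session_days = 21L, cells_per_day = c(`21` = 20),
                     radial_scale_per_day = c(`21` = 150))
  seeds <- simulate_tracks(cfg) |> dplyr::filter(frame == 1)
  dmin <- min(stats::dist(cbind(seeds$x_um, seeds$y_um)))
  expect_gte(dmin, cfg$min_separation_um)
})

test_that("calcium field honours baseline, lesions and the ionomycin preset", {
  cfg <- tiny_config()
  expect_true(all(simulate_calcium(cfg) == 100e-9))
  iono <- tiny_config(ionomycin = TRUE)
  expect_true(all(simulate_calcium(iono) == 3e-6))
  # a zero-radius lesion changes nothing
  zero <- tiny_config(calcium_lesions = list(
    list(center_um = c(400, 400), radius_um = 0, concentration_M = 2e-6)))
  expect_identical(simulate_calcium(zero), simulate_calcium(cfg))
  # a finite lesion overrides the baseline inside its disc only
  les <- tiny_config(calcium_lesions = list(
    list(center_um = c(350, 350), radius_um = 150, concentration_M = 2e-6)))
  ca <- simulate_calcium(les)
  expect_setequal(unique(as.vector(ca)), c(100e-9, 2e-6))
  expect_error(
    tiny_config(calcium_lesions = list(
      list(center_um = c(0, 0), radius_um = 10, concentration_M = -1))),
    class = "retinaivm_config_error")
})

test_that("rendered FRET channels round-trip the calcium field (noise off)", {
  cal <- fit_calibration()
  cfg <- tiny_config(calcium_baseline_M = 1e-6,
                     cells_per_day = c(`14` = 0, `21` = 0))
  bg <- generate_background(cfg)
  s <- render_session(bg, simulate_tracks(cfg), simulate_calcium(cfg),
                      cal, cfg, 14L)
  fm <- session_fret(s, cfg$channel_cal)
  # 1 uM corresponds to a 47% FRET ratio; shadows are undefined, not zero
  vals <- fm$ratio[, , 1][bg$shadow_mask]
  expect_equal(vals, rep(0.47, length(vals)), tolerance = 1e-9)
  expect_true(all(is.na(fm$ratio[, , 1][!bg$shadow_mask])))
  # voxelwise round trip at every defined neuronal-layer voxel
  ratio_direct <- calcium_to_ratio(simulate_calcium(cfg), cal)
  expect_equal(fm$ratio[, , 1][bg$shadow_mask],
               ratio_direct[bg$shadow_mask], tolerance = 1e-9)
})

test_that("the brightest cell-channel voxel sits at the rendered cell", {
  cfg <- tiny_config(session_days = 21L, cells_per_day = c(`21` = 1),
                     radial_scale_per_day = c(`21` = 200),
                     drift_rate_um_min = 0, step_sigma = 0)
  tr <- simulate_tracks(cfg)
  s <- render_session(generate_background(cfg), tr, simulate_calcium(cfg),
                      fit_calibration(), cfg, 21L)
  vol <- session_channel(s, "cell")[, , , 1]
  peak <- which(vol == max(vol), arr.ind = TRUE)[1, ]
  px <- s$voxel_size_um
  truth <- tr[tr$frame == 1, ]
  expect_lt(abs((peak[2] - 0.5) * px[1] - truth$x_um), px[1])
  expect_lt(abs((peak[1] - 0.5) * px[2] - truth$y_um), px[2])
})

test_that("rendering with Poisson noise is deterministic given the seed", {
  cfg <- tiny_config(photon_scale = 1)
  bg <- generate_background(cfg)
  tr <- simulate_tracks(cfg)
  ca <- simulate_calcium(cfg)
  cal <- fit_calibration()
  s1 <- render_session(bg, tr, ca, cal, cfg, 21L)
  s2 <- render_session(bg, tr, ca, cal, cfg, 21L)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("every in-field ground-truth position yields exactly one rendered blob", {
  cfg <- tiny_config(n_pixels = 128L, n_z = 8L, session_days = 21L,
                     cells_per_day = c(`21` = 8),
                     radial_scale_per_day = c(`21` = 150),
                     min_separation_um = 60,
                     drift_rate_um_min = 2, step_sigma = 0.5,
                     motile_fraction = 1, rng_seed = 3L)
  tr <- simulate_tracks(cfg)
  s <- render_session(generate_background(cfg), tr, simulate_calcium(cfg),
                      fit_calibration(), cfg, 21L)
  det <- detect_cells(s, threshold = 4, size_range = c(100, 1e8))
  for (t in seq_len(cfg$n_frames)) {
    expect_equal(sum(det$frame == t), sum(tr$frame == t))
  }
})
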