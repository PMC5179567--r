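# Track linking, motility metrics, and signed radial displacement
# statistics relative to the optic nerve head.

test_that("frame-to-frame linking matches exhaustive minimal-cost matching", {
  set.seed(10)
  for (rep in 1:60) {
    n1 <- sample(0:6, 1)
    n2 <- sample(0:6, 1)
    pos1 <- matrix(runif(2 * n1, 0, 100), ncol = 2)
    pos2 <- matrix(runif(2 * n2, 0, 100), ncol = 2)
    D <- runif(1, 10, 60)
    expect_equal(linker_matching_cost(pos1, pos2, D),
                 oracle_matching_cost(pos1, pos2, D), tolerance = 1e-9)
  }
})

test_that("a single persistent cell yields one full-length track", {
  det <- tibble::tibble(frame = 1:10,
                        x_um = 100 + (1:10), y_um = 50)
  tr <- link_tracks(det, max_link_distance = 5)
  expect_equal(length(unique(tr$cell_id)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("links beyond the gate terminate tracks instead of cross-linking", {
  # two cells that would have to jump > max_link_distance to swap
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1:6, x_um = 0, y_um = 0),
    tibble::tibble(frame = 1:6, x_um = 100, y_um = 0)
  )
  # displace one cell far away at frame 4: its track must terminate
  det$x_um[det$frame >= 4 & det$x_um == 0] <- 40
  tr <- link_tracks(det, max_link_distance = 10, min_length = 3)
  # original cell 1 track covers frames 1..3 only; the displaced detections
  # form a new track; cell 2 remains whole
  lens <- tr |> dplyr::count(cell_id)
  expect_setequal(lens$n, c(3, 3, 6))
})

test_that("ground-truth identity is recovered on separable phantom tracks", {
  cfg <- tiny_config(session_days = 21L, cells_per_day = c(`21` = 6),
                     radial_scale_per_day = c(`21` = 150),
                     drift_rate_um_min = 2, step_sigma = 0.5,
                     motile_fraction = 1, n_frames = 10L, rng_seed = 8L)
  truth <- simulate_tracks(cfg)
  det <- truth[, c("frame", "x_um", "y_um")]
  tr <- link_tracks(det, max_link_distance = 15, min_length = 5)
  expect_equal(length(unique(tr$cell_id)), 6)
  # every linked track coincides with one ground-truth cell
  for (id in unique(tr$cell_id)) {
    pts <- tr[tr$cell_id == id, ]
    match_id <- truth$cell_id[truth$frame == 1 &
                                abs(truth$x_um - pts$x_um[1]) < 1e-9][1]
    gt <- truth[truth$cell_id == match_id, ]
    expect_equal(pts$x_um, gt$x_um, tolerance = 1e-12)
  }
})

test_that("track metrics follow their definitions", {
  # straight path: 20 um over 20 min -> rate 1 um/min
  straight <- tibble::tibble(cell_id = 1L, frame = c(1, 21),
                             x_um = c(0, 20), y_um = 0)
  s <- summarize_tracks(straight, frame_interval_min = 1)
  expect_equal(s$net_displacement_um, 20)
  expect_equal(s$duration_min, 20)
  expect_equal(s$displacement_rate_um_min, 1)

  # closed loop: zero net displacement, positive path length
  th <- seq(0, 2 * pi, length.out = 9)
  loop <- tibble::tibble(cell_id = 1L, frame = seq_along(th),
                         x_um = 10 * cos(th), y_um = 10 * sin(th))
  s <- summarize_tracks(loop)
  expect_equal(s$net_displacement_um, 0, tolerance = 1e-12)
  expect_gt(s$path_length_um, 0)

  # single point: zero metrics, flagged degenerate
  s <- summarize_tracks(tibble::tibble(cell_id = 1L, frame = 1L,
                                       x_um = 5, y_um = 5))
  expect_true(s$degenerate)
  expect_equal(s$net_displacement_um, 0)

  # path length always bounds net displacement
  set.seed(6)
  wiggly <- tibble::tibble(cell_id = 1L, frame = 1:30,
                           x_um = cumsum(rnorm(30)), y_um = cumsum(rnorm(30)))
  s <- summarize_tracks(wiggly)
  expect_gte(s$path_length_um, s$net_displacement_um)
})

test_that("a noise-off drifting phantom cell shows displacement 40 um at rate 2 um/min", {
  cfg <- tiny_config(session_days = 21L, cells_per_day = c(`21` = 3),
                     radial_scale_per_day = c(`21` = 150),
                     drift_rate_um_min = 2, step_sigma = 0,
                     motile_fraction = 1, n_frames = 21L)
  truth <- simulate_tracks(cfg)
  tr <- link_tracks(truth[, c("frame", "x_um", "y_um")],
                    max_link_distance = 10)
  s <- summarize_tracks(tr, 1, onh_center_um = cfg$onh_center_um)
  expect_equal(s$net_displacement_um, rep(40, 3), tolerance = 1e-9)
  expect_equal(s$displacement_rate_um_min, rep(2, 3), tolerance = 1e-9)
  expect_equal(s$radial_displacement_um, rep(40, 3), tolerance = 1e-9)
})

test_that("motile classification is strict at the threshold", {
  s <- tibble::tibble(cell_id = 1:3,
                      net_displacement_um = c(10, 11, 9.99),
                      radial_displacement_um = 0)
  cls <- classify_motile(s, 10)
  expect_identical(cls$motile, c(FALSE, TRUE, FALSE))
  # an all-sessile phantom yields no motile track
  cfg <- tiny_config(session_days = 21L, cells_per_day = c(`21` = 10),
                     radial_scale_per_day = c(`21` = 150),
                     motile_fraction = 0, step_sigma = 0.5, n_frames = 21L)
  truth <- simulate_tracks(cfg)
  summ <- summarize_tracks(truth, 1, onh_center_um = cfg$onh_center_um) |>
    classify_motile(10)
  expect_false(any(summ$motile))
})

test_that("signed radial displacement follows the end-minus-start convention", {
  onh <- c(0, 0)
  # 3-4-5 triangle scaled: radius 50 -> 100, centrifugal +50
  tr <- tibble::tibble(frame = 1:2, x_um = c(30, 60), y_um = c(40, 80))
  expect_equal(radial_displacement(tr, onh), 50)
  # centripetal motion is negative
  tr <- tibble::tibble(frame = 1:2, x_um = c(200, 100), y_um = 0)
  expect_equal(radial_displacement(tr, onh), -100)
  # purely tangential motion on a circle has zero radial displacement
  tr <- tibble::tibble(frame = 1:2, x_um = 100 * cos(c(0, 1)),
                       y_um = 100 * sin(c(0, 1)))
  expect_equal(radial_displacement(tr, onh), 0, tolerance = 1e-12)
  # a track starting on the ONH centre is valid
  tr <- tibble::tibble(frame = 1:2, x_um = c(0, 30), y_um = c(0, 40))
  expect_equal(radial_displacement(tr, onh), 50)
})

test_that("motility metrics are invariant under translation and rotation about the ONH", {
  set.seed(7)
  onh <- c(700, 700)
  pts <- tibble::tibble(cell_id = rep(1:4, each = 8),
                        frame = rep(1:8, 4),
                        x_um = 700 + rnorm(32, 0, 80),
                        y_um = 700 + rnorm(32, 0, 80))
  base <- summarize_tracks(pts, 1, onh_center_um = onh)
  shifted <- dplyr::mutate(pts, x_um = x_um + 123, y_um = y_um - 45)
  s2 <- summarize_tracks(shifted, 1, onh_center_um = onh + c(123, -45))
  expect_equal(base$net_displacement_um, s2$net_displacement_um)
  expect_equal(base$radial_displacement_um, s2$radial_displacement_um)
  rot <- rotate90(pts$x_um, pts$y_um, onh[1], onh[2])
  s3 <- summarize_tracks(dplyr::mutate(pts, x_um = rot$x, y_um = rot$y),
                         1, onh_center_um = onh)
  expect_equal(base$net_displacement_um, s3$net_displacement_um,
               tolerance = 1e-12)
  expect_equal(base$radial_displacement_um, s3$radial_displacement_um,
               tolerance = 1e-12)
})

test_that("the global displacement vector cancels, adds, and flips sign correctly", {
  mk <- function(radial, motile = TRUE) {
    tibble::tibble(cell_id = seq_along(radial),
                   radial_displacement_um = radial,
                   net_displacement_um = abs(radial), motile = motile)
  }
  expect_equal(global_displacement_vector(mk(c(25, -25, 10, -10))), 0)
  # linearity over disjoint unions
  a <- mk(c(5, 10))
  b <- mk(c(-3, 7, 1))
  expect_equal(global_displacement_vector(dplyr::bind_rows(a, b)),
               global_displacement_vector(a) + global_displacement_vector(b))
  # empty selection warns and returns 0
  expect_warning(
    out <- global_displacement_vector(mk(numeric(0))),
    class = "retinaivm_empty_selection_warning")
  expect_equal(out, 0)
})

test_that("opposite drifts yield mirrored global displacement vectors", {
  run <- function(drift) {
    cfg <- tiny_config(session_days = 21L, cells_per_day = c(`21` = 20),
                       radial_scale_per_day = c(`21` = 180),
                       drift_rate_um_min = drift, step_sigma = 0,
                       motile_fraction = 1, n_frames = 21L, rng_seed = 12L)
    truth <- simulate_tracks(cfg)
    summ <- summarize_tracks(truth, 1, onh_center_um = cfg$onh_center_um) |>
      classify_motile(10)
    global_displacement_vector(summ)
  }
  up <- run(2)
  down <- run(-2)
  expect_gt(up, 0)
  expect_lt(down, 0)
  # mirror symmetry up to cells reflected through the ONH or clipped at the
  # field edge (both rare at this seeding scale)
  expect_equal(up, -down, tolerance = 0.15)
})
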