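test_that("a motionless fundus phantom renders identical frames", {
  sp <- fundus_spec(grid = c(40L, 40L), spacing = c(2, 2), n_frames = 6L,
                    semi_axes = c(18, 12), oscillation_amp = 0, emptying = 0,
                    resp_amp_px = 0, noise_sd = 0, seed = 1L)
  ph <- make_fundus_phantom(sp)
  for (i in 2:6)
    expect_equal(ph$stack$frames[, , i], ph$stack$frames[, , 1])
  expect_equal(diff(range(ph$truth$area)), 0)
})

test_that("phantom generation is bit-reproducible from its seed", {
  sp <- fundus_spec(grid = c(32L, 32L), spacing = c(2, 2), n_frames = 4L,
                    semi_axes = c(12, 9), noise_sd = 0.05, resp_amp_px = 2,
                    seed = 77L)
  expect_identical(make_fundus_phantom(sp)$stack$frames,
                   make_fundus_phantom(sp)$stack$frames)
})

test_that("5% area oscillation over whole periods gives DM(A) near the
           sinusoid RMS", {
  nf <- 40L; dt <- 0.656
  sp <- fundus_spec(grid = c(48L, 48L), spacing = c(2, 2), n_frames = nf,
                    frame_interval = dt, semi_axes = c(20, 14),
                    oscillation_amp = 0.05,
                    oscillation_period = nf * dt / 2,  # two whole periods
                    seed = 5L)
  ph <- make_fundus_phantom(sp, render = FALSE)
  expect_equal(dm_area(ph$truth$area), 100 * 0.05 / sqrt(2), tolerance = 0.02)
})

test_that("oversized structures and bad ring widths raise errors", {
  expect_error(make_fundus_phantom(
    fundus_spec(grid = c(24L, 24L), spacing = c(1, 1), semi_axes = c(30, 20))),
    "fit")
  expect_error(make_duodenum_phantom(
    duodenum_spec(grid = c(64L, 64L), spacing = c(2, 2),
                  centerline = circle_points(5, 20, c(60, 60))[1:4, ],
                  ring_width = 40)),
    "ring width")
})

test_that("a zero-depth duodenum phantom is static with zero ground-truth
           velocities", {
  sp <- duodenum_spec(grid = c(64L, 64L), spacing = c(2, 2), n_frames = 5L,
                      depth = 0, noise_sd = 0, seed = 2L)
  ph <- make_duodenum_phantom(sp, render = FALSE)
  expect_true(all(ph$truth$vn == 0))
  expect_true(all(ph$truth$vt == 0))
  for (i in 2:5)
    expect_equal(ph$truth$boundary[[i]], ph$truth$boundary[[1]])
})

test_that("ground-truth tangential velocity is zero by construction and
           stored area/centroid agree with polygon formulas", {
  sp <- duodenum_spec(grid = c(72L, 72L), spacing = c(2, 2), n_frames = 8L,
                      depth = 0.5, seed = 3L)
  ph <- make_duodenum_phantom(sp, render = FALSE)
  expect_true(all(ph$truth$vt == 0))
  for (i in c(1L, 5L, 8L)) {
    expect_equal(ph$truth$area[i], polygon_area(ph$truth$boundary[[i]]),
                 tolerance = 1e-9)
    expect_equal(unname(ph$truth$centroid[i, ]),
                 unname(polygon_centroid(ph$truth$boundary[[i]])),
                 tolerance = 1e-9)
  }
})

test_that("pipeline-measured DM(V_N) matches analytic ground truth within
           10 percent", {
  sp <- duodenum_spec(grid = c(80L, 80L), spacing = c(1.8, 1.8),
                      n_frames = 15L, depth = 0.5, ring_width = 8,
                      ring_speed = 3, ring_period = 10, seed = 3L)
  ph <- make_duodenum_phantom(sp, render = FALSE)
  ser <- build_contour_series(ph$seeds, 100, sp$frame_interval)
  measured <- dm_velocity(wall_velocities(ser))[["vn"]]
  expect_gt(ph$truth$dm_vn, 0)
  expect_lt(abs(measured - ph$truth$dm_vn) / ph$truth$dm_vn, 0.10)
})

test_that("rendered intensity-integral area converges to ground truth with
           finer pixels", {
  area_err <- function(spacing, grid) {
    sp <- fundus_spec(grid = c(grid, grid), spacing = c(spacing, spacing),
                      n_frames = 1L, semi_axes = c(18, 12),
                      oscillation_amp = 0, noise_sd = 0, seed = 6L)
    ph <- make_fundus_phantom(sp)
    est <- sum((ph$stack$frames[, , 1] - 0.1) / 0.8) * spacing^2
    abs(est - ph$truth$area[1]) / ph$truth$area[1]
  }
  coarse <- area_err(3, 24L)
  fine <- area_err(1, 72L)
  expect_lt(fine, coarse)
  expect_lt(fine, 0.01)
})

test_that("study parameter draws have the prescribed condition means", {
  means <- vapply(1:50, function(s) {
    pars <- draw_study_parameters(study_spec(n_subjects = 8L, seed = s))
    tapply(pars$emptying_ms3, pars$condition, mean)[c("noMSG", "MSG")]
  }, c(noMSG = 0, MSG = 0))
  grand <- rowMeans(means)
  # 50 studies of n = 8: Monte-Carlo SE of the grand mean ~ 0.007
  expect_lt(abs(grand["noMSG"] - 0.16), 0.025)
  expect_lt(abs(grand["MSG"] - 0.27), 0.025)
  # paired structure: within-subject differences much tighter than the
  # between-subject spread
  sp <- study_spec(n_subjects = 50L, seed = 99L)
  pars <- draw_study_parameters(sp)
  wide <- merge(pars[pars$condition == "noMSG", c("subject", "resid_ms3_pct")],
                pars[pars$condition == "MSG", c("subject", "resid_ms3_pct")],
                by = "subject")
  expect_lt(sd(wide$resid_ms3_pct.x - wide$resid_ms3_pct.y),
            sd(wide$resid_ms3_pct.x) + sd(wide$resid_ms3_pct.y))
  expect_error(study_spec(subject_sd = -1), "non-negative")
})

test_that("the same master seed regenerates an identical study tree", {
  sp <- study_spec(n_subjects = 2L, grid = c(32L, 32L), spacing = c(3, 3),
                   n_frames = 3L, noise_sd = 0.03, seed = 21L)
  d1 <- file.path(withr::local_tempdir(), "s1")
  d2 <- file.path(withr::local_tempdir(), "s2")
  make_study(sp, d1, render = TRUE)
  make_study(sp, d2, render = TRUE)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})
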