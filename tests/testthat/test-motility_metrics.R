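test_that("DM(A) equals 100 * sample SD / mean and is scale invariant", {
  expect_equal(dm_area(rep(250, 40)), 0)
  areas <- rep(c(90, 110), 20)
  want <- 100 * sqrt(sum((areas - mean(areas))^2) / 39) / mean(areas)
  expect_equal(dm_area(areas), want)
  expect_equal(want, 10.13, tolerance = 1e-3)
  expect_equal(dm_area(areas * 3.7), dm_area(areas))
  expect_error(dm_area(c(0, 0)), "mean area")
})

test_that("DM(G) is the centroid path length", {
  expect_equal(dm_gravity(matrix(5, 10, 2)), 0)
  steps <- cbind(rep(2, 40), seq(0, 39))   # 1 mm per frame in y, 39 steps
  expect_equal(dm_gravity(steps), 39)
  circ <- circle_points(40, 7)
  closed <- rbind(circ, circ[1, ])          # return to start: 40 chords
  expect_equal(dm_gravity(closed), 40 * 2 * 7 * sin(pi / 40))
})

test_that("DG_Y trace is the first-frame-anchored Y shift", {
  expect_equal(dgy_trace(matrix(3, 8, 2)), rep(0, 8))
  drift <- cbind(rep(0, 5), 0.2 * (0:4))
  expect_equal(dgy_trace(drift), c(0, 0.2, 0.4, 0.6, 0.8))
  expect_equal(dgy_trace(sweep(drift, 2, c(11, -6))), dgy_trace(drift))
})

test_that("expanding and rotating circles give the predicted V_N / V_T", {
  dt <- 0.656
  grow <- lapply(0:5, function(i) circle_points(100, 50 + 0.5 * i))
  vf <- wall_velocities(as_series(grow, dt))
  # outward growth is negative under the inward-positive convention
  expect_equal(max(abs(vf$vn + 0.5 / dt)), 0, tolerance = 1e-6)
  expect_equal(max(abs(vf$vt)), 0, tolerance = 1e-6)

  r <- 30; dth <- 0.02
  rot <- lapply(0:5, function(i) circle_points(100, r, phase = i * dth))
  vr <- wall_velocities(as_series(rot, dt))
  expect_equal(mean(vr$vt), r * dth / dt, tolerance = 0.01)
  expect_lt(max(abs(vr$vn)), 0.01 * r * dth / dt + 1e-9)

  still <- as_series(rep(list(circle_points(50, 20)), 3))
  vs <- wall_velocities(still)
  expect_true(all(vs$vn == 0) && all(vs$vt == 0))

  bad <- structure(list(contours = list(circle_points(50, 20),
                                        circle_points(40, 20)),
                        n_points = 50L, label = "d", frame_interval = dt),
                   class = "contour_series")
  expect_error(wall_velocities(bad), "mismatched")
})

test_that("velocity decomposition conserves squared speed to 1e-9 relative", {
  set.seed(7)
  dt <- 0.656
  cons <- lapply(0:6, function(i) {
    th <- 2 * pi * (0:79) / 80
    r <- 40 + 3 * sin(3 * th + 0.4 * i) + 2 * cos(5 * th - 0.2 * i)
    cbind(r * cos(th), r * sin(th))
  })
  vf <- wall_velocities(as_series(cons, dt))
  for (n in 2:7) {
    speed2 <- rowSums(((cons[[n]] - cons[[n - 1]]) / dt)^2)
    got <- vf$vn[n - 1, ]^2 + vf$vt[n - 1, ]^2
    expect_lt(max(abs(got - speed2) / pmax(speed2, 1e-12)), 1e-9)
  }
})

test_that("DM velocity summaries are mean absolute values", {
  f <- structure(list(vn = matrix(2, 4, 10), vt = matrix(0, 4, 10), dt = 1),
                 class = "velocity_field")
  expect_equal(dm_velocity(f), c(vn = 2, vt = 0))
  f2 <- structure(list(vn = matrix(c(1, -1), 4, 10), vt = matrix(0.5, 4, 10),
                       dt = 1), class = "velocity_field")
  expect_equal(dm_velocity(f2), c(vn = 1, vt = 0.5))
  grow <- lapply(0:5, function(i) circle_points(100, 50 + 0.5 * i))
  vf <- wall_velocities(as_series(grow, 0.656))
  expect_equal(unname(dm_velocity(vf)["vn"]), 0.5 / 0.656, tolerance = 1e-6)
  expect_equal(unname(dm_velocity(vf)["vt"]), 0, tolerance = 1e-6)
})

test_that("DM indices respond correctly to constant vs per-frame translation", {
  set.seed(11)
  dt <- 0.656
  cons <- lapply(0:5, function(i) {
    th <- 2 * pi * (0:59) / 60
    r <- 30 + 2 * sin(2 * th + 0.5 * i)
    cbind(r * cos(th), r * sin(th))
  })
  ser <- as_series(cons, dt)
  areas <- vapply(cons, polygon_area, 0)
  cent <- t(vapply(cons, polygon_centroid, c(x = 0, y = 0)))
  v <- dm_velocity(wall_velocities(ser))

  # one constant translation applied to every frame: everything invariant
  shift <- c(13, -8)
  cons_c <- lapply(cons, function(m) sweep(m, 2, -shift))
  ser_c <- as_series(cons_c, dt)
  cent_c <- t(vapply(cons_c, polygon_centroid, c(x = 0, y = 0)))
  expect_equal(dm_area(vapply(cons_c, polygon_area, 0)), dm_area(areas))
  expect_equal(dm_gravity(cent_c), dm_gravity(cent))
  expect_equal(dgy_trace(cent_c), dgy_trace(cent))
  expect_equal(dm_velocity(wall_velocities(ser_c)), v)

  # per-frame translation: DM(G) and DG_Y must change, area index must not
  cons_p <- lapply(seq_along(cons), function(i)
    sweep(cons[[i]], 2, -c(0, 2 * i)))
  cent_p <- t(vapply(cons_p, polygon_centroid, c(x = 0, y = 0)))
  expect_equal(dm_area(vapply(cons_p, polygon_area, 0)), dm_area(areas))
  expect_gt(dm_gravity(cent_p), dm_gravity(cent))
  expect_false(isTRUE(all.equal(dgy_trace(cent_p), dgy_trace(cent))))
})

test_that("velocity indices are zero iff the series is constant", {
  cons <- rep(list(circle_points(60, 25)), 4)
  v0 <- dm_velocity(wall_velocities(as_series(cons)))
  expect_equal(unname(v0), c(0, 0))
  cons2 <- cons; cons2[[3]] <- circle_points(60, 25.2)
  v1 <- dm_velocity(wall_velocities(as_series(cons2)))
  expect_true(all(v1 >= 0) && v1["vn"] > 0)
})

test_that("gastric residual sums frame-mean plane areas, normalized to MS1", {
  base <- expand.grid(scan = c("MS1", "MS2", "MS3"), plane = 1:4,
                      frame = 1:5, stringsAsFactors = FALSE)
  base$area <- 100 + 5 * base$plane
  res <- gastric_residual(base)
  expect_equal(res$pct, c(100, 100, 100))

  half <- base
  half$area[half$scan == "MS3"] <- half$area[half$scan == "MS3"] / 2
  res2 <- gastric_residual(half)
  expect_equal(res2$pct[res2$scan == "MS1"], 100)
  expect_equal(res2$pct[res2$scan == "MS3"], 50)

  expect_error(gastric_residual(base[base$scan != "MS1", ]), "MS1")
  expect_error(gastric_residual(base[!(base$scan == "MS2" & base$plane == 3), ]),
               "same plane set")
})

test_that("paired comparison matches the closed-form t-test and is
           antisymmetric", {
  a <- c(10, 12, 9, 14); b <- c(9, 10, 6, 10)   # differences 1, 2, 3, 4
  got <- compare_paired(a, b)
  want <- oracle_paired_t(a, b)
  expect_equal(got$t, want$t)
  expect_equal(got$p, want$p)
  expect_equal(got$df, 3)
  swapped <- compare_paired(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  same <- compare_paired(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
})
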