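test_that("circle seeds resample to uniform equidistant points on the circle", {
  seed <- circle_points(20, 50, centre = c(100, 100))
  rc <- resample_contour(seed, 100)
  expect_equal(nrow(rc), 100L)
  radii <- sqrt(rowSums((rc - 100)^2))
  expect_lt(max(abs(radii - 50)) / 50, 0.005)
  sp <- sqrt(rowSums(diff(rbind(rc, rc[1, ]))^2))
  expect_lt((max(sp) - min(sp)) / mean(sp), 0.01)
  expect_gt(cinemotility:::signed_area(rc), 0)
  # start point is the spline point nearest the first seed
  expect_lt(sqrt(sum((rc[1, ] - seed[1, ])^2)), 1e-3)
})

test_that("clockwise seeds are normalized to positive orientation", {
  cw <- circle_points(20, 30)[20:1, ]
  rc <- resample_contour(cw, 60)
  expect_gt(cinemotility:::signed_area(rc), 0)
})

test_that("square seeds reproduce the closed-form perimeter up to cubic
           corner overshoot", {
  sq <- rbind(c(0, 0), c(20, 0), c(40, 0), c(40, 20), c(40, 40),
              c(20, 40), c(0, 40), c(0, 20))
  rc <- resample_contour(sq, 100)
  per <- sum(sqrt(rowSums(diff(rbind(rc, rc[1, ]))^2)))
  # a periodic interpolating cubic bulges at right-angle corners; the
  # resampled perimeter carries that overshoot (measured ~1.7%)
  expect_lt(abs(per - 160) / 160, 0.02)
})

test_that("resampling is idempotent and preserves convexity", {
  seed <- circle_points(20, 50, centre = c(80, 80))
  rc <- resample_contour(seed, 100)
  rc2 <- resample_contour(rc, 100)
  hd <- max(vapply(seq_len(100), function(i)
    min(sqrt(rowSums(sweep(rc2, 2, rc[i, ])^2))), 0))
  expect_lt(hd / 50, 0.001)

  # smooth convex seeds resample to exactly convex contours
  ell <- cbind(40 * cos(2 * pi * (0:19) / 20), 25 * sin(2 * pi * (0:19) / 20))
  expect_lt(hull_deviation(resample_contour(ell, 100)) / 80, 0.001)
  expect_lt(hull_deviation(resample_contour(circle_points(8, 30), 100)) / 60,
            0.001)
  # right-angle corners concede cubic overshoot (measured ~3.2% of side)
  sq <- rbind(c(0, 0), c(20, 0), c(40, 0), c(40, 20), c(40, 40),
              c(20, 40), c(0, 40), c(0, 20))
  expect_lt(hull_deviation(resample_contour(sq, 100)) / 40, 0.04)
})

test_that("self-intersecting or undersized seeds raise errors", {
  expect_error(resample_contour(rbind(c(0, 0), c(1, 1)), 50), "3 seed")
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(resample_contour(bow, 50), "self-intersecting")
})

test_that("shoelace area matches closed forms and is rigid-motion invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  gon <- circle_points(100, 10)
  expect_equal(polygon_area(gon), 0.5 * 100 * 10^2 * sin(2 * pi / 100),
               tolerance = 1e-12)
  expect_equal(polygon_area(sweep(gon, 2, c(-17, 9))), polygon_area(gon))
  th <- 0.71; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(polygon_area(gon %*% rot), polygon_area(gon))
  # cyclic renumbering
  expect_equal(polygon_area(gon[c(38:100, 1:37), ]), polygon_area(gon))
})

test_that("area centroid matches closed forms and a decomposition oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_centroid(sq), c(x = 0.5, y = 0.5))
  gon <- circle_points(7, 12, centre = c(3, -4))
  expect_equal(polygon_centroid(gon), c(x = 3, y = -4), tolerance = 1e-10)
  # L-shape = rect (0,0)-(2,1) [A=2, c=(1,0.5)] + rect (0,1)-(1,3) [A=2, c=(0.5,2)]
  L <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 3), c(0, 3))
  expect_equal(polygon_centroid(L), c(x = 0.75, y = 1.25))
  # invariant to cyclic renumbering and translation
  expect_equal(polygon_centroid(L[c(4:6, 1:3), ]), polygon_centroid(L))
  expect_equal(polygon_centroid(sweep(L, 2, c(-5, 2))),
               polygon_centroid(L) - c(x = -5, y = 2))
  expect_error(polygon_centroid(rbind(c(0, 0), c(1, 1), c(2, 2))), "area")
})

test_that("contour frames give unit inward normals and ccw tangents", {
  circ <- circle_points(100, 25, centre = c(5, 5))
  fr <- contour_frames(circ)
  expect_lt(max(abs(rowSums(fr$tangent^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$normal^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$tangent * fr$normal))), 1e-12)
  inward <- -(circ - 5) / sqrt(rowSums((circ - 5)^2))
  expect_lt(max(abs(fr$normal - inward)), 1e-2)
  # tangents point counterclockwise: positive cross product with radius
  radial <- (circ - 5)
  crossz <- radial[, 1] * fr$tangent[, 2] - radial[, 2] * fr$tangent[, 1]
  expect_true(all(crossz > 0))
})

test_that("average_image is the pixelwise mean", {
  fr <- matrix(runif(100), 10, 10)
  st <- frame_stack(replicate(4, fr, simplify = FALSE), 1, 1, 1)
  expect_equal(average_image(st), fr)
  st2 <- frame_stack(list(matrix(0, 5, 5), matrix(2, 5, 5)), 1, 1, 1)
  expect_equal(average_image(st2), matrix(1, 5, 5))
  set.seed(3)
  sig <- 0.2; nf <- 60L
  st3 <- frame_stack(array(rnorm(25 * nf, sd = sig), dim = c(5, 5, nf)), 1, 1, 1)
  expect_equal(sd(average_image(st3)), sig / sqrt(nf), tolerance = 0.2)
})

test_that("start-point correspondence undoes cyclic renumbering", {
  base <- resample_contour(circle_points(20, 40), 80)
  shifted <- base[c(25:80, 1:24), ]
  aligned <- cinemotility:::align_start_point(shifted, base)
  expect_equal(aligned, base)
})
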