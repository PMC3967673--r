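# Independent oracles and small fixture builders, written without reference
# to the package internals they check.

# Exhaustive SSD registration oracle: plain nested loops over candidate
# shifts, energies accumulated pixel by pixel, ties broken by magnitude then
# (dy, dx).
oracle_ssd_shift <- function(a, b, roi, radius) {
  best <- NULL
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      e <- 0
      for (i in roi[1]:roi[2]) {
        for (j in roi[3]:roi[4]) {
          e <- e + (a[i, j] - b[i + dy, j + dx])^2
        }
      }
      e <- e / ((roi[2] - roi[1] + 1) * (roi[4] - roi[3] + 1))
      cand <- list(dx = dx, dy = dy, e = e)
      if (is.null(best) || e < best$e ||
          (e == best$e && (dx^2 + dy^2 < best$dx^2 + best$dy^2 ||
                           (dx^2 + dy^2 == best$dx^2 + best$dy^2 &&
                            (dy < best$dy || (dy == best$dy && dx < best$dx))))))
        best <- cand
    }
  }
  best
}

# Closed-form paired t-test: t = mean(d) / (sd(d)/sqrt(n)), p two-sided.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

# Points on a circle (counterclockwise in the shoelace-positive sense).
circle_points <- function(n, r, centre = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# Assemble a contour_series from a list of point matrices without going
# through seed resampling.
as_series <- function(contours, dt = 0.656, label = "duodenum") {
  structure(list(contours = contours, n_points = nrow(contours[[1]]),
                 label = label, frame_interval = dt),
            class = "contour_series")
}

# Smooth random frame: low-frequency sinusoid mixture, reproducible.
smooth_frame <- function(nr, nc, seed) {
  set.seed(seed)
  fy <- runif(3, 0.5, 2); fx <- runif(3, 0.5, 2); ph <- runif(3, 0, 2 * pi)
  out <- matrix(0, nr, nc)
  for (k in 1:3) {
    out <- out + outer(sin(2 * pi * fy[k] * seq_len(nr) / nr + ph[k]),
                       cos(2 * pi * fx[k] * seq_len(nc) / nc))
  }
  (out - min(out)) / (max(out) - min(out))
}

# Max distance from polygon vertices to the polygon's own convex hull edges
# (a measure of concave oscillation).
hull_deviation <- function(xy) {
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  m <- nrow(hull)
  segdist <- function(p, a, b) {
    ab <- b - a
    t <- pmin(pmax(sum((p - a) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  max(apply(xy, 1, function(p) {
    min(vapply(seq_len(m), function(i)
      segdist(p, hull[i, ], hull[(i %% m) + 1L, ]), 0))
  }))
}
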