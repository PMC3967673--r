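#' Resample a seed polygon into an equidistant closed wall contour
#'
#' Manual wall outlines are sparse (20 points for the gastric fundus, 30 for
#' the duodenum). For geometry and velocity analysis the wall is represented
#' by `n_points` (default 100) points at equal arc-length spacing: a periodic
#' cubic spline is fitted through the seeds, its arc length is evaluated on a
#' 20x-dense polyline, and the spline is sampled at `n_points` equal
#' arc-length intervals starting at the first seed point. Orientation is
#' normalized so the signed (shoelace) area is positive ("counterclockwise"
#' in the algebraic sense), making the inward-normal and tangential sign
#' conventions of the velocity decomposition well defined.
#'
#' @param seed m x 2 matrix of seed points (mm), or a seed record from
#'   [read_seed_contours()]. Must be a simple polygon with m >= 3.
#' @param n_points number of output points (default 100).
#' @return n_points x 2 matrix of contour points (mm), positively oriented,
#'   with consecutive arc spacings equal to within 1 percent.
#' @export
resample_contour <- function(seed, n_points = 100L) {
  xy <- if (is.list(seed)) seed$xy else seed
  stopifnot(is.matrix(xy), ncol(xy) == 2L)
  m <- nrow(xy)
  if (m < 3L) stop("need at least 3 seed points")
  if (!is_simple_polygon(xy)) stop("seed polygon is self-intersecting")

  closed <- rbind(xy, xy[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  if (any(seg == 0)) stop("seed polygon has coincident consecutive points")
  tt <- c(0, cumsum(seg))
  fx <- stats::splinefun(tt, closed[, 1], method = "periodic")
  fy <- stats::splinefun(tt, closed[, 2], method = "periodic")

  # arc-length table on a dense polyline of the spline
  td <- seq(0, tt[length(tt)], length.out = 20L * n_points + 1L)
  dx <- fx(td); dy <- fy(td)
  darc <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
  perim <- darc[length(darc)]

  target <- perim * (seq_len(n_points) - 1L) / n_points
  tq <- stats::approx(darc, td, xout = target, ties = "ordered")$y
  out <- cbind(fx(tq), fy(tq))

  if (signed_area(out) < 0)  # reverse, keeping the start point first
    out <- out[c(1L, n_points:2L), , drop = FALSE]
  if (!is_simple_polygon(out))
    stop("resampled contour self-intersects; supply denser seed points")
  out
}

signed_area <- function(xy) {
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]) / 2
}

#' Polygon area by the shoelace formula
#'
#' @param xy n x 2 matrix of polygon vertices (closed implicitly).
#' @return absolute enclosed area (mm^2 for mm coordinates).
#' @export
polygon_area <- function(xy) abs(signed_area(xy))

#' Area centroid (center of gravity) of a polygon
#'
#' The first-moment centroid of the enclosed region (not the vertex mean),
#' matching the "center of gravity of the area" used for the DG_Y trace and
#' the centroid path-length index.
#'
#' @param xy n x 2 matrix of polygon vertices.
#' @return length-2 vector `c(x, y)` in the coordinate units of `xy`.
#' @export
polygon_centroid <- function(xy) {
  a <- signed_area(xy)
  if (abs(a) < 1e-12) stop("polygon area is (near) zero; centroid undefined")
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]
  c(x = sum((xy[, 1] + xy[nxt, 1]) * cr) / (6 * a),
    y = sum((xy[, 2] + xy[nxt, 2]) * cr) / (6 * a))
}

#' Per-point unit tangents and inward normals of a closed contour
#'
#' Tangents are central differences of each point's neighbours along the
#' closed sequence, normalized to unit length; the normal is the tangent
#' rotated a quarter turn towards the enclosed region (the left of travel for
#' a positively oriented polygon), so it points inward. These define the sign
#' conventions of the wall-velocity decomposition: inward-normal motion and
#' counterclockwise tangential motion are positive.
#'
#' @param xy n x 2 positively oriented contour matrix.
#' @return list with `tangent` and `normal`, each n x 2 with unit rows.
#' @export
contour_frames <- function(xy) {
  n <- nrow(xy)
  stopifnot(n >= 3L)
  nxt <- c(seq_len(n)[-1], 1L)
  prv <- c(n, seq_len(n)[-n])
  tg <- xy[nxt, , drop = FALSE] - xy[prv, , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  if (any(len == 0)) stop("degenerate contour: coincident neighbour points")
  tg <- tg / len
  nr <- cbind(-tg[, 2], tg[, 1])
  list(tangent = tg, normal = nr)
}

#' Pixelwise mean frame of a cine stack
#'
#' Averaging the cine series blurs out spontaneous contractions and leaves
#' the organ's resting shape, used to assess stomach shape and position.
#'
#' @param stack a [frame_stack()].
#' @return matrix of the same frame dimensions.
#' @export
average_image <- function(stack) {
  rowSums(stack$frames, dims = 2L) / n_frames(stack)
}

# Cyclic-shift start-point correspondence: rotate point numbering of `xy` so
# the summed squared distance to `ref` is minimal. Returns the shifted matrix.
align_start_point <- function(xy, ref) {
  n <- nrow(xy)
  stopifnot(nrow(ref) == n)
  cost <- vapply(seq_len(n) - 1L, function(s) {
    idx <- ((seq_len(n) - 1L + s) %% n) + 1L
    sum((xy[idx, , drop = FALSE] - ref)^2)
  }, 0)
  s <- which.min(cost) - 1L
  idx <- ((seq_len(n) - 1L + s) %% n) + 1L
  xy[idx, , drop = FALSE]
}

#' Build a frame-to-frame corresponding contour series from seed outlines
#'
#' Each frame's seeds are resampled with [resample_contour()]; then, treating
#' point k as the same material wall point across frames, the start index of
#' every contour after the first is chosen to minimize the summed squared
#' distance to the previous frame's points over cyclic shifts.
#'
#' @param seeds list of per-frame seed records (see [read_seed_contours()]),
#'   in frame order.
#' @param n_points points per resampled contour.
#' @param frame_interval seconds between frames.
#' @return object of class `contour_series`: list with `contours` (list of
#'   n_points x 2 matrices), `n_points`, `label`, `frame_interval`.
#' @export
build_contour_series <- function(seeds, n_points = 100L,
                                 frame_interval = 0.656) {
  stopifnot(length(seeds) >= 1L)
  contours <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    ci <- resample_contour(seeds[[i]], n_points)
    if (i > 1L) ci <- align_start_point(ci, contours[[i - 1L]])
    contours[[i]] <- ci
  }
  structure(list(contours = contours, n_points = as.integer(n_points),
                 label = if (is.list(seeds[[1]])) seeds[[1]]$label else "wall",
                 frame_interval = frame_interval),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("contour_series: %d frames x %d points (%s), dt = %.4g s\n",
              length(x$contours), x$n_points, x$label, x$frame_interval))
  invisible(x)
}
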