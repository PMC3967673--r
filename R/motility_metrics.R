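#' Percent area variability index DM(A)
#'
#' Variability of the enclosed wall area over the cine series, reported as
#' the sample standard deviation of the per-frame areas as a percentage of
#' their mean. Scale invariant: doubling every area leaves DM(A) unchanged.
#'
#' @param areas numeric vector of per-frame areas (mm^2), length >= 2.
#' @return DM(A) in percent.
#' @export
dm_area <- function(areas) {
  stopifnot(length(areas) >= 2L)
  m <- mean(areas)
  if (m == 0) stop("mean area is zero; DM(A) undefined")
  100 * stats::sd(areas) / m
}

#' Centroid path-length index DM(G)
#'
#' Total shift of the area centroid over the series: the sum of Euclidean
#' displacements between consecutive frames (2D path length, mm).
#'
#' @param centroids frames x 2 matrix of centroid coordinates (mm).
#' @return path length in mm.
#' @export
dm_gravity <- function(centroids) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2L,
            nrow(centroids) >= 2L)
  sum(sqrt(rowSums(diff(centroids)^2)))
}

#' Centroid Y-shift trace DG_Y(t)
#'
#' Per-frame vertical displacement of the area centroid relative to the
#' first frame; the time course plotted to visualize peristaltic activity.
#'
#' @param centroids frames x 2 matrix of centroid coordinates (mm).
#' @return numeric vector, one value per frame, first element 0.
#' @export
dgy_trace <- function(centroids) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2L,
            nrow(centroids) >= 1L)
  centroids[, 2] - centroids[1, 2]
}

#' Signed normal/tangential wall velocities of a contour series
#'
#' For every consecutive frame pair (n-1, n) and wall point k, the
#' displacement of point k divided by the frame interval gives the velocity
#' vector, which is projected onto the unit inward normal and unit
#' counterclockwise tangent of the later (frame n) contour at point k.
#' Inward motion and counterclockwise motion are positive. Because normal
#' and tangent are orthonormal the decomposition is exact:
#' `V_N^2 + V_T^2` equals the squared point speed.
#'
#' @param series a `contour_series` from [build_contour_series()] with
#'   frame-to-frame point correspondence already applied.
#' @return object of class `velocity_field`: list with `vn`, `vt`
#'   ((frames-1) x n_points matrices, mm/s) and `dt` (s).
#' @export
wall_velocities <- function(series) {
  stopifnot(inherits(series, "contour_series"))
  contours <- series$contours
  nf <- length(contours)
  if (nf < 2L) stop("need at least 2 frames for velocities")
  np <- series$n_points
  if (any(vapply(contours, nrow, 0L) != np))
    stop("mismatched point counts between frames")
  dt <- series$frame_interval
  vn <- vt <- matrix(NA_real_, nf - 1L, np)
  for (n in 2L:nf) {
    disp <- (contours[[n]] - contours[[n - 1L]]) / dt
    fr <- contour_frames(contours[[n]])
    vn[n - 1L, ] <- rowSums(disp * fr$normal)
    vt[n - 1L, ] <- rowSums(disp * fr$tangent)
  }
  structure(list(vn = vn, vt = vt, dt = dt), class = "velocity_field")
}

#' Mean absolute wall-velocity indices DM(V_N), DM(V_T)
#'
#' Summarizes a velocity field as the mean absolute velocity over all frame
#' pairs and wall points, separately for the normal and tangential
#' components. Absolute values prevent simultaneous contraction and
#' relaxation in the same frame from cancelling.
#'
#' @param field a `velocity_field` from [wall_velocities()].
#' @return named vector `c(vn = DM(V_N), vt = DM(V_T))` in mm/s.
#' @export
dm_velocity <- function(field) {
  stopifnot(inherits(field, "velocity_field"), length(field$vn) > 0L)
  c(vn = mean(abs(field$vn)), vt = mean(abs(field$vt)))
}

#' Gastric residual volume index across motility scans
#'
#' For each motility scan (MS1, MS2, MS3) the per-plane fundus area is the
#' mean over the cine frames (averaging out spontaneous contractions), and
#' the scan's index is the sum of those means over the designated coronal
#' planes. Percentages are relative to MS1, which is exactly 100.
#'
#' @param areas data.frame with columns `scan`, `plane`, `area` — one row
#'   per frame (frame-level areas in mm^2). Every scan must cover the same
#'   plane set and MS1 must be present.
#' @return data.frame with one row per scan: `scan`, `total_area` (mm^2,
#'   summed frame-mean areas) and `pct` (percent of MS1), ordered by scan id.
#' @export
gastric_residual <- function(areas) {
  stopifnot(is.data.frame(areas),
            all(c("scan", "plane", "area") %in% names(areas)))
  scans <- sort(unique(areas$scan))
  if (!"MS1" %in% scans) stop("MS1 is required for normalization")
  plane_sets <- lapply(scans, function(s) sort(unique(areas$plane[areas$scan == s])))
  if (length(unique(plane_sets)) != 1L)
    stop("all scans must cover the same plane set")
  per_scan <- vapply(scans, function(s) {
    sub <- areas[areas$scan == s, ]
    sum(tapply(sub$area, sub$plane, mean))
  }, 0)
  data.frame(scan = scans,
             total_area = as.numeric(per_scan),
             pct = 100 * as.numeric(per_scan) / per_scan[scans == "MS1"],
             row.names = NULL)
}

#' Paired t-test between conditions, matched by subject
#'
#' Classical two-sided paired t-test on within-subject differences.
#' When every difference is exactly zero the test statistic is undefined;
#' the result then reports `p = 1` with a degeneracy flag rather than an
#' error, so study-level loops keep running on null data.
#'
#' @param a,b numeric vectors of per-subject values, same subject order,
#'   length >= 2.
#' @return list with `t`, `df`, `p`, `mean_diff` and `degenerate`.
#' @export
compare_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (all(d == 0))
    return(list(t = NA_real_, df = length(d) - 1L, p = 1,
                mean_diff = 0, degenerate = TRUE))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}
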