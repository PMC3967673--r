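#' Specification for a gastric-fundus digital phantom
#'
#' The fundus phantom is a bright ellipse on a dark background whose area
#' follows `baseline * (1 - emptying) * (1 + amp * sin(2*pi*t/period))`:
#' a slow sinusoidal oscillation (gastric pacemaker rhythm, ~3 cycles/min by
#' default) on top of a between-scan emptying step. The whole frame is
#' translated by an integer-pixel respiratory signal before noise is added.
#'
#' @param grid c(rows, cols) in pixels.
#' @param spacing c(x, y) pixel spacing in mm/px.
#' @param n_frames frames per cine series.
#' @param frame_interval seconds between frames (0.656 in the protocol).
#' @param center ellipse centre in mm; default is the grid centre.
#' @param semi_axes c(a, b) baseline ellipse semi-axes in mm.
#' @param oscillation_amp fractional area-oscillation amplitude (0.05 = 5%).
#' @param oscillation_period pacemaker period in seconds.
#' @param emptying fraction of baseline area lost in this scan (0-1).
#' @param resp_amp_px respiratory translation amplitude in pixels (y).
#' @param resp_period respiratory period in seconds.
#' @param noise_sd additive Gaussian noise SD as a fraction of the dynamic
#'   range.
#' @param seed RNG seed fixing every random draw.
#' @param plane_id,scan_id stack metadata labels.
#' @return list of class `fundus_spec`.
#' @export
fundus_spec <- function(grid = c(192L, 288L), spacing = c(1.7, 1.7),
                        n_frames = 40L, frame_interval = 0.656,
                        center = NULL, semi_axes = c(40, 28),
                        oscillation_amp = 0.05, oscillation_period = 20,
                        emptying = 0, resp_amp_px = 0, resp_period = 4,
                        noise_sd = 0, seed = 1L,
                        plane_id = 1L, scan_id = "MS1") {
  if (is.null(center))
    center <- c((grid[2] - 1) * spacing[1] / 2, (grid[1] - 1) * spacing[2] / 2)
  stopifnot(all(grid >= 8L), all(spacing > 0), n_frames >= 1L,
            frame_interval > 0, all(semi_axes > 0),
            oscillation_amp >= 0, emptying >= 0, emptying < 1, noise_sd >= 0)
  structure(as.list(environment()), class = "fundus_spec")
}

#' Specification for a duodenum digital phantom
#'
#' A C-shaped tube of constant resting radius along a spline centerline.
#' Peristalsis is modelled as Gaussian-profile contraction rings: each ring
#' locally reduces the tube radius by `depth * r0`, travels along the
#' centerline at `ring_speed`, recurs every `ring_period` seconds, and is
#' amplitude-tapered near the tube ends so the end caps stay static.
#'
#' @inheritParams fundus_spec
#' @param centerline control points (mm, k x 2) of the tube centerline;
#'   default is a 200-degree C-arc of 32 mm radius about the grid centre.
#' @param tube_radius resting tube radius r0 in mm.
#' @param depth fractional radius reduction at the ring centre (0-1).
#' @param ring_width Gaussian sigma of the ring profile in mm.
#' @param ring_speed propagation speed along the centerline, mm/s.
#' @param ring_period seconds between successive ring launches.
#' @return list of class `duodenum_spec`.
#' @export
duodenum_spec <- function(grid = c(192L, 288L), spacing = c(1.7, 1.7),
                          n_frames = 40L, frame_interval = 0.656,
                          centerline = NULL, tube_radius = 9,
                          depth = 0.5, ring_width = 8, ring_speed = 3,
                          ring_period = 15, resp_amp_px = 0, resp_period = 4,
                          noise_sd = 0, seed = 1L,
                          plane_id = 1L, scan_id = "MS1") {
  if (is.null(centerline)) {
    cen <- c((grid[2] - 1) * spacing[1] / 2, (grid[1] - 1) * spacing[2] / 2)
    ang <- seq(100, -100, length.out = 7L) * pi / 180
    centerline <- cbind(cen[1] + 32 * cos(ang), cen[2] + 32 * sin(ang))
  }
  stopifnot(all(grid >= 8L), all(spacing > 0), n_frames >= 1L,
            frame_interval > 0, tube_radius > 0, depth >= 0, depth < 1,
            ring_width > 0, ring_speed > 0, ring_period > 0, noise_sd >= 0,
            is.matrix(centerline), ncol(centerline) == 2L,
            nrow(centerline) >= 3L)
  structure(as.list(environment()), class = "duodenum_spec")
}

# ---- rendering helpers ------------------------------------------------------

# Subpixel-centre coordinate vectors (mm) for a supersampled grid.
super_coords <- function(n, spacing, ss) {
  px <- rep(seq_len(n) - 1L, each = ss)
  sub <- rep((seq_len(ss) - 0.5) / ss - 0.5, times = n)
  (px + sub) * spacing
}

# Average an (nr*ss) x (nc*ss) matrix down to nr x nc by ss x ss block means.
downsample_blocks <- function(M, ss) {
  nr <- nrow(M) %/% ss; nc <- ncol(M) %/% ss
  B <- colSums(array(M, c(ss, nr, ss * nc)))      # (nr, ss*nc) summed over u
  B <- array(B, c(nr, ss, nc))
  B <- colSums(aperm(B, c(2, 1, 3)))              # sum over v -> (nr, nc)
  matrix(B, nr, nc) / (ss * ss)
}

# Map occupancy in [0,1] to intensity, shift by integer respiratory pixels,
# then add clamped Gaussian noise. Background 0.1, foreground 0.9.
finish_frame <- function(occ, resp_dy, noise_sd) {
  img <- 0.1 + 0.8 * occ
  if (resp_dy != 0) img <- translate_frame(img, 0L, resp_dy, fill = 0.1)
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd * 0.8)
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

respiration_px <- function(spec) {
  tt <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval
  as.integer(round(spec$resp_amp_px * sin(2 * pi * tt / spec$resp_period)))
}

# Equal-arc-length resample of a dense polygon down to m vertices (linear
# interpolation along the polygon; independent of the spline machinery).
polygon_equal_arc <- function(xy, m) {
  closed <- rbind(xy, xy[1L, ])
  arc <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  target <- arc[length(arc)] * (seq_len(m) - 1L) / m
  cbind(stats::approx(arc, closed[, 1], xout = target, ties = "ordered")$y,
        stats::approx(arc, closed[, 2], xout = target, ties = "ordered")$y)
}

seed_records <- function(truth_boundary, resp_px, spacing, m, label) {
  lapply(seq_along(truth_boundary), function(i) {
    xy <- polygon_equal_arc(truth_boundary[[i]], m)
    xy[, 2] <- xy[, 2] + resp_px[i] * spacing[2]
    list(frame = i - 1L, label = label, xy = xy)
  })
}

# ---- fundus phantom ---------------------------------------------------------

#' Render a gastric-fundus phantom cine stack with ground truth
#'
#' Frames are rendered by 4x supersampled binary occupancy averaged down to
#' gray levels (soft, partial-volume-like edges). Ground truth carries the
#' exact boundary polygon, area and centroid per frame in anatomy coordinates
#' (respiration excluded) plus the injected respiratory shift; seeds are 20
#' equally spaced ground-truth boundary points in raw image coordinates
#' (respiration included), i.e. what an observer would mark on raw frames.
#'
#' @param spec a [fundus_spec()].
#' @param render if FALSE, skip image rendering (stack frames all background)
#'   while keeping seeds and ground truth; useful for kinematics-only tests.
#' @return list with `stack` ([frame_stack()]), `seeds` (list of per-frame
#'   seed records) and `truth` (list: `boundary`, `area`, `centroid`,
#'   `resp_px`, `area_multiplier`).
#' @export
make_fundus_phantom <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "fundus_spec"))
  set.seed(spec$seed)
  ss <- 4L
  tt <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval
  mult <- (1 - spec$emptying) *
    (1 + spec$oscillation_amp * sin(2 * pi * tt / spec$oscillation_period))
  sc <- sqrt(mult)
  amax <- spec$semi_axes[1] * max(sc); bmax <- spec$semi_axes[2] * max(sc)
  fov <- c((spec$grid[2] - 1) * spec$spacing[1],
           (spec$grid[1] - 1) * spec$spacing[2])
  if (spec$center[1] - amax < 0 || spec$center[1] + amax > fov[1] ||
      spec$center[2] - bmax < 0 || spec$center[2] + bmax > fov[2])
    stop("fundus ellipse does not fit inside the image grid")

  theta <- 2 * pi * (seq_len(200L) - 1L) / 200L
  boundary <- lapply(seq_len(spec$n_frames), function(i)
    cbind(spec$center[1] + spec$semi_axes[1] * sc[i] * cos(theta),
          spec$center[2] + spec$semi_axes[2] * sc[i] * sin(theta)))
  resp <- respiration_px(spec)

  frames <- array(0.1, dim = c(spec$grid[1], spec$grid[2], spec$n_frames))
  if (render) {
    xs <- super_coords(spec$grid[2], spec$spacing[1], ss)
    ys <- super_coords(spec$grid[1], spec$spacing[2], ss)
    for (i in seq_len(spec$n_frames)) {
      a <- spec$semi_axes[1] * sc[i]; b <- spec$semi_axes[2] * sc[i]
      occ <- outer(((ys - spec$center[2]) / b)^2,
                   ((xs - spec$center[1]) / a)^2, "+") <= 1
      frames[, , i] <- finish_frame(downsample_blocks(occ + 0, ss),
                                    resp[i], spec$noise_sd)
    }
  }
  stack <- frame_stack(frames, spec$spacing[1], spec$spacing[2],
                       spec$frame_interval, spec$plane_id, spec$scan_id)
  truth <- list(
    boundary = boundary,
    area = vapply(boundary, polygon_area, 0),
    centroid = t(vapply(boundary, polygon_centroid, c(x = 0, y = 0))),
    resp_px = resp,
    area_multiplier = mult)
  seeds <- seed_records(boundary, resp, spec$spacing, 20L, "fundus")
  list(stack = stack, seeds = seeds, truth = truth)
}

# ---- duodenum phantom -------------------------------------------------------

# Arc-parameterized centerline: dense points, unit tangents/normals, length.
centerline_geometry <- function(ctrl, n_dense = 600L) {
  tt <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  fx <- stats::splinefun(tt, ctrl[, 1], method = "natural")
  fy <- stats::splinefun(tt, ctrl[, 2], method = "natural")
  td <- seq(0, tt[length(tt)], length.out = 4L * n_dense)
  px <- fx(td); py <- fy(td)
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  L <- arc[length(arc)]
  s <- seq(0, L, length.out = n_dense)
  tq <- stats::approx(arc, td, xout = s, ties = "ordered")$y
  x <- fx(tq); y <- fy(tq)
  tx <- fx(tq, deriv = 1L); ty <- fy(tq, deriv = 1L)
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  list(s = s, xy = cbind(x, y), tangent = cbind(tx, ty),
       normal = cbind(-ty, tx), length = L)
}

# Tube radius at arc positions s and time t: resting radius minus tapered,
# recurring Gaussian contraction rings.
tube_radius_at <- function(s, t, spec, L) {
  w <- spec$ring_width
  s_min <- 3 * w; s_max <- L - 3 * w
  red <- numeric(length(s))
  if (spec$depth > 0 && s_max > s_min) {
    ramp <- function(c0) {
      min(1, (c0 - s_min) / (2 * w), (s_max - c0) / (2 * w))
    }
    i_max <- floor(t / spec$ring_period)
    for (i in 0:i_max) {
      c0 <- s_min + spec$ring_speed * (t - i * spec$ring_period)
      if (c0 < s_min || c0 > s_max) next
      red <- red + max(0, ramp(c0)) * exp(-(s - c0)^2 / (2 * w^2))
    }
    red <- pmin(red, 1) * spec$depth
  }
  spec$tube_radius * (1 - red)
}

# Ground-truth boundary polygon at time t plus the signed inward-normal
# velocity weight layout: side points (fixed arc positions) and static caps.
duodenum_boundary <- function(geom, spec, t, n_half = 100L, n_cap = 12L) {
  s <- seq(0, geom$length, length.out = n_half)
  r <- tube_radius_at(s, t, spec, geom$length)
  Cxy <- cbind(stats::approx(geom$s, geom$xy[, 1], s)$y,
               stats::approx(geom$s, geom$xy[, 2], s)$y)
  Nx <- stats::approx(geom$s, geom$normal[, 1], s)$y
  Ny <- stats::approx(geom$s, geom$normal[, 2], s)$y
  nl <- sqrt(Nx^2 + Ny^2); Nx <- Nx / nl; Ny <- Ny / nl
  side_plus <- Cxy + r * cbind(Nx, Ny)
  side_minus <- (Cxy - r * cbind(Nx, Ny))[n_half:1, , drop = FALSE]
  r0 <- spec$tube_radius
  cap_arc <- function(centre, phi_from, phi_to) {
    th <- seq(phi_from, phi_to, length.out = n_cap + 2L)[-c(1L, n_cap + 2L)]
    cbind(centre[1] + r0 * cos(th), centre[2] + r0 * sin(th))
  }
  phiL <- atan2(Ny[n_half], Nx[n_half])
  phi0 <- atan2(Ny[1], Nx[1])
  capL <- cap_arc(Cxy[n_half, ], phiL, phiL - pi)        # through +T(L)
  cap0 <- cap_arc(Cxy[1, ], phi0 + pi, phi0)             # through -T(0)
  xy <- rbind(side_plus, capL, side_minus, cap0)
  # per-point radius-rate slots: sides carry r(s); caps are static (NA)
  r_slot <- c(r, rep(NA_real_, n_cap), r[n_half:1], rep(NA_real_, n_cap))
  list(xy = xy, r_slot = r_slot)
}

#' Render a duodenum phantom cine stack with ground truth
#'
#' The tube interior is rendered from a per-stack nearest-centerline distance
#' field (4x supersampled, averaged down), so contraction rings appear as
#' travelling local narrowings, as in cine images of duodenal peristalsis.
#' Ground-truth wall velocities are analytic: wall points sit at fixed
#' centerline arc positions, move only along the centerline normal at the
#' radius field's finite-difference rate, so `V_N = -dr/dt` under the
#' inward-positive convention and `V_T = 0`; end caps are static. The
#' ground-truth mean absolute normal velocity `dm_vn` is the arc-length
#' weighted mean of `|V_N|` over the boundary, averaged over frame pairs.
#'
#' @param spec a [duodenum_spec()].
#' @param render if FALSE, skip image rendering (frames all background).
#' @return list with `stack`, `seeds` (30-point raw-coordinate outlines) and
#'   `truth` (list: `boundary`, `area`, `centroid`, `vn`, `vt`, `weights`,
#'   `dm_vn`, `resp_px`).
#' @export
make_duodenum_phantom <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "duodenum_spec"))
  set.seed(spec$seed)
  ss <- 4L
  geom <- centerline_geometry(spec$centerline)
  if (6 * spec$ring_width >= geom$length)
    stop("ring width too large for the tube length")
  tt <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval
  resp <- respiration_px(spec)

  bnds <- lapply(tt, function(t) duodenum_boundary(geom, spec, t))
  # normalize orientation once, consistently across frames
  flip <- signed_area(bnds[[1]]$xy) < 0
  if (flip) bnds <- lapply(bnds, function(b) {
    n <- nrow(b$xy)
    idx <- c(1L, n:2L)
    list(xy = b$xy[idx, , drop = FALSE], r_slot = b$r_slot[idx])
  })

  fov <- c((spec$grid[2] - 1) * spec$spacing[1],
           (spec$grid[1] - 1) * spec$spacing[2])
  ext <- apply(bnds[[1]]$xy, 2, range)
  if (ext[1, 1] < 0 || ext[1, 2] < 0 || ext[2, 1] > fov[1] || ext[2, 2] > fov[2])
    stop("duodenum tube does not fit inside the image grid")

  frames <- array(0.1, dim = c(spec$grid[1], spec$grid[2], spec$n_frames))
  if (render) {
    xs <- super_coords(spec$grid[2], spec$spacing[1], ss)
    ys <- super_coords(spec$grid[1], spec$spacing[2], ss)
    nx <- length(xs); ny <- length(ys)
    # nearest-centerline index and distance, computed once (static centerline)
    idx_m <- matrix(0L, ny, nx); dist_m <- matrix(0, ny, nx)
    clx <- geom$xy[, 1]; cly <- geom$xy[, 2]
    dx2 <- outer(xs, clx, "-")^2          # shared across rows
    for (rr in seq_len(ny)) {
      d2 <- dx2 + matrix((ys[rr] - cly)^2, nx, length(clx), byrow = TRUE)
      wmin <- max.col(-d2, ties.method = "first")
      idx_m[rr, ] <- wmin
      dist_m[rr, ] <- sqrt(d2[cbind(seq_len(nx), wmin)])
    }
    for (i in seq_len(spec$n_frames)) {
      r_dense <- tube_radius_at(geom$s, tt[i], spec, geom$length)
      occ <- (dist_m <= matrix(r_dense[idx_m], nrow(idx_m), ncol(idx_m))) + 0
      frames[, , i] <- finish_frame(downsample_blocks(occ, ss),
                                    resp[i], spec$noise_sd)
    }
  }
  stack <- frame_stack(frames, spec$spacing[1], spec$spacing[2],
                       spec$frame_interval, spec$plane_id, spec$scan_id)

  boundary <- lapply(bnds, `[[`, "xy")
  np <- nrow(boundary[[1]])
  vn <- vt <- NULL
  weights <- NULL
  dm_vn <- 0
  if (spec$n_frames >= 2L) {
    vn <- matrix(0, spec$n_frames - 1L, np)
    for (n in 2:spec$n_frames) {
      dr <- bnds[[n]]$r_slot - bnds[[n - 1L]]$r_slot
      dr[is.na(dr)] <- 0                     # static caps
      vn[n - 1L, ] <- -dr / spec$frame_interval
    }
    vt <- matrix(0, spec$n_frames - 1L, np)
    # arc-length weights from the later frame's polygon
    wts <- matrix(0, spec$n_frames - 1L, np)
    for (n in 2:spec$n_frames) {
      xy <- boundary[[n]]
      nxt <- c(2:np, 1L); prv <- c(np, 1:(np - 1L))
      seg_n <- sqrt(rowSums((xy[nxt, ] - xy)^2))
      seg_p <- sqrt(rowSums((xy - xy[prv, ])^2))
      wts[n - 1L, ] <- (seg_n + seg_p) / 2
    }
    weights <- wts
    dm_vn <- mean(rowSums(wts * abs(vn)) / rowSums(wts))
  }
  truth <- list(
    boundary = boundary,
    area = vapply(boundary, polygon_area, 0),
    centroid = t(vapply(boundary, polygon_centroid, c(x = 0, y = 0))),
    vn = vn, vt = vt, weights = weights, dm_vn = dm_vn,
    resp_px = resp)
  seeds <- seed_records(boundary, resp, spec$spacing, 30L, "duodenum")
  list(stack = stack, seeds = seeds, truth = truth)
}

# ---- study generation -------------------------------------------------------

#' Specification for a synthetic crossover study
#'
#' Emulates the study design: each subject is imaged in two conditions; each
#' condition has three motility scans (MS1, MS2, MS3) of four coronal fundus
#' planes plus one duodenum plane. The treated condition empties faster
#' (smaller MS3 residual) and has deeper peristaltic rings. Per-subject
#' emptying at MS3 is `condition mean + shared subject effect + noise`, the
#' paired structure a crossover design implies; MS2 emptying is half the MS3
#' value.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param conditions two condition labels; the second is the treated one.
#' @param emptying_mean per-condition mean MS3 emptying fraction.
#' @param subject_sd SD of the shared (condition-independent) subject effect
#'   on emptying, in fraction units.
#' @param emptying_sd SD of condition-specific emptying noise.
#' @param depth_mean per-condition mean contraction-ring depth.
#' @param depth_sd SD of per-subject ring depth.
#' @param grid,spacing,n_frames,frame_interval per-stack raster/timing.
#' @param oscillation_amp fundus pacemaker area-oscillation amplitude.
#' @param resp_amp_px,resp_period,noise_sd imaging nuisance parameters.
#' @param seed master seed; every random draw derives from it.
#' @return list of class `study_spec`.
#' @export
study_spec <- function(n_subjects = 8L, conditions = c("noMSG", "MSG"),
                       emptying_mean = c(0.16, 0.27), subject_sd = 0.115,
                       emptying_sd = 0.07,
                       depth_mean = c(0.12, 0.55), depth_sd = 0.05,
                       grid = c(96L, 96L), spacing = c(2.3, 2.3),
                       n_frames = 40L, frame_interval = 0.656,
                       oscillation_amp = 0.05,
                       resp_amp_px = 3, resp_period = 4, noise_sd = 0.02,
                       seed = 1L) {
  stopifnot(n_subjects >= 2L, length(conditions) == 2L,
            length(emptying_mean) == 2L, length(depth_mean) == 2L)
  if (subject_sd < 0 || emptying_sd < 0 || depth_sd < 0)
    stop("standard deviations must be non-negative")
  structure(as.list(environment()), class = "study_spec")
}

#' Draw per-subject ground-truth study parameters
#'
#' @param spec a [study_spec()].
#' @return data.frame with one row per subject x condition: `subject`,
#'   `condition`, `emptying_ms3`, `emptying_ms2`, `depth` and
#'   `resid_ms3_pct` (the true MS3 residual percentage, 100*(1-emptying)).
#' @export
draw_study_parameters <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  subj_eff <- stats::rnorm(spec$n_subjects, 0, spec$subject_sd)
  rows <- list()
  for (si in seq_along(subjects)) {
    for (ci in 1:2) {
      e3 <- spec$emptying_mean[ci] + subj_eff[si] +
        stats::rnorm(1, 0, spec$emptying_sd)
      e3 <- min(max(e3, 0), 0.6)
      dep <- min(max(stats::rnorm(1, spec$depth_mean[ci], spec$depth_sd),
                     0), 0.85)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[si], condition = spec$conditions[ci],
        emptying_ms3 = e3, emptying_ms2 = e3 / 2, depth = dep,
        resid_ms3_pct = 100 * (1 - e3))
    }
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic study on disk
#'
#' Writes, per subject x condition x scan, four fundus plane stacks and one
#' duodenum stack (TIFF + sidecar) with their seed files, the ground-truth
#' parameter table, and a JSON manifest describing the layout. All randomness
#' derives from the master seed; regeneration is bit-reproducible.
#'
#' @param spec a [study_spec()].
#' @param out_dir output directory (created if needed).
#' @param render render pixel data (TRUE) or background-only stacks (FALSE,
#'   much faster; seeds and ground truth are unaffected).
#' @return the study layout (list with `root` and `manifest`), invisibly
#'   readable back with [read_study_layout()].
#' @export
make_study <- function(spec, out_dir, render = TRUE) {
  stopifnot(inherits(spec, "study_spec"))
  pars <- draw_study_parameters(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scans <- c("MS1", "MS2", "MS3")
  # per-plane fundus baseline sizes: largest mid-planes, scaled to the grid
  fov_min <- min((spec$grid[2] - 1) * spec$spacing[1],
                 (spec$grid[1] - 1) * spec$spacing[2])
  ax <- fov_min * c(0.24, 0.28, 0.30, 0.26)
  bx <- fov_min * c(0.17, 0.20, 0.21, 0.18)
  cl_scale <- fov_min / 3.4   # default centerline radius relative to FOV
  manifest <- list(version = 1L, conditions = as.list(spec$conditions),
                   subjects = list())
  set.seed(spec$seed + 1L)  # stack-level noise seeds, distinct from pars
  stack_seed <- function() sample.int(2^31 - 2L, 1L)

  for (si in unique(pars$subject)) {
    manifest$subjects[[si]] <- list()
    for (cond in spec$conditions) {
      p <- pars[pars$subject == si & pars$condition == cond, ]
      manifest$subjects[[si]][[cond]] <- list()
      for (scan in scans) {
        empty <- switch(scan, MS1 = 0, MS2 = p$emptying_ms2,
                        MS3 = p$emptying_ms3)
        entry <- list(fundus = list(), duodenum = NULL)
        for (plane in 1:4) {
          fs <- fundus_spec(grid = spec$grid, spacing = spec$spacing,
                            n_frames = spec$n_frames,
                            frame_interval = spec$frame_interval,
                            semi_axes = c(ax[plane], bx[plane]),
                            oscillation_amp = spec$oscillation_amp,
                            emptying = empty,
                            resp_amp_px = spec$resp_amp_px,
                            resp_period = spec$resp_period,
                            noise_sd = spec$noise_sd, seed = stack_seed(),
                            plane_id = plane, scan_id = scan)
          ph <- make_fundus_phantom(fs, render = render)
          rel <- file.path(si, cond, sprintf("%s_fundus_P%d", scan, plane))
          write_phantom_files(ph, out_dir, rel)
          entry$fundus[[as.character(plane)]] <-
            list(stack = paste0(rel, ".tif"), seeds = paste0(rel, "_seeds.txt"))
        }
        cen <- c((spec$grid[2] - 1) * spec$spacing[1] / 2,
                 (spec$grid[1] - 1) * spec$spacing[2] / 2)
        ang <- seq(100, -100, length.out = 7L) * pi / 180
        ds <- duodenum_spec(grid = spec$grid, spacing = spec$spacing,
                            n_frames = spec$n_frames,
                            frame_interval = spec$frame_interval,
                            centerline = cbind(cen[1] + cl_scale * cos(ang),
                                               cen[2] + cl_scale * sin(ang)),
                            tube_radius = cl_scale * 0.28,
                            depth = p$depth,
                            ring_width = cl_scale * 0.25,
                            resp_amp_px = spec$resp_amp_px,
                            resp_period = spec$resp_period,
                            noise_sd = spec$noise_sd, seed = stack_seed(),
                            plane_id = 5L, scan_id = scan)
        ph <- make_duodenum_phantom(ds, render = render)
        rel <- file.path(si, cond, sprintf("%s_duodenum", scan))
        write_phantom_files(ph, out_dir, rel)
        entry$duodenum <- list(stack = paste0(rel, ".tif"),
                               seeds = paste0(rel, "_seeds.txt"))
        manifest$subjects[[si]][[cond]][[scan]] <- entry
      }
    }
  }
  utils::write.csv(pars, file.path(out_dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "layout.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(root = out_dir, manifest = manifest, truth = pars))
}

write_phantom_files <- function(ph, root, rel) {
  dir.create(dirname(file.path(root, rel)), recursive = TRUE,
             showWarnings = FALSE)
  write_frame_stack(ph$stack, file.path(root, paste0(rel, ".tif")))
  write_contour_series(ph$seeds, file.path(root, paste0(rel, "_seeds.txt")))
  invisible(NULL)
}

#' Read a study layout manifest
#'
#' @param path path to a `layout.json` written by [make_study()], or the
#'   directory containing it.
#' @return list with `root`, `manifest` and `truth` (the ground-truth
#'   parameter table, if present).
#' @export
read_study_layout <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "layout.json")
  if (!file.exists(path)) stop("no such manifest: ", path)
  root <- dirname(path)
  manifest <- jsonlite::read_json(path)
  truth_path <- file.path(root, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  list(root = root, manifest = manifest, truth = truth)
}
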