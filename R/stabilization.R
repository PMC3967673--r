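#' Estimate the translation between two frames by SSD energy minimization
#'
#' Respiratory motion in free-breathing cine MRI is dominated by whole-field
#' translation. The shift between consecutive frames is estimated by
#' exhaustive search over integer shifts `b` in
#' `[-search_radius, +search_radius]^2`, minimizing the energy
#'
#'   E(b) = sum over ROI pixels x of ( I_a(x) - I_b(x + b) )^2 / |ROI|
#'
#' i.e. the mean squared intensity difference between frame `a` at `x` and
#' frame `b` at the shifted position. The returned shift is the content
#' translation of `b` relative to `a` in pixels (`x` = columns, `y` = rows).
#'
#' Ties in energy are broken deterministically: smallest shift magnitude
#' first, then lexicographic (row, then column) — favouring the null shift
#' under degeneracy.
#'
#' @param frame_a,frame_b numeric matrices on the same grid.
#' @param roi integer vector `c(row_min, row_max, col_min, col_max)`
#'   (1-based, inclusive). The ROI must keep a margin of at least
#'   `search_radius` pixels to every frame border.
#' @param search_radius non-negative integer search half-width in pixels.
#' @return list with `shift` (named integer vector `c(x, y)`), `energy`
#'   (minimum mean squared difference) and `degenerate` (TRUE when the ROI has
#'   zero intensity variance in both frames, in which case the shift is 0).
#' @export
compute_shift <- function(frame_a, frame_b, roi, search_radius) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            all(dim(frame_a) == dim(frame_b)))
  r <- as.integer(search_radius)
  if (r < 0L) stop("search_radius must be a non-negative integer")
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi must be c(row_min, row_max, col_min, col_max) with min <= max")
  if (roi[1] - r < 1L || roi[2] + r > nrow(frame_a) ||
      roi[3] - r < 1L || roi[4] + r > ncol(frame_a))
    stop("roi is too close to the frame border for search radius ", r)

  rows <- roi[1]:roi[2]
  cols <- roi[3]:roi[4]
  a <- frame_a[rows, cols, drop = FALSE]
  npix <- length(a)

  offs <- (-r):r
  energies <- matrix(NA_real_, length(offs), length(offs),
                     dimnames = list(dy = offs, dx = offs))
  for (iy in seq_along(offs)) {
    for (ix in seq_along(offs)) {
      b <- frame_b[rows + offs[iy], cols + offs[ix], drop = FALSE]
      energies[iy, ix] <- sum((a - b)^2) / npix
    }
  }

  emin <- min(energies)
  hits <- which(energies == emin, arr.ind = TRUE)
  dy <- offs[hits[, 1]]
  dx <- offs[hits[, 2]]
  ord <- order(dx^2 + dy^2, dy, dx)
  best <- ord[1]

  zero_var <- stats::var(as.vector(a)) == 0 &&
    stats::var(as.vector(frame_b[(roi[1] - r):(roi[2] + r),
                                 (roi[3] - r):(roi[4] + r)])) == 0
  if (zero_var)
    return(list(shift = c(x = 0L, y = 0L), energy = emin, degenerate = TRUE))

  list(shift = c(x = as.integer(dx[best]), y = as.integer(dy[best])),
       energy = emin, degenerate = FALSE)
}

# Shift a frame's content by integer (dx, dy) pixels; vacated pixels get `fill`.
translate_frame <- function(frame, dx, dy, fill = 0) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy   # new[r, c] = old[r - dy, c - dx]
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Stabilize a cine stack against respiratory translation
#'
#' Pairwise shifts between consecutive raw frames are estimated with
#' [compute_shift()] and accumulated, so frame `n` carries the cumulative
#' content shift relative to frame 1. Each frame is then translated by the
#' negative of its cumulative shift, aligning the whole series to frame 1.
#' Pixels vacated by the translation are filled with the frame's edge-median
#' intensity and flagged invalid in the returned mask.
#'
#' @param stack a [frame_stack()].
#' @inheritParams compute_shift
#' @return list with `stack` (stabilized [frame_stack()]), `trace`
#'   (data.frame `pair, dx, dy, energy, degenerate` of pairwise shifts),
#'   `cumulative` (frames x 2 matrix of cumulative content shifts, columns
#'   `x`, `y`) and `validity` (logical array marking untouched pixels).
#' @export
stabilize_stack <- function(stack, roi, search_radius) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  cumulative <- matrix(0L, nf, 2L, dimnames = list(NULL, c("x", "y")))
  trace <- data.frame(pair = integer(0), dx = integer(0), dy = integer(0),
                      energy = numeric(0), degenerate = logical(0))
  if (nf >= 2L) {
    for (n in seq_len(nf - 1L)) {
      s <- compute_shift(stack$frames[, , n], stack$frames[, , n + 1L],
                         roi, search_radius)
      trace <- rbind(trace, data.frame(
        pair = n, dx = s$shift["x"], dy = s$shift["y"],
        energy = s$energy, degenerate = s$degenerate, row.names = NULL))
      cumulative[n + 1L, ] <- cumulative[n, ] + s$shift
    }
  }

  out <- stack$frames
  validity <- array(TRUE, dim = dim(out))
  for (n in seq_len(nf)) {
    cs <- cumulative[n, ]
    if (all(cs == 0L)) next
    fr <- stack$frames[, , n]
    edge <- c(fr[1, ], fr[nrow(fr), ], fr[, 1], fr[, ncol(fr)])
    out[, , n] <- translate_frame(fr, -cs["x"], -cs["y"],
                                  fill = stats::median(edge))
    validity[, , n] <- translate_frame(matrix(1, nrow(fr), ncol(fr)),
                                       -cs["x"], -cs["y"], fill = 0) > 0
  }

  stab <- stack
  stab$frames <- out
  list(stack = stab, trace = trace, cumulative = cumulative,
       validity = validity)
}
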