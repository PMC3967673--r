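#' Construct a cine frame stack
#'
#' A frame stack is one imaging plane's cine series: a set of 2D intensity
#' frames acquired at a fixed interval, with the pixel spacing needed to work
#' in physical millimetre coordinates. All geometry downstream is done in mm
#' (image origin at the top-left pixel centre, x rightward along columns,
#' y downward along rows, physical mm = 0-based pixel index times spacing),
#' so anisotropic spacing is handled uniformly.
#'
#' @param frames numeric 3D array (rows x cols x frames) or a list of
#'   identically sized matrices; intensities are arbitrary non-negative units.
#' @param spacing_x,spacing_y pixel spacing in mm/px (x = columns, y = rows).
#' @param frame_interval time between frames in seconds.
#' @param plane_id integer plane index (1-11 in the acquisition protocol).
#' @param scan_id scan label, one of "MS1", "MS2", "MS3".
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, spacing_x, spacing_y, frame_interval,
                        plane_id = 1L, scan_id = "MS1") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L)
  if (!is.numeric(spacing_x) || !is.numeric(spacing_y) ||
      spacing_x <= 0 || spacing_y <= 0)
    stop("pixel spacings must be positive numbers")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (dim(frames)[3] < 1L) stop("frame count must be >= 1")
  structure(list(
    frames = frames,
    spacing = c(x = as.numeric(spacing_x), y = as.numeric(spacing_y)),
    frame_interval = as.numeric(frame_interval),
    plane_id = as.integer(plane_id),
    scan_id = as.character(scan_id)
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "frame_stack: %d frames of %d x %d px (%.4g x %.4g mm/px), dt = %.4g s, plane %d, %s\n",
    d[3], d[1], d[2], x$spacing["y"], x$spacing["x"],
    x$frame_interval, x$plane_id, x$scan_id))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

# ---- sidecar metadata -------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta")

write_sidecar <- function(stack, path) {
  lines <- c(
    sprintf("pixel_spacing_x = %.10g", stack$spacing["x"]),
    sprintf("pixel_spacing_y = %.10g", stack$spacing["y"]),
    sprintf("frame_interval = %.10g", stack$frame_interval),
    sprintf("plane_id = %d", stack$plane_id),
    sprintf("scan_id = %s", stack$scan_id))
  writeLines(lines, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("metadata sidecar not found: ", sp)
  lines <- readLines(sp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  meta <- stats::setNames(as.list(vals), keys)
  for (field in c("pixel_spacing_x", "pixel_spacing_y", "frame_interval"))
    if (is.null(meta[[field]]))
      stop("sidecar ", sp, " is missing required field '", field, "'")
  meta
}

# ---- stack I/O --------------------------------------------------------------

#' Read a cine frame stack from disk
#'
#' Reads a multi-page TIFF stack plus its plain-text `key = value` sidecar
#' (`<path>.meta`) carrying pixel spacing, frame interval, plane and scan ids.
#' Frames are ordered by page index; intensities are returned unmodified.
#'
#' @param path path to the multi-page TIFF file.
#' @param format one of `"auto"` or `"tiff"`. DICOM series are not supported
#'   by this reader; convert to TIFF + sidecar first.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, format = c("auto", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; ",
         "supply a multi-page TIFF with a '.meta' sidecar")
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("mixed frame dimensions in ", path)
  frame_stack(pages,
              spacing_x = as.numeric(meta$pixel_spacing_x),
              spacing_y = as.numeric(meta$pixel_spacing_y),
              frame_interval = as.numeric(meta$frame_interval),
              plane_id = if (is.null(meta$plane_id)) 1L else as.integer(meta$plane_id),
              scan_id = if (is.null(meta$scan_id)) "MS1" else meta$scan_id)
}

#' Write a cine frame stack to disk
#'
#' Writes the frames as a 32-bit float multi-page TIFF and the metadata as a
#' plain-text sidecar next to it. Intensities must lie in `[0, 1]`.
#'
#' @param stack a [frame_stack()].
#' @param path destination TIFF path; the sidecar is written to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  pages <- lapply(seq_len(n_frames(stack)), function(i) stack$frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  write_sidecar(stack, path)
  invisible(path)
}

# ---- contour I/O ------------------------------------------------------------

#' Read wall-contour seed points
#'
#' Seed files are line-oriented text, one record per frame:
#' `frame label x1 y1 x2 y2 ...` with coordinates in mm. Each record must be
#' a simple (non-self-intersecting) closed polygon of at least 3 points.
#'
#' @param path path to the seed file.
#' @return A list of seed contours, each a list with elements `frame`
#'   (integer), `label` (character) and `xy` (m x 2 matrix, mm).
#' @export
read_seed_contours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(tok) < 2L) stop("record ", i, ": malformed line")
    frame <- suppressWarnings(as.integer(tok[1]))
    label <- tok[2]
    coords <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(coords) || is.na(frame))
      stop("record ", i, " (frame ", tok[1], "): non-numeric coordinates")
    if (length(coords) %% 2L != 0L)
      stop("record ", i, " (frame ", frame, "): odd coordinate count")
    xy <- matrix(coords, ncol = 2L, byrow = TRUE)
    if (nrow(xy) < 3L)
      stop("record ", i, " (frame ", frame, "): fewer than 3 points")
    if (anyDuplicated(xy))
      stop("record ", i, " (frame ", frame, "): duplicate points")
    if (!is_simple_polygon(xy))
      stop("record ", i, " (frame ", frame, "): self-intersecting polygon")
    list(frame = frame, label = label, xy = xy)
  })
}

#' Write a contour series (or seed list) to a seed-format text file
#'
#' Coordinates are written in mm with 6 decimals, one frame per line in the
#' same `frame label x1 y1 ...` layout [read_seed_contours()] expects, so a
#' read/write round trip is lossless to that precision.
#'
#' @param contours a list of contours as returned by [read_seed_contours()],
#'   or a `contour_series` (see [build_contour_series()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_contour_series <- function(contours, path) {
  if (inherits(contours, "contour_series"))
    contours <- lapply(seq_along(contours$contours), function(i)
      list(frame = i - 1L, label = contours$label, xy = contours$contours[[i]]))
  lines <- vapply(contours, function(cn) {
    paste(cn$frame, cn$label,
          paste(sprintf("%.6f %.6f", cn$xy[, 1], cn$xy[, 2]), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- metrics table ----------------------------------------------------------

#' Write a metrics table as CSV
#'
#' Emits `subject,condition,scan,plane,metric,value,units` with a
#' deterministic row order (subject, condition, scan, metric, plane), so
#' identical inputs give byte-identical files.
#'
#' @param records data.frame with columns `subject`, `condition`, `scan`,
#'   `plane`, `metric`, `value`, `units`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  cols <- c("subject", "condition", "scan", "plane", "metric", "value", "units")
  if (nrow(records) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  records <- records[cols]
  ord <- order(records$subject, records$condition, records$scan,
               records$metric, records$plane)
  records <- records[ord, , drop = FALSE]
  records$value <- sprintf("%.8g", records$value)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- polygon validity -------------------------------------------------------

# Simple-polygon test by exhaustive proper segment-pair intersection.
# Adjacent edges share an endpoint and are exempt; O(n^2), fine for n <= ~400.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  a <- xy
  b <- xy[nxt, , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # first and last edge are adjacent
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Vectorized proper-intersection test of segment (p1,p2) against rows of (q1,q2).
segments_intersect <- function(p1, p2, q1, q2) {
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p1[1], p1[2])
  d2 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p2[1], p2[2])
  d3 <- cross(p1[1], p1[2], p2[1], p2[2], q1[, 1], q1[, 2])
  d4 <- cross(p1[1], p1[2], p2[1], p2[2], q2[, 1], q2[, 2])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
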