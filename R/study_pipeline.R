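#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis in one object
#' so every run is reproducible from its resolved configuration.
#'
#' @param stabilize cancel respiratory translation before contouring.
#' @param search_radius stabilization search half-width in pixels.
#' @param roi stabilization ROI `c(row_min, row_max, col_min, col_max)`
#'   (1-based inclusive), or NULL for the largest centred rectangle leaving a
#'   `search_radius` margin.
#' @param n_points resampled points per wall contour.
#' @param planes fundus plane ids summed into the residual-volume index.
#' @param fundus_dma_plane plane whose area series yields the fundus DM(A).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stabilize = TRUE, search_radius = 10L,
                            roi = NULL, n_points = 100L, planes = 1:4,
                            fundus_dma_plane = 4L) {
  structure(list(stabilize = stabilize,
                 search_radius = as.integer(search_radius), roi = roi,
                 n_points = as.integer(n_points), planes = planes,
                 fundus_dma_plane = fundus_dma_plane),
            class = "pipeline_config")
}

default_roi <- function(stack, radius) {
  d <- dim(stack$frames)
  c(radius + 1L, d[1] - radius, radius + 1L, d[2] - radius)
}

#' Analyse one cine stack: stabilize and build its wall-contour series
#'
#' The per-stack unit of the pipeline: reads the stack and its seed file,
#' optionally cancels respiratory translation with [stabilize_stack()]
#' (mapping seed coordinates, which refer to the raw frames, into the
#' stabilized frame by the recovered cumulative shifts), and resamples the
#' seeds into a corresponding contour series.
#'
#' @param stack_path path to the TIFF stack (with `.meta` sidecar).
#' @param seeds_path path to the per-frame seed contour file.
#' @param config a [pipeline_config()].
#' @return list with `stack` (stabilized [frame_stack()]) and `series`
#'   (a `contour_series`).
#' @export
analyze_stack <- function(stack_path, seeds_path, config = pipeline_config()) {
  stack <- read_frame_stack(stack_path)
  seeds <- read_seed_contours(seeds_path)
  nf <- n_frames(stack)
  frames_idx <- vapply(seeds, `[[`, 0L, "frame") + 1L
  if (any(frames_idx < 1L | frames_idx > nf))
    stop("seed frame indices outside stack range in ", seeds_path)
  if (config$stabilize && nf >= 2L) {
    roi <- if (is.null(config$roi)) default_roi(stack, config$search_radius)
           else config$roi
    st <- stabilize_stack(stack, roi, config$search_radius)
    cum_mm <- cbind(st$cumulative[, "x"] * stack$spacing["x"],
                    st$cumulative[, "y"] * stack$spacing["y"])
    seeds <- lapply(seeds, function(sd) {
      sd$xy <- sweep(sd$xy, 2L, cum_mm[sd$frame + 1L, ])
      sd
    })
    stack <- st$stack
  }
  series <- build_contour_series(seeds, config$n_points,
                                 stack$frame_interval)
  list(stack = stack, series = series)
}

series_areas <- function(series) vapply(series$contours, polygon_area, 0)
series_centroids <- function(series)
  t(vapply(series$contours, polygon_centroid, c(x = 0, y = 0)))

#' Run the full analysis for one subject
#'
#' For every condition and motility scan: stabilize each stack, resample the
#' wall seeds into corresponding contour series, and compute per-frame areas
#' and centroids. Fundus planes are combined into the residual-volume index
#' (percent of MS1); the configured fundus plane yields DM(A); the duodenum
#' stack yields DM(A), DM(G), the DG_Y trace and the velocity indices
#' DM(V_N), DM(V_T). Deterministic given inputs and configuration.
#'
#' @param layout a study layout from [read_study_layout()] or [make_study()].
#' @param subject subject id present in the layout.
#' @param config a [pipeline_config()].
#' @return list of class `subject_result` with elements `subject`,
#'   `residual` (data.frame condition, scan, total_area, pct),
#'   `fundus_dma` (data.frame condition, scan, dm_a),
#'   `duodenum` (data.frame condition, scan, dm_a, dm_g, dm_vn, dm_vt) and
#'   `dgy` (named list of per-condition, per-scan DG_Y traces).
#' @export
run_subject <- function(layout, subject, config = pipeline_config()) {
  subj <- layout$manifest$subjects[[subject]]
  if (is.null(subj)) stop("subject ", subject, " not in layout")
  residual <- fundus_dma <- duo <- NULL
  dgy <- list()
  for (cond in names(subj)) {
    fund_areas <- NULL
    for (scan in names(subj[[cond]])) {
      entry <- subj[[cond]][[scan]]
      for (plane in names(entry$fundus)) {
        ps <- withCallingHandlers(
          analyze_stack(file.path(layout$root, entry$fundus[[plane]]$stack),
                        file.path(layout$root, entry$fundus[[plane]]$seeds),
                        config),
          error = function(e) stop("subject ", subject, " ", cond, " ", scan,
                                   " fundus plane ", plane, ": ",
                                   conditionMessage(e), call. = FALSE))
        areas <- series_areas(ps$series)
        fund_areas <- rbind(fund_areas, data.frame(
          scan = scan, plane = as.integer(plane), area = areas))
        if (as.integer(plane) == config$fundus_dma_plane && length(areas) >= 2L)
          fundus_dma <- rbind(fundus_dma, data.frame(
            condition = cond, scan = scan, dm_a = dm_area(areas)))
      }
      dd <- analyze_stack(file.path(layout$root, entry$duodenum$stack),
                          file.path(layout$root, entry$duodenum$seeds),
                          config)
      cent <- series_centroids(dd$series)
      areas <- series_areas(dd$series)
      vel <- if (length(dd$series$contours) >= 2L)
        dm_velocity(wall_velocities(dd$series)) else c(vn = NA_real_, vt = NA_real_)
      duo <- rbind(duo, data.frame(
        condition = cond, scan = scan,
        dm_a = if (length(areas) >= 2L) dm_area(areas) else NA_real_,
        dm_g = if (nrow(cent) >= 2L) dm_gravity(cent) else NA_real_,
        dm_vn = vel[["vn"]], dm_vt = vel[["vt"]]))
      dgy[[paste(cond, scan, sep = ".")]] <- dgy_trace(cent)
    }
    fund_areas <- fund_areas[fund_areas$plane %in% config$planes, ]
    res <- gastric_residual(fund_areas)
    res <- data.frame(condition = cond, res)
    residual <- rbind(residual, res)
  }
  structure(list(subject = subject, residual = residual,
                 fundus_dma = fundus_dma, duodenum = duo, dgy = dgy),
            class = "subject_result")
}

#' Run the study-level analysis
#'
#' Runs [run_subject()] for every (or a designated subset of) subject(s),
#' then compares the two conditions with paired t-tests per metric and scan:
#' MS2/MS3 residual percentage, fundus DM(A), and the duodenal indices.
#' Subjects failing any stage are excluded with a warning; subset selection
#' (e.g. responder subgroups) is explicit user input, never automatic.
#' P values are reported unadjusted for multiple comparisons.
#'
#' @param layout a study layout from [read_study_layout()] or [make_study()].
#' @param config a [pipeline_config()].
#' @param subset optional character vector of subject ids to analyse.
#' @return list of class `study_result` with `per_subject` (data.frame of
#'   per-subject metric values), `paired` (data.frame metric, scan, mean/sd
#'   per condition, t, p, n, degenerate), `subjects` (results list) and
#'   `conditions`.
#' @export
run_study <- function(layout, config = pipeline_config(), subset = NULL) {
  ids <- names(layout$manifest$subjects)
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, ids)
    if (length(missing_ids))
      stop("subset subjects not in layout: ", paste(missing_ids, collapse = ", "))
    ids <- intersect(ids, subset)
  }
  conditions <- unlist(layout$manifest$conditions)
  results <- list()
  for (s in ids) {
    r <- tryCatch(run_subject(layout, s, config), error = function(e) {
      warning("subject ", s, " excluded: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(r)) results[[s]] <- r
  }
  if (length(results) < 2L) stop("fewer than 2 analysable subjects")

  per_subject <- do.call(rbind, lapply(results, function(r) {
    res <- r$residual[, c("condition", "scan", "pct")]
    names(res)[3] <- "value"; res$metric <- "residual_pct"
    fd <- r$fundus_dma[, c("condition", "scan", "dm_a")]
    names(fd)[3] <- "value"; fd$metric <- "fundus_dm_a"
    duo_long <- do.call(rbind, lapply(
      c(dm_a = "dm_a", dm_g = "dm_g", dm_vn = "dm_vn", dm_vt = "dm_vt"),
      function(mcol) {
        d <- r$duodenum[, c("condition", "scan", mcol)]
        names(d)[3] <- "value"; d$metric <- paste0("duodenum_", mcol); d
      }))
    out <- rbind(res, fd, duo_long)
    out$subject <- r$subject
    rownames(out) <- NULL
    out[, c("subject", "condition", "scan", "metric", "value")]
  }))
  rownames(per_subject) <- NULL

  paired <- NULL
  for (metric in unique(per_subject$metric)) {
    for (scan in unique(per_subject$scan[per_subject$metric == metric])) {
      if (metric == "residual_pct" && scan == "MS1") next  # identically 100
      sub <- per_subject[per_subject$metric == metric &
                           per_subject$scan == scan, ]
      wide <- merge(sub[sub$condition == conditions[1], c("subject", "value")],
                    sub[sub$condition == conditions[2], c("subject", "value")],
                    by = "subject", suffixes = c("_a", "_b"))
      wide <- wide[stats::complete.cases(wide), ]
      if (nrow(wide) < 2L) next
      ht <- compare_paired(wide$value_a, wide$value_b)
      paired <- rbind(paired, data.frame(
        metric = metric, scan = scan,
        mean_a = mean(wide$value_a), sd_a = stats::sd(wide$value_a),
        mean_b = mean(wide$value_b), sd_b = stats::sd(wide$value_b),
        t = ht$t, p = ht$p, n = nrow(wide), degenerate = ht$degenerate))
    }
  }
  structure(list(per_subject = per_subject, paired = paired,
                 subjects = results, conditions = conditions),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d subjects, conditions %s vs %s\n",
              length(x$subjects), x$conditions[1], x$conditions[2]))
  print(x$paired, digits = 3)
  invisible(x)
}
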