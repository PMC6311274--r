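#' Unit tangents along a polyline axis
#'
#' Central differences in the interior, one-sided at the ends, normalised to
#' unit length.
#'
#' @param axis n x 3 matrix of ordered world points (mm); consecutive points
#'   must be distinct.
#' @return n x 3 matrix of unit tangents.
#' @export
axis_tangents <- function(axis) {
  axis <- as.matrix(axis)
  n <- nrow(axis)
  if (n < 2) stop("axis needs at least 2 points")
  if (any(rowSums(diff(axis)^2) == 0)) stop("axis has repeated consecutive points")
  tang <- matrix(0, n, 3)
  tang[1, ] <- axis[2, ] - axis[1, ]
  tang[n, ] <- axis[n, ] - axis[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- axis[3:n, ] - axis[1:(n - 2), ]
  len <- sqrt(rowSums(tang^2))
  if (any(len == 0)) stop("zero tangent on axis")
  tang / len
}

#' Parallel-transported orthonormal frames along an axis
#'
#' Produces, at every axis point, two in-plane unit vectors orthogonal to the
#' tangent and to each other. The first frame is seeded from the coordinate
#' axis least aligned with the tangent; subsequent frames are rotated by the
#' minimal rotation taking one tangent to the next (parallel transport), which
#' avoids the frame flips a Frenet frame suffers at inflection points.
#'
#' @param axis n x 3 matrix of world points (mm).
#' @param tangents optional n x 3 unit tangents (computed if missing).
#' @return A list with `u` and `v`, each an n x 3 matrix of unit vectors.
#' @export
parallel_transport_frames <- function(axis, tangents = NULL) {
  axis <- as.matrix(axis)
  if (is.null(tangents)) tangents <- axis_tangents(axis)
  n <- nrow(axis)
  u <- matrix(0, n, 3); v <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  seed <- diag(3)[, which.min(abs(t1))]
  u1 <- seed - sum(seed * t1) * t1
  u[1, ] <- u1 / sqrt(sum(u1^2))
  v[1, ] <- cross3(t1, u[1, ])
  for (i in seq_len(n - 1)) {
    a <- tangents[i, ]; b <- tangents[i + 1, ]
    ax <- cross3(a, b)
    s <- sqrt(sum(ax^2)); cth <- sum(a * b)
    if (s < 1e-12) {
      u[i + 1, ] <- u[i, ]; v[i + 1, ] <- v[i, ]
    } else {
      k <- ax / s
      u[i + 1, ] <- rodrigues(u[i, ], k, cth, s)
      v[i + 1, ] <- rodrigues(v[i, ], k, cth, s)
    }
    # re-orthogonalise against accumulated round-off
    u[i + 1, ] <- u[i + 1, ] - sum(u[i + 1, ] * b) * b
    u[i + 1, ] <- u[i + 1, ] / sqrt(sum(u[i + 1, ]^2))
    v[i + 1, ] <- cross3(b, u[i + 1, ])
  }
  list(u = u, v = v)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

rodrigues <- function(p, k, cos_th, sin_th) {
  p * cos_th + cross3(k, p) * sin_th + k * sum(k * p) * (1 - cos_th)
}

#' Cross-section frame at one axis point
#'
#' @param axis n x 3 matrix of axis points (mm).
#' @param index which axis point.
#' @return A list with `origin`, `tangent`, and in-plane unit vectors `u`,
#'   `v`.
#' @export
cross_section_frame <- function(axis, index) {
  axis <- as.matrix(axis)
  if (index < 1 || index > nrow(axis)) stop("index out of range")
  tang <- axis_tangents(axis)
  fr <- parallel_transport_frames(axis, tang)
  list(origin = axis[index, ], tangent = tang[index, ],
       u = fr$u[index, ], v = fr$v[index, ])
}

#' Cast equally spaced rays on a cross-section
#'
#' Rays start at the axis point and step radially outwards in the plane
#' spanned by the frame's `u`, `v` vectors; at the default 5 degree spacing a
#' cross-section carries 72 rays.
#'
#' @param frame a frame from [cross_section_frame()] (or any list with
#'   `origin`, `u`, `v`).
#' @param angular_step_deg angular spacing; must divide 360.
#' @param n_samples samples per ray (default 18).
#' @param step_mm radial sample spacing in mm.
#' @return A list of rays, each a list with `angle_deg`, `step_mm` and
#'   `points` (`n_samples` x 3, first row the axis point).
#' @export
cast_rays <- function(frame, angular_step_deg = 5, n_samples = 18, step_mm = 0.7) {
  if (360 %% angular_step_deg != 0) stop("angular_step_deg must divide 360")
  angles <- seq(0, 360 - angular_step_deg, by = angular_step_deg)
  radii <- (seq_len(n_samples) - 1) * step_mm
  lapply(angles, function(a) {
    th <- a * pi / 180
    dirv <- cos(th) * frame$u + sin(th) * frame$v
    pts <- cbind(frame$origin[1] + radii * dirv[1],
                 frame$origin[2] + radii * dirv[2],
                 frame$origin[3] + radii * dirv[3])
    list(angle_deg = a, step_mm = step_mm, points = pts)
  })
}

#' Sample a voxel series along one ray
#'
#' Trilinear interpolation of the volume at the ray's sample points. Rays
#' leaving the volume raise an error naming the ray rather than being
#' zero-padded, which would corrupt the observation statistics.
#'
#' @param volume a [vol3d].
#' @param ray a ray from [cast_rays()].
#' @return Numeric vector of interpolated intensities.
#' @export
sample_series <- function(volume, ray) {
  tryCatch(interp_trilinear(volume, ray$points),
           error = function(e) stop(sprintf(
             "ray at %g deg leaves the volume: %s", ray$angle_deg, conditionMessage(e)),
             call. = FALSE))
}

#' Tissue labels along one ray, with intima stripping
#'
#' Samples the label volume (nearest voxel) along the ray and re-derives the
#' intima: the last `wall_thickness_vox` consecutive vessel samples before the
#' first non-vessel sample are relabelled intima (the stripped outermost
#' layer); earlier vessel samples are lumen. Beyond the vessel, pathology is
#' taken from the label volume and everything else is adventitia. Pathology
#' can therefore only appear after the intima block, matching a model in which
#' pathological tissue exists outside the intima.
#'
#' @param labels a [vol3d] of integer codes (0 background, 1 lumen, 2 intima,
#'   3 pathology).
#' @param ray a ray from [cast_rays()].
#' @param wall_thickness_vox 2, 3 or 4.
#' @return Integer vector of labels in 1..4 (1 lumen, 2 intima, 3 pathology,
#'   4 adventitia) with attributes `valid` (first sample is vessel and no
#'   backward transition) and `flag` (reason when invalid).
#' @export
label_series <- function(labels, ray, wall_thickness_vox = 3) {
  if (!wall_thickness_vox %in% 2:4) stop("wall_thickness_vox must be 2, 3 or 4")
  raw <- interp_nearest(labels, ray$points)
  n <- length(raw)
  vessel <- raw == 1L | raw == 2L
  out <- integer(n)
  flag <- NULL
  if (!vessel[1]) {
    # axis assumed inside the lumen; flagged for exclusion from training
    flag <- "first sample is not vessel"
  }
  first_nonvessel <- which(!vessel)[1]
  if (is.na(first_nonvessel)) {
    out[] <- 1L                      # huge vessel: no boundary within the ray
  } else {
    nv <- first_nonvessel - 1L       # leading vessel run
    k <- min(wall_thickness_vox, nv)
    if (nv > 0) {
      out[seq_len(nv)] <- 1L
      if (k > 0) out[(nv - k + 1L):nv] <- 2L
    }
    rest <- first_nonvessel:n
    out[rest] <- ifelse(raw[rest] == 3L, 3L, 4L)
    # vessel reappearing after the boundary would be a backward transition
    if (any(vessel[rest])) flag <- c(flag, "vessel after boundary")
  }
  attr(out, "valid") <- is.null(flag)
  attr(out, "flag") <- flag
  out
}

#' Collect ray series over a whole phantom or volume
#'
#' Places a cross-section at every axis point, casts rays, and samples
#' intensity, optional tissue labels, and any supplied feature volumes at the
#' 18 points of every ray. This is the tabular exchange format between the
#' geometry and the classifier: one row per sample.
#'
#' @param volume a [vol3d].
#' @param axis n x 3 matrix of axis points (mm).
#' @param labels optional label [vol3d]; adds a `label` column (1 lumen,
#'   2 intima, 3 pathology, 4 adventitia) and drops rays flagged invalid.
#' @param features optional named list of feature [vol3d]s; adds one column
#'   per feature.
#' @param angular_step_deg,n_samples,step_mm ray geometry; `step_mm` defaults
#'   to the smallest voxel dimension.
#' @param wall_thickness_vox intima thickness used in label stripping.
#' @param phantom_id identifier recorded in the table.
#' @return A data.frame with columns `phantom_id`, `series_uid`, `axis_index`,
#'   `angle_deg`, `sample_index`, `x`, `y`, `z`, `intensity`, then optional
#'   `label` and feature columns.
#' @export
collect_series <- function(volume, axis, labels = NULL, features = NULL,
                           angular_step_deg = 5, n_samples = 18,
                           step_mm = NULL, wall_thickness_vox = 3,
                           phantom_id = "phantom") {
  stopifnot_vol3d(volume)
  if (is.null(step_mm)) step_mm <- min(volume$spacing)
  axis <- as.matrix(axis)
  tang <- axis_tangents(axis)
  frames <- parallel_transport_frames(axis, tang)
  n_axis <- nrow(axis)
  rows <- vector("list", n_axis)
  for (i in seq_len(n_axis)) {
    frame <- list(origin = axis[i, ], u = frames$u[i, ], v = frames$v[i, ])
    rays <- cast_rays(frame, angular_step_deg, n_samples, step_mm)
    pts <- do.call(rbind, lapply(rays, `[[`, "points"))
    inten <- interp_trilinear(volume, pts)
    df <- data.frame(
      phantom_id = phantom_id,
      series_uid = paste0(phantom_id, ":", i, ":",
                          rep(vapply(rays, `[[`, 0, "angle_deg"), each = n_samples)),
      axis_index = i,
      angle_deg = rep(vapply(rays, `[[`, 0, "angle_deg"), each = n_samples),
      sample_index = rep(seq_len(n_samples), times = length(rays)),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      intensity = inten,
      stringsAsFactors = FALSE)
    if (!is.null(labels)) {
      labs <- lapply(rays, function(r) label_series(labels, r, wall_thickness_vox))
      keep <- vapply(labs, attr, TRUE, "valid")
      df$label <- unlist(lapply(labs, as.integer))
      df <- df[rep(keep, each = n_samples), , drop = FALSE]
    }
    if (!is.null(features)) {
      fv <- lapply(features, function(f) interp_trilinear(f, pts))
      if (!is.null(labels)) {
        keepvec <- rep(vapply(labs, attr, TRUE, "valid"), each = n_samples)
        fv <- lapply(fv, function(v) v[keepvec])
      }
      for (nm in names(fv)) df[[nm]] <- fv[[nm]]
    }
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
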