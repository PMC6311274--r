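#' Configuration for a synthetic vessel phantom
#'
#' Builds and validates the parameter set for [generate_phantom()]. The
#' phantom emulates a contrast-filled vessel in CT: a bright tubular lumen of
#' 0.7--6.0 mm diameter, a thin darker wall (intima) shell 2--4 voxels thick,
#' optional hyperdense calcified plaque arcs sitting on the outside of the
#' wall, darker background tissue, and (via [add_gaussian_noise()]) additive
#' Gaussian noise.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size in mm (scalar or length 3). Default 0.7 mm
#'   isotropic.
#' @param axis_spec either an n x 3 matrix of world-coordinate (mm) axis
#'   points, or a list with `type` one of `"straight"`, `"helical"`,
#'   `"bifurcating"` and optional fields `margin_vox` (default 10),
#'   `amplitude_mm`, `turns`, `branch_angle_deg`.
#' @param radius_mm lumen radius along arclength: a scalar, a function of the
#'   arclength fraction in `[0, 1]`, or a numeric vector interpolated over
#'   arclength. Values must lie in `[0.35, 3]` mm (vessel diameters of
#'   0.7--6.0 mm).
#' @param stenosis optional `list(center = frac, width = frac, depth = frac)`
#'   multiplying the radius by `1 - depth` at the dip centre with a smooth
#'   cosine profile; `depth = 0.5` halves the radius (a 50\% stenosis).
#' @param wall_thickness_vox intima shell thickness in voxels, one of 2, 3, 4.
#' @param intensity_means named numeric: `background`, `lumen`, `wall`,
#'   `calcification`. Must satisfy calcification > lumen > wall >= background
#'   (plaque is hyperdense; the wall obscures the boundary).
#' @param plaque_spec list of calcified arcs, each a list with `arc = c(t0,
#'   t1)` (arclength fractions), `angle_deg = c(a0, a1)` (angular range in the
#'   cross-sectional plane), `thickness_mm` (radial thickness).
#' @param noise_variance Gaussian noise variance added by
#'   [generate_phantom()]; 0 keeps the volume noise-free.
#' @param blur_sigma_vox optional Gaussian partial-volume blur (in voxels) of
#'   the piecewise-constant image before noise; 0 (off) by default.
#' @param seed integer seed driving the noise field.
#' @return A validated list of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(grid_shape = c(32, 32, 32), radius_mm = 1.5)
phantom_config <- function(grid_shape = c(48, 48, 48),
                           spacing_mm = 0.7,
                           axis_spec = list(type = "straight"),
                           radius_mm = 2,
                           stenosis = NULL,
                           wall_thickness_vox = 3,
                           intensity_means = c(background = 40, lumen = 250,
                                               wall = 120, calcification = 1100),
                           plaque_spec = list(),
                           noise_variance = 0,
                           blur_sigma_vox = 0,
                           seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 4L)) stop("grid_shape too small")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (!wall_thickness_vox %in% c(2L, 3L, 4L))
    stop("wall_thickness_vox must be 2, 3 or 4")
  im <- intensity_means
  need <- c("background", "lumen", "wall", "calcification")
  if (!all(need %in% names(im))) stop("intensity_means must name ", paste(need, collapse = ", "))
  if (!(im["calcification"] > im["lumen"] && im["lumen"] > im["wall"] &&
        im["wall"] >= im["background"]))
    stop("intensity ordering must satisfy calcification > lumen > wall >= background")
  if (is.numeric(radius_mm)) {
    if (any(radius_mm < 0.35 - 1e-12) || any(radius_mm > 3 + 1e-12))
      stop("radius_mm values must lie in [0.35, 3] mm")
  }
  if (!is.null(stenosis)) {
    stopifnot(is.list(stenosis), stenosis$depth >= 0, stenosis$depth < 1)
  }
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 axis_spec = axis_spec, radius_mm = radius_mm,
                 stenosis = stenosis,
                 wall_thickness_vox = as.integer(wall_thickness_vox),
                 intensity_means = im, plaque_spec = plaque_spec,
                 noise_variance = noise_variance,
                 blur_sigma_vox = blur_sigma_vox, seed = as.integer(seed)),
            class = "phantom_config")
}

# Build branch polylines (world mm) from an axis_spec.
phantom_axes <- function(config) {
  spec <- config$axis_spec
  if (is.matrix(spec)) return(list(unname(spec)))
  extent <- (config$grid_shape - 1) * config$spacing_mm
  margin <- if (!is.null(spec$margin_vox)) spec$margin_vox else 10
  z0 <- margin * config$spacing_mm[3]
  z1 <- extent[3] - margin * config$spacing_mm[3]
  if (z1 <= z0) stop("grid too small for the requested axis margin")
  step <- min(config$spacing_mm)
  zs <- seq(z0, z1, by = step)
  cx <- extent[1] / 2; cy <- extent[2] / 2
  type <- spec$type %||% "straight"
  if (type == "straight") {
    list(cbind(cx, cy, zs))
  } else if (type == "helical") {
    amp <- spec$amplitude_mm %||% 1.5
    turns <- spec$turns %||% 1
    ph <- 2 * pi * turns * (zs - z0) / (z1 - z0)
    list(cbind(cx + amp * cos(ph), cy + amp * sin(ph), zs))
  } else if (type == "bifurcating") {
    ang <- (spec$branch_angle_deg %||% 25) * pi / 180
    zb <- (z0 + z1) / 2
    zp <- zs[zs <= zb]
    zc <- zs[zs > zb]
    parent <- cbind(cx, cy, zp)
    dx <- tan(ang) * (zc - zb)
    child1 <- cbind(cx + dx, cy, zc)
    child2 <- cbind(cx - dx, cy, zc)
    list(rbind(parent, child1), rbind(parent[nrow(parent), , drop = FALSE], child2))
  } else stop("unknown axis type: ", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radius (mm) at arclength fractions t in [0,1].
eval_radius <- function(config, t) {
  r <- config$radius_mm
  base <- if (is.function(r)) {
    r(t)
  } else if (length(r) == 1L) {
    rep(r, length(t))
  } else {
    stats::approx(seq(0, 1, length.out = length(r)), r, xout = t, rule = 2)$y
  }
  st <- config$stenosis
  if (!is.null(st)) {
    u <- (t - st$center) / (st$width / 2)
    dip <- ifelse(abs(u) < 1, st$depth * (cos(u * pi) + 1) / 2, 0)
    base <- base * (1 - dip)
  }
  pmax(base, 0.05)
}

# For every voxel: distance to the nearest axis segment, the arclength
# fraction there, and the angular coordinate in the transported frame.
polyline_field <- function(config, axes) {
  d <- config$grid_shape; sp <- config$spacing_mm
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  P <- cbind(rep(xs, times = d[2] * d[3]),
             rep(rep(ys, each = d[1]), times = d[3]),
             rep(zs, each = d[1] * d[2]))
  n <- nrow(P)
  best_d2 <- rep(Inf, n); best_t <- numeric(n); best_ang <- numeric(n)
  for (axis in axes) {
    if (nrow(axis) < 2) next
    tang <- axis_tangents(axis)
    frames <- parallel_transport_frames(axis, tang)
    seg <- diff(axis)
    seglen <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(seglen))
    total <- cum[length(cum)]
    nseg <- nrow(seg)
    ax_d2 <- rep(Inf, n); ax_t <- numeric(n); ax_ang <- numeric(n)
    for (s in seq_len(nseg)) {
      a <- axis[s, ]; u <- seg[s, ]; L2 <- sum(u^2)
      w1 <- P[, 1] - a[1]; w2 <- P[, 2] - a[2]; w3 <- P[, 3] - a[3]
      tt <- pmin(pmax((w1 * u[1] + w2 * u[2] + w3 * u[3]) / L2, 0), 1)
      dx <- w1 - tt * u[1]; dy <- w2 - tt * u[2]; dz <- w3 - tt * u[3]
      d2 <- dx * dx + dy * dy + dz * dz
      upd <- d2 < ax_d2
      if (any(upd)) {
        ax_d2[upd] <- d2[upd]
        ax_t[upd] <- (cum[s] + tt[upd] * seglen[s]) / total
        U <- frames$u[s, ]; V <- frames$v[s, ]
        ax_ang[upd] <- atan2(dx[upd] * V[1] + dy[upd] * V[2] + dz[upd] * V[3],
                             dx[upd] * U[1] + dy[upd] * U[2] + dz[upd] * U[3])
      }
    }
    # flat tube ends: voxels beyond the terminal cross-section planes do not
    # belong to this branch (end discs lie in the terminal cross-sections,
    # which the ray casting covers; spherical caps would not be)
    lo <- (P[, 1] - axis[1, 1]) * tang[1, 1] + (P[, 2] - axis[1, 2]) * tang[1, 2] +
      (P[, 3] - axis[1, 3]) * tang[1, 3]
    hi <- (P[, 1] - axis[nrow(axis), 1]) * tang[nrow(axis), 1] +
      (P[, 2] - axis[nrow(axis), 2]) * tang[nrow(axis), 2] +
      (P[, 3] - axis[nrow(axis), 3]) * tang[nrow(axis), 3]
    tol <- 1e-9
    ax_d2[lo < -tol | hi > tol] <- Inf
    upd <- ax_d2 < best_d2
    best_d2[upd] <- ax_d2[upd]; best_t[upd] <- ax_t[upd]; best_ang[upd] <- ax_ang[upd]
  }
  list(dist = sqrt(best_d2), t = best_t, ang = best_ang * 180 / pi)
}

#' Generate a synthetic vessel phantom
#'
#' Deterministic for a fixed config: the tissue-label volume and the noiseless
#' intensity image depend only on the geometry, and the noise field only on
#' `config$seed`. Labels are 0 background/adventitia, 1 lumen, 2 intima,
#' 3 pathology; the intima is a shell of `wall_thickness_vox` voxels around
#' the lumen and pathology is only ever placed outside the intima.
#'
#' @param config a [phantom_config()].
#' @return A list of class `vessel_phantom` with elements `volume` ([vol3d]),
#'   `labels` ([vol3d] of integer codes), `axes` (list of n x 3 matrices, mm),
#'   and `config`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
#'                                       axis_spec = list(type = "straight",
#'                                                        margin_vox = 4),
#'                                       radius_mm = 1.5))
#' table(ph$labels$data)
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop("'config' must be a phantom_config")
  axes <- phantom_axes(config)
  extent <- (config$grid_shape - 1) * config$spacing_mm
  for (axis in axes) {
    out <- axis[, 1] < 0 | axis[, 1] > extent[1] |
      axis[, 2] < 0 | axis[, 2] > extent[2] |
      axis[, 3] < 0 | axis[, 3] > extent[3]
    if (any(out)) {
      p <- axis[which(out)[1], ]
      stop(sprintf("axis point (%.2f, %.2f, %.2f) mm exits the grid", p[1], p[2], p[3]))
    }
  }
  fld <- polyline_field(config, axes)
  r <- eval_radius(config, fld$t)
  wall_mm <- config$wall_thickness_vox * min(config$spacing_mm)
  lab <- integer(length(fld$dist))
  lab[fld$dist <= r + wall_mm] <- 2L
  lab[fld$dist <= r] <- 1L
  # calcified plaque arcs, strictly outside the intima shell
  for (pl in config$plaque_spec) {
    th <- pl$thickness_mm %||% 1.5
    a0 <- pl$angle_deg[1]; a1 <- pl$angle_deg[2]
    ang <- (fld$ang - a0) %% 360
    span <- (a1 - a0) %% 360
    if (span == 0) span <- 360
    sel <- fld$t >= pl$arc[1] & fld$t <= pl$arc[2] &
      ang <= span &
      fld$dist > r + wall_mm & fld$dist <= r + wall_mm + th &
      lab == 0L
    lab[sel] <- 3L
  }
  labels <- array(lab, config$grid_shape)
  # the voxel containing each axis point is lumen by construction
  for (axis in axes) {
    idx <- round(sweep(axis, 2, config$spacing_mm, "/")) + 1
    storage.mode(idx) <- "integer"
    labels[idx] <- 1L
  }
  im <- config$intensity_means
  vals <- c(im[["background"]], im[["lumen"]], im[["wall"]], im[["calcification"]])
  vol <- array(vals[labels + 1L], config$grid_shape)
  if (config$blur_sigma_vox > 0)
    vol <- gaussian_blur(vol, config$blur_sigma_vox)
  volume <- vol3d(vol, config$spacing_mm)
  if (config$noise_variance > 0)
    volume <- add_gaussian_noise(volume, config$noise_variance, config$seed)
  structure(list(volume = volume,
                 labels = vol3d(labels, config$spacing_mm),
                 axes = axes, config = config),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  d <- x$config$grid_shape
  cat(sprintf("<vessel_phantom> %d x %d x %d voxels, %d ax%s, noise var %.3g\n",
              d[1], d[2], d[3], length(x$axes),
              if (length(x$axes) == 1) "is" else "es",
              x$config$noise_variance))
  print(table(factor(x$labels$data, levels = 0:3,
                     labels = c("background", "lumen", "intima", "pathology"))))
  invisible(x)
}

# separable Gaussian blur in voxel units (isotropic sigma, small kernels)
gaussian_blur <- function(arr, sigma_vox) {
  rad <- max(1L, ceiling(3 * sigma_vox))
  x <- (-rad):rad
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  for (dim_i in 1:3) arr <- conv_along(arr, k, dim_i)
  arr
}

#' Add i.i.d. Gaussian noise to a volume
#'
#' @param volume a [vol3d].
#' @param variance noise variance in squared intensity units; the empirical
#'   variance of the added field matches to within sampling error.
#' @param seed integer seed; the same seed yields an identical noise field.
#' @return A [vol3d] with the noise added.
#' @export
add_gaussian_noise <- function(volume, variance, seed = 1L) {
  stopifnot_vol3d(volume)
  if (variance < 0) stop("variance must be >= 0")
  if (variance == 0) return(volume)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  noise <- array(stats::rnorm(length(volume$data), 0, sqrt(variance)),
                 dim(volume$data))
  vol3d(volume$data + noise, volume$spacing)
}

#' Draw a randomised phantom configuration
#'
#' Samples a training/testing phantom the way the noise-sweep experiment does:
#' straight or gently helical axis, lumen radius 1.2--2.2 mm, optional
#' stenosis dip up to 50\%, and with high probability one calcified arc
#' touching the wall. Wall thickness follows the local radius (2 voxels below
#' 1.5 mm, 3 up to 2.5 mm, 4 above).
#'
#' @param seed integer seed for the draw (and for the phantom's noise field).
#' @param noise_variance noise variance passed through to the config.
#' @param grid_shape,spacing_mm grid geometry.
#' @return A [phantom_config()].
#' @export
random_phantom_config <- function(seed, noise_variance = 0,
                                  grid_shape = c(48, 48, 48), spacing_mm = 0.7) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  radius <- stats::runif(1, 1.2, 2.2)
  wall <- if (radius < 1.5) 2L else if (radius < 2.5) 3L else 4L
  axis_spec <- if (stats::runif(1) < 0.5) list(type = "straight") else
    list(type = "helical", amplitude_mm = stats::runif(1, 0.5, 1.5),
         turns = stats::runif(1, 0.5, 1))
  stenosis <- if (stats::runif(1) < 0.5)
    list(center = stats::runif(1, 0.3, 0.7), width = stats::runif(1, 0.2, 0.4),
         depth = stats::runif(1, 0.2, 0.5)) else NULL
  plaques <- list()
  if (stats::runif(1) < 0.75) {
    t0 <- stats::runif(1, 0.1, 0.6)
    a0 <- stats::runif(1, 0, 360)
    plaques[[1]] <- list(arc = c(t0, t0 + stats::runif(1, 0.2, 0.35)),
                         angle_deg = c(a0, a0 + stats::runif(1, 60, 180)),
                         thickness_mm = stats::runif(1, 1, 2.5))
  }
  phantom_config(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 axis_spec = axis_spec, radius_mm = radius,
                 stenosis = stenosis, wall_thickness_vox = wall,
                 plaque_spec = plaques, noise_variance = noise_variance,
                 seed = seed)
}

#' Write a phantom to disk
#'
#' Volume and labels as NIfTI (spacing in the header), axes as JSON in world
#' (mm) coordinates, and the configuration as YAML.
#'
#' @param phantom a `vessel_phantom`.
#' @param dir output directory (created if missing).
#' @param stem filename stem.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, paste0(stem, "_volume.nii.gz")))
  write_volume(phantom$labels, file.path(dir, paste0(stem, "_labels.nii.gz")))
  write_axes_json(phantom$axes, file.path(dir, paste0(stem, "_axes.json")))
  cfg <- phantom$config
  cfg$axis_spec <- if (is.matrix(cfg$axis_spec)) list(type = "polyline") else cfg$axis_spec
  cfg$radius_mm <- if (is.function(cfg$radius_mm)) "function" else cfg$radius_mm
  yaml::write_yaml(unclass(cfg), file.path(dir, paste0(stem, "_config.yaml")))
  invisible(dir)
}
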