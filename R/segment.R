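#' Decode the rays of one cross-section
#'
#' Casts the 72 rays of the cross-section at `axis_index`, computes the
#' five-feature mixture posterior for each ray and returns the MAP state
#' sequences (plus the cached posterior rows used by the volumetric fusion).
#'
#' @param model an [mhmm] fit.
#' @param volume a [vol3d].
#' @param axis n x 3 matrix of axis points (mm).
#' @param axis_index which cross-section.
#' @param features named list of precomputed multiscale feature [vol3d]s
#'   (from [vessel_features()]); computed on the fly when `NULL`.
#' @param angular_step_deg,n_samples,step_mm ray geometry.
#' @return A list with `states` (rays x samples integer matrix), `posteriors`
#'   (one n x 4 matrix per ray) and the `rays`.
#' @export
segment_cross_section <- function(model, volume, axis, axis_index,
                                  features = NULL, angular_step_deg = 5,
                                  n_samples = 18, step_mm = NULL) {
  if (is.null(features)) features <- standardize_features(vessel_features(volume), axis)
  if (is.null(step_mm)) step_mm <- min(volume$spacing)
  frame <- cross_section_frame(axis, axis_index)
  rays <- cast_rays(frame, angular_step_deg, n_samples, step_mm)
  posts <- vector("list", length(rays))
  states <- matrix(0L, length(rays), n_samples)
  for (r in seq_along(rays)) {
    fs <- lapply(features, function(f) interp_trilinear(f, rays[[r]]$points))
    sm <- mhmm_posterior(model, fs)
    posts[[r]] <- sm$posteriors
    states[r, ] <- map_decode(sm)
  }
  list(states = states, posteriors = posts, rays = rays)
}

#' Fuse per-sample posteriors into a label volume
#'
#' Every ray sample is assigned to its nearest voxel; for each voxel touched
#' by at least one sample the mean of the contributing 4-vector posteriors is
#' taken and the state with maximum mean similarity wins (ties toward the
#' lower state index -- a lumen/intima tie is vessel either way). Voxels
#' never sampled by any ray are background/adventitia (0): the classifier is
#' deliberately axis-constrained.
#'
#' @param posteriors n x 4 matrix of posterior rows.
#' @param points n x 3 matrix of world sample positions (mm).
#' @param template a [vol3d] defining the grid.
#' @return A [vol3d] of integer labels (0 background/adventitia, 1 lumen,
#'   2 intima, 3 pathology).
#' @export
fuse_labels <- function(posteriors, points, template) {
  stopifnot_vol3d(template)
  d <- dim(template$data)
  idx <- nearest_voxel_index(template, points)
  lin <- idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
  sums <- rowsum(posteriors, group = lin)
  cnt <- as.numeric(rowsum(rep(1, length(lin)), group = lin))
  means <- sums / cnt
  state <- max.col(means, ties.method = "first")   # 1 lumen .. 4 adventitia
  lab <- array(0L, d)
  lab[as.numeric(rownames(sums))] <- ifelse(state == 4L, 0L, state)
  vol3d(lab, template$spacing)
}

#' Segment a vessel volume along its axis
#'
#' The full detection pass: a cross-section at every axis point, 72 rays per
#' cross-section, five-feature mixture posteriors per ray, MAP decoding, and
#' per-voxel posterior-mean fusion. The final vessel mask is the union of the
#' fused lumen and intima states.
#'
#' @inheritParams segment_cross_section
#' @param axes one axis matrix or a list of branch axes.
#' @return A list of class `vessel_segmentation`: `labels` (fused 4-class
#'   [vol3d]), `vessel` (binary [vol3d]), `series` (the decoded series
#'   table).
#' @export
segment_vessel <- function(model, volume, axes, features = NULL,
                           angular_step_deg = 5, n_samples = 18, step_mm = NULL) {
  stopifnot_vol3d(volume)
  if (is.matrix(axes)) axes <- list(axes)
  if (is.null(features)) features <- standardize_features(vessel_features(volume), axes)
  if (is.null(step_mm)) step_mm <- min(volume$spacing)
  tabs <- lapply(seq_along(axes), function(b)
    collect_series(volume, axes[[b]], labels = NULL, features = features,
                   angular_step_deg = angular_step_deg, n_samples = n_samples,
                   step_mm = step_mm, phantom_id = paste0("branch", b)))
  tab <- do.call(rbind, tabs)
  tab <- tab[order(tab$series_uid, tab$sample_index), , drop = FALSE]
  post <- predict(model, tab, type = "posterior")
  tab$state <- map_decode(post)
  labels <- fuse_labels(post, as.matrix(tab[, c("x", "y", "z")]), volume)
  vessel <- vol3d(array(as.integer(labels$data == 1L | labels$data == 2L),
                        dim(labels$data)), volume$spacing)
  structure(list(labels = labels, vessel = vessel, series = tab),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("<vessel_segmentation> %d vessel voxels of %d\n",
              sum(x$vessel$data), length(x$vessel$data)))
  invisible(x)
}
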