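#' Dice overlap coefficient in percent
#'
#' `100 * 2|A∩B| / (|A| + |B|)`; two empty masks overlap perfectly (100).
#'
#' @param seg,ref binary masks: logical/integer arrays or [vol3d]s on the
#'   same grid.
#' @return Percent overlap in `[0, 100]`.
#' @export
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
#' dice_overlap(a, a)   # 100
dice_overlap <- function(seg, ref) {
  seg <- as_mask(seg); ref <- as_mask(ref)
  if (!identical(dim(seg), dim(ref))) stop("mask shapes differ")
  na <- sum(seg); nb <- sum(ref)
  if (na + nb == 0) return(100)
  100 * 2 * sum(seg & ref) / (na + nb)
}

as_mask <- function(x) {
  if (is_vol3d(x)) x <- x$data
  if (!is.array(x)) stop("mask must be an array or vol3d")
  x != 0
}

# boundary voxels by 6-connectivity erosion difference: a mask voxel is
# boundary if any face neighbour (or the outside of the grid) is background
boundary_mask <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift_and <- function(m, dim_i, by) {
    n <- d[dim_i]
    idx <- seq_len(n) + by
    pad <- idx < 1L | idx > n
    idx <- pmin(pmax(idx, 1L), n)
    s <- switch(dim_i, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                m[, , idx, drop = FALSE])
    if (any(pad)) {
      switch(dim_i,
             s[pad, , ] <- FALSE,
             s[, pad, ] <- FALSE,
             s[, , pad] <- FALSE)
    }
    s
  }
  for (dim_i in 1:3) for (by in c(-1L, 1L)) {
    interior <- interior & shift_and(mask, dim_i, by)
  }
  mask & !interior
}

#' Average symmetric surface distance in mm
#'
#' Boundary voxel sets are taken by 6-connectivity erosion difference; the
#' symmetric mean of nearest-boundary distances is computed exactly (pairwise,
#' spacing-aware) between the two sets.
#'
#' @param seg,ref nonempty binary masks ([vol3d] or array).
#' @param spacing voxel size in mm (taken from `seg` when it is a [vol3d]).
#' @return Distance in mm (0 for identical masks).
#' @export
average_surface_distance <- function(seg, ref, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- if (is_vol3d(seg)) seg$spacing else c(1, 1, 1)
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  seg <- as_mask(seg); ref <- as_mask(ref)
  if (!identical(dim(seg), dim(ref))) stop("mask shapes differ")
  if (!any(seg) || !any(ref)) stop("masks must be nonempty")
  pa <- boundary_points_mm(seg, spacing)
  pb <- boundary_points_mm(ref, spacing)
  da <- nearest_distances(pa, pb)
  db <- nearest_distances(pb, pa)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

boundary_points_mm <- function(mask, spacing) {
  b <- which(boundary_mask(mask), arr.ind = TRUE)
  sweep(b - 1, 2, spacing, "*")
}

# exact nearest-neighbour distances from each row of a to the set b,
# chunked so the pairwise matrix stays small
nearest_distances <- function(a, b, chunk = 1024L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    aa <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), nb2, "+") - 2 * tcrossprod(aa, b)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Paired two-sided t-test on segmentation scores
#'
#' Compares two score lists paired by dataset, flagging significance at
#' `p < 0.05`. Degenerate cases: all differences zero gives `p = 1`; a
#' nonzero constant difference gives `p = 0` (the zero-variance limit).
#'
#' @param scores_a,scores_b equal-length numeric vectors (n >= 2).
#' @param alpha significance level.
#' @return A list with `p_value`, `statistic`, `df`, `mean_difference`,
#'   `significant`.
#' @export
paired_t_test <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b)) stop("score lists must be paired")
  if (length(scores_a) < 2) stop("need at least 2 pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
    return(list(p_value = p, statistic = if (p == 1) 0 else Inf,
                df = length(d) - 1, mean_difference = mean(d),
                significant = p < alpha))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       df = unname(tt$parameter), mean_difference = unname(tt$estimate),
       significant = tt$p.value < alpha)
}

#' Evaluate a segmentation against a reference
#'
#' @param seg,ref binary masks ([vol3d] or array).
#' @param spacing voxel size in mm.
#' @return A list with `doc_percent` and `asd_mm`.
#' @export
evaluate_segmentation <- function(seg, ref, spacing = NULL) {
  list(doc_percent = dice_overlap(seg, ref),
       asd_mm = average_surface_distance(seg, ref, spacing))
}
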