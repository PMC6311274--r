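#' 3-D scalar volume with anisotropic voxel spacing
#'
#' A `vol3d` is the package's lightweight container for a 3-D image grid: a
#' numeric array plus a per-axis voxel size in millimetres. Voxel `(i, j, k)`
#' (1-based) has its centre at world coordinate `((i-1)*sx, (j-1)*sy,
#' (k-1)*sz)` mm. Label volumes use the same container with integer codes
#' 0 = background/adventitia, 1 = lumen, 2 = intima, 3 = pathology.
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3 voxel size in mm (recycled if length 1).
#' @return An object of class `vol3d`.
#' @export
#' @examples
#' v <- vol3d(array(0, c(8, 8, 8)), spacing = 0.7)
#' dim(v$data)
vol3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be positive and finite")
  structure(list(data = data, spacing = spacing), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

is_vol3d <- function(x) inherits(x, "vol3d")

stopifnot_vol3d <- function(x, what = "volume") {
  if (!is_vol3d(x)) stop("'", what, "' must be a vol3d object")
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that carry the voxel spacing through the
#' NIfTI header (`pixdim`).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [vol3d] object.
#' @return `read_volume()` returns a [vol3d]; `write_volume()` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume: ", path)
  vol3d(arr, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot_vol3d(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write vessel axes as JSON
#'
#' Axes are stored as `[{"points": [[x,y,z], ...]}, ...]` in world (mm)
#' coordinates.
#'
#' @param path file path.
#' @param axes a single axis matrix (n x 3) or a list of them.
#' @return `read_axes_json()` returns a list of n x 3 matrices.
#' @export
read_axes_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  pts <- obj$points
  if (is.null(pts)) stop("no 'points' field in ", path)
  if (!is.list(pts)) pts <- list(pts)
  lapply(pts, function(p) {
    m <- matrix(as.numeric(p), ncol = 3)
    colnames(m) <- c("x", "y", "z")
    m
  })
}

#' @rdname read_axes_json
#' @export
write_axes_json <- function(axes, path) {
  if (is.matrix(axes)) axes <- list(axes)
  obj <- data.frame(points = I(lapply(axes, function(a) unname(as.matrix(a)))))
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Trilinear interpolation of a volume at world points
#'
#' Values outside the grid raise an error: silently padding or clamping would
#' corrupt the observation statistics fed to the classifier.
#'
#' @param vol a [vol3d].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return numeric vector of length n.
#' @export
interp_trilinear <- function(vol, points) {
  stopifnot_vol3d(vol)
  points <- rbind(points)
  d <- dim(vol$data)
  # continuous 1-based voxel index
  ix <- points[, 1] / vol$spacing[1] + 1
  iy <- points[, 2] / vol$spacing[2] + 1
  iz <- points[, 3] / vol$spacing[3] + 1
  eps <- 1e-9
  out <- ix < 1 - eps | ix > d[1] + eps | iy < 1 - eps | iy > d[2] + eps |
    iz < 1 - eps | iz > d[3] + eps
  if (any(out)) {
    i <- which(out)[1]
    stop(sprintf("sample point (%.3f, %.3f, %.3f) mm lies outside the volume",
                 points[i, 1], points[i, 2], points[i, 3]))
  }
  ix <- pmin(pmax(ix, 1), d[1]); iy <- pmin(pmax(iy, 1), d[2])
  iz <- pmin(pmax(iz, 1), d[3])
  x0 <- pmin(floor(ix), d[1] - 1L); y0 <- pmin(floor(iy), d[2] - 1L)
  z0 <- pmin(floor(iz), d[3] - 1L)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  at <- function(i, j, k) vol$data[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);         v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0);     v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1);     v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Nearest-voxel lookup at world points
#'
#' @inheritParams interp_trilinear
#' @return for `nearest_voxel_index()`, an n x 3 integer matrix of 1-based
#'   voxel indices; for `interp_nearest()`, the stored values at those voxels.
#' @export
nearest_voxel_index <- function(vol, points) {
  stopifnot_vol3d(vol)
  points <- rbind(points)
  d <- dim(vol$data)
  idx <- round(sweep(points, 2, vol$spacing, "/")) + 1
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("sample point (%.3f, %.3f, %.3f) mm lies outside the volume",
                 points[i, 1], points[i, 2], points[i, 3]))
  }
  storage.mode(idx) <- "integer"
  idx
}

#' @rdname nearest_voxel_index
#' @export
interp_nearest <- function(vol, points) {
  vol$data[nearest_voxel_index(vol, points)]
}
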