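#' Scale schedule and parameters for the vesselness features
#'
#' The scale schedule `s = 0.6 * 2^((w-1)/2)`, `w = 1..6` (mm) covers vessel
#' diameters from 0.7 to 6 mm; `alpha1`/`alpha2` drive the Sato response and
#' `alpha`/`beta` the Frangi/Manniesing ratios. `gamma` (the structureness
#' scale) is recomputed from the Hessian of each volume at each scale; `c`
#' (the Manniesing noise sensitivity) defaults to `gamma / 2` when left
#' `NULL`.
#'
#' @param alpha1,alpha2 Sato exponent parameters, `alpha1 < alpha2`.
#' @param alpha,beta Frangi/Manniesing ratio parameters.
#' @param gamma structureness scale; `NULL` means compute per volume/scale.
#' @param c Manniesing sensitivity; `NULL` means `gamma / 2`.
#' @param scales_mm the multiscale schedule (6 scales by default).
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(alpha1 = 0.5, alpha2 = 2, alpha = 0.5, beta = 0.5,
                           gamma = NULL, c = NULL,
                           scales_mm = default_scales()) {
  if (!(alpha1 < alpha2)) stop("alpha1 must be < alpha2")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha = alpha, beta = beta,
                 gamma = gamma, c = c, scales_mm = scales_mm),
            class = "feature_params")
}

#' @rdname feature_params
#' @export
default_scales <- function() 0.6 * 2^((1:6 - 1) / 2)

#' Feature identifiers
#' @return Character vector of the five vesselness feature names.
#' @export
feature_names <- function() c("sato", "frangi", "shikata", "li", "manniesing")

# ---- separable correlation machinery -------------------------------------

# correlate arr with kernel k along dimension dim_i, replicate-edge padding;
# k has odd length with offsets -(r)..r
conv_along <- function(arr, k, dim_i) {
  d <- dim(arr)
  n <- d[dim_i]
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (j in seq_along(k)) {
    if (k[j] == 0) next
    idx <- pmin(pmax(base + (j - r - 1L), 1L), n)
    out <- out + k[j] * switch(dim_i,
                               arr[idx, , , drop = FALSE],
                               arr[, idx, , drop = FALSE],
                               arr[, , idx, drop = FALSE])
  }
  out
}

# Gaussian (order 0/1/2) correlation kernels sampled at voxel pitch h with
# standard deviation sigma (both mm). Discrete calibration: order 0 sums to
# one; order 1 is zero-mean and reproduces unit slope on a ramp; order 2 is
# zero-mean and reproduces d2/dx2 x^2 = 2.
gauss_kernel <- function(sigma, h, order = 0L) {
  r <- max(2L, ceiling(3.5 * sigma / h))
  x <- (-r):r * h
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    k <- x / sigma^2 * g          # correlation kernel for d/dx (note sign)
    k <- k - mean(k)
    k / sum(k * x)
  } else {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)
    k * (2 / sum(k * x^2))
  }
}

# all six Hessian components of a volume at scale s (mm); spacing-aware
hessian_components <- function(vol, scale_s) {
  sp <- vol$spacing
  k0 <- lapply(1:3, function(d) gauss_kernel(scale_s, sp[d], 0L))
  k1 <- lapply(1:3, function(d) gauss_kernel(scale_s, sp[d], 1L))
  k2 <- lapply(1:3, function(d) gauss_kernel(scale_s, sp[d], 2L))
  a <- vol$data
  smooth_except <- function(x, skip) {
    for (d in setdiff(1:3, skip)) x <- conv_along(x, k0[[d]], d)
    x
  }
  H <- list()
  H$h11 <- smooth_except(conv_along(a, k2[[1]], 1L), 1L)
  H$h22 <- smooth_except(conv_along(a, k2[[2]], 2L), 2L)
  H$h33 <- smooth_except(conv_along(a, k2[[3]], 3L), 3L)
  H$h12 <- smooth_except(conv_along(conv_along(a, k1[[1]], 1L), k1[[2]], 2L), c(1L, 2L))
  H$h13 <- smooth_except(conv_along(conv_along(a, k1[[1]], 1L), k1[[3]], 3L), c(1L, 3L))
  H$h23 <- smooth_except(conv_along(conv_along(a, k1[[2]], 2L), k1[[3]], 3L), c(2L, 3L))
  H
}

# closed-form eigenvalues of many symmetric 3x3 matrices (vectors of the six
# components), polished by two Newton steps on the characteristic polynomial;
# returns a list of three vectors sorted descending by value
sym3_eigenvalues <- function(h11, h22, h33, h12, h13, h23) {
  q <- (h11 + h22 + h33) / 3
  p1 <- h12^2 + h13^2 + h23^2
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (h11 - q) / safe_p; b22 <- (h22 - q) / safe_p; b33 <- (h33 - q) / safe_p
  b12 <- h12 / safe_p; b13 <- h13 / safe_p; b23 <- h23 / safe_p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  # Newton polish on p(x) = -x^3 + c2 x^2 - c1 x + c0
  c2 <- h11 + h22 + h33
  c1 <- h11 * h22 + h11 * h33 + h22 * h33 - h12^2 - h13^2 - h23^2
  c0 <- h11 * (h22 * h33 - h23^2) - h12 * (h12 * h33 - h23 * h13) +
    h13 * (h12 * h23 - h22 * h13)
  polish <- function(x) {
    for (i in 1:2) {
      f <- ((-x + c2) * x - c1) * x + c0
      fp <- -3 * x^2 + 2 * c2 * x - c1
      ok <- abs(fp) > 1e-30
      x <- ifelse(ok, x - f / fp, x)
    }
    x
  }
  e1 <- polish(e1); e2 <- polish(e2); e3 <- polish(e3)
  l1 <- pmax(e1, e2, e3)
  l3 <- pmin(e1, e2, e3)
  l2 <- e1 + e2 + e3 - l1 - l3
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Hessian eigenvalues of a volume at one scale
#'
#' Second derivatives are Gaussian derivatives computed in mm (spacing-aware)
#' at standard deviation `scale_s`; eigenvalues are sorted descending by value
#' (`lambda1 > lambda2 > lambda3`), so the two cross-sectional eigenvalues of
#' a bright tube are the negative `lambda2`, `lambda3`.
#'
#' @param volume a [vol3d].
#' @param scale_s Gaussian standard deviation in mm (> 0).
#' @return A list of class `hessian_eigs` with arrays `lambda1`, `lambda2`,
#'   `lambda3` and the scalar `scale_s`.
#' @export
hessian_eigenvalues <- function(volume, scale_s) {
  stopifnot_vol3d(volume)
  if (scale_s <= 0) stop("scale_s must be positive")
  H <- hessian_components(volume, scale_s)
  ev <- sym3_eigenvalues(H$h11, H$h22, H$h33, H$h12, H$h13, H$h23)
  structure(list(lambda1 = array(ev$l1, dim(volume$data)),
                 lambda2 = array(ev$l2, dim(volume$data)),
                 lambda3 = array(ev$l3, dim(volume$data)),
                 scale_s = scale_s),
            class = "hessian_eigs")
}

#' Structureness scale gamma from a volume's Hessian
#'
#' Half the maximum Frobenius norm of the Hessian over the whole image at the
#' given scale. A constant volume yields 0; the downstream structureness term
#' is then defined as 1.
#'
#' @inheritParams hessian_eigenvalues
#' @return A scalar.
#' @export
gamma_from_volume <- function(volume, scale_s) {
  gamma_from_eigs(hessian_eigenvalues(volume, scale_s))
}

gamma_from_eigs <- function(eigs) {
  0.5 * sqrt(max(eigs$lambda1^2 + eigs$lambda2^2 + eigs$lambda3^2))
}

# ---- the five single-scale responses -------------------------------------
# Each returns the magnitude of its formula's value, with the eigen-sign
# guards applied first; bright tubes then map to large positive responses
# suitable for binning.

#' Sato vesselness response at one scale
#'
#' `|lambda2| * exp(-lambda1^2 / (2 a^2 lambda2^2))` with `a = alpha1` where
#' `lambda1 <= 0` and `a = alpha2` where `lambda1 > 0`; 0 where `lambda2 = 0`.
#'
#' @param eigs a `hessian_eigs` from [hessian_eigenvalues()] (or any list with
#'   `lambda1..lambda3` arrays).
#' @param params a [feature_params()].
#' @return Array of nonnegative responses.
#' @export
sato_feature <- function(eigs, params = feature_params()) {
  l1 <- eigs$lambda1; l2 <- eigs$lambda2
  a <- ifelse(l1 <= 0, params$alpha1, params$alpha2)
  out <- ifelse(l2 == 0, 0, abs(l2) * exp(-l1^2 / (2 * a^2 * pmax(l2^2, 1e-300))))
  array(out, dim(l1))
}

# magnitude-sorted |lambda| triple and the Frangi-form factors; R_A and R_B
# use magnitude ordering (|m1| <= |m2| <= |m3|) as in the original filter
frangi_factors <- function(eigs, params, gamma) {
  a1 <- abs(eigs$lambda1); a2 <- abs(eigs$lambda2); a3 <- abs(eigs$lambda3)
  m3 <- pmax(a1, a2, a3)
  m1 <- pmin(a1, a2, a3)
  m2 <- a1 + a2 + a3 - m1 - m3
  S2 <- a1^2 + a2^2 + a3^2
  RA2 <- ifelse(m3 > 0, (m2 / m3)^2, 0)
  RB2 <- ifelse(m2 * m3 > 0, m1^2 / (m2 * m3), 0)
  s_term <- if (gamma > 0) 1 - exp(-S2 / (2 * gamma^2)) else 1
  list(plate = 1 - exp(-RA2 / (2 * params$alpha^2)),
       blob = exp(-RB2 / (2 * params$beta^2)),
       noise = s_term, m2 = m2, m3 = m3)
}

#' Frangi vesselness response at one scale
#'
#' `(1 - exp(-R_A^2/2a^2)) * exp(-R_B^2/2b^2) * (1 - exp(-S^2/2g^2))`, zero
#' where `lambda2 > 0` or `lambda3 > 0`. The ratios use magnitude-sorted
#' eigenvalues; the zero-guard uses the value-sorted convention.
#'
#' @inheritParams sato_feature
#' @param gamma structureness scale; computed from `eigs` when `NULL`.
#' @return Array of responses in `[0, 1]`.
#' @export
frangi_feature <- function(eigs, params = feature_params(), gamma = NULL) {
  if (is.null(gamma)) gamma <- params$gamma %||% gamma_from_eigs(eigs)
  ff <- frangi_factors(eigs, params, gamma)
  out <- ff$plate * ff$blob * ff$noise
  out[eigs$lambda2 > 0 | eigs$lambda3 > 0] <- 0
  array(out, dim(eigs$lambda1))
}

#' Shikata vesselness response at one scale
#'
#' `s^2 * |lambda2| / I(x)`, assuming a 2-D Gaussian cross-sectional intensity
#' profile; sensitive to small vessels. Intensities are shifted so the
#' minimum is at least 1 before dividing (CT values can be non-positive).
#'
#' @param volume the [vol3d] the eigenvalues came from.
#' @inheritParams sato_feature
#' @return Array of nonnegative responses.
#' @export
shikata_feature <- function(volume, eigs) {
  stopifnot_vol3d(volume)
  i_off <- volume$data + max(0, 1 - min(volume$data))
  array(eigs$scale_s^2 * abs(eigs$lambda2) / i_off, dim(volume$data))
}

#' Li vesselness response at one scale
#'
#' `lambda2 (lambda2 - lambda3) / lambda1` where `lambda1 < 0` and
#' `lambda2 < 0`, 0 otherwise.
#'
#' @inheritParams sato_feature
#' @return Array of nonnegative responses.
#' @export
li_feature <- function(eigs) {
  l1 <- eigs$lambda1; l2 <- eigs$lambda2; l3 <- eigs$lambda3
  out <- ifelse(l1 < 0 & l2 < 0, abs(l2 * (l2 - l3) / l1), 0)
  array(out, dim(l1))
}

#' Manniesing vesselness response at one scale
#'
#' The Frangi-form response multiplied by the noise-suppression factor
#' `exp(-2c^2 / (|lambda2| lambda3^2))` of the vessel-enhancing-diffusion
#' filter, zero where `lambda2 >= 0` or `lambda3 >= 0`. The factor tends to 1
#' for strong second-order structure and crushes weak (noise) responses; it
#' increases as `c` decreases and equals 1 in the `c -> 0` limit.
#'
#' @inheritParams frangi_feature
#' @param c sensitivity; `params$c`, or `gamma / 2` when both are `NULL`.
#' @return Array of responses in `[0, 1]`.
#' @export
manniesing_feature <- function(eigs, params = feature_params(), gamma = NULL,
                               c = NULL) {
  if (is.null(gamma)) gamma <- params$gamma %||% gamma_from_eigs(eigs)
  if (is.null(c)) c <- params$c %||% (gamma / 2)
  ff <- frangi_factors(eigs, params, gamma)
  x <- abs(eigs$lambda2) * eigs$lambda3^2
  supp <- ifelse(x > 0, exp(-2 * c^2 / pmax(x, 1e-300)), 0)
  if (c == 0) supp <- ifelse(x > 0, 1, 0)
  out <- ff$plate * ff$blob * ff$noise * supp
  out[eigs$lambda2 >= 0 | eigs$lambda3 >= 0] <- 0
  array(out, dim(eigs$lambda1))
}

# ---- multiscale -----------------------------------------------------------

# scale-normalised eigenvalues (Lindeberg s^2 normalisation) make responses
# comparable across the schedule; Shikata's own s^2 factor is exactly this
# normalisation, so all five features share the normalised eigenvolumes
normalized_eigs <- function(volume, s) {
  e <- hessian_eigenvalues(volume, s)
  e$lambda1 <- s^2 * e$lambda1
  e$lambda2 <- s^2 * e$lambda2
  e$lambda3 <- s^2 * e$lambda3
  e
}

single_scale_response <- function(feature_id, volume, eigs, params) {
  switch(feature_id,
         sato = sato_feature(eigs, params),
         frangi = frangi_feature(eigs, params),
         shikata = array(abs(eigs$lambda2) /
                           (volume$data + max(0, 1 - min(volume$data))),
                         dim(volume$data)),
         li = li_feature(eigs),
         manniesing = manniesing_feature(eigs, params),
         stop("unknown feature: ", feature_id))
}

#' Maximum vesselness response over the scale schedule
#'
#' Computes the chosen feature at every scale in `params$scales_mm` on
#' scale-normalised (`s^2`-weighted) Hessian eigenvalues and takes the
#' voxelwise maximum; the structureness scale `gamma` (and Manniesing's `c`)
#' are recomputed per scale.
#'
#' @param volume a [vol3d].
#' @param feature_id one of [feature_names()], or `"all"`.
#' @param params a [feature_params()].
#' @return A [vol3d] response volume, or a named list of them for `"all"`.
#' @export
multiscale_max <- function(volume, feature_id = "sato", params = feature_params()) {
  stopifnot_vol3d(volume)
  ids <- if (identical(feature_id, "all")) feature_names() else feature_id
  if (!all(ids %in% feature_names())) stop("unknown feature: ", feature_id)
  acc <- lapply(ids, function(i) array(-Inf, dim(volume$data)))
  names(acc) <- ids
  for (s in params$scales_mm) {
    eigs <- normalized_eigs(volume, s)
    p <- params
    p$gamma <- gamma_from_eigs(eigs)
    if (is.null(p$c)) p$c <- p$gamma / 2
    for (id in ids) {
      resp <- single_scale_response(id, volume, eigs, p)
      acc[[id]] <- pmax(acc[[id]], resp)
    }
  }
  out <- lapply(acc, function(a) vol3d(array(a, dim(volume$data)), volume$spacing))
  if (identical(feature_id, "all")) out else out[[1]]
}

#' All five multiscale feature volumes
#'
#' Convenience wrapper around [multiscale_max()] sharing one Hessian
#' eigen-decomposition per scale across the five features.
#'
#' @inheritParams multiscale_max
#' @return Named list of five [vol3d] response volumes.
#' @export
vessel_features <- function(volume, params = feature_params()) {
  multiscale_max(volume, "all", params)
}

#' Standardize feature volumes by their response at the vessel axis
#'
#' Absolute vesselness responses are not comparable between volumes: the
#' structureness scale gamma is defined from each volume's maximum Hessian
#' norm, so a single hyperdense calcification rescales the Frangi and
#' Manniesing responses of the whole volume, and intensity contrast moves the
#' others. The axis, however, is a known-lumen input (the same fact that
#' fixes the initial state distribution at the lumen), so dividing each
#' feature volume by its median response over the axis points puts every
#' volume on a common lumen-relative scale before the fixed training
#' calibration is applied. Monotone per volume, label-free at test time.
#'
#' @param features named list of feature [vol3d]s.
#' @param axes one n x 3 axis matrix or a list of them (world mm).
#' @return The standardized list of [vol3d]s.
#' @export
standardize_features <- function(features, axes) {
  if (is.matrix(axes)) axes <- list(axes)
  pts <- do.call(rbind, axes)
  lapply(features, function(f) {
    med <- stats::median(interp_trilinear(f, pts))
    if (!is.finite(med) || med <= 0) med <- max(f$data, 1e-12)
    vol3d(f$data / med, f$spacing)
  })
}
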