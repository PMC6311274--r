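#' Overlap-aware bin scheme for one feature
#'
#' Observation symbols are produced by binning normalised feature values (a
#' 0--100 scale, see [fit_calibration()]). The feature axis is split into
#' `[0, a1)` (one bin), `[a1, a2)` (`K1` equal sub-bins), `[a2, a3)` (`K2`
#' equal sub-bins) and `[a3, Inf)` (one bin); `[a1, a2)` and `[a2, a3)` are
#' the intervals where the pathology feature distribution overlaps the intima
#' and lumen distributions, so extra resolution is spent exactly where the
#' classifier must discriminate. With the defaults `K1 = 5`, `K2 = 3` every
#' feature has `N = 10` symbols (coded 0..9). Intervals are half-open,
#' left-closed.
#'
#' @param feature_id one of [feature_names()].
#' @param a1,a2,a3 breakpoints on the normalised scale, `0 < a1 < a2 < a3`.
#' @param K1,K2 sub-bin counts for the two overlap intervals.
#' @return A list of class `bin_scheme` with the full ordered `edges`.
#' @export
bin_scheme <- function(feature_id, a1, a2, a3, K1 = 5L, K2 = 3L) {
  if (!(0 < a1 && a1 < a2 && a2 < a3)) stop("need 0 < a1 < a2 < a3")
  edges <- c(0,
             seq(a1, a2, length.out = K1 + 1L),
             seq(a2, a3, length.out = K2 + 1L)[-1])
  structure(list(feature_id = feature_id, a1 = a1, a2 = a2, a3 = a3,
                 K1 = as.integer(K1), K2 = as.integer(K2),
                 edges = edges, n_symbols = 2L + K1 + K2),
            class = "bin_scheme")
}

#' Default per-feature breakpoints
#'
#' The calibrated overlap intervals for the five features: Sato
#' `[25,35),[35,50)`; Frangi `[15,20),[20,30)`; Shikata `[85,95),[95,120)`;
#' Li `[40,45),[45,55)`; Manniesing `[15,25),[25,45)`.
#'
#' @param feature_id one of [feature_names()].
#' @return A [bin_scheme()].
#' @export
#' @examples
#' default_bin_scheme("sato")$a1   # 25
default_bin_scheme <- function(feature_id) {
  brk <- switch(feature_id,
                sato = c(25, 35, 50),
                frangi = c(15, 20, 30),
                shikata = c(85, 95, 120),
                li = c(40, 45, 55),
                manniesing = c(15, 25, 45),
                stop("unknown feature: ", feature_id))
  bin_scheme(feature_id, brk[1], brk[2], brk[3])
}

#' Fit / apply the per-feature normalisation
#'
#' The bin breakpoints live on a normalised 0--100 scale; raw feature ranges
#' differ by orders of magnitude (Frangi lies in `[0, 1]`), so each feature is
#' mapped linearly so that the robust upper anchor -- the 99.5th percentile of
#' the training values -- lands at 100. The calibration is fitted once on
#' training data and reused unchanged at test time.
#'
#' @param values numeric training values (nonnegative).
#' @param prob anchor percentile.
#' @return `fit_calibration()` returns a list of class `feature_calibration`;
#'   `normalize_feature()` returns the normalised values.
#' @export
fit_calibration <- function(values, prob = 0.995) {
  anchor <- stats::quantile(values, prob, names = FALSE, na.rm = TRUE)
  if (!is.finite(anchor) || anchor <= 0)
    stop("degenerate calibration: anchor percentile is not positive")
  structure(list(anchor = anchor, prob = prob), class = "feature_calibration")
}

#' @rdname fit_calibration
#' @param labels tissue labels (1 lumen, 2 intima, 3 pathology, 4 adventitia)
#'   aligned with `values`.
#' @param scheme the [bin_scheme()] whose overlap band the lumen distribution
#'   should occupy.
#' @details `fit_calibration_overlap()` is the label-aware variant used by
#'   the training pipeline. The binning design assumes the tissue classes
#'   occupy the scheme's bands in order -- background below `a1`, the
#'   intima/boundary mass across the intima--pathology overlap `[a1, a2)`,
#'   the lumen mass across `[a2, a3)`, and hyperdense pathology above `a3` --
#'   which a single scale factor cannot arrange for features whose class
#'   distributions sit at arbitrary relative positions (and the plain
#'   percentile anchor collapses entirely for heavy-tailed features such as
#'   the Li ratio, which spans many orders of magnitude near `lambda1 = 0`).
#'   The overlap calibration therefore builds a monotone piecewise-linear map
#'   through labelled training quantiles: the adventitia 90th percentile maps
#'   to `a1`, the intima median to the centre of `[a1, a2)`, the lumen median
#'   to the centre of `[a2, a3)`, and the pathology 25th percentile to `a3`;
#'   control points violating monotonicity are dropped (classes whose
#'   distributions invert simply share a band), and the map extends linearly
#'   beyond the last control point.
#' @param probs class quantiles used as control points: adventitia,
#'   intima, lumen, pathology.
#' @export
fit_calibration_overlap <- function(values, labels, scheme,
                                    probs = c(adventitia = 0.90, intima = 0.50,
                                              lumen = 0.50, pathology = 0.25)) {
  q <- function(cls, p) {
    v <- values[labels == cls]
    if (!length(v)) return(NA_real_)
    stats::quantile(v, p, names = FALSE, na.rm = TRUE)
  }
  xs <- c(q(4L, probs[[1]]), q(2L, probs[[2]]), q(1L, probs[[3]]), q(3L, probs[[4]]))
  ys <- c(scheme$a1, (scheme$a1 + scheme$a2) / 2,
          (scheme$a2 + scheme$a3) / 2, scheme$a3)
  keep <- !is.na(xs) & xs > 0
  xs <- xs[keep]; ys <- ys[keep]
  # enforce strictly increasing control points (greedy left to right)
  ord <- logical(length(xs)); last <- 0
  for (i in seq_along(xs)) if (xs[i] > last * (1 + 1e-9)) { ord[i] <- TRUE; last <- xs[i] }
  xs <- c(0, xs[ord]); ys <- c(0, ys[ord])
  if (length(xs) < 2) stop("degenerate calibration: no usable control points")
  structure(list(xs = xs, ys = ys, method = "overlap"),
            class = "feature_calibration")
}

#' @rdname fit_calibration
#' @param calibration a `feature_calibration`.
#' @export
normalize_feature <- function(values, calibration) {
  if (!inherits(calibration, "feature_calibration"))
    stop("'calibration' must come from fit_calibration()")
  if (!is.null(calibration$anchor)) return(100 * values / calibration$anchor)
  xs <- calibration$xs; ys <- calibration$ys
  n <- length(xs)
  out <- stats::approx(xs, ys, xout = pmin(values, xs[n]), rule = 2)$y
  over <- values > xs[n]
  if (any(over)) {
    slope <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out[over] <- ys[n] + slope * (values[over] - xs[n])
  }
  out
}

#' Quantize a normalised feature series into observation symbols
#'
#' Total and deterministic on `[0, Inf)`: symbol 0 for `[0, a1)`, symbols
#' `1..K1` for the sub-bins of `[a1, a2)`, `K1+1..K1+K2` for the sub-bins of
#' `[a2, a3)`, and `K1+K2+1` for `[a3, Inf)`. Edges are half-open,
#' left-closed, so `quantize_series(a1, s)` is symbol 1.
#'
#' @param values nonnegative normalised values.
#' @param scheme a [bin_scheme()].
#' @return Integer symbols in `0 .. scheme$n_symbols - 1`.
#' @export
#' @examples
#' quantize_series(c(10, 30, 1000), default_bin_scheme("sato"))  # 0 3 9
quantize_series <- function(values, scheme) {
  if (!inherits(scheme, "bin_scheme")) stop("'scheme' must be a bin_scheme")
  if (any(values < 0)) stop("feature values must be nonnegative")
  findInterval(values, scheme$edges[-1], left.open = FALSE) |>
    pmin(scheme$n_symbols - 1L) |>
    as.integer()
}

#' Re-fit overlap breakpoints from labelled training data
#'
#' Optional alternative to the fixed default breakpoints: estimates where the
#' pathology feature distribution overlaps the intima distribution (giving
#' `[a1, a2)`) and the lumen distribution (giving `[a2, a3)`) from kernel
#' density estimates of the normalised training values per tissue class. The
#' overlap interval of two classes is taken where both densities exceed a
#' fraction of their joint maximum; degenerate geometries fall back to the
#' default scheme.
#'
#' @param values normalised training values.
#' @param labels tissue labels (1 lumen, 2 intima, 3 pathology, 4 adventitia)
#'   aligned with `values`.
#' @param feature_id feature name (for the fallback and the result).
#' @param threshold density fraction defining "overlap".
#' @return A [bin_scheme()].
#' @export
fit_overlap_scheme <- function(values, labels, feature_id, threshold = 0.05) {
  ok <- is.finite(values)
  values <- values[ok]; labels <- labels[ok]
  fallback <- default_bin_scheme(feature_id)
  if (!all(c(1, 2, 3) %in% labels)) return(fallback)
  grid <- seq(0, max(values, 120), length.out = 512)
  dens <- function(cls) {
    v <- values[labels == cls]
    if (length(v) < 10 || stats::sd(v) == 0) return(NULL)
    d <- stats::density(v, from = grid[1], to = grid[length(grid)], n = length(grid))
    d$y / max(d$y)
  }
  dl <- dens(1); di <- dens(2); dp <- dens(3)
  if (is.null(dl) || is.null(di) || is.null(dp)) return(fallback)
  ov_ip <- grid[pmin(di, dp) > threshold]
  ov_lp <- grid[pmin(dl, dp) > threshold]
  if (!length(ov_ip) || !length(ov_lp)) return(fallback)
  a1 <- min(ov_ip); a2 <- max(ov_ip)
  a3 <- max(ov_lp)
  if (!(0 < a1 && a1 < a2 && a2 < a3)) return(fallback)
  bin_scheme(feature_id, a1, a2, a3, fallback$K1, fallback$K2)
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %s: [0,%g) | %d bins over [%g,%g) | %d bins over [%g,%g) | [%g,Inf) -> %d symbols\n",
              x$feature_id, x$a1, x$K1, x$a1, x$a2, x$K2, x$a2, x$a3, x$a3,
              x$n_symbols))
  invisible(x)
}
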