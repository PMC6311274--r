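#' Fit a multiple hidden Markov model to labelled ray series
#'
#' The main fitting function. Each of the five vesselness features gets its
#' own discrete four-state HMM: the feature values are normalised (see
#' [fit_calibration_overlap()]), quantized into 10 observation symbols
#' ([default_bin_scheme()]), and the HMM is estimated from the labelled
#' series (supervised default) or trained by Baum-Welch ([baum_welch()])
#' from a uniform or random start. The five experts are combined with
#' nonnegative
#' weights `alpha_k = Precision_k / sum(Precision)` derived from each HMM's
#' per-voxel training precision, so better experts speak louder; the
#' combined posterior is the convex mixture of the per-feature similarity
#' maps.
#'
#' @param data a series table from [collect_series()] with a `label` column
#'   and one column per feature; rows are ordered within each series by
#'   `sample_index`.
#' @param features which feature columns to use (default all five).
#' @param init `"supervised"` (default; label-count initialisation that fixes
#'   state semantics, then Baum-Welch refinement), `"uniform"` (the
#'   general-principle uniform start), or `"random"`. Non-supervised starts
#'   are state-matched to the labels afterwards ([match_states()]).
#' @param bin_schemes optional named list of [bin_scheme()]s; `"fit"` re-fits
#'   the overlap breakpoints from the training data
#'   ([fit_overlap_scheme()]); default uses the fixed per-feature schemes.
#' @param calibration `"overlap"` (default; [fit_calibration_overlap()],
#'   which aligns the lumen feature distribution with each scheme's overlap
#'   band) or `"percentile"` ([fit_calibration()]).
#' @param tol,max_iter,floor Baum-Welch controls. `max_iter = NULL` (default)
#'   resolves to 0 refinement iterations under supervised initialisation --
#'   the labelled counts are already the semantically constrained
#'   maximum-likelihood estimates, and unconstrained EM drifts the state
#'   meanings -- and to 500 under the uniform/random starts, which need EM to
#'   learn anything.
#' @return An object of class `mhmm`: list with `hmms`, `weights`,
#'   `precisions`, `bin_schemes`, `calibrations`, `features`, `init`,
#'   `n_series`, `logliks`.
#' @seealso [predict.mhmm()], [segment_vessel()], [run_experiment()]
#' @export
mhmm <- function(data, features = feature_names(), init = c("supervised", "uniform", "random"),
                 bin_schemes = NULL, calibration = c("overlap", "percentile"),
                 tol = 1e-6, max_iter = NULL, floor = 1e-6) {
  init <- match.arg(init)
  calibration <- match.arg(calibration)
  if (is.null(max_iter)) max_iter <- if (init == "supervised") 0L else 500L
  if (!all(features %in% names(data)))
    stop("missing feature columns: ",
         paste(setdiff(features, names(data)), collapse = ", "))
  if (is.null(data$label)) stop("'data' must carry a label column")
  data <- data[order(data$series_uid, data$sample_index), , drop = FALSE]
  uid <- data$series_uid
  n_per <- table(uid)
  if (length(unique(n_per)) != 1L)
    stop("all series must have the same length")
  Tn <- as.integer(n_per[1])
  S <- length(n_per)
  # series-major matrices (S x Tn); split() orders groups consistently
  as_mat <- function(v) do.call(rbind, split(v, uid))
  labmat <- as_mat(as.integer(data$label))
  hmms <- list(); cals <- list(); schemes <- list()
  precisions <- numeric(0); logliks <- list()
  lab_list <- asplit(labmat, 1)
  for (f in features) {
    scheme <- if (is.list(bin_schemes) && !is.null(bin_schemes[[f]])) {
      bin_schemes[[f]]
    } else default_bin_scheme(f)
    cal <- if (calibration == "overlap") {
      fit_calibration_overlap(data[[f]], data$label, scheme)
    } else fit_calibration(data[[f]])
    nv <- normalize_feature(data[[f]], cal)
    if (identical(bin_schemes, "fit")) {
      scheme <- fit_overlap_scheme(nv, data$label, f)
    }
    sym <- quantize_series(nv, scheme)
    om <- as_mat(sym)
    start <- switch(init,
                    supervised = supervised_hmm_mat(om, labmat),
                    uniform = init_hmm(4L, scheme$n_symbols),
                    random = random_hmm(4L, scheme$n_symbols, seed = 1L))
    fit <- baum_welch(start, om, tol = tol, max_iter = max_iter, floor = floor)
    if (!isTRUE(attr(fit, "converged")) && max_iter >= 500L)
      stop("Baum-Welch failed to converge for feature '", f, "'")
    obs_list <- asplit(om, 1)
    if (init != "supervised") fit <- match_states(fit, obs_list, lab_list)
    precisions[f] <- training_precision(fit, obs_list, lab_list)
    hmms[[f]] <- fit
    cals[[f]] <- cal
    schemes[[f]] <- scheme
    logliks[[f]] <- attr(fit, "loglik")
  }
  if (sum(precisions) == 0) stop("all training precisions are zero")
  weights <- precisions / sum(precisions)
  structure(list(hmms = hmms, weights = weights, precisions = precisions,
                 bin_schemes = schemes, calibrations = cals,
                 features = features, init = init,
                 n_series = S, series_length = Tn, logliks = logliks),
            class = "mhmm")
}

# vectorised supervised initialisation from series-major matrices
supervised_hmm_mat <- function(obsmat, labmat, M = 4L, N_obs = 10L) {
  Tn <- ncol(labmat)
  from <- labmat[, -Tn]; to <- labmat[, -1]
  A_cnt <- matrix(tabulate(from + (to - 1L) * M, M * M), M, M) + 1
  o <- obsmat + 1L
  B_cnt <- matrix(tabulate(o + (labmat - 1L) * N_obs, N_obs * M), N_obs, M) + 1
  new_hmm(pi = c(1, rep(0, M - 1L)),
          A = A_cnt / rowSums(A_cnt),
          B = sweep(B_cnt, 2, colSums(B_cnt), "/"),
          state_names = c("lumen", "intima", "pathology", "adventitia"))
}

#' Combined posterior similarity map for one ray
#'
#' Applies the per-feature calibration, quantization and forward-backward
#' posterior, then mixes the five similarity maps with the precision weights:
#' `P(T | Phi, F') = sum_k alpha_k P(T | phi_k, F'^k)`. Rows of the result
#' sum to 1 (a convex combination of stochastic rows).
#'
#' @param model an [mhmm] fit.
#' @param feature_series named list with one numeric vector of raw feature
#'   values per feature; all the same length.
#' @return A `similarity_map` (the `log_likelihood` is the weighted mean of
#'   the per-expert log-likelihoods).
#' @export
mhmm_posterior <- function(model, feature_series) {
  stopifnot(inherits(model, "mhmm"))
  miss <- setdiff(model$features, names(feature_series))
  if (length(miss)) stop("missing feature series: ", paste(miss, collapse = ", "))
  lens <- lengths(feature_series[model$features])
  if (length(unique(lens)) != 1L) stop("feature series length mismatch")
  post <- NULL; ll <- 0
  for (f in model$features) {
    nv <- normalize_feature(feature_series[[f]], model$calibrations[[f]])
    sym <- quantize_series(nv, model$bin_schemes[[f]])
    sm <- forward_backward(model$hmms[[f]], sym)
    contrib <- model$weights[[f]] * sm$posteriors
    post <- if (is.null(post)) contrib else post + contrib
    ll <- ll + model$weights[[f]] * sm$log_likelihood
  }
  structure(list(posteriors = post, log_likelihood = ll),
            class = "similarity_map")
}

#' Predict posteriors or states for new ray series
#'
#' @param object an [mhmm] fit.
#' @param newdata a series table (as from [collect_series()]) with the model's
#'   feature columns; all series must share one length.
#' @param type `"posterior"` for the n x 4 mixture similarity rows aligned
#'   with `newdata` (sorted by series then sample), `"state"` for the decoded
#'   state per row.
#' @param ... unused.
#' @return A matrix of posteriors or an integer vector of states, in the
#'   order of `newdata` sorted by (`series_uid`, `sample_index`).
#' @export
predict.mhmm <- function(object, newdata, type = c("posterior", "state"), ...) {
  type <- match.arg(type)
  newdata <- newdata[order(newdata$series_uid, newdata$sample_index), , drop = FALSE]
  uid <- newdata$series_uid
  n_per <- table(uid)
  if (length(unique(n_per)) != 1L) stop("all series must have the same length")
  Tn <- as.integer(n_per[1]); S <- length(n_per)
  M <- 4L
  acc <- NULL
  for (f in object$features) {
    nv <- normalize_feature(newdata[[f]], object$calibrations[[f]])
    sym <- quantize_series(nv, object$bin_schemes[[f]])
    om <- do.call(rbind, split(sym, uid))
    fb <- fb_batch(object$hmms[[f]], om)
    g <- simplify2array(fb$gamma)               # S x M x Tn
    contrib <- object$weights[[f]] * g
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  # rows ordered series-major, sample fastest: aperm to Tn x S x M
  post <- matrix(aperm(acc, c(3, 1, 2)), nrow = Tn * S, ncol = M)
  colnames(post) <- object$hmms[[1]]$state_names
  if (type == "posterior") post else map_decode(post)
}

#' @export
print.mhmm <- function(x, ...) {
  cat(sprintf("<mhmm> %d per-feature HMMs over %d series of length %d (%s init)\n",
              length(x$hmms), x$n_series, x$series_length, x$init))
  w <- format(round(x$weights, 3))
  cat("  weights:", paste(sprintf("%s=%s", x$features, w), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mhmm <- function(object, ...) {
  out <- list(
    features = object$features,
    precisions = object$precisions,
    weights = object$weights,
    iterations = vapply(object$logliks, length, 0L),
    final_loglik = vapply(object$logliks, function(l)
      if (length(l)) l[length(l)] else NA_real_, 0),
    n_series = object$n_series,
    series_length = object$series_length,
    init = object$init)
  class(out) <- "summary.mhmm"
  out
}

#' @export
print.summary.mhmm <- function(x, ...) {
  cat(sprintf("Multiple HMM fit (%s initialisation): %d series x %d samples\n",
              x$init, x$n_series, x$series_length))
  tab <- data.frame(precision = round(x$precisions, 4),
                    weight = round(x$weights, 4),
                    em_iterations = x$iterations,
                    logLik = round(x$final_loglik, 1))
  rownames(tab) <- x$features
  print(tab)
  invisible(x)
}

#' @export
coef.mhmm <- function(object, complete = FALSE, ...) {
  if (!complete) return(object$weights)
  list(weights = object$weights,
       A = lapply(object$hmms, `[[`, "A"),
       B = lapply(object$hmms, `[[`, "B"),
       pi = lapply(object$hmms, `[[`, "pi"))
}

#' Simulate ray series from a fitted MHMM
#'
#' Draws one shared tissue-state path per series from the precision-weighted
#' average transition matrix, then per-feature observation symbols
#' conditionally independently from each expert's emission columns (the
#' model's naive-Bayes-style generative reading).
#'
#' @param object an [mhmm] fit.
#' @param nsim number of series.
#' @param seed optional seed.
#' @param length_out series length.
#' @param ... unused.
#' @return A list with `states` (`nsim x length_out`) and `symbols`, a named
#'   list of per-feature symbol matrices.
#' @export
simulate.mhmm <- function(object, nsim = 1, seed = NULL, length_out = 18L, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  Abar <- Reduce(`+`, Map(function(w, h) w * h$A, object$weights, object$hmms))
  Abar <- Abar / rowSums(Abar)
  M <- nrow(Abar)
  states <- matrix(0L, nsim, length_out)
  for (i in seq_len(nsim)) {
    s <- 1L
    for (t in seq_len(length_out)) {
      if (t > 1) s <- sample.int(M, 1, prob = Abar[s, ])
      states[i, t] <- s
    }
  }
  symbols <- lapply(object$hmms, function(h) {
    matrix(vapply(states, function(s) sample.int(h$N_obs, 1, prob = h$B[, s]) - 1L, 0L),
           nsim, length_out)
  })
  list(states = states, symbols = symbols)
}

#' Plot the similarity map of one ray
#'
#' Posterior probability of each tissue state against the sample position
#' along the ray.
#'
#' @param x an [mhmm] fit.
#' @param feature_series as in [mhmm_posterior()].
#' @param ... passed to [graphics::matplot()].
#' @return The similarity map, invisibly.
#' @export
plot.mhmm <- function(x, feature_series, ...) {
  sm <- mhmm_posterior(x, feature_series)
  graphics::matplot(sm$posteriors, type = "b", pch = 1:4, lty = 1,
                    xlab = "sample along ray", ylab = "posterior similarity",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(sm$posteriors),
                   col = 1:4, pch = 1:4, lty = 1, bty = "n")
  invisible(sm)
}

#' Serialize / read an MHMM as YAML
#'
#' @param model an [mhmm].
#' @param path file path.
#' @return `read_mhmm_yaml()` returns the `mhmm`.
#' @export
write_mhmm_yaml <- function(model, path) {
  obj <- list(format_version = 1L,
              features = model$features,
              weights = as.list(model$weights),
              precisions = as.list(model$precisions),
              init = model$init,
              n_series = model$n_series,
              series_length = model$series_length,
              calibrations = lapply(model$calibrations, unclass),
              bin_schemes = lapply(model$bin_schemes, function(s)
                list(feature_id = s$feature_id, a1 = s$a1, a2 = s$a2, a3 = s$a3,
                     K1 = s$K1, K2 = s$K2)),
              hmms = lapply(model$hmms, function(h)
                list(state_names = h$state_names, pi = h$pi,
                     A = apply(h$A, 1, identity, simplify = FALSE),
                     B = apply(h$B, 2, identity, simplify = FALSE))))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_mhmm_yaml
#' @export
read_mhmm_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  feats <- as.character(obj$features)
  hmms <- lapply(obj$hmms, function(h)
    new_hmm(pi = as.numeric(h$pi), A = do.call(rbind, h$A),
            B = do.call(cbind, h$B), state_names = as.character(h$state_names)))
  cals <- lapply(obj$calibrations, function(cl) {
    cl <- lapply(cl, function(x) if (is.list(x)) unlist(x) else x)
    structure(cl, class = "feature_calibration")
  })
  schemes <- lapply(obj$bin_schemes, function(s)
    bin_scheme(s$feature_id, s$a1, s$a2, s$a3, s$K1, s$K2))
  structure(list(hmms = stats::setNames(hmms, feats),
                 weights = unlist(obj$weights)[feats],
                 precisions = unlist(obj$precisions)[feats],
                 bin_schemes = stats::setNames(schemes, feats),
                 calibrations = stats::setNames(cals, feats),
                 features = feats, init = obj$init,
                 n_series = obj$n_series, series_length = obj$series_length,
                 logliks = NULL),
            class = "mhmm")
}
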