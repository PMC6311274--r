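#' Discrete-observation hidden Markov model over tissue states
#'
#' The classifier for one vesselness feature: `M = 4` hidden tissue states
#' (lumen, intima, pathology, adventitia) and `N_obs = 10` observation
#' symbols. The initial distribution is fixed at `pi = (1, 0, ..., 0)` --
#' decoding starts at the axis point, which lies in the lumen. `A` is the
#' `M x M` row-stochastic transition matrix and `B` the `N_obs x M` emission
#' matrix whose columns are per-state symbol distributions.
#'
#' @param M number of hidden states.
#' @param N_obs number of observation symbols.
#' @param state_names names for the states.
#' @return `init_hmm()` returns an `hmm` with uniform `A` and `B` (the
#'   general-principle initialisation); `random_hmm()` draws Dirichlet-like
#'   rows/columns for restarts.
#' @export
#' @examples
#' m <- init_hmm()
#' m$A[1, 1]   # 0.25
init_hmm <- function(M = 4L, N_obs = 10L,
                     state_names = c("lumen", "intima", "pathology", "adventitia")) {
  M <- as.integer(M); N_obs <- as.integer(N_obs)
  if (M < 1L || N_obs < 1L) stop("M and N_obs must be positive")
  if (length(state_names) != M) state_names <- paste0("S", seq_len(M))
  new_hmm(pi = c(1, rep(0, M - 1L)),
          A = matrix(1 / M, M, M),
          B = matrix(1 / N_obs, N_obs, M),
          state_names = state_names)
}

#' @rdname init_hmm
#' @param seed integer seed for the random draw.
#' @export
random_hmm <- function(M = 4L, N_obs = 10L, seed = 1L,
                       state_names = c("lumen", "intima", "pathology", "adventitia")) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  if (length(state_names) != M) state_names <- paste0("S", seq_len(M))
  A <- matrix(stats::rgamma(M * M, 1), M, M)
  B <- matrix(stats::rgamma(N_obs * M, 1), N_obs, M)
  new_hmm(pi = c(1, rep(0, M - 1L)),
          A = A / rowSums(A),
          B = sweep(B, 2, colSums(B), "/"),
          state_names = state_names)
}

new_hmm <- function(pi, A, B, state_names) {
  structure(list(M = length(pi), N_obs = nrow(B), pi = pi, A = A, B = B,
                 state_names = state_names),
            class = "hmm")
}

check_hmm <- function(model) {
  stopifnot(inherits(model, "hmm"))
  if (abs(sum(model$pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(abs(rowSums(model$A) - 1) > 1e-8)) stop("rows of A must sum to 1")
  if (any(abs(colSums(model$B) - 1) > 1e-8)) stop("columns of B must sum to 1")
  invisible(model)
}

#' @export
print.hmm <- function(x, ...) {
  cat(sprintf("<hmm> %d states (%s), %d symbols\n", x$M,
              paste(x$state_names, collapse = ", "), x$N_obs))
  cat("transition matrix A:\n")
  print(round(x$A, 3))
  invisible(x)
}

check_obs <- function(obs, N_obs) {
  obs <- as.integer(obs)
  if (any(obs < 0L) || any(obs >= N_obs))
    stop("observation symbols must lie in 0..", N_obs - 1L)
  obs
}

#' Posterior similarity map by the forward-backward algorithm
#'
#' Exact posterior state marginals `P(state_t | model, series)` for one
#' observation series, computed with per-position scaling (no underflow for
#' series far longer than the 18-sample rays).
#'
#' @param model an `hmm`.
#' @param obs integer symbols in `0 .. N_obs - 1`.
#' @return A list of class `similarity_map` with `posteriors` (n x M matrix,
#'   rows summing to 1) and `log_likelihood`.
#' @export
forward_backward <- function(model, obs) {
  check_hmm(model)
  obs <- check_obs(obs, model$N_obs)
  fb <- fb_batch(model, matrix(obs, nrow = 1))
  post <- do.call(rbind, lapply(fb$gamma, function(g) g[1, , drop = FALSE]))
  colnames(post) <- model$state_names
  rownames(post) <- NULL
  structure(list(posteriors = post, log_likelihood = fb$loglik[1]),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> %d positions x %d states, logLik %.3f\n",
              nrow(x$posteriors), ncol(x$posteriors), x$log_likelihood))
  print(round(utils::head(x$posteriors, 6), 3))
  if (nrow(x$posteriors) > 6) cat("  ...\n")
  invisible(x)
}

# forward-backward over a batch of equal-length series (S x T symbol matrix,
# 0-based); returns per-position gammas, per-series logliks, and the
# Baum-Welch accumulators
fb_batch <- function(model, obsmat, accumulate = FALSE) {
  S <- nrow(obsmat); Tn <- ncol(obsmat); M <- model$M
  o <- obsmat + 1L
  A <- model$A; B <- model$B
  AH <- vector("list", Tn)
  cs <- matrix(0, S, Tn)
  a <- matrix(model$pi, S, M, byrow = TRUE) * B[o[, 1], , drop = FALSE]
  cs[, 1] <- rowSums(a)
  if (any(cs[, 1] == 0))
    stop("impossible sequence under the model at step 1")
  AH[[1]] <- a / cs[, 1]
  for (t in seq_len(Tn - 1L) + 1L) {
    a <- (AH[[t - 1L]] %*% A) * B[o[, t], , drop = FALSE]
    cs[, t] <- rowSums(a)
    if (any(cs[, t] == 0))
      stop("impossible sequence under the model at step ", t)
    AH[[t]] <- a / cs[, t]
  }
  gam <- vector("list", Tn)
  bh <- matrix(1, S, M)
  gam[[Tn]] <- AH[[Tn]]
  A_num <- if (accumulate) matrix(0, M, M) else NULL
  B_num <- if (accumulate) matrix(0, model$N_obs, M) else NULL
  for (t in rev(seq_len(Tn - 1L))) {
    R <- (B[o[, t + 1L], , drop = FALSE] * bh) / cs[, t + 1L]
    if (accumulate) A_num <- A_num + A * crossprod(AH[[t]], R)
    bh <- R %*% t(A)
    g <- AH[[t]] * bh
    gam[[t]] <- g / rowSums(g)
  }
  if (accumulate) {
    for (t in seq_len(Tn)) {
      agg <- rowsum(gam[[t]], group = o[, t])
      B_num[as.integer(rownames(agg)), ] <- B_num[as.integer(rownames(agg)), ] + agg
    }
  }
  list(gamma = gam, loglik = rowSums(log(cs)), A_num = A_num, B_num = B_num)
}

# forward-only log-likelihood (independent route used in invariants)
forward_loglik <- function(model, obs) {
  check_hmm(model)
  obs <- check_obs(obs, model$N_obs) + 1L
  a <- model$pi * model$B[obs[1], ]
  ll <- log(sum(a)); a <- a / sum(a)
  for (t in seq_along(obs)[-1]) {
    a <- as.numeric(a %*% model$A) * model$B[obs[t], ]
    s <- sum(a)
    if (s == 0) stop("impossible sequence under the model at step ", t)
    ll <- ll + log(s); a <- a / s
  }
  ll
}

#' Baum-Welch training of a discrete HMM
#'
#' Expectation-maximisation over a set of observation series. The initial
#' distribution is held fixed at `(1, 0, ..., 0)` throughout re-estimation
#' (every ray starts in the lumen); `A` rows and `B` columns are renormalised
#' with a smoothing floor after every iteration to avoid zero-probability
#' lock-in. The total log-likelihood is non-decreasing across iterations (EM
#' monotonicity); training stops when the relative improvement drops below
#' `tol` or after `max_iter` iterations.
#'
#' @param model starting `hmm` (see [init_hmm()], [random_hmm()], or
#'   [supervised_hmm()]).
#' @param training list of integer symbol series (or a matrix, one series per
#'   row).
#' @param tol relative log-likelihood tolerance.
#' @param max_iter maximum EM iterations.
#' @param floor smoothing floor applied to `A` and `B` entries.
#' @return The trained `hmm`, with attributes `loglik` (per-iteration trace)
#'   and `converged`.
#' @export
baum_welch <- function(model, training, tol = 1e-6, max_iter = 500L,
                       floor = 1e-6) {
  check_hmm(model)
  if (is.matrix(training)) training <- asplit(training, 1)
  if (!length(training)) stop("empty training set")
  training <- lapply(training, check_obs, N_obs = model$N_obs)
  lens <- lengths(training)
  groups <- split(training, lens)
  obsmats <- lapply(groups, function(g) do.call(rbind, g))
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    A_num <- matrix(0, model$M, model$M)
    B_num <- matrix(0, model$N_obs, model$M)
    ll <- 0
    for (om in obsmats) {
      fb <- fb_batch(model, om, accumulate = TRUE)
      A_num <- A_num + fb$A_num
      B_num <- B_num + fb$B_num
      ll <- ll + sum(fb$loglik)
    }
    trace <- c(trace, ll)
    if (is.finite(prev)) {
      if (abs(ll - prev) < tol * (abs(prev) + 1e-12)) { converged <- TRUE; break }
    }
    prev <- ll
    A <- A_num / pmax(rowSums(A_num), 1e-300)
    A[rowSums(A_num) == 0, ] <- 1 / model$M
    B <- sweep(B_num, 2, pmax(colSums(B_num), 1e-300), "/")
    B[, colSums(B_num) == 0] <- 1 / model$N_obs
    A <- pmax(A, floor); A <- A / rowSums(A)
    B <- pmax(B, floor); B <- sweep(B, 2, colSums(B), "/")
    model$A <- A; model$B <- B
  }
  attr(model, "loglik") <- trace
  attr(model, "converged") <- converged
  model
}

#' Supervised initialisation from labelled series
#'
#' Builds `A` from labelled state-transition counts and `B` from labelled
#' symbol counts (add-one smoothing), fixing the semantic identity of the
#' four states; Baum-Welch can then refine from this start. This is the
#' default initialisation for the full pipeline, since the uniform
#' general-principle start cannot guarantee which hidden state ends up
#' meaning "lumen".
#'
#' @param training list of integer symbol series.
#' @param labels list of integer state sequences (1-based) aligned with
#'   `training`.
#' @param M,N_obs,state_names model dimensions.
#' @return An `hmm`.
#' @export
supervised_hmm <- function(training, labels, M = 4L, N_obs = 10L,
                           state_names = c("lumen", "intima", "pathology", "adventitia")) {
  if (length(training) != length(labels)) stop("training/labels length mismatch")
  A_cnt <- matrix(1, M, M)           # add-one smoothing
  B_cnt <- matrix(1, N_obs, M)
  for (i in seq_along(training)) {
    o <- check_obs(training[[i]], N_obs) + 1L
    s <- as.integer(labels[[i]])
    if (length(o) != length(s)) stop("series ", i, ": obs/label length mismatch")
    n <- length(s)
    if (n > 1)
      for (t in seq_len(n - 1L)) A_cnt[s[t], s[t + 1L]] <- A_cnt[s[t], s[t + 1L]] + 1
    for (t in seq_len(n)) B_cnt[o[t], s[t]] <- B_cnt[o[t], s[t]] + 1
  }
  new_hmm(pi = c(1, rep(0, M - 1L)),
          A = A_cnt / rowSums(A_cnt),
          B = sweep(B_cnt, 2, colSums(B_cnt), "/"),
          state_names = state_names)
}

#' MAP decoding of a similarity map
#'
#' Per-position argmax of the posterior state probabilities; ties break
#' toward the lower state index (lumen before intima -- both count as vessel,
#' so the tie does not affect the final segmentation).
#'
#' @param similarity a `similarity_map` or a plain posterior matrix.
#' @return Integer state sequence (1-based).
#' @export
map_decode <- function(similarity) {
  post <- if (inherits(similarity, "similarity_map")) similarity$posteriors else similarity
  max.col(post, ties.method = "first")
}

#' Training precision of an HMM
#'
#' Decodes each labelled series and counts per-voxel vessel-positive
#' decisions: a decision is positive when the decoded state is lumen or
#' intima, and true when the label is lumen or intima. Returns
#' `TP / (TP + FP)`, or 0 (with a warning) when nothing is called positive.
#'
#' @param model an `hmm`.
#' @param training list of integer symbol series.
#' @param labels list of integer state sequences aligned with `training`.
#' @return A fraction in `[0, 1]`.
#' @export
training_precision <- function(model, training, labels) {
  if (length(training) != length(labels)) stop("training/labels length mismatch")
  tp <- 0; fp <- 0
  lens <- lengths(training)
  for (len in unique(lens)) {
    sel <- which(lens == len)
    om <- do.call(rbind, training[sel])
    lm <- do.call(rbind, lapply(labels[sel], as.integer))
    if (any(dim(lm) != dim(om))) stop("obs/label length mismatch")
    fb <- fb_batch(model, om)
    for (t in seq_len(len)) {
      dec <- max.col(fb$gamma[[t]], ties.method = "first")
      pos <- dec <= 2L
      truth <- lm[, t] <= 2L
      tp <- tp + sum(pos & truth)
      fp <- fp + sum(pos & !truth)
    }
  }
  if (tp + fp == 0) {
    warning("no positive calls; precision defined as 0")
    return(0)
  }
  tp / (tp + fp)
}

#' Match trained states to tissue labels
#'
#' Unsupervised Baum-Welch cannot guarantee which hidden state means which
#' tissue; this relabels states by the permutation maximising per-voxel
#' agreement between decoded states and the supplied labels (exhaustive over
#' the `M!` permutations; `M = 4` has 24).
#'
#' @inheritParams training_precision
#' @return The permuted `hmm` (with attribute `permutation`), whose state `k`
#'   is the tissue `state_names[k]`.
#' @export
match_states <- function(model, training, labels) {
  M <- model$M
  perms <- permutations_of(M)
  dec <- lapply(seq_along(training), function(i) {
    map_decode(forward_backward(model, training[[i]]))
  })
  lab <- lapply(labels, as.integer)
  best <- NULL; best_score <- -1
  for (p in perms) {
    score <- sum(mapply(function(d, l) sum(p[d] == l), dec, lab))
    if (score > best_score) { best_score <- score; best <- p }
  }
  inv <- order(best)      # tissue k is internal state inv[k]
  out <- new_hmm(pi = model$pi[inv], A = model$A[inv, inv, drop = FALSE],
                 B = model$B[, inv, drop = FALSE], state_names = model$state_names)
  attr(out, "permutation") <- best
  out
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

#' Simulate observation series from an HMM
#'
#' Draws a state path from `pi` and `A`, then symbols from the per-state
#' emission columns of `B`.
#'
#' @param object an `hmm`.
#' @param nsim number of series.
#' @param seed optional integer seed.
#' @param length_out series length (18 matches the ray sampling).
#' @param ... unused.
#' @return A list with matrices `states` and `symbols` (`nsim` x
#'   `length_out`; symbols 0-based).
#' @export
simulate.hmm <- function(object, nsim = 1, seed = NULL, length_out = 18L, ...) {
  check_hmm(object)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  M <- object$M
  states <- matrix(0L, nsim, length_out)
  symbols <- matrix(0L, nsim, length_out)
  for (i in seq_len(nsim)) {
    s <- sample.int(M, 1, prob = object$pi)
    for (t in seq_len(length_out)) {
      if (t > 1) s <- sample.int(M, 1, prob = object$A[s, ])
      states[i, t] <- s
      symbols[i, t] <- sample.int(object$N_obs, 1, prob = object$B[, s]) - 1L
    }
  }
  list(states = states, symbols = symbols)
}

#' Serialize / read an HMM as YAML
#'
#' @param model an `hmm`.
#' @param path file path.
#' @return `read_hmm_yaml()` returns the `hmm`.
#' @export
write_hmm_yaml <- function(model, path) {
  check_hmm(model)
  yaml::write_yaml(list(format_version = 1L,
                        state_names = model$state_names,
                        pi = model$pi,
                        A = apply(model$A, 1, identity, simplify = FALSE),
                        B = apply(model$B, 2, identity, simplify = FALSE)),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_hmm_yaml
#' @export
read_hmm_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  A <- do.call(rbind, obj$A)
  B <- do.call(cbind, obj$B)
  new_hmm(pi = as.numeric(obj$pi), A = A, B = B,
          state_names = as.character(obj$state_names))
}
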