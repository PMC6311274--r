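# Shared fixtures: small HMMs, analytic volumes, and brute-force oracles.

# a well-separated 4-state / 10-symbol left-to-right-ish model used by the
# parameter-recovery and decoding tests
reference_hmm <- function() {
  A <- rbind(c(0.70, 0.25, 0.03, 0.02),
             c(0.02, 0.58, 0.15, 0.25),
             c(0.01, 0.04, 0.75, 0.20),
             c(0.005, 0.005, 0.04, 0.95))
  B <- matrix(0.004, 10, 4)
  B[8, 1] <- B[9, 1] <- 0.4                      # lumen: high symbols
  B[3, 2] <- B[4, 2] <- B[5, 2] <- 0.25          # intima: mid symbols
  B[10, 3] <- 0.8                                # pathology: overflow bin
  B[1, 4] <- 0.85; B[2, 4] <- 0.1                # adventitia: near zero
  B <- sweep(B, 2, colSums(B), "/")
  A <- A / rowSums(A)
  m <- init_hmm(4, 10)
  m$A <- A; m$B <- B
  m
}

# exhaustive-path posterior marginals and likelihood: sums over all M^n
# state paths, independent of the forward-backward implementation
brute_force_posterior <- function(model, obs) {
  M <- model$M; n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), n)))
  o <- obs + 1L
  probs <- apply(paths, 1, function(s) {
    p <- model$pi[s[1]] * model$B[o[1], s[1]]
    if (n > 1) for (t in 2:n) p <- p * model$A[s[t - 1], s[t]] * model$B[o[t], s[t]]
    p
  })
  lik <- sum(probs)
  post <- matrix(0, n, M)
  for (t in seq_len(n)) for (m in seq_len(M))
    post[t, m] <- sum(probs[paths[, t] == m]) / lik
  list(posteriors = post, likelihood = lik)
}

# straight-tube phantom used across feature and rays tests
straight_tube_phantom <- function(radius_mm = 1.5, grid = 40, noise = 0,
                                  margin = 6, wall = 2L, seed = 1L,
                                  plaque = list()) {
  generate_phantom(phantom_config(
    grid_shape = c(grid, grid, grid),
    axis_spec = list(type = "straight", margin_vox = margin),
    radius_mm = radius_mm, wall_thickness_vox = wall,
    plaque_spec = plaque, noise_variance = noise, seed = seed))
}

# analytic bright cylinder (no wall layer, no noise): the pure tube used by
# the scale-selectivity oracle
analytic_tube <- function(radius_mm, grid = 36, margin = 6) {
  generate_phantom(phantom_config(
    grid_shape = c(grid, grid, grid),
    axis_spec = list(type = "straight", margin_vox = margin),
    radius_mm = radius_mm, wall_thickness_vox = 2L,
    intensity_means = c(background = 40, lumen = 250, wall = 40,
                        calcification = 1100)))
}

# mean single-scale response over interior axis points, per scale
scale_response_profile <- function(feature_id, phantom, scales = default_scales()) {
  ax <- phantom$axes[[1]]
  ax <- ax[4:(nrow(ax) - 3), , drop = FALSE]
  p <- feature_params()
  sapply(scales, function(s) {
    e <- mhmmseg:::normalized_eigs(phantom$volume, s)
    pp <- p; pp$gamma <- mhmmseg:::gamma_from_eigs(e); pp$c <- pp$gamma / 2
    r <- mhmmseg:::single_scale_response(feature_id, phantom$volume, e, pp)
    mean(interp_trilinear(vol3d(r, phantom$volume$spacing), ax))
  })
}

# synthetic eigenvalue container for the single-scale feature formulas
eigs_of <- function(l1, l2, l3, s = 1) {
  structure(list(lambda1 = array(l1, c(length(l1), 1, 1)),
                 lambda2 = array(l2, c(length(l1), 1, 1)),
                 lambda3 = array(l3, c(length(l1), 1, 1)),
                 scale_s = s),
            class = "hessian_eigs")
}

# random eigen-triples sorted descending (lambda1 > lambda2 > lambda3)
random_eig_triples <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(3 * n, 0, 5), n, 3)
  t(apply(m, 1, sort, decreasing = TRUE))
}

# the printed 18 x 4 similarity map worked example (one voxel series);
# rows are positions along the ray, columns the four tissue states
table3_similarity <- function() {
  matrix(c(
    0.943, 0.055, 0.002, 0.000,
    0.901, 0.098, 0.001, 0.000,
    0.842, 0.153, 0.004, 0.001,
    0.801, 0.195, 0.002, 0.002,
    0.744, 0.254, 0.001, 0.001,
    0.706, 0.290, 0.002, 0.002,
    0.301, 0.593, 0.101, 0.005,
    0.001, 0.643, 0.151, 0.205,
    0.007, 0.301, 0.572, 0.120,
    0.001, 0.165, 0.732, 0.102,
    0.002, 0.044, 0.812, 0.142,
    0.001, 0.020, 0.509, 0.470,
    0.001, 0.006, 0.401, 0.592,
    0.002, 0.002, 0.303, 0.693,
    0.001, 0.001, 0.265, 0.733,
    0.001, 0.002, 0.115, 0.882,
    0.000, 0.001, 0.109, 0.890,
    0.000, 0.000, 0.043, 0.957), ncol = 4, byrow = TRUE)
}
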