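# Discrete HMM core: initialisation, forward-backward, Baum-Welch, decoding.

test_that("initialisation follows the uniform general principle with the lumen start", {
  m <- init_hmm()
  expect_equal(m$pi, c(1, 0, 0, 0))
  expect_true(all(m$A == 0.25))
  expect_true(all(m$B == 0.1))
  expect_equal(init_hmm(M = 1, N_obs = 3)$A, matrix(1, 1, 1))
  expect_error(init_hmm(M = 0), "positive")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    m <- random_hmm(4, 10, seed = i)
    # random (possibly soft) start still exercises the general recursion
    obs <- sample(0:9, n, replace = TRUE)
    fb <- forward_backward(m, obs)
    bf <- brute_force_posterior(m, obs)
    expect_equal(unname(fb$posteriors), bf$posteriors, tolerance = 1e-12)
    expect_equal(fb$log_likelihood, log(bf$likelihood), tolerance = 1e-12)
  }
})

test_that("forward-backward degenerate cases and contracts", {
  m1 <- init_hmm(M = 1, N_obs = 4)
  fb <- forward_backward(m1, c(0, 1, 2))
  expect_true(all(fb$posteriors == 1))
  # no evidence beyond the prior: uniform model, length-1 series
  m <- init_hmm()
  expect_equal(unname(forward_backward(m, 3L)$posteriors[1, ]), m$pi)
  # impossible sequence: starting state cannot emit symbol with prob 0
  m2 <- init_hmm()
  m2$B[, 1] <- c(1, rep(0, 9))
  expect_error(forward_backward(m2, c(5L)), "impossible.*step 1")
  expect_error(forward_backward(m, c(0L, 11L)), "symbols")
})

test_that("forward-backward likelihood agrees with the forward-only recursion", {
  for (i in 1:20) {
    m <- random_hmm(4, 10, seed = 100 + i)
    obs <- simulate(m, 1, seed = i, length_out = 18)$symbols[1, ]
    expect_equal(forward_backward(m, obs)$log_likelihood,
                 mhmmseg:::forward_loglik(m, obs), tolerance = 1e-12)
  }
})

test_that("scaled forward-backward survives very long series", {
  m <- reference_hmm()
  obs <- simulate(m, 1, seed = 7, length_out = 10000)$symbols[1, ]
  fb <- forward_backward(m, obs)
  expect_true(is.finite(fb$log_likelihood))
  expect_true(all(abs(rowSums(fb$posteriors) - 1) < 1e-9))
})

test_that("one EM step never decreases the likelihood (50 random starts)", {
  gen <- reference_hmm()
  sims <- simulate(gen, 40, seed = 5, length_out = 18)
  for (i in 1:50) {
    m0 <- random_hmm(4, 10, seed = 2000 + i)
    fit <- baum_welch(m0, sims$symbols, tol = 0, max_iter = 6, floor = 0)
    ll <- attr(fit, "loglik")
    expect_true(all(diff(ll) > -1e-8),
                label = sprintf("monotone log-likelihood, start %d", i))
  }
})

test_that("Baum-Welch recovers a known model from simulated series", {
  gen <- reference_hmm()
  sims <- simulate(gen, 2000, seed = 11, length_out = 18)
  # several random restarts; keep the best by likelihood
  fits <- lapply(1:5, function(i) {
    f <- baum_welch(random_hmm(4, 10, seed = 300 + i), sims$symbols,
                    tol = 1e-8, max_iter = 200)
    list(fit = f, ll = max(attr(f, "loglik")))
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]$fit
  # align states to the generator by best agreement, then compare rows/cols
  obs_list <- asplit(sims$symbols, 1)
  lab_list <- asplit(sims$states, 1)
  aligned <- match_states(best, obs_list[1:200], lab_list[1:200])
  tv_A <- max(rowSums(abs(aligned$A - gen$A)) / 2)
  tv_B <- max(colSums(abs(aligned$B - gen$B)) / 2)
  expect_lt(tv_A, 0.05)
  expect_lt(tv_B, 0.05)
})

test_that("Baum-Welch degenerate data concentrates emissions", {
  m0 <- random_hmm(4, 10, seed = 9)
  series <- matrix(4L, nrow = 30, ncol = 18)   # single repeated symbol
  fit <- baum_welch(m0, series, max_iter = 50)
  reach <- which(fit$pi > 0.5)                 # state 1 is surely reachable
  expect_gt(fit$B[5, reach[1]], 0.99)
  expect_error(baum_welch(m0, list()), "empty")
})

test_that("Baum-Welch preserves stochasticity and the fixed start", {
  gen <- reference_hmm()
  sims <- simulate(gen, 100, seed = 3, length_out = 18)
  fit <- baum_welch(init_hmm(), sims$symbols, max_iter = 20)
  expect_equal(fit$pi, c(1, 0, 0, 0))
  expect_true(all(abs(rowSums(fit$A) - 1) < 1e-10))
  expect_true(all(abs(colSums(fit$B) - 1) < 1e-10))
  expect_true(all(fit$A >= 1e-6 / 2) && all(fit$B >= 1e-6 / 2))
})

test_that("training from boundary-topology labels yields few backward transitions", {
  ph <- straight_tube_phantom(radius_mm = 2, noise = 10)
  feats <- standardize_features(vessel_features(ph$volume), ph$axes)
  tab <- collect_series(ph$volume, ph$axes[[1]], labels = ph$labels,
                        features = feats, angular_step_deg = 15,
                        wall_thickness_vox = 2)
  fit <- mhmm(tab, features = "sato", max_iter = 10)$hmms$sato
  expect_lt(fit$A[2, 1] + fit$A[4, 1], 0.05)   # intima/adventitia -> lumen
})

test_that("MAP decoding takes the per-position argmax with low-index ties", {
  post <- rbind(c(0.2, 0.5, 0.2, 0.1),
                c(0.5, 0.5, 0, 0),
                c(0.25, 0.25, 0.25, 0.25))
  expect_equal(map_decode(post), c(2L, 1L, 1L))
  # invariant to positive rescaling of a row
  post2 <- post * 7
  expect_equal(map_decode(post2), map_decode(post))
})

test_that("training precision counts vessel-positive voxels", {
  # decoder that is perfect by construction: emissions pin the state
  m <- init_hmm(4, 4)
  m$B <- diag(4)[, ]                     # symbol k <=> state k+1
  m$A <- matrix(0.25, 4, 4)
  m$pi <- c(1, 0, 0, 0)                  # series all start in lumen
  obs <- list(c(0L, 1L, 3L), c(0L, 0L, 3L))
  labs <- list(c(1L, 2L, 4L), c(1L, 1L, 4L))
  expect_equal(training_precision(m, obs, labs), 1)
  # everything-vessel decoder on a half-vessel set scores 0.5
  m2 <- init_hmm(4, 4)
  m2$pi <- c(1, 0, 0, 0); m2$A <- rbind(c(1, 0, 0, 0))[rep(1, 4), ]
  obs2 <- list(rep(0L, 4))
  labs2 <- list(c(1L, 1L, 4L, 4L))
  expect_equal(training_precision(m2, obs2, labs2), 0.5)
  # no positive calls
  m3 <- m2; m3$pi <- c(0, 0, 0, 1); m3$A <- rbind(c(0, 0, 0, 1))[rep(1, 4), ]
  expect_warning(p <- training_precision(m3, obs2, labs2), "no positive")
  expect_equal(p, 0)
})

test_that("hmm yaml serialization round-trips", {
  m <- reference_hmm()
  path <- tempfile(fileext = ".yaml")
  write_hmm_yaml(m, path)
  m2 <- read_hmm_yaml(path)
  expect_equal(m2$A, m$A, tolerance = 1e-12)
  expect_equal(m2$B, m$B, tolerance = 1e-12)
  expect_equal(m2$pi, m$pi)
})
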