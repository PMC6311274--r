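# Multiscale Hessian vesselness features: eigen-decomposition, the five
# response formulas with their sign guards, gamma, and scale selectivity.

test_that("Hessian eigenvalues vanish on a constant volume and reject bad scales", {
  v <- vol3d(array(5, c(12, 12, 12)), spacing = 0.7)
  e <- hessian_eigenvalues(v, 1)
  expect_lt(max(abs(e$lambda1), abs(e$lambda2), abs(e$lambda3)), 1e-10)
  expect_error(hessian_eigenvalues(v, 0), "positive")
  expect_equal(gamma_from_volume(v, 1), 0)
})

test_that("Hessian of an analytic quadratic has one eigenvalue 2", {
  n <- 21
  xs <- (seq_len(n) - 1) * 0.5
  arr <- array(rep(xs^2, times = n * n), c(n, n, n))
  v <- vol3d(arr, spacing = 0.5)
  e <- hessian_eigenvalues(v, 1)
  mid <- 11
  expect_equal(e$lambda1[mid, mid, mid], 2, tolerance = 1e-3)
  expect_lt(abs(e$lambda2[mid, mid, mid]), 1e-3)
  expect_lt(abs(e$lambda3[mid, mid, mid]), 1e-3)
})

test_that("eigenvalues agree with base eigen() on sampled voxels", {
  set.seed(4)
  v <- vol3d(array(stats::rnorm(16^3, 100, 20), c(16, 16, 16)), spacing = 0.7)
  H <- mhmmseg:::hessian_components(v, 1.2)
  e <- hessian_eigenvalues(v, 1.2)
  idx <- cbind(sample(3:14, 40, TRUE), sample(3:14, 40, TRUE), sample(3:14, 40, TRUE))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]; l <- idx[k, 3]
    Hm <- matrix(c(H$h11[i, j, l], H$h12[i, j, l], H$h13[i, j, l],
                   H$h12[i, j, l], H$h22[i, j, l], H$h23[i, j, l],
                   H$h13[i, j, l], H$h23[i, j, l], H$h33[i, j, l]), 3, 3)
    ev <- sort(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    got <- c(e$lambda1[i, j, l], e$lambda2[i, j, l], e$lambda3[i, j, l])
    expect_equal(got, ev, tolerance = 1e-10)
  }
})

test_that("a bright Gaussian tube has the expected eigen-structure on axis", {
  n <- 31; sp <- 0.5
  xs <- (seq_len(n) - 1) * sp - (n - 1) * sp / 2
  sigma0 <- 1.5
  cross <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma0^2))
  arr <- array(rep(cross, times = n), c(n, n, n)) * 100
  e <- hessian_eigenvalues(vol3d(arr, sp), sigma0)
  m <- (n + 1) / 2
  l <- c(e$lambda1[m, m, m], e$lambda2[m, m, m], e$lambda3[m, m, m])
  expect_lt(abs(l[1]), 0.05 * abs(l[3]))        # axial curvature ~ 0
  expect_lt(l[2], 0); expect_lt(l[3], 0)        # cross-section negative
  expect_equal(l[2], l[3], tolerance = 0.02 * abs(l[3]))
})

test_that("Sato response follows its formula and guards", {
  e <- eigs_of(l1 = c(0, 0, -1, 2), l2 = c(0, -8, -2, -2), l3 = c(0, -9, -3, -3))
  r <- sato_feature(e, feature_params(alpha1 = 0.5, alpha2 = 2))
  expect_equal(r[1], 0)                                   # lambda2 = 0
  expect_equal(r[2], 8)                                   # lambda1 = 0
  expect_equal(r[3], 2 * exp(-0.5))                       # direct evaluation
  expect_equal(r[4], 2 * exp(-4 / (2 * 4 * 4)))           # lambda1 > 0 branch
})

test_that("Frangi response follows its formula and guards", {
  p <- feature_params()
  e <- eigs_of(c(1, 0), c(1, -10), c(-2, -10))
  r <- frangi_feature(e, p, gamma = 10)
  expect_equal(r[1], 0)                                   # lambda2 > 0
  S2 <- 200
  expect_equal(r[2], (1 - exp(-1 / (2 * 0.25))) * 1 * (1 - exp(-S2 / 200)),
               tolerance = 1e-12)
  # gamma -> Inf limit sends the structureness term to 0
  expect_lt(frangi_feature(e, p, gamma = 1e9)[2], 1e-6)
})

test_that("Shikata response is s^2 |lambda2| / I with the intensity offset", {
  v <- vol3d(array(2, c(2, 1, 1)), spacing = 1)
  e <- eigs_of(c(0, 0), c(-4, 0), c(-5, 0), s = 1)
  r <- shikata_feature(v, e)
  expect_equal(r[1], 2)                                    # 1*4/2
  expect_equal(r[2], 0)                                    # zero numerator
  e2 <- eigs_of(0, -4, -5, s = 2)
  expect_equal(shikata_feature(vol3d(array(2, c(1, 1, 1)), 1), e2)[1], 8) # s^2 law
  # non-positive intensities are shifted to >= 1 before dividing
  vneg <- vol3d(array(c(-3, 1), c(2, 1, 1)), spacing = 1)
  rneg <- shikata_feature(vneg, eigs_of(c(0, 0), c(-4, -4), c(-5, -5), s = 1))
  expect_equal(rneg[1], 4)                                 # I shifted to 1
  expect_true(all(is.finite(rneg)))
})

test_that("Li response follows its formula and guards", {
  e <- eigs_of(c(1, -1, -1), c(-2, -2, -2), c(-3, -3, -2))
  r <- li_feature(e)
  expect_equal(r[1], 0)                                    # lambda1 >= 0
  expect_equal(r[2], 2)                                    # (-2)(1)/(-1)
  expect_equal(r[3], 0)                                    # lambda2 = lambda3
})

test_that("Manniesing response guards, limits and monotonicity in c", {
  p <- feature_params()
  e <- eigs_of(c(-1, -1), c(0, -10), c(-3, -10))
  expect_equal(manniesing_feature(e, p, gamma = 10)[1], 0)  # lambda2 >= 0
  # c -> 0 limit recovers the Frangi form under the stricter guard
  r0 <- manniesing_feature(e, p, gamma = 10, c = 0)[2]
  fr <- frangi_feature(e, p, gamma = 10)[2]
  expect_equal(r0, fr, tolerance = 1e-12)
  # the noise-suppression factor decreases the response as c grows
  r_small <- manniesing_feature(e, p, gamma = 10, c = 1)[2]
  r_big <- manniesing_feature(e, p, gamma = 10, c = 2)[2]
  expect_gt(r_small, r_big)
  expect_gt(r0, r_small)
})

test_that("zero-guards hold over 1e5 random eigen-triples", {
  tr <- random_eig_triples(1e5, seed = 8)
  e <- eigs_of(tr[, 1], tr[, 2], tr[, 3])
  p <- feature_params()
  sat <- sato_feature(e, p)
  expect_true(all(sat[e$lambda2 == 0] == 0))
  fr <- frangi_feature(e, p, gamma = 5)
  expect_true(all(fr[e$lambda2 > 0 | e$lambda3 > 0] == 0))
  expect_true(all(fr >= 0 & fr <= 1))
  li <- li_feature(e)
  expect_true(all(li[!(e$lambda1 < 0 & e$lambda2 < 0)] == 0))
  man <- manniesing_feature(e, p, gamma = 5, c = 2)
  expect_true(all(man[e$lambda2 >= 0 | e$lambda3 >= 0] == 0))
  expect_true(all(man >= 0 & man <= 1))
  expect_true(all(is.finite(sat)) && all(is.finite(li)))
  expect_true(all(sat >= 0) && all(li >= 0))
})

test_that("gamma is half the max Frobenius norm and shift-invariant", {
  e <- eigs_of(c(1, 0), c(2, 0), c(3, 0))
  expect_equal(mhmmseg:::gamma_from_eigs(e), sqrt(14) / 2)
  set.seed(2)
  v <- vol3d(array(stats::rnorm(12^3), c(12, 12, 12)), spacing = 1)
  v2 <- vol3d(v$data + 1000, v$spacing)
  expect_equal(gamma_from_volume(v, 1), gamma_from_volume(v2, 1),
               tolerance = 1e-8)
})

test_that("multiscale argmax scale tracks the tube radius for all features", {
  radius <- 1.2
  ph <- analytic_tube(radius)
  scales <- default_scales()
  best <- sapply(feature_names(), function(f)
    scales[which.max(scale_response_profile(f, ph, scales))])
  # within one schedule step (factor sqrt 2) of the radius
  expect_true(all(best >= radius / sqrt(2) - 1e-3 & best <= radius * sqrt(2) + 1e-3),
              label = paste(names(best), round(best, 2), collapse = ", "))
})

test_that("multiscale response is nonnegative and a max over single scales", {
  set.seed(6)
  v <- vol3d(array(stats::rnorm(14^3, 50, 10), c(14, 14, 14)), spacing = 0.7)
  for (f in feature_names()) {
    r <- multiscale_max(v, f)
    expect_true(all(r$data >= 0), label = f)
    expect_true(all(is.finite(r$data)), label = f)
  }
  # single-scale schedule reduces to that scale's response
  p1 <- feature_params(scales_mm = 1.2)
  r1 <- multiscale_max(v, "sato", p1)
  e <- mhmmseg:::normalized_eigs(v, 1.2)
  expect_equal(r1$data, sato_feature(e), tolerance = 1e-12)
})

test_that("responses are equivariant to 90-degree rotation of a tube", {
  ph <- straight_tube_phantom(radius_mm = 1.5, grid = 28, margin = 5)
  vz <- ph$volume
  vx <- vol3d(aperm(vz$data, c(3, 2, 1)), vz$spacing)   # tube now along x
  rz <- multiscale_max(vz, "sato")
  rx <- multiscale_max(vx, "sato")
  dr <- diff(range(rz$data))
  expect_lt(max(abs(aperm(rz$data, c(3, 2, 1)) - rx$data)) / dr, 1e-3)
})

test_that("every feature separates axis from background on a clean tube", {
  ph <- straight_tube_phantom(radius_mm = 1.5, grid = 32, margin = 6)
  feats <- vessel_features(ph$volume)
  on_axis <- ph$labels$data == 1L
  bg <- ph$labels$data == 0L
  for (f in feature_names()) {
    expect_gt(mean(feats[[f]]$data[on_axis]), mean(feats[[f]]$data[bg]),
              label = f)
  }
})
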