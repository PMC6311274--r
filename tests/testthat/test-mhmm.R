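# The five-expert mixture: fitting, weights, posterior combination, fusion.

# one small labelled training table shared across tests (cached: the feature
# volumes dominate the cost and the table is read-only)
.tab_cache <- new.env(parent = emptyenv())
make_training_tab <- function(noise = 10, seeds = 1:2) {
  key <- paste0("n", noise, "_", paste(seeds, collapse = "-"))
  if (!is.null(.tab_cache[[key]])) return(.tab_cache[[key]])
  .tab_cache[[key]] <- build_training_tab(noise, seeds)
  .tab_cache[[key]]
}
build_training_tab <- function(noise = 10, seeds = 1:2) {
  do.call(rbind, lapply(seeds, function(s) {
    ph <- generate_phantom(random_phantom_config(s, noise_variance = noise,
                                                 grid_shape = c(40, 40, 40)))
    feats <- standardize_features(vessel_features(ph$volume), ph$axes)
    collect_series(ph$volume, ph$axes[[1]], labels = ph$labels, features = feats,
                   angular_step_deg = 15,
                   wall_thickness_vox = ph$config$wall_thickness_vox,
                   phantom_id = paste0("p", s))
  }))
}

test_that("mhmm fitting produces five matched experts with convex weights", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  expect_s3_class(fit, "mhmm")
  expect_named(fit$hmms, feature_names())
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$weights >= 0))
  expect_true(all(fit$precisions >= 0 & fit$precisions <= 1))
  for (h in fit$hmms) {
    expect_equal(h$pi, c(1, 0, 0, 0))
    expect_true(all(abs(rowSums(h$A) - 1) < 1e-10))
    expect_true(all(abs(colSums(h$B) - 1) < 1e-10))
  }
  expect_error(mhmm(tab[, setdiff(names(tab), "sato")]), "missing feature")
  expect_error(mhmm(tab[, setdiff(names(tab), "label")]), "label")
  expect_output(print(fit), "mhmm")
  expect_output(print(summary(fit)), "precision")
  expect_equal(coef(fit), fit$weights)
})

test_that("precision weighting follows alpha_k = P_k / sum(P)", {
  # arithmetic on the weight rule itself
  prec <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  expect_equal((prec / sum(prec))[1], 0.9 / 3.5)
  expect_equal(rep(0.2, 5), rep(1, 5) / 5)   # equal precisions -> uniform
})

test_that("mixture posterior is the weighted sum with stochastic rows", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  one <- tab[tab$series_uid == tab$series_uid[1], ]
  fs <- as.list(one[, feature_names()])
  sm <- mhmm_posterior(fit, fs)
  expect_equal(rowSums(sm$posteriors), rep(1, 18), tolerance = 1e-9)
  # manual weighted sum over the experts
  manual <- Reduce(`+`, lapply(feature_names(), function(f) {
    nv <- normalize_feature(fs[[f]], fit$calibrations[[f]])
    sym <- quantize_series(pmax(nv, 0), fit$bin_schemes[[f]])
    fit$weights[[f]] * forward_backward(fit$hmms[[f]], sym)$posteriors
  }))
  expect_equal(unname(sm$posteriors), unname(manual), tolerance = 1e-12)
  expect_error(mhmm_posterior(fit, fs[-1]), "missing feature")
  fs_bad <- fs; fs_bad$sato <- fs_bad$sato[-1]
  expect_error(mhmm_posterior(fit, fs_bad), "length mismatch")
})

test_that("single-expert limit reproduces that expert exactly", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  fit$weights[] <- c(1, 0, 0, 0, 0)
  one <- tab[tab$series_uid == tab$series_uid[10], ]
  fs <- as.list(one[, feature_names()])
  sm <- mhmm_posterior(fit, fs)
  nv <- normalize_feature(fs$sato, fit$calibrations$sato)
  solo <- forward_backward(fit$hmms$sato,
                           quantize_series(pmax(nv, 0), fit$bin_schemes$sato))
  expect_equal(unname(sm$posteriors), unname(solo$posteriors), tolerance = 1e-12)
  # mixture of identical experts equals any single posterior
  fit2 <- fit
  for (f in feature_names()) {
    fit2$hmms[[f]] <- fit$hmms$sato
    fit2$calibrations[[f]] <- fit$calibrations$sato
    fit2$bin_schemes[[f]] <- fit$bin_schemes$sato
  }
  fit2$weights[] <- 0.2
  fs_same <- stats::setNames(rep(list(fs$sato), 5), feature_names())
  expect_equal(unname(mhmm_posterior(fit2, fs_same)$posteriors),
               unname(solo$posteriors), tolerance = 1e-12)
})

test_that("predict() aligns posteriors and states with the series table", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  sub <- tab[tab$axis_index <= 2, ]
  post <- predict(fit, sub, type = "posterior")
  expect_equal(nrow(post), nrow(sub))
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
  st <- predict(fit, sub, type = "state")
  expect_equal(st, map_decode(post))
  # row alignment: the per-ray path through a clean tube starts in lumen
  sub_sorted <- sub[order(sub$series_uid, sub$sample_index), ]
  expect_true(mean(st[sub_sorted$sample_index == 1] == 1L) > 0.95)
})

test_that("fusion averages posteriors per voxel and applies the tie rule", {
  template <- vol3d(array(0, c(4, 4, 4)), spacing = 1)
  # two samples in the same voxel whose mean ties lumen/intima -> lumen (vessel)
  post <- rbind(c(0.8, 0.2, 0, 0), c(0.2, 0.8, 0, 0),
                c(0, 0, 0.1, 0.9))
  pts <- rbind(c(1, 1, 1), c(1.2, 1.2, 1.2), c(3, 3, 3))
  lab <- fuse_labels(post, pts, template)
  expect_equal(lab$data[2, 2, 2], 1L)          # tie -> lumen -> vessel
  expect_equal(lab$data[4, 4, 4], 0L)          # adventitia -> background code
  expect_equal(lab$data[1, 1, 1], 0L)          # untouched voxel
  # voxel visited by one sample inherits that sample's decoded label
  lab2 <- fuse_labels(rbind(c(0, 0.1, 0.7, 0.2)), rbind(c(2, 2, 2)), template)
  expect_equal(lab2$data[3, 3, 3], 3L)
})

test_that("segmentation is deterministic and covers the axis", {
  ph <- straight_tube_phantom(radius_mm = 2, grid = 40, margin = 8, wall = 2L,
                              noise = 20, seed = 5)
  tab <- make_training_tab(noise = 20)
  fit <- mhmm(tab, max_iter = 0L)
  seg1 <- segment_vessel(fit, ph$volume, ph$axes)
  seg2 <- segment_vessel(fit, ph$volume, ph$axes)
  expect_identical(seg1$labels$data, seg2$labels$data)
  idx <- nearest_voxel_index(seg1$vessel, ph$axes[[1]])
  expect_true(all(seg1$vessel$data[idx] == 1L))
  # 72 decoded sequences per cross-section
  cs <- segment_cross_section(fit, ph$volume, ph$axes[[1]], 5)
  expect_equal(dim(cs$states), c(72L, 18L))
  expect_length(cs$posteriors, 72L)
})

test_that("a ray through empty background never decodes lumen after the start", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  # synthetic negative control: constant background feature series
  fs <- stats::setNames(rep(list(rep(0, 18)), 5), feature_names())
  st <- map_decode(mhmm_posterior(fit, fs))
  expect_true(all(st[3:18] != 1L))
})

test_that("simulate.mhmm draws coherent series", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  sim <- simulate(fit, nsim = 5, seed = 4, length_out = 18)
  expect_equal(dim(sim$states), c(5L, 18L))
  expect_named(sim$symbols, feature_names())
  expect_true(all(sim$states[, 1] == 1L))                 # starts in lumen
  expect_true(all(sim$symbols$sato >= 0 & sim$symbols$sato <= 9))
  sim2 <- simulate(fit, nsim = 5, seed = 4, length_out = 18)
  expect_identical(sim$states, sim2$states)
})

test_that("mhmm yaml serialization round-trips the whole classifier", {
  tab <- make_training_tab()
  fit <- mhmm(tab, max_iter = 0L)
  path <- tempfile(fileext = ".yaml")
  write_mhmm_yaml(fit, path)
  back <- read_mhmm_yaml(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-9)
  one <- tab[tab$series_uid == tab$series_uid[1], ]
  fs <- as.list(one[, feature_names()])
  expect_equal(mhmm_posterior(back, fs)$posteriors,
               mhmm_posterior(fit, fs)$posteriors, tolerance = 1e-7)
})
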