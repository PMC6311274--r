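#' Configuration for the noise-sweep experiment
#'
#' Desk-scale re-creation of the synthetic noise experiment: per noise level,
#' `n_train` randomised phantoms train an MHMM and `n_test` held-out phantoms
#' are segmented and scored. Train and test phantoms draw from disjoint seed
#' ranges derived from the one experiment seed.
#'
#' @param n_train,n_test phantoms per noise level.
#' @param noise_levels Gaussian noise variances.
#' @param seed master seed; phantom seeds are derived from it.
#' @param grid_shape,spacing_mm phantom geometry.
#' @param init HMM initialisation mode (see [mhmm()]).
#' @param max_iter Baum-Welch iteration cap for the per-feature HMMs.
#' @param angular_step_deg ray spacing in degrees.
#' @param out_dir optional directory for the per-case CSV, summary CSV and
#'   box-plot figure.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_train = 15L, n_test = 5L,
                              noise_levels = c(20, 40, 60, 80),
                              seed = 1L,
                              grid_shape = c(48, 48, 48), spacing_mm = 0.7,
                              init = "supervised", max_iter = 0L,
                              angular_step_deg = 5, out_dir = NULL) {
  stopifnot(n_train >= 1, n_test >= 1, all(noise_levels >= 0))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 noise_levels = noise_levels, seed = as.integer(seed),
                 grid_shape = grid_shape, spacing_mm = spacing_mm,
                 init = init, max_iter = as.integer(max_iter),
                 angular_step_deg = angular_step_deg, out_dir = out_dir),
            class = "experiment_config")
}

# disjoint deterministic seed blocks per (experiment seed, noise level);
# kept well below 2^31
phantom_seeds <- function(config, level, role) {
  base <- (config$seed %% 1000L) * 1000000L +
    match(level, config$noise_levels) * 10000L
  if (role == "train") base + seq_len(config$n_train)
  else base + 5000L + seq_len(config$n_test)
}

# phantom -> labelled series table with the five multiscale feature columns
phantom_series <- function(phantom, config) {
  feats <- standardize_features(vessel_features(phantom$volume), phantom$axes)
  do.call(rbind, lapply(seq_along(phantom$axes), function(b)
    collect_series(phantom$volume, phantom$axes[[b]],
                   labels = phantom$labels, features = feats,
                   angular_step_deg = config$angular_step_deg,
                   wall_thickness_vox = phantom$config$wall_thickness_vox,
                   phantom_id = sprintf("p%d_b%d", phantom$config$seed, b))))
}

#' Train an MHMM on a set of phantoms
#'
#' @param phantoms list of `vessel_phantom`s.
#' @param config an [experiment_config()].
#' @return An [mhmm] fit.
#' @export
train_on_phantoms <- function(phantoms, config = experiment_config()) {
  tabs <- lapply(phantoms, phantom_series, config = config)
  mhmm(do.call(rbind, tabs), init = config$init, max_iter = config$max_iter)
}

#' Run the full noise-sweep experiment
#'
#' For each noise level: generate training phantoms, train the five-feature
#' MHMM, segment held-out test phantoms, and score the fused vessel mask
#' against the phantom ground truth (vessel = lumen + intima) with Dice
#' overlap and average symmetric surface distance. Fully deterministic for a
#' fixed config.
#'
#' @param config an [experiment_config()].
#' @param progress print per-stage progress.
#' @return A list of class `noise_sweep` with `cases` (per-phantom scores),
#'   `summary` (per-level mean and sd), and the `config`. When
#'   `config$out_dir` is set, writes `cases.csv`, `summary.csv` and
#'   `doc_boxplot.png` there.
#' @export
run_experiment <- function(config = experiment_config(), progress = interactive()) {
  t0 <- Sys.time()
  cases <- list()
  models <- list()
  for (level in config$noise_levels) {
    if (progress) message(sprintf("[noise %g] training on %d phantoms", level, config$n_train))
    train_ph <- lapply(phantom_seeds(config, level, "train"), function(s)
      generate_phantom(random_phantom_config(s, noise_variance = level,
                                             grid_shape = config$grid_shape,
                                             spacing_mm = config$spacing_mm)))
    model <- train_on_phantoms(train_ph, config)
    models[[as.character(level)]] <- model
    rm(train_ph)
    for (s in phantom_seeds(config, level, "test")) {
      ph <- generate_phantom(random_phantom_config(s, noise_variance = level,
                                                   grid_shape = config$grid_shape,
                                                   spacing_mm = config$spacing_mm))
      seg <- segment_vessel(model, ph$volume, ph$axes,
                            angular_step_deg = config$angular_step_deg)
      truth <- ph$labels$data == 1L | ph$labels$data == 2L
      sc <- evaluate_segmentation(seg$vessel, truth, spacing = ph$volume$spacing)
      cases[[length(cases) + 1L]] <- data.frame(
        noise_variance = level, phantom_seed = s,
        doc_percent = sc$doc_percent, asd_mm = sc$asd_mm)
      if (progress) message(sprintf("  test phantom %d: DOC %.1f%%, ASD %.2f mm",
                                    s, sc$doc_percent, sc$asd_mm))
    }
  }
  cases <- do.call(rbind, cases)
  summ <- do.call(rbind, lapply(split(cases, cases$noise_variance), function(d)
    data.frame(noise_variance = d$noise_variance[1],
               n = nrow(d),
               doc_mean = mean(d$doc_percent), doc_sd = stats::sd(d$doc_percent),
               asd_mean = mean(d$asd_mm), asd_sd = stats::sd(d$asd_mm))))
  summ <- summ[order(summ$noise_variance), , drop = FALSE]
  rownames(summ) <- NULL
  out <- structure(list(cases = cases, summary = summ, config = config,
                        models = models,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "noise_sweep")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

write_experiment <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$cases, file.path(dir, "cases.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  grDevices::png(file.path(dir, "doc_boxplot.png"), width = 800, height = 500)
  graphics::boxplot(doc_percent ~ noise_variance, data = report$cases,
                    xlab = "noise variance", ylab = "Dice overlap (%)",
                    main = "Vessel segmentation vs noise level")
  grDevices::dev.off()
  cfg <- report$config
  cfg$out_dir <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.noise_sweep <- function(x, ...) {
  cat(sprintf("<noise_sweep> %d train / %d test phantoms per level, %.0f s\n",
              x$config$n_train, x$config$n_test, x$elapsed_s))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  noise %3g: DOC %.2f +/- %.2f %%, ASD %.2f +/- %.2f mm (n=%d)\n",
                s$noise_variance[i], s$doc_mean[i], s$doc_sd[i],
                s$asd_mean[i], s$asd_sd[i], s$n[i]))
  }
  invisible(x)
}
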