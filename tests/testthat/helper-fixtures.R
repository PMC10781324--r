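# Shared fixtures: tiny deterministic series and a memoised cache for
# expensive trained models so several test files can reuse one run.

random_series <- function(n, site = "shoe", seed = 1, sample_rate = 50) {
  withr::with_seed(seed, {
    imu_series(as.data.frame(matrix(stats::rnorm(n * 6), n,
      dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))),
      sample_rate, site)
  })
}

random_window <- function(site = "shoe", seed = 1, scaled = FALSE) {
  withr::with_seed(seed, {
    v <- matrix(stats::runif(256 * 6), 256, 6)
    imu_window(if (scaled) v else v * 10 - 5, site, scaled = scaled)
  })
}

# noiseless, jitter-free study session reused across detector tests
noiseless_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_session(sim_config(n_strides = 12,
                                            period_jitter_sd = 0,
                                            noise_sd = 0, seed = 11))
    cache
  }
})

# Memoised small training runs shared between learnability tests and
# the architecture-comparison tests.  One paired task, fixed study
# conditions: noiseless deterministic wrist-to-shoe map.
.trained_cache <- new.env(parent = emptyenv())

learnability_task <- function() {
  if (is.null(.trained_cache$task)) {
    cfg <- sim_config(n_strides = 240, period_jitter_sd = 0,
                      noise_sd = 0, seed = 101)
    pd <- generate_paired_dataset(cfg, n_windows = 48)
    tc <- training_config(epochs = 30, batch_size = 16,
                          early_stop_patience = 8, seed = 7)
    prep <- prepare_paired_dataset(pd$wrist, pd$target, tc)
    .trained_cache$task <- list(
      pd = pd, tc = tc, paired = prep$paired, split = prep$split,
      wrist_all_scaled = scale_dataset(pd$wrist, prep$paired$wrist_scaling))
  }
  .trained_cache$task
}

trained_model <- function(arch, seed = 7, epochs = 30) {
  key <- sprintf("%s_%d_%d", arch, seed, epochs)
  if (is.null(.trained_cache[[key]])) {
    task <- learnability_task()
    tc <- training_config(epochs = epochs, batch_size = 16,
                          early_stop_patience = 8, seed = seed)
    m <- build_model(arch, seed = seed)
    if (arch != "cnn_lstm") {
      pretrain_autoencoder(m, task$wrist_all_scaled,
        training_config(epochs = 10, batch_size = 16,
                        early_stop_patience = 5, seed = seed))
      m <- freeze_encoder(m)
    }
    train_translation(m, task$paired, tc, task$split)
    .trained_cache[[key]] <- m
  }
  .trained_cache[[key]]
}

# constant-mean baseline MAE on the scaled test targets
baseline_mae <- function() {
  task <- learnability_task()
  y <- gaittrans:::dataset_to_array(task$paired$target)
  ytr <- y[task$split$train, , , drop = FALSE]
  yte <- y[task$split$test, , , drop = FALSE]
  mean(abs(sweep(yte, 3, apply(ytr, 3, mean), "-")))
}
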