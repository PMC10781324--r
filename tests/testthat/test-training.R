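# Tiny training tasks: 12 windows of 64 samples would break the fixed
# 256-sample contract, so tiny runs use few 256-sample windows and few
# epochs.

tiny_task <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_strides = 70, period_jitter_sd = 0, noise_sd = 0,
                        seed = 55)
      pd <- generate_paired_dataset(cfg, n_windows = 12)
      tc <- training_config(epochs = 3, batch_size = 4,
                            early_stop_patience = 3, seed = 3)
      prep <- prepare_paired_dataset(pd$wrist, pd$target, tc)
      cache <<- list(pd = pd, tc = tc, paired = prep$paired,
                     split = prep$split,
                     wrist_scaled = scale_dataset(pd$wrist,
                                                  prep$paired$wrist_scaling))
    }
    cache
  }
})

test_that("split honours the floor/floor/remainder rule and partitions", {
  expect_equal(lengths(split_dataset(1000, seed = 1)),
               c(train = 700L, val = 150L, test = 150L))
  expect_equal(lengths(split_dataset(10, seed = 1)),
               c(train = 7L, val = 1L, test = 2L))
  expect_error(split_dataset(2), "at least 3")
  # partition property over random n
  withr::with_seed(20, {
    for (i in 1:20) {
      n <- sample(3:500, 1)
      sp <- split_dataset(n, seed = i)
      all_idx <- c(sp$train, sp$val, sp$test)
      expect_equal(sort(all_idx), seq_len(n))
      expect_equal(length(all_idx), length(unique(all_idx)))
    }
  })
  # same seed, same split; different seed, different permutation
  expect_identical(split_dataset(100, seed = 4), split_dataset(100, seed = 4))
  expect_false(identical(split_dataset(100, seed = 4),
                         split_dataset(100, seed = 5)))
})

test_that("pretraining reduces reconstruction loss and is deterministic", {
  task <- tiny_task()
  m1 <- build_dense_autoencoder(seed = 3)
  r1 <- pretrain_autoencoder(m1, task$wrist_scaled, task$tc)
  expect_lte(r1$history$train_loss[r1$best_epoch], r1$history$train_loss[1])
  expect_true(all(r1$history$train_loss >= 0))
  # identical seeds give identical loss curves
  m2 <- build_dense_autoencoder(seed = 3)
  r2 <- pretrain_autoencoder(m2, task$wrist_scaled, task$tc)
  expect_identical(r1$history, r2$history)
  # the lstm hybrid has no pretraining stage
  expect_error(pretrain_autoencoder(build_cnn_lstm(seed = 1),
                                    task$wrist_scaled, task$tc),
               "cnn_lstm")
})

test_that("freezing keeps encoder weights bit-identical through training", {
  task <- tiny_task()
  m <- build_dense_autoencoder(seed = 6)
  pretrain_autoencoder(m, task$wrist_scaled, task$tc)
  total <- n_trainable_params(m)
  m <- freeze_encoder(m)
  enc_count <- 1536 * 512 + 512 + 512 * 256 + 256 + 256 * 128 + 128
  expect_equal(total - n_trainable_params(m), enc_count)
  expect_true(is_encoder_frozen(m))

  enc_before <- lapply(m$encoder, function(nm) m$layers[[nm]]$params)
  dec_before <- m$layers$dec1$params
  train_translation(m, task$paired, task$tc, task$split)
  enc_after <- lapply(m$encoder, function(nm) m$layers[[nm]]$params)
  expect_identical(enc_before, enc_after)
  expect_false(identical(dec_before, m$layers$dec1$params))
})

test_that("translation training requires the frozen encoder and scaled data", {
  task <- tiny_task()
  m <- build_dense_autoencoder(seed = 2)
  expect_error(train_translation(m, task$paired, task$tc), "freeze")
  raw <- windowed_dataset(task$pd$wrist$windows)
  expect_error(paired_dataset(raw, task$paired$target,
                              task$paired$wrist_scaling,
                              task$paired$target_scaling),
               "scaled")
})

test_that("validation loss at the best epoch never exceeds the first epoch's", {
  task <- tiny_task()
  m <- build_cnn_lstm(seed = 8)
  r <- train_translation(m, task$paired, task$tc, task$split)
  expect_lte(r$history$val_loss[r$best_epoch], r$history$val_loss[1])
})

test_that("fine-tuning unfreezes, uses the low rate, and does not hurt the fit", {
  task <- tiny_task()
  m <- build_dense_autoencoder(seed = 4)
  pretrain_autoencoder(m, task$wrist_scaled, task$tc)
  m <- freeze_encoder(m)
  train_translation(m, task$paired, task$tc, task$split)
  before <- evaluate_scaled(m, task$paired, task$split$test)
  r <- fine_tune(m, task$paired, task$tc, task$split)
  expect_false(is_encoder_frozen(m))
  expect_equal(r$learning_rate, 1e-4)
  after <- evaluate_scaled(m, task$paired, task$split$test)
  expect_lte(after$mse, before$mse + 1e-12)
  # no fine-tuning path for the lstm hybrid
  expect_error(fine_tune(build_cnn_lstm(seed = 1), task$paired, task$tc),
               "cnn_lstm")
})

test_that("the full pipeline is reproducible end to end under one seed", {
  task <- tiny_task()
  run <- function() {
    out <- train_pipeline("dense_ae", task$wrist_scaled, task$paired,
                          task$tc, task$split, do_fine_tune = TRUE)
    evaluate_scaled(out$model, task$paired, task$split$test)$mse
  }
  expect_identical(run(), run())
})

test_that("training logs serialise per-epoch losses with stage labels", {
  task <- tiny_task()
  m <- build_cnn_lstm(seed = 5)
  r <- train_translation(m, task$paired, task$tc, task$split)
  p <- withr::local_tempfile(fileext = ".csv")
  write_training_log(list(r), p)
  log <- read.csv(p)
  expect_named(log, c("epoch", "train_loss", "val_loss", "stage"))
  expect_equal(unique(log$stage), "translate")
})
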