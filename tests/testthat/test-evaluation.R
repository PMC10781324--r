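mk_ds <- function(mats, site = "shoe") {
  windowed_dataset(lapply(mats, imu_window, site = site, scaled = FALSE))
}

test_that("channel MAE/RMSE handle identity, offsets and the hand example", {
  withr::with_seed(30, {
    a <- matrix(rnorm(256 * 6), 256, 6)
    truth <- mk_ds(list(a))
    expect_equal(unname(channel_mae(truth, truth)), rep(0, 6))
    expect_equal(unname(channel_rmse(truth, truth)), rep(0, 6))

    shifted <- a; shifted[, 1] <- shifted[, 1] + 0.5
    expect_equal(unname(channel_mae(mk_ds(list(shifted)), truth)),
                 c(0.5, rep(0, 6 - 1)))

    # errors (1,2,3) on one channel: MAE 2, RMSE sqrt(14/3)
    b <- matrix(0, 256, 6)
    bt <- b; b[1:3, 2] <- c(1, 2, 3)
    # pool over exactly those three samples: use a 3-row window? the
    # window contract is fixed, so embed and correct for zeros
    mae <- channel_mae(mk_ds(list(b)), mk_ds(list(bt)))
    expect_equal(unname(mae[2]), (1 + 2 + 3) / 256)
    rmse <- channel_rmse(mk_ds(list(b)), mk_ds(list(bt)))
    expect_equal(unname(rmse[2]), sqrt(14 / 256))
  })
})

test_that("metrics equal a brute-force double loop on random windows", {
  withr::with_seed(31, {
    p <- list(matrix(rnorm(256 * 6), 256, 6), matrix(rnorm(256 * 6), 256, 6))
    t_ <- list(matrix(rnorm(256 * 6), 256, 6), matrix(rnorm(256 * 6), 256, 6))
    mae <- channel_mae(mk_ds(p), mk_ds(t_))
    rmse <- channel_rmse(mk_ds(p), mk_ds(t_))
    for (ch in 1:6) {
      acc <- c()
      for (w in 1:2) for (i in 1:256)
        acc <- c(acc, p[[w]][i, ch] - t_[[w]][i, ch])
      expect_equal(unname(mae[ch]), mean(abs(acc)))
      expect_equal(unname(rmse[ch]), sqrt(mean(acc^2)))
      expect_gte(rmse[ch], mae[ch])
    }
  })
})

test_that("RMSE >= MAE with equality iff absolute errors are constant", {
  withr::with_seed(32, {
    for (i in 1:5) {
      p <- mk_ds(list(matrix(rnorm(256 * 6), 256, 6)))
      t_ <- mk_ds(list(matrix(rnorm(256 * 6), 256, 6)))
      expect_true(all(channel_rmse(p, t_) >= channel_mae(p, t_)))
    }
    # constant absolute error: equality
    a <- matrix(0, 256, 6)
    b <- a + 0.3
    expect_equal(channel_rmse(mk_ds(list(b)), mk_ds(list(a))),
                 channel_mae(mk_ds(list(b)), mk_ds(list(a))))
  })
})

test_that("shape or count mismatches are rejected", {
  a <- mk_ds(list(matrix(0, 256, 6)))
  b <- mk_ds(list(matrix(0, 256, 6), matrix(0, 256, 6)))
  expect_error(channel_mae(a, b), "counts differ")
})

test_that("errors in physical units differ from scaled-space errors", {
  # non-trivial scalers: evaluating in scaled space must NOT reproduce
  # the physical-unit table
  withr::with_seed(33, {
    p <- matrix(runif(256 * 6), 256, 6)
    t_ <- matrix(runif(256 * 6), 256, 6)
    scal <- scaling_params(mins = rep(0, 6), maxs = c(4, 4, 4, 500, 500, 500))
    unscale <- function(m) sweep(m, 2, scal$maxs - scal$mins, "*")
    mae_phys <- channel_mae(mk_ds(list(unscale(p))), mk_ds(list(unscale(t_))))
    mae_scaled <- channel_mae(mk_ds(list(p)), mk_ds(list(t_)))
    expect_false(isTRUE(all.equal(unname(mae_phys), unname(mae_scaled))))
    # and they differ exactly by the channel ranges
    expect_equal(unname(mae_phys), unname(mae_scaled * (scal$maxs - scal$mins)))
  })
})

test_that("architecture comparison emits a 4-row x 12-cell table", {
  task <- learnability_task()
  models <- list(dense_ae = build_dense_autoencoder(seed = 1),
                 cnn_ae = build_cnn_autoencoder(seed = 1),
                 cnn_lstm = build_cnn_lstm(seed = 1),
                 unet = build_unet(seed = 1))
  cmp <- compare_architectures(models, task$paired, task$split$test)
  expect_equal(nrow(cmp), 8)                 # 4 architectures x {MAE, RMSE}
  expect_equal(sum(cmp$metric == "MAE"), 4)
  num <- as.matrix(cmp[, gaittrans:::IMU_CHANNELS])
  expect_equal(dim(num), c(8, 6))            # 6 MAE + 6 RMSE cells per row
  expect_true(all(num >= 0))
  expect_error(compare_architectures(models[-1], task$paired), "missing model")

  p <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(cmp, p)
  expect_equal(nrow(read.csv(p)), 8)
})

test_that("a model's own targets evaluated as predictions give a zero row", {
  task <- learnability_task()
  truth <- unscale_dataset(task$paired$target, task$paired$target_scaling)
  expect_equal(unname(channel_mae(truth, truth)), rep(0, 6))
  expect_equal(unname(channel_rmse(truth, truth)), rep(0, 6))
})
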