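closed_form_dense <- function(n_in, n_out) n_in * n_out + n_out
closed_form_conv <- function(n_in, k, n_out) n_in * k * n_out + n_out
closed_form_lstm <- function(n_in, units) 4 * ((n_in + units) * units + units)

test_that("dense autoencoder: widths, output contract, parameter counts", {
  m <- build_dense_autoencoder(seed = 1)
  widths <- vapply(c("enc1", "enc2", "enc3"),
                   function(nm) m$layers[[nm]]$meta$n_out, numeric(1))
  expect_equal(unname(widths), c(512, 256, 128))
  # first encoder layer: 1536*512 + 512
  expect_equal(gaittrans:::layer_n_params(m$layers$enc1), 786944)
  expect_equal(n_params(m),
               closed_form_dense(1536, 512) + closed_form_dense(512, 256) +
               closed_form_dense(256, 128) + closed_form_dense(128, 256) +
               closed_form_dense(256, 512) + closed_form_dense(512, 1536))
  y <- gaittrans:::model_forward(m, array(rnorm(2 * 256 * 6, sd = 5), c(2, 256, 6)))
  expect_equal(dim(y), c(2, 256, 6))
  expect_true(all(y >= 0 & y <= 1))
})

test_that("cnn autoencoder: filter sequence, latent shape, parameter counts", {
  m <- build_cnn_autoencoder(seed = 1)
  filters <- vapply(c("enc_conv1", "enc_conv2", "enc_conv3", "dec_tconv1",
                      "dec_tconv2", "dec_tconv3", "head"),
                    function(nm) m$layers[[nm]]$meta$filters, numeric(1))
  expect_equal(unname(filters), c(64, 128, 256, 256, 128, 64, 6))
  # encoder output is 64 samples x 256 filters
  x <- array(runif(256 * 6), c(1, 256, 6))
  h <- x
  for (nm in c("enc_conv1", "pool1", "enc_conv2", "pool2", "enc_conv3"))
    h <- gaittrans:::layer_forward(m$layers[[nm]], h)
  expect_equal(dim(h), c(1, 64, 256))
  expect_equal(n_params(m),
               closed_form_conv(6, 3, 64) + closed_form_conv(64, 3, 128) +
               closed_form_conv(128, 3, 256) + closed_form_conv(256, 3, 256) +
               closed_form_conv(256, 3, 128) + closed_form_conv(128, 3, 64) +
               closed_form_conv(64, 3, 6))
})

test_that("cnn-lstm: units, conv parameter count, full-sequence output", {
  m <- build_cnn_lstm(seed = 1)
  expect_equal(m$layers$conv$meta$filters, 64)
  expect_equal(m$layers$lstm1$meta$units, 64)
  expect_equal(m$layers$lstm2$meta$units, 6)
  expect_equal(gaittrans:::layer_n_params(m$layers$conv), 1216)  # 6*3*64 + 64
  expect_equal(n_params(m),
               closed_form_conv(6, 3, 64) + closed_form_lstm(64, 64) +
               closed_form_lstm(64, 6))
  y <- gaittrans:::model_forward(m, array(runif(256 * 6), c(1, 256, 6)))
  expect_equal(dim(y), c(1, 256, 6))
  expect_true(all(y > -1 & y < 1))          # tanh head
})

test_that("unet: skip concatenation arithmetic and layer order", {
  m <- build_unet(seed = 1)
  # decoder input channel counts reflect the concatenations
  expect_equal(m$layers$dec_tconv2$meta$n_in, 384)   # 256 + 128
  expect_equal(m$layers$dec_tconv3$meta$n_in, 192)   # 128 + 64
  tr <- layer_shape_trace(m)
  expect_equal(tr$kind[6:9], c("tconv1d", "tconv1d", "tconv1d", "conv1d"))
  expect_equal(tr$shape[nrow(tr)], "256 x 6")
  y <- gaittrans:::model_forward(m, array(runif(2 * 256 * 6), c(2, 256, 6)))
  expect_true(all(y >= 0 & y <= 1))
})

test_that("every architecture's shape trace is consistent and ends at 256 x 6", {
  for (arch in c("dense_ae", "cnn_ae", "cnn_lstm", "unet")) {
    tr <- layer_shape_trace(build_model(arch, seed = 2))
    expect_equal(tr$shape[nrow(tr)], "256 x 6", label = arch)
    expect_equal(sum(tr$params), n_params(build_model(arch, seed = 2)),
                 label = arch)
  }
})

test_that("sigmoid-headed outputs stay in [0,1] across many random windows", {
  withr::with_seed(77, {
    # 1000 random windows in batches; inputs well outside the unit band
    for (arch in c("dense_ae", "cnn_ae", "unet")) {
      m <- build_model(arch, seed = 5)
      ok <- TRUE
      for (b in 1:10) {
        x <- array(rnorm(100 * 256 * 6, sd = 3), c(100, 256, 6))
        y <- gaittrans:::model_forward(m, x)
        ok <- ok && all(y >= 0 & y <= 1)
      }
      expect_true(ok, label = arch)
    }
  })
})

test_that("translate_window maps into the target's physical range", {
  m <- build_cnn_autoencoder(seed = 9)
  w <- random_window(site = "wrist", seed = 4, scaled = TRUE)
  scal <- scaling_params(rep(0, 6), rep(10, 6))
  out <- translate_window(m, w, scal, "shoe")
  expect_equal(dim(out$values), c(256, 6))
  expect_false(out$scaled)
  expect_equal(out$site, "shoe")
  expect_true(all(out$values >= 0 & out$values <= 10))
  expect_error(translate_window(m, random_window(site = "wrist", seed = 4),
                                scal, "shoe"), "scaled")
})

test_that("models survive a save/load round trip bit-exactly", {
  dir <- withr::local_tempdir()
  m <- build_cnn_lstm(seed = 31)
  p <- file.path(dir, "m.rds")
  save_model(m, p)
  m2 <- load_model(p)
  x <- array(runif(256 * 6), c(1, 256, 6))
  expect_identical(gaittrans:::model_forward(m, x),
                   gaittrans:::model_forward(m2, x))
})
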