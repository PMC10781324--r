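# The four wrist-to-lower-limb translation architectures.
#
# All four share one contract: a scaled 256 x 6 window in, a 256 x 6
# matrix out.  The dense and convolutional autoencoders and the U-Net
# end in a sigmoid head, so their outputs live in [0, 1], matching the
# unit-scaled target band; the CNN-LSTM ends in the tanh output of its
# last LSTM layer, whose (-1, 1) range covers the same band without an
# extra squashing layer.

ARCHITECTURES <- c("dense_ae", "cnn_ae", "cnn_lstm", "unet")

new_translation_model <- function(architecture, layers, order, encoder) {
  state <- new.env(parent = emptyenv())
  state$encoder_frozen <- FALSE
  state$trained_stages <- character(0)
  structure(list(architecture = architecture,
                 layers = layers,       # named list of nn_layer envs
                 order = order,         # forward order (sequential part)
                 encoder = encoder,     # names of feature-extraction layers
                 state = state),        # mutable training state
            class = "translation_model")
}

#' Is the encoder currently frozen?
#' @param model a `translation_model`.
#' @return Logical.
#' @export
is_encoder_frozen <- function(model) model$state$encoder_frozen

#' Training stages a model has completed
#' @param model a `translation_model`.
#' @return Character vector of stage labels.
#' @export
trained_stages <- function(model) model$state$trained_stages

#' @export
print.translation_model <- function(x, ...) {
  cat(sprintf("<translation_model> %s  (%s trainable / %s total parameters)%s\n",
              x$architecture,
              format(n_trainable_params(x), big.mark = ","),
              format(n_params(x), big.mark = ","),
              if (is_encoder_frozen(x)) "  [encoder frozen]" else ""))
  print(layer_shape_trace(x))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Build the dense (fully connected) autoencoder
#'
#' The 256 x 6 input is flattened to a 1536-vector, encoded through
#' ReLU layers of 512, 256 and 128 units, decoded through 256 and 512
#' units, projected back to 1536 values by a sigmoid layer and
#' reshaped to 256 x 6.  The final layer must have width 1536 (not
#' 1024): a narrower layer could not be reshaped into six 256-sample
#' sequences.
#'
#' @param seed integer seed for weight initialisation.
#' @return A `translation_model` of architecture `"dense_ae"`.
#' @export
build_dense_autoencoder <- function(seed = 1L) {
  with_seed(seed, {
    layers <- list(
      flatten = layer_flatten(WINDOW_LENGTH, 6),
      enc1 = layer_dense(1536, 512, "relu"),
      enc2 = layer_dense(512, 256, "relu"),
      enc3 = layer_dense(256, 128, "relu"),
      dec1 = layer_dense(128, 256, "relu"),
      dec2 = layer_dense(256, 512, "relu"),
      dec3 = layer_dense(512, 1536, "sigmoid"),
      reshape = layer_reshape(WINDOW_LENGTH, 6))
    new_translation_model("dense_ae", layers, names(layers),
                          encoder = c("enc1", "enc2", "enc3"))
  })
}

#' Build the 1-D convolutional autoencoder
#'
#' Encoder: three length-preserving kernel-3 ReLU convolutions with
#' 64, 128 and 256 filters, the first two each followed by max
#' pooling of size 2 (sequence length 256 -> 128 -> 64).  Decoder:
#' transposed convolutions with 256, 128 and 64 filters (strides 2,
#' 2, 1, restoring length 64 -> 128 -> 256) and a kernel-3 sigmoid
#' convolution down to 6 channels.
#'
#' @inheritParams build_dense_autoencoder
#' @return A `translation_model` of architecture `"cnn_ae"`.
#' @export
build_cnn_autoencoder <- function(seed = 1L) {
  with_seed(seed, {
    layers <- list(
      enc_conv1 = layer_conv1d(6, 64, 3, "relu"),
      pool1 = layer_maxpool(2),
      enc_conv2 = layer_conv1d(64, 128, 3, "relu"),
      pool2 = layer_maxpool(2),
      enc_conv3 = layer_conv1d(128, 256, 3, "relu"),
      dec_tconv1 = layer_tconv1d(256, 256, 3, stride = 2, "relu"),
      dec_tconv2 = layer_tconv1d(256, 128, 3, stride = 2, "relu"),
      dec_tconv3 = layer_tconv1d(128, 64, 3, stride = 1, "relu"),
      head = layer_conv1d(64, 6, 3, "sigmoid"))
    new_translation_model("cnn_ae", layers, names(layers),
                          encoder = c("enc_conv1", "enc_conv2", "enc_conv3"))
  })
}

#' Build the CNN-LSTM hybrid
#'
#' A single kernel-3 ReLU convolution with 64 filters extracts local
#' features; two stacked LSTM layers (64 and 6 units, both returning
#' the full sequence) model the temporal relations, so one call
#' translates a whole 256-sample window.
#'
#' @inheritParams build_dense_autoencoder
#' @return A `translation_model` of architecture `"cnn_lstm"`.
#' @export
build_cnn_lstm <- function(seed = 1L) {
  with_seed(seed, {
    layers <- list(
      conv = layer_conv1d(6, 64, 3, "relu"),
      lstm1 = layer_lstm(64, 64),
      lstm2 = layer_lstm(64, 6))
    new_translation_model("cnn_lstm", layers, names(layers),
                          encoder = character(0))
  })
}

#' Build the 1-D U-Net
#'
#' The contraction path is identical to the convolutional
#' autoencoder's encoder.  The expansion path interleaves transposed
#' convolutions with skip connections: each upsampled activation is
#' concatenated with the contraction activation of matching sequence
#' length (256 + 128 = 384 channels at length 128, then 128 + 64 =
#' 192 channels at length 256) before the next layer, so the decoder
#' sees both high- and low-level features while rebuilding the
#' signal.
#'
#' @inheritParams build_dense_autoencoder
#' @return A `translation_model` of architecture `"unet"`.
#' @export
build_unet <- function(seed = 1L) {
  with_seed(seed, {
    layers <- list(
      enc_conv1 = layer_conv1d(6, 64, 3, "relu"),
      pool1 = layer_maxpool(2),
      enc_conv2 = layer_conv1d(64, 128, 3, "relu"),
      pool2 = layer_maxpool(2),
      enc_conv3 = layer_conv1d(128, 256, 3, "relu"),
      dec_tconv1 = layer_tconv1d(256, 256, 3, stride = 2, "relu"),
      dec_tconv2 = layer_tconv1d(256 + 128, 128, 3, stride = 2, "relu"),
      dec_tconv3 = layer_tconv1d(128 + 64, 64, 3, stride = 1, "relu"),
      head = layer_conv1d(64, 6, 3, "sigmoid"))
    new_translation_model("unet", layers, names(layers),
                          encoder = c("enc_conv1", "enc_conv2", "enc_conv3"))
  })
}

#' Build a translation model by architecture name
#'
#' @param architecture one of `"dense_ae"`, `"cnn_ae"`, `"cnn_lstm"`,
#'   `"unet"`.
#' @param seed integer seed for weight initialisation.
#' @return A `translation_model`.
#' @export
build_model <- function(architecture = ARCHITECTURES, seed = 1L) {
  architecture <- match.arg(architecture)
  switch(architecture,
         dense_ae = build_dense_autoencoder(seed),
         cnn_ae = build_cnn_autoencoder(seed),
         cnn_lstm = build_cnn_lstm(seed),
         unet = build_unet(seed))
}

# concatenate along the channel dimension
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , (da[3] + 1):(da[3] + db[3])] <- b
  out
}

# ------------------------------------------------- forward / backward

model_forward <- function(model, x) {
  if (model$architecture == "unet") return(unet_forward(model, x))
  for (nm in model$order) x <- layer_forward(model$layers[[nm]], x)
  x
}

model_backward <- function(model, dy) {
  if (model$architecture == "unet") return(unet_backward(model, dy))
  for (nm in rev(model$order)) dy <- layer_backward(model$layers[[nm]], dy)
  dy
}

unet_forward <- function(model, x) {
  ly <- model$layers
  a1 <- layer_forward(ly$enc_conv1, x)       # 256 x 64
  p1 <- layer_forward(ly$pool1, a1)          # 128 x 64
  a2 <- layer_forward(ly$enc_conv2, p1)      # 128 x 128
  p2 <- layer_forward(ly$pool2, a2)          #  64 x 128
  a3 <- layer_forward(ly$enc_conv3, p2)      #  64 x 256
  u1 <- layer_forward(ly$dec_tconv1, a3)     # 128 x 256
  c1 <- concat_channels(u1, a2)              # 128 x 384
  u2 <- layer_forward(ly$dec_tconv2, c1)     # 256 x 128
  c2 <- concat_channels(u2, a1)              # 256 x 192
  u3 <- layer_forward(ly$dec_tconv3, c2)     # 256 x 64
  layer_forward(ly$head, u3)                 # 256 x 6
}

unet_backward <- function(model, dy) {
  ly <- model$layers
  du3 <- layer_backward(ly$head, dy)
  dc2 <- layer_backward(ly$dec_tconv3, du3)
  du2 <- dc2[, , 1:128, drop = FALSE]
  da1_skip <- dc2[, , 129:192, drop = FALSE]
  dc1 <- layer_backward(ly$dec_tconv2, du2)
  du1 <- dc1[, , 1:256, drop = FALSE]
  da2_skip <- dc1[, , 257:384, drop = FALSE]
  da3 <- layer_backward(ly$dec_tconv1, du1)
  dp2 <- layer_backward(ly$enc_conv3, da3)
  da2 <- layer_backward(ly$pool2, dp2) + da2_skip
  dp1 <- layer_backward(ly$enc_conv2, da2)
  da1 <- layer_backward(ly$pool1, dp1) + da1_skip
  layer_backward(ly$enc_conv1, da1)
}

# ------------------------------------------------------- introspection

#' Total and trainable parameter counts
#'
#' `n_params` counts every weight and bias; `n_trainable_params`
#' excludes frozen layers.
#'
#' @param model a `translation_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, layer_n_params, numeric(1)))
}

#' @rdname n_params
#' @export
n_trainable_params <- function(model) {
  sum(vapply(model$layers,
             function(ly) if (ly$frozen) 0 else layer_n_params(ly),
             numeric(1)))
}

#' Per-layer output-shape trace
#'
#' Propagates a probe window through the model and records every
#' layer's output shape (sequence length x channels, or flat width
#' for dense layers), ending at 256 x 6 for every architecture.
#'
#' @param model a `translation_model`.
#' @return A data frame with columns `layer`, `kind`, `shape`,
#'   `params`.
#' @export
layer_shape_trace <- function(model) {
  x <- array(0.5, c(1, WINDOW_LENGTH, 6))
  rows <- list()
  push <- function(nm, ly, out) {
    shape <- if (length(dim(out)) == 3)
      sprintf("%d x %d", dim(out)[2], dim(out)[3])
    else sprintf("%d", ncol(out))
    rows[[length(rows) + 1]] <<- data.frame(
      layer = nm, kind = ly$kind, shape = shape,
      params = layer_n_params(ly))
  }
  if (model$architecture == "unet") {
    ly <- model$layers
    a1 <- layer_forward(ly$enc_conv1, x); push("enc_conv1", ly$enc_conv1, a1)
    p1 <- layer_forward(ly$pool1, a1); push("pool1", ly$pool1, p1)
    a2 <- layer_forward(ly$enc_conv2, p1); push("enc_conv2", ly$enc_conv2, a2)
    p2 <- layer_forward(ly$pool2, a2); push("pool2", ly$pool2, p2)
    a3 <- layer_forward(ly$enc_conv3, p2); push("enc_conv3", ly$enc_conv3, a3)
    u1 <- layer_forward(ly$dec_tconv1, a3); push("dec_tconv1", ly$dec_tconv1, u1)
    c1 <- concat_channels(u1, a2)
    u2 <- layer_forward(ly$dec_tconv2, c1); push("dec_tconv2 (after concat 384)", ly$dec_tconv2, u2)
    c2 <- concat_channels(u2, a1)
    u3 <- layer_forward(ly$dec_tconv3, c2); push("dec_tconv3 (after concat 192)", ly$dec_tconv3, u3)
    y <- layer_forward(ly$head, u3); push("head", ly$head, y)
  } else {
    for (nm in model$order) {
      x <- layer_forward(model$layers[[nm]], x)
      push(nm, model$layers[[nm]], x)
    }
  }
  for (ly in model$layers) layer_clear_cache(ly)
  do.call(rbind, rows)
}

#' Translate one window to the target site
#'
#' Runs the forward pass on a unit-scaled wrist window and maps the
#' network output back to physical units with the target site's
#' scaling parameters.
#'
#' @param model a trained `translation_model`.
#' @param window a scaled [imu_window()] (wrist scaler).
#' @param target_scaling [scaling_params()] of the target site.
#' @param target_site site tag for the output window.
#' @return An unscaled [imu_window()] at the target site.
#' @export
translate_window <- function(model, window, target_scaling,
                             target_site = c("shoe", "tibia")) {
  target_site <- match.arg(target_site)
  if (!window$scaled) stop("input window must be scaled")
  x <- array(window$values, c(1, nrow(window$values), 6))
  y <- model_forward(model, x)[1, , ]
  # tanh-headed models may leave the unit band slightly; clamp before
  # mapping back so the output respects the target's physical range
  y <- pmin(pmax(y, 0), 1)
  rng <- target_scaling$maxs - target_scaling$mins
  v <- sweep(sweep(y, 2, rng, "*"), 2, target_scaling$mins, "+")
  for (ly in model$layers) layer_clear_cache(ly)
  imu_window(v, target_site, scaled = FALSE)
}

#' Translate every window of a dataset
#'
#' @param model a trained `translation_model`.
#' @param dataset scaled wrist [windowed_dataset()].
#' @param target_scaling [scaling_params()] of the target site.
#' @param target_site site tag for the outputs.
#' @return An unscaled [windowed_dataset()] at the target site.
#' @export
translate_dataset <- function(model, dataset, target_scaling,
                              target_site = c("shoe", "tibia")) {
  target_site <- match.arg(target_site)
  if (!dataset$scaled) stop("input dataset must be scaled")
  x <- dataset_to_array(dataset)
  y <- model_forward(model, x)
  y <- pmin(pmax(y, 0), 1)
  rng <- target_scaling$maxs - target_scaling$mins
  for (j in 1:6) y[, , j] <- y[, , j] * rng[j] + target_scaling$mins[j]
  for (ly in model$layers) layer_clear_cache(ly)
  array_to_dataset(y, target_site, scaled = FALSE)
}

#' Save / load a translation model
#'
#' Serialises the architecture name, layer manifest and weights into
#' a single file.
#'
#' @param model a `translation_model`.
#' @param path file path.
#' @return `load_model` returns the restored `translation_model`.
#' @export
save_model <- function(model, path) {
  for (ly in model$layers) layer_clear_cache(ly)
  payload <- list(architecture = model$architecture,
                  order = model$order,
                  encoder = model$encoder,
                  encoder_frozen = is_encoder_frozen(model),
                  trained_stages = trained_stages(model),
                  layer_spec = lapply(model$layers, function(ly)
                    list(kind = ly$kind, meta = ly$meta)),
                  weights = lapply(model$layers, function(ly) ly$params))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  model <- build_model(payload$architecture, seed = 0L)
  stopifnot(identical(names(model$layers), names(payload$weights)))
  for (nm in names(model$layers)) {
    if (length(payload$weights[[nm]]))
      model$layers[[nm]]$params <- payload$weights[[nm]]
  }
  model$state$encoder_frozen <- payload$encoder_frozen
  model$state$trained_stages <- payload$trained_stages
  if (payload$encoder_frozen)
    for (nm in model$encoder) model$layers[[nm]]$frozen <- TRUE
  model
}
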