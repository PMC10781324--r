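# Two-stage training protocol.
#
# The autoencoders and the U-Net are first pretrained unsupervised on
# wrist windows (input = label), their feature-extraction layers are
# frozen, the reconstruction layers are trained on paired
# wrist-to-target windows, and the whole network is finally fine-tuned
# with the encoder unfrozen at a ten-fold lower learning rate.  The
# CNN-LSTM has no pretraining stage and is trained directly on the
# translation pairs.

#' Training configuration
#'
#' @param learning_rate Adam learning rate for pretraining and
#'   translation training (default 1e-3).
#' @param fine_tune_rate Adam learning rate for the fine-tuning stage
#'   (default 1e-4).
#' @param epochs maximum number of epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param early_stop_patience epochs without validation improvement
#'   before stopping; the best-epoch weights are restored (default 10).
#' @param split_fractions train/validation/test fractions, summing to
#'   1 (default 0.70/0.15/0.15).
#' @param seed integer seed governing the split permutation and epoch
#'   shuffling.
#' @return A `training_config` list.  The loss is always mean squared
#'   error and the optimizer always Adam.
#' @export
training_config <- function(learning_rate = 1e-3, fine_tune_rate = 1e-4,
                            epochs = 100L, batch_size = 32L,
                            early_stop_patience = 10L,
                            split_fractions = c(0.70, 0.15, 0.15),
                            seed = 1L) {
  stopifnot(learning_rate > 0, fine_tune_rate > 0, epochs >= 1,
            batch_size >= 1, early_stop_patience >= 1,
            length(split_fractions) == 3,
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(loss = "mse", optimizer = "adam",
                 learning_rate = learning_rate,
                 fine_tune_rate = fine_tune_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Split indices into train / validation / test
#'
#' A seeded permutation assigns `floor(f_train * n)` indices to
#' training, `floor(f_val * n)` to validation and the remainder to
#' testing; the three parts are disjoint and exhaustive.
#'
#' @param n number of items (>= 3), or a [windowed_dataset()] whose
#'   length is used.
#' @param fractions length-3 fractions summing to 1.
#' @param seed integer seed for the permutation.
#' @return A list of integer index vectors `train`, `val`, `test`.
#' @export
#' @examples
#' sizes <- lengths(split_dataset(1000, seed = 7))  # 700 150 150
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (inherits(n, "windowed_dataset")) n <- length(n)
  n <- as.integer(n)
  if (n < 3) stop("need at least 3 items to form a 3-way split")
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[(n_train + 1):(n_train + n_val)]),
       test = sort(perm[(n_train + n_val + 1):n]))
}

#' Index-aligned scaled wrist/target window pairs
#'
#' Both sides are scaled with their own site's parameters (fitted on
#' the training portion of each side).
#'
#' @param wrist,target [windowed_dataset()]s of equal length, both
#'   scaled.
#' @param wrist_scaling,target_scaling the [scaling_params()] used.
#' @return A `paired_dataset` list.
#' @export
paired_dataset <- function(wrist, target, wrist_scaling, target_scaling) {
  if (length(wrist) != length(target))
    stop("wrist and target window counts differ")
  if (!wrist$scaled || !target$scaled)
    stop("both sides must be scaled with their site scalers")
  structure(list(wrist = wrist, target = target,
                 target_site = target$site,
                 wrist_scaling = wrist_scaling,
                 target_scaling = target_scaling),
            class = "paired_dataset")
}

#' Build a scaled paired dataset from raw windows
#'
#' Splits the pairs 70/15/15, fits each side's unit scaler on the
#' training portion only, scales everything with those parameters and
#' returns the paired dataset together with the split indices.
#'
#' @param wrist,target unscaled [windowed_dataset()]s of equal
#'   length.
#' @param config a [training_config()].
#' @return A list with `paired` (a [paired_dataset()]) and `split`.
#' @export
prepare_paired_dataset <- function(wrist, target, config = training_config()) {
  split <- split_dataset(length(wrist), config$split_fractions, config$seed)
  w_scaler <- fit_unit_scaler(windowed_dataset(wrist$windows[split$train]))
  t_scaler <- fit_unit_scaler(windowed_dataset(target$windows[split$train]))
  list(paired = paired_dataset(scale_dataset(wrist, w_scaler),
                               scale_dataset(target, t_scaler),
                               w_scaler, t_scaler),
       split = split)
}

mse_loss <- function(pred, truth) mean((pred - truth)^2)

snapshot_weights <- function(model) lapply(model$layers, function(ly) ly$params)

restore_weights <- function(model, snap) {
  for (nm in names(snap)) model$layers[[nm]]$params <- snap[[nm]]
  invisible(model)
}

reset_adam <- function(model) {
  for (ly in model$layers) ly$adam <- NULL
  invisible(model)
}

# Core minibatch loop shared by all stages.  x, y: (n, 256, 6) arrays.
train_loop <- function(model, x, y, x_val, y_val, lr, config, stage) {
  n <- dim(x)[1]
  steps <- 0L
  best_val <- Inf; best_epoch <- 0L; best_snap <- snapshot_weights(model)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  reset_adam(model)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + 7919L * epoch, sample.int(n))
    ep_loss <- 0
    for (b in seq(1, n, by = config$batch_size)) {
      idx <- ord[b:min(b + config$batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx, , , drop = FALSE]
      pred <- model_forward(model, xb)
      ep_loss <- ep_loss + mse_loss(pred, yb) * length(idx)
      dpred <- 2 * (pred - yb) / length(pred)
      model_backward(model, dpred)
      steps <- steps + 1L
      for (ly in model$layers) adam_step(ly, lr, steps)
    }
    ep_loss <- ep_loss / n
    val_pred <- model_forward(model, x_val)
    val_loss <- mse_loss(val_pred, y_val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_epoch <- epoch
      best_snap <- snapshot_weights(model)
    } else if (epoch - best_epoch >= config$early_stop_patience) {
      break
    }
  }
  restore_weights(model, best_snap)
  for (ly in model$layers) layer_clear_cache(ly)
  structure(list(history = hist, best_epoch = best_epoch,
                 best_val_loss = best_val, stage = stage,
                 learning_rate = lr),
            class = "training_report")
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("<training_report> stage=%s  %d epochs  best epoch %d (val loss %.5f)\n",
              x$stage, nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Unsupervised wrist pretraining
#'
#' Trains an autoencoding architecture with the wrist windows as both
#' input and label, so the encoder learns a generic representation of
#' wrist motion before any paired data is seen.  Not applicable to
#' the CNN-LSTM, which is trained directly on the translation pairs.
#'
#' @param model a `translation_model` of architecture `dense_ae`,
#'   `cnn_ae` or `unet`.
#' @param wrist_dataset scaled wrist [windowed_dataset()].
#' @param config a [training_config()].
#' @return A `training_report`; the model is updated in place (its
#'   layers and training state are mutable environments).
#' @export
pretrain_autoencoder <- function(model, wrist_dataset, config = training_config()) {
  if (model$architecture == "cnn_lstm")
    stop("cnn_lstm has no pretraining stage; train it directly on the translation pairs")
  if (!wrist_dataset$scaled) stop("pretraining data must be scaled")
  split <- split_dataset(length(wrist_dataset), config$split_fractions,
                         config$seed)
  x <- dataset_to_array(wrist_dataset)
  rep <- train_loop(model,
                    x[split$train, , , drop = FALSE], x[split$train, , , drop = FALSE],
                    x[split$val, , , drop = FALSE], x[split$val, , , drop = FALSE],
                    config$learning_rate, config, "pretrain")
  model$state$trained_stages <- c(model$state$trained_stages, "pretrain")
  rep
}

#' Freeze the feature-extraction layers
#'
#' Marks the encoder (contraction) layers non-trainable so subsequent
#' translation training only updates the reconstruction layers.
#'
#' @param model a pretrained `translation_model`.
#' @return The model, with `encoder_frozen = TRUE`.
#' @export
freeze_encoder <- function(model) {
  if (!length(model$encoder))
    stop("architecture has no encoder stage to freeze")
  for (nm in model$encoder) model$layers[[nm]]$frozen <- TRUE
  model$state$encoder_frozen <- TRUE
  model
}

#' Unfreeze all layers
#' @param model a `translation_model`.
#' @return The model with every layer trainable.
#' @export
unfreeze_encoder <- function(model) {
  for (ly in model$layers) ly$frozen <- FALSE
  model$state$encoder_frozen <- FALSE
  model
}

#' Paired translation training
#'
#' Minimises the mean squared error between the model's output on
#' scaled wrist windows and the scaled target-site windows.  For the
#' autoencoders and the U-Net the encoder must be frozen (pretrained
#' features are kept); the CNN-LSTM trains all its weights here.
#'
#' @param model a `translation_model`.
#' @param paired a [paired_dataset()].
#' @param config a [training_config()].
#' @param split optional index split from [split_dataset()]; computed
#'   from `config` when absent.
#' @return A `training_report`.
#' @export
train_translation <- function(model, paired, config = training_config(),
                              split = NULL) {
  if (model$architecture != "cnn_lstm" && !is_encoder_frozen(model))
    stop("freeze the pretrained encoder before translation training")
  if (is.null(split))
    split <- split_dataset(length(paired$wrist), config$split_fractions,
                           config$seed)
  x <- dataset_to_array(paired$wrist)
  y <- dataset_to_array(paired$target)
  rep <- train_loop(model,
                    x[split$train, , , drop = FALSE], y[split$train, , , drop = FALSE],
                    x[split$val, , , drop = FALSE], y[split$val, , , drop = FALSE],
                    config$learning_rate, config, "translate")
  model$state$trained_stages <- c(model$state$trained_stages, "translate")
  rep
}

#' Fine-tune with the encoder unfrozen
#'
#' Unfreezes every layer and continues translation training at the
#' lower `fine_tune_rate`.
#'
#' @inheritParams train_translation
#' @return A `training_report`.
#' @export
fine_tune <- function(model, paired, config = training_config(),
                      split = NULL) {
  if (model$architecture == "cnn_lstm")
    stop("cnn_lstm has no frozen stage, so there is nothing to fine-tune")
  if (!("translate" %in% trained_stages(model)))
    stop("run train_translation() before fine-tuning")
  unfreeze_encoder(model)
  if (is.null(split))
    split <- split_dataset(length(paired$wrist), config$split_fractions,
                           config$seed)
  x <- dataset_to_array(paired$wrist)
  y <- dataset_to_array(paired$target)
  rep <- train_loop(model,
                    x[split$train, , , drop = FALSE], y[split$train, , , drop = FALSE],
                    x[split$val, , , drop = FALSE], y[split$val, , , drop = FALSE],
                    config$fine_tune_rate, config, "fine_tune")
  model$state$trained_stages <- c(model$state$trained_stages, "fine_tune")
  rep
}

#' Test-set loss of a model on a paired dataset
#'
#' @param model a trained `translation_model`.
#' @param paired a [paired_dataset()].
#' @param indices which pairs to evaluate (default all).
#' @return A list with `mse` and `mae` in scaled units.
#' @export
evaluate_scaled <- function(model, paired, indices = NULL) {
  x <- dataset_to_array(paired$wrist)
  y <- dataset_to_array(paired$target)
  if (!is.null(indices)) {
    x <- x[indices, , , drop = FALSE]
    y <- y[indices, , , drop = FALSE]
  }
  pred <- model_forward(model, x)
  for (ly in model$layers) layer_clear_cache(ly)
  list(mse = mean((pred - y)^2), mae = mean(abs(pred - y)))
}

#' Run the full two-stage protocol for one architecture
#'
#' Convenience driver: pretraining on wrist windows (when the
#' architecture has an encoder stage), encoder freezing, paired
#' translation training, and optional fine-tuning.
#'
#' @param architecture architecture name, see [build_model()].
#' @param pretrain_wrist scaled wrist [windowed_dataset()] for the
#'   unsupervised stage (ignored for `cnn_lstm`).
#' @param paired a [paired_dataset()].
#' @param config a [training_config()].
#' @param split optional pair-index split reused across stages.
#' @param do_fine_tune run the fine-tuning stage (default `TRUE`).
#' @return A list with `model` and `reports`.
#' @export
train_pipeline <- function(architecture, pretrain_wrist, paired,
                           config = training_config(), split = NULL,
                           do_fine_tune = TRUE) {
  model <- build_model(architecture, seed = config$seed)
  reports <- list()
  if (architecture != "cnn_lstm") {
    reports$pretrain <- pretrain_autoencoder(model, pretrain_wrist, config)
    model <- freeze_encoder(model)
  }
  reports$translate <- train_translation(model, paired, config, split)
  if (do_fine_tune && architecture != "cnn_lstm")
    reports$fine_tune <- fine_tune(model, paired, config, split)
  list(model = model, reports = reports)
}

#' Write per-epoch training logs as CSV
#'
#' @param reports list of `training_report`s.
#' @param path output CSV path (`epoch,train_loss,val_loss,stage`).
#' @return Invisibly, the path.
#' @export
write_training_log <- function(reports, path) {
  logs <- do.call(rbind, lapply(reports, function(r)
    cbind(r$history, stage = r$stage)))
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}
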