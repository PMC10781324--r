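# Per-channel error metrics in physical units.
#
# Errors are always computed after mapping predictions back to g and
# deg/s with the target site's scaling parameters: an error of 0.3 g
# on ax means the same thing whatever unit range the network was
# trained in.  Aggregation pools every sample of every test window
# (not per-window means of means).

#' Per-channel mean absolute error
#'
#' @param predicted,truth [windowed_dataset()]s with equal window
#'   counts and shapes, both in physical units.
#' @return Named length-6 numeric vector (ax, ay, az, gx, gy, gz);
#'   units g for acceleration channels, deg/s for gyroscope channels.
#' @export
channel_mae <- function(predicted, truth) {
  stack2 <- check_pair(predicted, truth)
  stats::setNames(colMeans(abs(stack2$p - stack2$t)), IMU_CHANNELS)
}

#' Per-channel root-mean-square error
#'
#' @inheritParams channel_mae
#' @return Named length-6 numeric vector; RMSE is never below MAE on
#'   the same data.
#' @export
channel_rmse <- function(predicted, truth) {
  stack2 <- check_pair(predicted, truth)
  stats::setNames(sqrt(colMeans((stack2$p - stack2$t)^2)), IMU_CHANNELS)
}

check_pair <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("window counts differ")
  if (length(predicted) == 0) stop("empty datasets")
  p <- do.call(rbind, lapply(predicted$windows, function(w) w$values))
  t_ <- do.call(rbind, lapply(truth$windows, function(w) w$values))
  if (!all(dim(p) == dim(t_))) stop("window shapes differ")
  list(p = p, t = t_)
}

#' Channel errors of one model on one test set
#'
#' Translates the scaled wrist windows, inverts the target scaling
#' and computes per-channel MAE and RMSE against the unscaled truth.
#'
#' @param model a trained `translation_model`.
#' @param paired a [paired_dataset()].
#' @param indices which pairs form the test set (default all).
#' @return A `channel_errors` list with `mae` and `rmse` vectors.
#' @export
channel_errors <- function(model, paired, indices = NULL) {
  wrist <- paired$wrist; target <- paired$target
  if (!is.null(indices)) {
    wrist <- windowed_dataset(wrist$windows[indices],
                              scaling = paired$wrist_scaling)
    target <- windowed_dataset(target$windows[indices],
                               scaling = paired$target_scaling)
  }
  pred <- translate_dataset(model, wrist, paired$target_scaling,
                            paired$target_site)
  truth <- unscale_dataset(target, paired$target_scaling)
  structure(list(mae = channel_mae(pred, truth),
                 rmse = channel_rmse(pred, truth)),
            class = "channel_errors")
}

#' @export
print.channel_errors <- function(x, ...) {
  m <- rbind(MAE = x$mae, RMSE = x$rmse)
  print(round(m, 4))
  invisible(x)
}

#' Compare the four architectures on one shared test set
#'
#' Evaluates each trained model on the same paired test windows and
#' assembles a per-architecture table of per-channel MAE and RMSE in
#' physical units.
#'
#' @param models named list with (any subset of) elements `dense_ae`,
#'   `cnn_ae`, `cnn_lstm`, `unet`, each a trained
#'   `translation_model`; all four are required unless
#'   `allow_missing`.
#' @param paired a [paired_dataset()]; all models must target its
#'   site.
#' @param indices test-set pair indices (default all).
#' @param allow_missing evaluate whatever subset is present.
#' @return An `architecture_comparison`: a data frame with one row
#'   per architecture and metric, columns ax..gz.
#' @export
compare_architectures <- function(models, paired, indices = NULL,
                                  allow_missing = FALSE) {
  if (!allow_missing) {
    missing <- setdiff(ARCHITECTURES, names(models))
    if (length(missing))
      stop("missing model(s): ", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (arch in intersect(ARCHITECTURES, names(models))) {
    err <- channel_errors(models[[arch]], paired, indices)
    rows[[length(rows) + 1]] <-
      data.frame(architecture = arch, metric = "MAE", t(err$mae))
    rows[[length(rows) + 1]] <-
      data.frame(architecture = arch, metric = "RMSE", t(err$rmse))
  }
  out <- do.call(rbind, rows)
  attr(out, "site") <- paired$target_site
  class(out) <- c("architecture_comparison", class(out))
  out
}

#' Write an architecture comparison as CSV
#'
#' Column order mirrors the channel order ax, ay, az, gx, gy, gz.
#'
#' @param comparison an `architecture_comparison`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}
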