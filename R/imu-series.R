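#' @keywords internal
"_PACKAGE"

# Fixed channel order used throughout the package.
IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")
IMU_SITES <- c("wrist", "tibia", "shoe")
WINDOW_LENGTH <- 256L

#' Six-channel inertial recording
#'
#' Container for one continuous recording from a single inertial
#' measurement unit: tri-axial acceleration in g and tri-axial angular
#' velocity in deg/s, sampled at a fixed rate and tagged with the body
#' site the sensor was worn on.
#'
#' @param channels a data frame or named list with numeric elements
#'   `ax`, `ay`, `az` (acceleration, g) and `gx`, `gy`, `gz`
#'   (angular velocity, deg/s), all the same length.
#' @param sample_rate sampling frequency in Hz (positive scalar).
#' @param site body site, one of `"wrist"`, `"tibia"`, `"shoe"`.
#' @param start_time time of the first sample in seconds (default 0).
#'
#' @return An object of class `imu_series`: a list with elements
#'   `channels` (an n x 6 numeric matrix in fixed order ax, ay, az,
#'   gx, gy, gz), `sample_rate`, `site` and `start_time`.
#' @export
#' @examples
#' s <- imu_series(data.frame(ax = 0, ay = 0, az = 1,
#'                            gx = 0, gy = 0, gz = 0)[rep(1, 100), ],
#'                 sample_rate = 50, site = "wrist")
#' n_samples(s)
imu_series <- function(channels, sample_rate, site, start_time = 0) {
  site <- match.arg(site, IMU_SITES)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar (Hz)")
  missing_ch <- setdiff(IMU_CHANNELS, names(channels))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  lens <- vapply(IMU_CHANNELS, function(ch) length(channels[[ch]]), integer(1))
  if (length(unique(lens)) != 1)
    stop("all six channels must have identical length")
  mat <- vapply(IMU_CHANNELS, function(ch) as.numeric(channels[[ch]]),
                numeric(lens[1]))
  if (lens[1] == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, IMU_CHANNELS))
  structure(list(channels = mat, sample_rate = sample_rate,
                 site = site, start_time = start_time),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> site=%s  %d samples @ %g Hz (%.2f s)\n",
              x$site, nrow(x$channels), x$sample_rate,
              nrow(x$channels) / x$sample_rate))
  invisible(x)
}

#' Number of samples in a series
#' @param series an [imu_series()].
#' @return Integer sample count.
#' @export
n_samples <- function(series) nrow(series$channels)

#' Sample times of a series
#' @param series an [imu_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(series) {
  series$start_time + (seq_len(n_samples(series)) - 1) / series$sample_rate
}

#' Fixed-length window of inertial samples
#'
#' The unit consumed and produced by every translation model: a
#' `length x 6` matrix in the fixed channel order (ax, ay, az, gx,
#' gy, gz), tagged with its site and a flag saying whether the values
#' have been min-max scaled to the unit range.
#'
#' @param values numeric matrix with 6 columns.
#' @param site body site the window was cut from.
#' @param scaled logical; `TRUE` when all values lie in [0, 1].
#' @return An `imu_window` object.
#' @export
imu_window <- function(values, site, scaled = FALSE) {
  site <- match.arg(site, IMU_SITES)
  values <- as.matrix(values)
  if (ncol(values) != 6)
    stop("window must have exactly 6 columns")
  if (scaled && (min(values) < 0 || max(values) > 1))
    stop("scaled window has values outside [0, 1]")
  colnames(values) <- IMU_CHANNELS
  structure(list(values = values, site = site, scaled = scaled),
            class = "imu_window")
}

#' @export
print.imu_window <- function(x, ...) {
  cat(sprintf("<imu_window> site=%s  %d x 6  scaled=%s\n",
              x$site, nrow(x$values), x$scaled))
  invisible(x)
}

#' Ordered collection of equally shaped windows
#'
#' @param windows list of [imu_window()] objects sharing site, length
#'   and scaled flag.
#' @param scaling optional [scaling_params()] that produced the scaled
#'   values.
#' @return A `windowed_dataset` object.
#' @export
windowed_dataset <- function(windows, scaling = NULL) {
  if (length(windows)) {
    sites <- unique(vapply(windows, function(w) w$site, character(1)))
    flags <- unique(vapply(windows, function(w) w$scaled, logical(1)))
    lens <- unique(vapply(windows, function(w) nrow(w$values), integer(1)))
    if (length(sites) != 1) stop("all windows must share one site")
    if (length(flags) != 1) stop("all windows must share the scaled flag")
    if (length(lens) != 1) stop("all windows must share one length")
    site <- sites
    scaled <- flags
  } else {
    site <- NA_character_
    scaled <- FALSE
  }
  structure(list(windows = windows, site = site, scaled = scaled,
                 scaling = scaling),
            class = "windowed_dataset")
}

#' @export
length.windowed_dataset <- function(x) length(x$windows)

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> site=%s  %d windows  scaled=%s\n",
              x$site, length(x$windows), x$scaled))
  invisible(x)
}

#' Cut a series into fixed-length windows
#'
#' Slides a window of `length` samples over the recording with step
#' `hop`; trailing samples that do not fill a whole window are
#' dropped.  At the default 256 samples and a 50 Hz sampling rate one
#' window spans 5.12 s, long enough to contain at least two full
#' strides of ordinary walking.
#'
#' @param series an [imu_series()].
#' @param length window length in samples (default 256).
#' @param hop step between window starts in samples (default
#'   `length`, i.e. non-overlapping tiling).
#' @return A [windowed_dataset()] with
#'   `floor((n - length)/hop) + 1` windows (zero when the series is
#'   shorter than one window).
#' @export
#' @examples
#' s <- imu_series(as.data.frame(matrix(rnorm(600 * 6), 600,
#'        dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))),
#'      50, "shoe")
#' length(window_signal(s, 256, 128))  # windows start at 0, 128, 256
window_signal <- function(series, length = WINDOW_LENGTH, hop = length) {
  if (length < 1 || hop < 1) stop("`length` and `hop` must be >= 1")
  length <- as.integer(length); hop <- as.integer(hop)
  n <- n_samples(series)
  if (n < 1) stop("series has no samples")
  n_win <- if (n >= length) (n - length) %/% hop + 1L else 0L
  windows <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    from <- (i - 1L) * hop + 1L
    windows[[i]] <- imu_window(series$channels[from:(from + length - 1L), ,
                                               drop = FALSE],
                               site = series$site, scaled = FALSE)
  }
  ds <- windowed_dataset(windows)
  if (n_win == 0L) ds$site <- series$site
  ds
}

#' Per-channel min-max scaling parameters
#'
#' @param mins,maxs numeric length-6 vectors in channel order.
#' @param fitted_on label of the data split the parameters were
#'   fitted on (bookkeeping only).
#' @return A `scaling_params` object.
#' @export
scaling_params <- function(mins, maxs, fitted_on = "train") {
  if (length(mins) != 6 || length(maxs) != 6)
    stop("mins and maxs must have length 6")
  if (any(maxs < mins)) stop("max must be >= min for every channel")
  structure(list(mins = stats::setNames(as.numeric(mins), IMU_CHANNELS),
                 maxs = stats::setNames(as.numeric(maxs), IMU_CHANNELS),
                 fitted_on = fitted_on),
            class = "scaling_params")
}

#' Fit unit-range scaling parameters on a dataset
#'
#' Computes per-channel minima and maxima over every sample of every
#' window.  Fit this on the training split only and reuse the same
#' parameters for validation, test and inference so no information
#' leaks across splits.
#'
#' @param dataset an unscaled [windowed_dataset()].
#' @param fitted_on split label recorded in the result.
#' @return A [scaling_params()] object.
#' @export
fit_unit_scaler <- function(dataset, fitted_on = "train") {
  if (length(dataset) == 0) stop("cannot fit a scaler on an empty dataset")
  if (dataset$scaled) stop("dataset is already scaled")
  stacked <- do.call(rbind, lapply(dataset$windows, function(w) w$values))
  scaling_params(apply(stacked, 2, min), apply(stacked, 2, max), fitted_on)
}

#' Map a window into the unit range
#'
#' Per channel, applies `(x - min) / (max - min)` and clips to
#' [0, 1]; a degenerate channel (max equal to min) maps to 0.
#' Clipping makes inference inputs bounded even when a value falls
#' outside the range seen at fit time.
#'
#' @param window an unscaled [imu_window()].
#' @param params [scaling_params()] fitted on the matching site.
#' @return The scaled window (`scaled = TRUE`).
#' @export
apply_scaler <- function(window, params) {
  if (window$scaled) stop("window is already scaled")
  rng <- params$maxs - params$mins
  v <- sweep(window$values, 2, params$mins, "-")
  v <- sweep(v, 2, ifelse(rng > 0, rng, 1), "/")
  v[, rng == 0] <- 0
  v <- pmin(pmax(v, 0), 1)
  imu_window(v, window$site, scaled = TRUE)
}

#' Map a scaled window back to physical units
#'
#' Inverse of [apply_scaler()]: per channel `x * (max - min) + min`.
#'
#' @param window a scaled [imu_window()].
#' @param params the [scaling_params()] of the window's site.
#' @return The window in physical units (`scaled = FALSE`).
#' @export
invert_scaler <- function(window, params) {
  if (!window$scaled) stop("window is not scaled")
  v <- sweep(window$values, 2, params$maxs - params$mins, "*")
  v <- sweep(v, 2, params$mins, "+")
  imu_window(v, window$site, scaled = FALSE)
}

#' Scale or unscale every window of a dataset
#'
#' @param dataset a [windowed_dataset()].
#' @param params [scaling_params()].
#' @return The transformed dataset; `scale_dataset` records `params`
#'   in the result's `scaling` field.
#' @export
scale_dataset <- function(dataset, params) {
  windowed_dataset(lapply(dataset$windows, apply_scaler, params = params),
                   scaling = params)
}

#' @rdname scale_dataset
#' @export
unscale_dataset <- function(dataset, params) {
  windowed_dataset(lapply(dataset$windows, invert_scaler, params = params))
}

#' Resultant (signal vector) magnitude
#'
#' Per-sample Euclidean norm across the three axes of one sensor
#' modality, e.g. the gyroscope resultant used by the gait event
#' detector.
#'
#' @param x,y,z equal-length numeric vectors.
#' @return Non-negative numeric vector `sqrt(x^2 + y^2 + z^2)`.
#' @export
#' @examples
#' resultant_magnitude(3, 4, 0)  # 5
resultant_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("x, y and z must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

# Stack a windowed dataset into a (n_windows, length, 6) array for the
# network layers.
dataset_to_array <- function(dataset) {
  n <- length(dataset)
  if (n == 0) stop("empty dataset")
  L <- nrow(dataset$windows[[1]]$values)
  arr <- array(0, dim = c(n, L, 6))
  for (i in seq_len(n)) arr[i, , ] <- dataset$windows[[i]]$values
  arr
}

array_to_dataset <- function(arr, site, scaled) {
  windows <- lapply(seq_len(dim(arr)[1]), function(i)
    imu_window(arr[i, , ], site = site, scaled = scaled))
  windowed_dataset(windows)
}
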