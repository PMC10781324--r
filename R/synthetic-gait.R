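# Synthetic paired-IMU gait simulator.
#
# Emulates the qualitative contrast between sensor sites seen in real
# walking data: shoe/tibia signals carry distinct short peaks (sharp
# heel-strike accelerations, toe-off/heel-strike gyroscope spikes)
# while the wrist signal is a smoothed, attenuated, phase-lagged,
# sine-like relative of the lower-limb motion.  Because the wrist
# channels are generated *from* the shoe channels by a fixed
# deterministic map, a sufficiently expressive model can in principle
# invert it, which grounds the translation-learnability tests.

#' Configuration of the synthetic gait simulator
#'
#' All amplitudes are in the physical units of the channel they apply
#' to (g for acceleration, deg/s for angular velocity); all times in
#' seconds.
#'
#' @param sample_rate sampling frequency in Hz.
#' @param n_strides number of complete strides to simulate.
#' @param stride_period mean stride duration in seconds.
#' @param period_jitter_sd standard deviation of per-stride period
#'   jitter in seconds (0 gives an exactly periodic gait).
#' @param stance_fraction fraction of each stride spent in stance
#'   (heel strike to toe-off), in (0, 1).
#' @param swing_lobe_amplitude peak of the smooth positive shoe-gyro-y
#'   swing lobe, deg/s.
#' @param spike_amplitude amplitude of the sharp negative gyro spikes
#'   at toe-off and heel strike, deg/s.
#' @param accel_peak_amplitude amplitude of the sharp heel-strike
#'   acceleration peak, g.
#' @param noise_sd additive white-noise standard deviation on the
#'   gyroscope channels, deg/s; acceleration channels receive the same
#'   noise scaled by `accel_peak_amplitude / swing_lobe_amplitude` so
#'   the relative noise level matches across modalities.
#' @param wrist_smoothing_cutoff low-pass cutoff (Hz) of the
#'   shoe-to-wrist smoothing that removes the sharp peaks.
#' @param wrist_gain amplitude ratio of wrist to shoe motion.
#' @param wrist_phase_lag delay of the wrist signal behind the shoe
#'   signal, seconds.
#' @param seed integer seed; every random draw in the simulator flows
#'   through one generator seeded with it.
#' @return A `sim_config` list with validated fields.
#' @export
sim_config <- function(sample_rate = 50,
                       n_strides = 30,
                       stride_period = 1.1,
                       period_jitter_sd = 0.02,
                       stance_fraction = 0.6,
                       swing_lobe_amplitude = 300,
                       spike_amplitude = 250,
                       accel_peak_amplitude = 3,
                       noise_sd = 5,
                       wrist_smoothing_cutoff = 3,
                       wrist_gain = 0.4,
                       wrist_phase_lag = 0.08,
                       seed = 1L) {
  stopifnot(sample_rate > 0, n_strides >= 1,
            stride_period > 0, period_jitter_sd >= 0,
            stance_fraction > 0, stance_fraction < 1,
            swing_lobe_amplitude >= 0, spike_amplitude >= 0,
            accel_peak_amplitude >= 0, noise_sd >= 0,
            wrist_smoothing_cutoff > 0, wrist_smoothing_cutoff < sample_rate / 2,
            wrist_gain > 0, wrist_phase_lag >= 0)
  structure(list(sample_rate = sample_rate, n_strides = as.integer(n_strides),
                 stride_period = stride_period,
                 period_jitter_sd = period_jitter_sd,
                 stance_fraction = stance_fraction,
                 swing_lobe_amplitude = swing_lobe_amplitude,
                 spike_amplitude = spike_amplitude,
                 accel_peak_amplitude = accel_peak_amplitude,
                 noise_sd = noise_sd,
                 wrist_smoothing_cutoff = wrist_smoothing_cutoff,
                 wrist_gain = wrist_gain,
                 wrist_phase_lag = wrist_phase_lag,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Narrow Gaussian bump centred on `centre` (seconds); width ~40 ms so
# a 50 Hz grid resolves it with 2-3 samples -- the "distinct short
# peak" shape of lower-limb sensors.
gauss_bump <- function(t, centre, sd = 0.017) exp(-(t - centre)^2 / (2 * sd^2))

#' Simulate one walking session recorded at three sites
#'
#' Builds, stride by stride, a shoe gyroscope-y signal made of a
#' smooth positive swing lobe (raised-cosine, so its value and slope
#' both vanish at the stride-phase boundaries) plus two sharp
#' negative spikes at the toe-off and heel-strike instants; sharp
#' positive acceleration peaks at each heel strike; a tibia series
#' that is an attenuated, slightly smoothed copy of the shoe series;
#' and a wrist series obtained by low-pass filtering, gain-scaling
#' and phase-lagging the shoe series and adding a stride-frequency
#' sinusoid, which makes it sine-like.  Ground-truth toe-off and
#' heel-strike times are the exact sample times used in construction.
#'
#' @param config a [sim_config()].
#' @return A `sim_session` list with fields `wrist`, `tibia`, `shoe`
#'   (equal-length [imu_series()]) and `truth` (a [gait_events()]
#'   object with the constructed toe-off/heel-strike times).
#' @export
#' @examples
#' sess <- generate_session(sim_config(n_strides = 5, seed = 42))
#' sess$truth
generate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  periods <- rep(config$stride_period, config$n_strides) +
    if (config$period_jitter_sd > 0)
      stats::rnorm(config$n_strides, 0, config$period_jitter_sd) else 0
  periods <- pmax(periods, 0.4)        # keep strides physiological
  swing <- (1 - config$stance_fraction) * periods

  # Heel strike k ends stride k; the toe-off preceding it starts the
  # swing phase.  Lead-in of one second before the first toe-off.
  t0 <- 1.0
  hs <- t0 + cumsum(periods)
  to <- hs - swing
  # snap events to the sampling grid so truth times are exact samples
  hs <- round(hs * fs) / fs
  to <- round(to * fs) / fs

  dur <- hs[length(hs)] + 1.0
  n <- floor(dur * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  # --- shoe gyroscope -------------------------------------------------
  gy <- numeric(n)
  for (k in seq_along(hs)) {
    sw <- hs[k] - to[k]
    idx <- t >= to[k] & t <= hs[k]
    # raised-cosine (Hann) lobe: zero value and slope at both ends
    gy[idx] <- gy[idx] + config$swing_lobe_amplitude *
      sin(pi * (t[idx] - to[k]) / sw)^2
    gy <- gy - config$spike_amplitude * gauss_bump(t, to[k])
    gy <- gy - config$spike_amplitude * gauss_bump(t, hs[k])
  }
  # secondary axes: scaled copies of the lobe pattern, no spikes on gx
  lobe_only <- numeric(n)
  for (k in seq_along(hs)) {
    sw <- hs[k] - to[k]
    idx <- t >= to[k] & t <= hs[k]
    lobe_only[idx] <- lobe_only[idx] + sin(pi * (t[idx] - to[k]) / sw)^2
  }
  gx <- 0.15 * config$swing_lobe_amplitude * lobe_only
  gz <- -0.25 * config$swing_lobe_amplitude * lobe_only

  # --- shoe acceleration ---------------------------------------------
  az <- rep(1, n)                       # gravity baseline, g
  ax <- numeric(n); ay <- numeric(n)
  for (k in seq_along(hs)) {
    ax <- ax + config$accel_peak_amplitude * gauss_bump(t, hs[k])
    az <- az + 0.8 * config$accel_peak_amplitude * gauss_bump(t, hs[k])
    ay <- ay + 0.3 * config$accel_peak_amplitude * gauss_bump(t, hs[k])
  }
  # mild periodic body motion on the horizontal axes
  f_stride <- 1 / mean(periods)
  ax <- ax + 0.1 * config$accel_peak_amplitude * sin(2 * pi * f_stride * t)
  ay <- ay + 0.1 * config$accel_peak_amplitude * cos(2 * pi * f_stride * t)

  shoe <- cbind(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)

  # --- tibia: attenuated, slightly smoothed copy ----------------------
  tibia <- apply(shoe, 2, moving_average3) * 0.7
  tibia[, "az"] <- tibia[, "az"] + 0.3    # keep ~1 g gravity baseline

  # --- wrist: smoothed + gain + lag + sinusoid ------------------------
  lag_samp <- round(config$wrist_phase_lag * fs)
  wrist <- apply(shoe, 2, function(ch) {
    sm <- butter_lowpass(ch, fs, config$wrist_smoothing_cutoff, order = 2)
    shift_signal(sm, lag_samp) * config$wrist_gain
  })
  phase <- 2 * pi * f_stride * t
  wrist[, "gy"] <- wrist[, "gy"] + 0.25 * config$swing_lobe_amplitude * sin(phase)
  wrist[, "gz"] <- wrist[, "gz"] + 0.20 * config$swing_lobe_amplitude * cos(phase)
  wrist[, "ax"] <- wrist[, "ax"] + 0.15 * config$accel_peak_amplitude * sin(phase)
  wrist[, "ay"] <- wrist[, "ay"] + 0.15 * config$accel_peak_amplitude * cos(phase)

  # --- additive noise -------------------------------------------------
  if (config$noise_sd > 0) {
    acc_sd <- config$noise_sd * config$accel_peak_amplitude /
      max(config$swing_lobe_amplitude, 1e-12)
    sds <- c(rep(acc_sd, 3), rep(config$noise_sd, 3))
    for (j in 1:6) {
      shoe[, j] <- shoe[, j] + stats::rnorm(n, 0, sds[j])
      tibia[, j] <- tibia[, j] + stats::rnorm(n, 0, sds[j])
      wrist[, j] <- wrist[, j] + stats::rnorm(n, 0, sds[j] * config$wrist_gain)
    }
  }

  mk <- function(mat, site) imu_series(as.data.frame(mat), fs, site)
  structure(list(wrist = mk(wrist, "wrist"),
                 tibia = mk(tibia, "tibia"),
                 shoe = mk(shoe, "shoe"),
                 truth = gait_events(toe_offs = to, heel_strikes = hs),
                 config = config),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %d strides, %d samples @ %g Hz\n",
              length(x$truth$heel_strikes), n_samples(x$shoe),
              x$shoe$sample_rate))
  invisible(x)
}

# centred 3-point moving average with edge replication
moving_average3 <- function(x) {
  n <- length(x)
  (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
}

# shift right by k samples, replicating the first value
shift_signal <- function(x, k) {
  if (k <= 0) return(x)
  c(rep(x[1], k), x[seq_len(length(x) - k)])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build an aligned wrist/target window-pair dataset from one session
#'
#' Simulates one long session and cuts the wrist series and the
#' requested target-site series into index-aligned windows: pair i of
#' the wrist dataset covers exactly the same sample range as pair i of
#' the target dataset.
#'
#' @param config a [sim_config()]; `n_strides` must be large enough
#'   that the session yields at least `n_windows` windows.
#' @param n_windows number of aligned window pairs required.
#' @param target target site, `"shoe"` (default) or `"tibia"`.
#' @param length,hop window geometry passed to [window_signal()].
#' @return A list with `wrist` and `target` ([windowed_dataset()]s of
#'   equal length), `truth` (the session's [gait_events()]) and
#'   `session`.
#' @export
generate_paired_dataset <- function(config, n_windows, target = c("shoe", "tibia"),
                                    length = WINDOW_LENGTH, hop = length) {
  target <- match.arg(target)
  stopifnot(n_windows >= 1)
  sess <- generate_session(config)
  wrist_ds <- window_signal(sess$wrist, length, hop)
  target_ds <- window_signal(sess[[target]], length, hop)
  if (base::length(wrist_ds) < n_windows)
    stop(sprintf("session yields only %d windows; %d requested (increase n_strides)",
                 base::length(wrist_ds), n_windows))
  keep <- seq_len(n_windows)
  list(wrist = windowed_dataset(wrist_ds$windows[keep]),
       target = windowed_dataset(target_ds$windows[keep]),
       truth = sess$truth,
       session = sess)
}

#' Write a simulated session to CSV files
#'
#' Writes one signal CSV per site in the package dialect
#' (`t,ax,ay,az,gx,gy,gz`) and a ground-truth events CSV
#' (`event_type,time_s` with `event_type` in TO/HS).
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (site in IMU_SITES) {
    p <- file.path(dir, paste0(site, ".csv"))
    write_imu_csv(session[[site]], p)
    paths <- c(paths, p)
  }
  ev <- file.path(dir, "events.csv")
  write_events_csv(session$truth, ev)
  invisible(c(paths, ev))
}
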