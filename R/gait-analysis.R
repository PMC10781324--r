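# Temporal gait-parameter estimation from gyroscope signals.
#
# Toe-off and heel-strike events both appear as sharp peaks in the
# (suitably oriented) y-axis angular velocity of a lower-limb sensor.
# The two are told apart with the gyroscope resultant: the resultant
# rises above a threshold for the duration of the swing phase, and the
# peak closest in time to the upward threshold crossing is the
# toe-off; the remaining boundary peak of the cycle is the heel
# strike.

#' Butterworth low-pass filter specification
#'
#' @param cutoff cutoff frequency in Hz.  The default 5 Hz is narrow
#'   enough to suppress reconstruction noise in translated signals; a
#'   12 Hz cutoff is the classical choice for raw lower-limb
#'   gyroscope data.
#' @param order filter order (default 4).
#' @param zero_phase apply the filter forward and backward
#'   (`signal::filtfilt`) so event times are not biased by phase lag
#'   (default `TRUE`).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(cutoff = 5, order = 4, zero_phase = TRUE) {
  stopifnot(cutoff > 0, order >= 1)
  structure(list(cutoff = cutoff, order = as.integer(order),
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Low-pass filter a signal
#'
#' Zero-phase (forward-backward) Butterworth filtering; with
#' `zero_phase = TRUE` the effective magnitude response is the square
#' of the single-pass Butterworth response
#' \eqn{1/\sqrt{1+(f/f_c)^{2\,order}}}.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass <- function(x, sample_rate, spec = filter_spec()) {
  if (spec$cutoff >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(spec$order, spec$cutoff / (sample_rate / 2),
                       type = "low")
  if (!spec$zero_phase) return(as.numeric(signal::filter(bf, x)))
  # remove the mean (unit DC gain, so it passes unchanged) and pad by
  # odd reflection: both suppress the start/end transients of the
  # forward-backward pass
  n <- length(x)
  dc <- mean(x)
  x <- x - dc
  p <- min(n - 1, 3 * (spec$order + 1), 25)
  y <- if (p > 0) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    signal::filtfilt(bf, xp)[(p + 1):(p + n)]
  } else signal::filtfilt(bf, x)
  y + dc
}

# convenience wrapper used by the simulator
butter_lowpass <- function(x, sample_rate, cutoff, order = 4) {
  lowpass(x, sample_rate, filter_spec(cutoff = cutoff, order = order))
}

#' Toe-off and heel-strike event times
#'
#' @param toe_offs,heel_strikes strictly increasing event times in
#'   seconds.  The merged sequence must alternate TO, HS, TO, HS, ...
#' @return A `gait_events` object.
#' @export
gait_events <- function(toe_offs = numeric(0), heel_strikes = numeric(0)) {
  toe_offs <- as.numeric(toe_offs); heel_strikes <- as.numeric(heel_strikes)
  if (is.unsorted(toe_offs, strictly = TRUE) && length(toe_offs) > 1)
    stop("toe-off times must be strictly increasing")
  if (is.unsorted(heel_strikes, strictly = TRUE) && length(heel_strikes) > 1)
    stop("heel-strike times must be strictly increasing")
  ev <- events_table(toe_offs, heel_strikes)
  if (nrow(ev) > 1 && any(ev$event_type[-1] == ev$event_type[-nrow(ev)]))
    stop("merged event sequence must alternate TO/HS")
  structure(list(toe_offs = toe_offs, heel_strikes = heel_strikes),
            class = "gait_events")
}

events_table <- function(toe_offs, heel_strikes) {
  ev <- data.frame(
    event_type = c(rep("TO", length(toe_offs)), rep("HS", length(heel_strikes))),
    time_s = c(toe_offs, heel_strikes))
  ev[order(ev$time_s), , drop = FALSE]
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d toe-offs, %d heel strikes\n",
              length(x$toe_offs), length(x$heel_strikes)))
  invisible(x)
}

# Peak prominence: height of the peak above the higher of the two
# minima separating it from taller terrain (or the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    taller_l <- which(left >= h)
    base_l <- if (length(taller_l)) min(x[(max(taller_l)):(p - 1)]) else min(c(left, h))
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    taller_r <- which(right >= h)
    base_r <- if (length(taller_r))
      min(x[(p + 1):(p + min(taller_r))]) else min(c(right, h))
    h - max(base_l, base_r)
  }, numeric(1))
}

# local maxima (strict rise, fall allowing plateaus of length 1)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect toe-off and heel-strike events
#'
#' Implements a threshold-assisted peak classification on two
#' pre-filtered inputs: the y-axis angular velocity and the gyroscope
#' resultant magnitude.  Candidate events are prominence-filtered
#' local maxima of the (optionally inverted) y signal.  Upward
#' crossings of `threshold` in the resultant mark the start of each
#' swing phase; within each inter-crossing cycle the candidate peak
#' closest in time to the upward crossing is labelled toe-off and the
#' last peak of the cycle heel strike.  If two same-label events end
#' up adjacent, the less prominent one is discarded so that the
#' output always alternates TO/HS.
#'
#' @param gyro_y y-axis angular velocity, deg/s, already low-pass
#'   filtered.
#' @param resultant gyroscope resultant magnitude, deg/s, already
#'   low-pass filtered; same length as `gyro_y`.
#' @param sample_rate sampling rate in Hz.
#' @param threshold swing-detection threshold on the resultant, deg/s.
#' @param invert_y negate `gyro_y` before peak picking; `TRUE` for
#'   shoe-mounted sensors, whose y axis points opposite to the
#'   orientation the peak convention assumes.
#' @param prominence_frac minimum peak prominence as a fraction of
#'   `max(abs(gyro_y))`.
#' @param min_swing_ms a threshold crossing only counts as a swing
#'   onset when the resultant stays (mostly) above the threshold for
#'   this long afterwards; rejects noise blips and the brief
#'   heel-strike spike, which both re-cross the threshold quickly.
#' @param start_time time of the first sample, seconds.
#' @return A [gait_events()] object; empty (no error) when less than
#'   one full gait cycle is found.
#' @export
detect_gait_events <- function(gyro_y, resultant, sample_rate,
                               threshold = 50, invert_y = TRUE,
                               prominence_frac = 0.2, min_swing_ms = 200,
                               start_time = 0) {
  if (length(gyro_y) != length(resultant))
    stop("gyro_y and resultant must have equal length")
  y <- if (invert_y) -gyro_y else gyro_y
  n <- length(y)

  cand <- local_maxima(y)
  if (length(cand)) {
    prom <- peak_prominence(y, cand)
    keep <- prom >= prominence_frac * max(abs(gyro_y))
    cand <- cand[keep]; prom <- prom[keep]
  } else prom <- numeric(0)

  up <- which(resultant[-1] >= threshold & resultant[-n] < threshold) + 1L
  # sustained-swing requirement: >= 80% of the following min_swing_ms
  # must sit above the threshold
  horizon <- max(1L, round(min_swing_ms / 1000 * sample_rate))
  up <- up[vapply(up, function(i) {
    win <- resultant[i:min(n, i + horizon - 1L)]
    mean(win >= threshold) >= 0.8
  }, logical(1))]
  if (length(cand) == 0 || length(up) == 0)
    return(gait_events())

  # Each accepted upward crossing starts a swing phase; the swing ends
  # where the resultant falls back below the threshold.  The candidate
  # peak nearest the upward crossing is the toe-off, the one nearest
  # the downward crossing the heel strike.
  lab <- rep(NA_character_, length(cand))
  cycle_end <- c(up[-1], n + 1L)
  for (j in seq_along(up)) {
    near_to <- which.min(abs(cand - up[j]))
    if (cand[near_to] < cycle_end[j] && (j == 1 || cand[near_to] >= up[j - 1]))
      lab[near_to] <- "TO"
    below <- which(resultant[up[j]:n] < threshold)
    if (length(below)) {
      down <- up[j] + below[1] - 1L
      near_hs <- which.min(abs(cand - down))
      if (near_hs != near_to && is.na(lab[near_hs]) &&
          cand[near_hs] < cycle_end[j] + 2L)
        lab[near_hs] <- "HS"
    }
  }
  keep <- !is.na(lab)
  cand <- cand[keep]; lab <- lab[keep]; prom <- prom[keep]
  if (!length(cand)) return(gait_events())

  # enforce alternation: drop the less prominent of same-label neighbours
  repeat {
    dup <- which(lab[-1] == lab[-length(lab)])
    if (!length(dup)) break
    d <- dup[1]
    drop <- if (prom[d] < prom[d + 1]) d else d + 1L
    cand <- cand[-drop]; lab <- lab[-drop]; prom <- prom[-drop]
  }

  times <- start_time + (cand - 1) / sample_rate
  gait_events(toe_offs = times[lab == "TO"], heel_strikes = times[lab == "HS"])
}

#' Detect gait events directly from an IMU series
#'
#' Convenience wrapper: low-pass filters each gyroscope channel,
#' computes the resultant magnitude of the filtered channels and
#' filters it once more, then calls [detect_gait_events()].
#' Filtering the axes before taking the norm matters at high noise:
#' rectification by the norm turns zero-mean wide-band noise into a
#' positive bias that no post-hoc low-pass can remove.
#'
#' @param series an [imu_series()].
#' @param spec a [filter_spec()].
#' @param ... passed to [detect_gait_events()]; `invert_y` defaults
#'   to `TRUE` for shoe- and tibia-site series.
#' @return A [gait_events()] object.
#' @export
detect_events_series <- function(series, spec = filter_spec(), ...) {
  ch <- series$channels
  fgx <- lowpass(ch[, "gx"], series$sample_rate, spec)
  fgy <- lowpass(ch[, "gy"], series$sample_rate, spec)
  fgz <- lowpass(ch[, "gz"], series$sample_rate, spec)
  res <- resultant_magnitude(fgx, fgy, fgz)
  args <- list(...)
  if (is.null(args$invert_y)) args$invert_y <- series$site %in% c("shoe", "tibia")
  do.call(detect_gait_events,
          c(list(gyro_y = fgy,
                 resultant = lowpass(res, series$sample_rate, spec),
                 sample_rate = series$sample_rate,
                 start_time = series$start_time),
            args))
}

#' Temporal gait parameters from detected events
#'
#' Stride durations are differences of successive heel strikes; the
#' gait (step) duration is half the stride duration, the single-foot
#' estimate available from one sensor; stance runs from a heel strike
#' to the next toe-off and swing from a toe-off to the next heel
#' strike.  Means are taken over all complete cycles.
#'
#' @param events a [gait_events()] with at least two heel strikes.
#' @return A `gait_parameters` list: `mean_stride_s`, `mean_gait_s`,
#'   `mean_stance_s`, `mean_swing_s`, `n_strides`.
#' @export
#' @examples
#' ev <- gait_events(toe_offs = c(0.6, 1.6, 2.6), heel_strikes = c(1, 2, 3))
#' compute_gait_parameters(ev)
compute_gait_parameters <- function(events) {
  hs <- events$heel_strikes; to <- events$toe_offs
  if (length(hs) < 2)
    stop("need at least two heel strikes to compute stride durations")
  strides <- diff(hs)
  # stance: HS -> next TO
  stance <- unlist(lapply(hs, function(h) {
    nxt <- to[to > h]
    if (length(nxt)) nxt[1] - h else NULL
  }))
  # swing: TO -> next HS
  swing <- unlist(lapply(to, function(s) {
    nxt <- hs[hs > s]
    if (length(nxt)) nxt[1] - s else NULL
  }))
  structure(list(mean_stride_s = mean(strides),
                 mean_gait_s = mean(strides) / 2,
                 mean_stance_s = if (length(stance)) mean(stance) else NA_real_,
                 mean_swing_s = if (length(swing)) mean(swing) else NA_real_,
                 n_strides = length(strides)),
            class = "gait_parameters")
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat("Temporal gait parameters\n")
  cat(sprintf("  mean stride duration [s]  %.3f\n", x$mean_stride_s))
  cat(sprintf("  mean gait duration [s]    %.3f\n", x$mean_gait_s))
  cat(sprintf("  mean stance duration [s]  %.3f\n", x$mean_stance_s))
  cat(sprintf("  mean swing duration [s]   %.3f\n", x$mean_swing_s))
  cat(sprintf("  strides                   %d\n", x$n_strides))
  invisible(x)
}

#' Compare two sets of gait parameters
#'
#' Absolute per-parameter differences between a reference estimate
#' (e.g. from the shoe-worn sensor) and a test estimate (e.g. from
#' translated signals), reported in milliseconds.
#'
#' @param reference,test `gait_parameters` objects.
#' @return A `gait_comparison` named numeric vector (ms):
#'   `stride_ms`, `gait_ms`, `stance_ms`, `swing_ms`.
#' @export
compare_gait_parameters <- function(reference, test) {
  d <- c(stride_ms = abs(reference$mean_stride_s - test$mean_stride_s),
         gait_ms = abs(reference$mean_gait_s - test$mean_gait_s),
         stance_ms = abs(reference$mean_stance_s - test$mean_stance_s),
         swing_ms = abs(reference$mean_swing_s - test$mean_swing_s)) * 1000
  structure(d, class = "gait_comparison")
}

#' @export
print.gait_comparison <- function(x, ...) {
  cat("Absolute differences [ms]\n")
  for (nm in names(x)) cat(sprintf("  %-10s %.1f\n", nm, x[[nm]]))
  invisible(x)
}

#' Construct gait parameters from known mean durations
#'
#' Builds a `gait_parameters` object directly from reported mean
#' durations (for example a published results table) so estimates can
#' be compared with [compare_gait_parameters()] without re-running
#' detection.  The gait duration defaults to half the stride
#' duration.
#'
#' @param mean_stride_s,mean_stance_s,mean_swing_s mean durations in
#'   seconds.
#' @param mean_gait_s mean gait (step) duration; default
#'   `mean_stride_s / 2`.
#' @param n_strides stride count, if known.
#' @return A `gait_parameters` object.
#' @export
gait_parameters <- function(mean_stride_s, mean_stance_s = NA_real_,
                            mean_swing_s = NA_real_,
                            mean_gait_s = mean_stride_s / 2,
                            n_strides = NA_integer_) {
  structure(list(mean_stride_s = mean_stride_s, mean_gait_s = mean_gait_s,
                 mean_stance_s = mean_stance_s, mean_swing_s = mean_swing_s,
                 n_strides = n_strides),
            class = "gait_parameters")
}
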