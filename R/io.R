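# CSV dialect and run configuration.
#
# Signal files use the header `t,ax,ay,az,gx,gy,gz`, comma-separated
# with decimal points, one row per sample, `t` in seconds.  Readers
# tolerate a missing `t` column and reconstruct it from the sampling
# rate.  Ground-truth / detected events use `event_type,time_s` with
# event_type TO or HS.

#' Read an inertial recording from CSV
#'
#' @param path CSV file with columns `ax,ay,az,gx,gy,gz` and an
#'   optional leading `t` column in seconds.
#' @param sample_rate sampling rate in Hz; when the file has a `t`
#'   column the rate is inferred from it unless given explicitly.
#' @param site body site of the recording.
#' @return An [imu_series()].
#' @export
read_imu_csv <- function(path, sample_rate = NULL, site = c("wrist", "tibia", "shoe")) {
  site <- match.arg(site)
  df <- utils::read.csv(path)
  start_time <- 0
  if ("t" %in% names(df)) {
    if (is.null(sample_rate)) {
      dt <- stats::median(diff(df$t))
      if (!is.finite(dt) || dt <= 0) stop("cannot infer sample rate from t column")
      sample_rate <- 1 / dt
    }
    start_time <- df$t[1]
  } else if (is.null(sample_rate)) {
    stop("file has no t column; supply `sample_rate`")
  }
  imu_series(df[IMU_CHANNELS], sample_rate, site, start_time)
}

#' Write an inertial recording to CSV
#'
#' @param series an [imu_series()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_imu_csv <- function(series, path) {
  df <- data.frame(t = sample_times(series), series$channels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write gait events CSV
#'
#' @param path CSV with columns `event_type` (TO/HS) and `time_s`.
#' @return `read_events_csv` returns a [gait_events()].
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("event_type", "time_s") %in% names(df)))
  gait_events(toe_offs = sort(df$time_s[df$event_type == "TO"]),
              heel_strikes = sort(df$time_s[df$event_type == "HS"]))
}

#' @rdname read_events_csv
#' @param events a [gait_events()].
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events_table(events$toe_offs, events$heel_strikes),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write gait parameters as CSV
#'
#' One row per parameter with the conventional row labels.
#'
#' @param params a `gait_parameters` object.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_parameters_csv <- function(params, path) {
  df <- data.frame(
    parameter = c("mean stride duration [s]", "mean gait duration [s]",
                  "mean stance duration [s]", "mean swing duration [s]"),
    value = c(params$mean_stride_s, params$mean_gait_s,
              params$mean_stance_s, params$mean_swing_s))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Nested key/value defaults for every stage; a YAML file with the
#' same structure can override any subset.  Unknown keys are
#' rejected.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulation = unclass(sim_config()),
    windowing = list(length = 256L, hop = 256L),
    model = list(architecture = "cnn_ae"),
    training = unclass(training_config()),
    gait = list(cutoff_hz = 5, order = 4L, threshold = 50,
                invert_y = TRUE, prominence_frac = 0.2))
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; absent fields keep their defaults.
#' @return The merged configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, "")
}

merge_config <- function(base, user, prefix) {
  for (nm in names(user)) {
    key <- paste0(prefix, nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], paste0(key, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}
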