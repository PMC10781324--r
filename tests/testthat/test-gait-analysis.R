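test_that("zero-phase Butterworth matches the analytic magnitude response", {
  fs <- 50
  t <- seq(0, 10, by = 1 / fs)
  spec <- filter_spec(cutoff = 5, order = 4)
  # DC gain is one
  expect_equal(lowpass(rep(3, 200), fs, spec), rep(3, 200), tolerance = 1e-6)
  # single-pass |H| = 1/sqrt(1 + (f/fc)^(2n)); squared for filtfilt
  gain <- function(f, fc, n) 1 / sqrt(1 + (f / fc)^(2 * n))
  mid <- 200:301                             # avoid edge transients
  y20 <- lowpass(sin(2 * pi * 20 * t), fs, spec)
  expect_lt(max(abs(y20[mid])), 1 / 100)     # attenuated >= 100x
  y1 <- lowpass(sin(2 * pi * 1 * t), fs, spec)
  expect_equal(max(abs(y1[mid])), gain(1, 5, 4)^2, tolerance = 0.01)
  expect_gt(max(abs(y1[mid])), 0.99)         # passband preserved within 1%
  expect_error(lowpass(t, fs, filter_spec(cutoff = 30)), "Nyquist")
})

test_that("flat signals produce no events", {
  ev <- detect_gait_events(rep(0, 500), rep(0, 500), 50)
  expect_length(ev$toe_offs, 0)
  expect_length(ev$heel_strikes, 0)
})

test_that("noiseless synthetic sessions are recovered within one sample", {
  sess <- noiseless_session()
  ev <- detect_events_series(sess$shoe)
  expect_length(ev$toe_offs, length(sess$truth$toe_offs))
  expect_length(ev$heel_strikes, length(sess$truth$heel_strikes))
  fs <- sess$shoe$sample_rate
  expect_lte(max(abs(ev$toe_offs - sess$truth$toe_offs)) * fs, 1)
  expect_lte(max(abs(ev$heel_strikes - sess$truth$heel_strikes)) * fs, 1)
})

test_that("shifting both inputs shifts all event times by the same offset", {
  sess <- noiseless_session()
  ch <- sess$shoe$channels
  fs <- sess$shoe$sample_rate
  spec <- filter_spec()
  fgy <- lowpass(ch[, "gy"], fs, spec)
  res <- lowpass(resultant_magnitude(lowpass(ch[, "gx"], fs, spec), fgy,
                                     lowpass(ch[, "gz"], fs, spec)), fs, spec)
  base <- detect_gait_events(fgy, res, fs)
  k <- 25                                    # half a second
  pad <- function(x) c(rep(x[1], k), x[seq_len(length(x) - k)])
  shifted <- detect_gait_events(pad(fgy), pad(res), fs)
  # truncation at the end may lose the final event(s); compare the rest
  m <- min(length(base$toe_offs), length(shifted$toe_offs))
  expect_gt(m, 5)
  expect_equal(shifted$toe_offs[seq_len(m)] - base$toe_offs[seq_len(m)],
               rep(k / fs, m), tolerance = 1e-9)
  mh <- min(length(base$heel_strikes), length(shifted$heel_strikes))
  expect_equal(shifted$heel_strikes[seq_len(mh)] - base$heel_strikes[seq_len(mh)],
               rep(k / fs, mh), tolerance = 1e-9)
})

test_that("detected events always alternate on noisy sessions", {
  for (seed in 1:6) {
    sess <- generate_session(sim_config(n_strides = 10, noise_sd = 30,
                                        seed = seed))
    ev <- detect_events_series(sess$shoe)
    merged <- gaittrans:::events_table(ev$toe_offs, ev$heel_strikes)
    if (nrow(merged) > 1)
      expect_true(all(merged$event_type[-1] != merged$event_type[-nrow(merged)]),
                  label = paste("seed", seed))
  }
})

test_that("mean stride survives 10% swing-amplitude noise across 20 seeds", {
  errs <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_strides = 15, noise_sd = 30, seed = seed)  # 10% of 300
    sess <- generate_session(cfg)
    ev <- detect_events_series(sess$shoe)
    abs(compute_gait_parameters(ev)$mean_stride_s - cfg$stride_period)
  }, numeric(1))
  expect_lt(max(errs), 1 / 50)               # within one sample period
})

test_that("gait parameters follow the half-stride and phase rules", {
  ev <- gait_events(toe_offs = c(0.6, 1.6, 2.6, 3.6) - 0.4,
                    heel_strikes = c(1, 2, 3, 4) - 0.4)
  gp <- compute_gait_parameters(ev)
  expect_equal(gp$mean_stride_s, 1.0)
  expect_equal(gp$mean_gait_s, 0.5)
  expect_equal(gp$n_strides, 3)

  # heel strikes every 1 s, toe-off 0.6 s after each: stance 0.6, swing 0.4
  hs <- 1:5
  to <- hs + 0.6
  gp2 <- compute_gait_parameters(gait_events(to, hs))
  expect_equal(gp2$mean_stance_s, 0.6)
  expect_equal(gp2$mean_swing_s, 0.4, tolerance = 1e-9)
  expect_equal(gp2$mean_stance_s + gp2$mean_swing_s, gp2$mean_stride_s,
               tolerance = 2 / 50)

  expect_error(compute_gait_parameters(gait_events(1, 2)), "two heel strikes")
})

test_that("stance + swing equals stride within two samples on detected events", {
  for (seed in c(2, 4)) {
    sess <- generate_session(sim_config(n_strides = 12, seed = seed))
    gp <- compute_gait_parameters(detect_events_series(sess$shoe))
    expect_lt(abs(gp$mean_stance_s + gp$mean_swing_s - gp$mean_stride_s),
              2 / 50)
  }
})

test_that("parameter comparison reports absolute differences in ms", {
  a <- gait_parameters(mean_stride_s = 1.136, mean_stance_s = 0.573,
                       mean_swing_s = 0.564, mean_gait_s = 0.568)
  b <- gait_parameters(mean_stride_s = 1.108, mean_stance_s = 0.493,
                       mean_swing_s = 0.608, mean_gait_s = 0.554)
  cmp <- compare_gait_parameters(a, b)
  expect_equal(unname(cmp["stride_ms"]), 28)
  expect_true(all(cmp >= 0))
  expect_equal(unname(compare_gait_parameters(a, a)), rep(0, 4))
  withr::with_seed(40, {
    x <- gait_parameters(runif(1), runif(1), runif(1))
    y <- gait_parameters(runif(1), runif(1), runif(1))
    cmp2 <- compare_gait_parameters(x, y)
    expect_equal(unname(cmp2["stance_ms"]),
                 abs(x$mean_stance_s - y$mean_stance_s) * 1000)
  })
})

test_that("events CSV survives a write/read round trip", {
  sess <- noiseless_session()
  p <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(sess$truth, p)
  back <- read_events_csv(p)
  expect_equal(back$toe_offs, sess$truth$toe_offs)
  expect_equal(back$heel_strikes, sess$truth$heel_strikes)
})
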