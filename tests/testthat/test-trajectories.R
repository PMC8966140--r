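test_that("drift correction removes constants, linear drift, and ramps", {
  expect_lt(max(abs(correct_eog_drift(rep(5, 2000)))), 1e-9)

  fs <- 33
  t <- seq(0, 60, by = 1 / fs)
  sig <- sin(2 * pi * 2 * t)
  out <- correct_eog_drift(sig + t / 60 * 20)
  expect_gt(cor(out, sig), 0.99)
  expect_lt(abs(mean(out)), 0.5)

  ramp <- seq(0, 40, length.out = 3000)
  resid <- correct_eog_drift(ramp)
  interior <- 400:2600
  expect_lt(max(abs(resid[interior])), 0.01 * diff(range(ramp)))

  expect_error(correct_eog_drift(rnorm(400), window = 500), "longer")
})

test_that("drift correction removes >= 95% of random-walk drift and keeps step amplitudes", {
  fs <- 33
  duration <- 600
  t <- seq(0, duration, by = 1 / fs)
  clean <- ifelse(t < 200, 0, ifelse(t < 400, 20, -10))
  resid_var <- drift_var <- numeric(0)
  for (seed in 1:6) {
    drift <- selfmotion:::with_seed(seed, cumsum(rnorm(length(t), 0, 0.05)))
    # linearity of the corrector isolates the drift component it leaves behind
    resid <- correct_eog_drift(clean + drift) - correct_eog_drift(clean)
    resid_var <- c(resid_var, var(resid))
    drift_var <- c(drift_var, var(drift))
    corrected <- correct_eog_drift(clean + drift)
    amp_at <- function(tc) {
      mean(corrected[t > tc + 0.1 & t < tc + 0.6]) -
        mean(corrected[t > tc - 0.6 & t < tc - 0.1])
    }
    expect_lt(abs(amp_at(200) - 20) / 20, 0.10)
    expect_lt(abs(amp_at(400) - (-30)) / 30, 0.10)
  }
  # a single path can wander too little for a per-path ratio to be
  # meaningful; the removal property is assessed over the seed ensemble
  expect_lt(sum(resid_var) / sum(drift_var), 0.05)
})

test_that("fusion sums constants exactly and interpolates steps tightly", {
  rec <- make_recording(30, head_fun = function(t) rep(10, length(t)),
                        eye_fun = function(t) rep(5, length(t)))
  g <- fuse(rec, eog_window = 0)
  expect_identical(unique(g$head_yaw), 10)
  expect_identical(unique(g$eye_in_head), 5)
  expect_identical(unique(g$gaze), 15)
  expect_identical(g$gaze, g$head_yaw + g$eye_in_head)

  rec2 <- make_recording(30, head_fun = function(t) ifelse(t < 10, 0, 30))
  g2 <- fuse(rec2, eog_window = 0)
  pre <- g2$gaze[g2$t < 10 - 1 / 120]
  post <- g2$gaze[g2$t > 10 + 1 / 120]
  expect_true(all(abs(pre) < 1e-9))
  expect_true(all(abs(post - 30) < 1e-9))
})

test_that("fusion rejects empty and non-overlapping streams", {
  rec <- make_recording(10)
  rec$t_eog <- numeric(0); rec$eog <- numeric(0)
  expect_error(fuse(rec), "two samples")
  rec2 <- make_recording(10)
  rec2$t_eog <- rec2$t_eog + 100
  expect_error(fuse(rec2, eog_window = 0), "overlap")
})

test_that("saccade detection counts velocity-threshold crossings", {
  fs <- 120
  t <- seq(0, 60, by = 1 / fs)
  expect_equal(nrow(detect_saccades(rep(3, length(t)), fs)), 0)

  steps <- ifelse(t < 15, 0, ifelse(t < 30, 20, ifelse(t < 45, 40, 60)))
  ev <- detect_saccades(steps, fs, v_thresh = 50, min_amp = 3)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$amplitude - 20) < 2))

  ramp <- seq(0, 20, length.out = 10 * fs)  # 2 deg/s, below threshold
  expect_equal(nrow(detect_saccades(ramp, fs, v_thresh = 50)), 0)
})

test_that("saccade count matches generator ground truth for separated jumps", {
  track <- target_track(t = c(0, 10, 20, 30, 40, 50),
                        azimuth = c(0, 30, -20, 25, -30, 10))
  for (seed in 1:3) {
    ds <- generate_behavior(track,
                            behavior_profile(gamma = 0.6, eog_noise_sigma = 0,
                                             eog_drift_step_sigma = 0,
                                             head_tremor_sigma = 0,
                                             saccade_rate_scale = 0),
                            duration = 60, seed = seed)
    g <- fuse(ds$rec)
    expect_equal(nrow(g$saccades$gaze), nrow(ds$truth$saccades))
  }
})

test_that("trajectory files round-trip through the text reader", {
  ds <- generate_behavior(target_track(azimuth = 10),
                          behavior_profile(gamma = 0.5), duration = 10,
                          seed = 4)
  d <- tempfile(); dir.create(d)
  paths <- write_generated_dataset(ds, d, stem = "roundtrip")
  rec <- read_motion_recording(paths[1], paths[2])
  expect_equal(rec$head_yaw, ds$rec$head_yaw, tolerance = 1e-6)
  expect_equal(rec$eog, ds$rec$eog, tolerance = 1e-6)
})
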