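test_that("default layout matches the 29-direction arrangement", {
  lay <- default_layout()
  expect_equal(lay$n, 29)
  expect_equal(sum(lay$ring == "h"), 16)
  expect_equal(sort(lay$az[lay$ring == "h"] %% 360)[1:2], c(11.25, 33.75))
  expect_equal(lay$el[lay$ring == "pole"], 90)
})

test_that("panning is energy-conserving and snaps to exact directions", {
  fs <- 44100
  sig <- sin(2 * pi * 440 * (0:(fs / 4 - 1)) / fs)
  sp <- scene_spec(list(scene_source(11.25, sig, role = "noise")),
                   duration = 0.25, fs = fs)
  ch <- render_to_array(sp)$noise
  expect_equal(sum(ch[, 1]^2), sum(sig^2))
  expect_true(all(colSums(ch[, -1]^2) == 0))

  # midway between slots 1 and 2: equal gains, power preserved
  sp2 <- scene_spec(list(scene_source(22.5, sig, role = "noise")),
                    duration = 0.25, fs = fs)
  ch2 <- render_to_array(sp2)$noise
  expect_equal(sum(ch2[, 1]^2), sum(ch2[, 2]^2), tolerance = 1e-9)
  expect_equal(sum(ch2^2), sum(sig^2), tolerance = 1e-9)

  # sweep: total power within 0.1 dB of the source power everywhere
  errs <- vapply(seq(0, 355, by = 5), function(az) {
    s <- scene_spec(list(scene_source(az, sig, role = "noise")),
                    duration = 0.25, fs = fs)
    10 * log10(sum(render_to_array(s)$noise^2) / sum(sig^2))
  }, 0)
  expect_lt(max(abs(errs)), 0.1)

  expect_error(render_to_array(
    scene_spec(list(scene_source(NaN, sig, role = "noise")),
               duration = 0.25, fs = fs)), "finite")
})

test_that("rendering is linear and keeps target/noise separated", {
  fs <- 44100
  s1 <- selfmotion:::with_seed(1, rnorm(fs / 4))
  s2 <- selfmotion:::with_seed(2, rnorm(fs / 4))
  mk <- function(sig, role) scene_spec(
    list(scene_source(50, sig, role = role),
         scene_source(200, s2, role = "noise")),
    duration = 0.25, fs = fs)
  both <- render_to_array(mk(s1, "target"))
  expect_false(is.null(both$target))
  expect_false(is.null(both$noise))
  # target channels are untouched by the noise source and vice versa
  solo <- render_to_array(scene_spec(list(scene_source(50, s1, role = "target"),
                                          scene_source(200, numeric(1), role = "noise")),
                                     duration = 0.25, fs = fs))
  expect_equal(both$target, solo$target)
})

test_that("head motion: identity, slot rotation, inversion, and errors", {
  fs <- 44100
  sig <- selfmotion:::with_seed(3, rnorm(fs / 4))
  sp <- scene_spec(list(scene_source(40, sig, role = "noise")),
                   duration = 0.25, fs = fs)
  ch <- render_to_array(sp)$noise

  out0 <- apply_head_motion(ch, head_pose(c(0, 1), yaw = 0), fs = fs)
  expect_identical(out0, ch)

  out1 <- apply_head_motion(ch, head_pose(c(0, 1), yaw = 22.5), fs = fs)
  expect_equal(out1[, 1:16], ch[, c(2:16, 1)])

  back <- apply_head_motion(out1, head_pose(c(0, 1), yaw = -22.5), fs = fs)
  expect_lt(10 * log10(sum((back - ch)^2) / sum(ch^2) + 1e-300), -40)

  out45 <- apply_head_motion(ch, head_pose(c(0, 1), yaw = 45), fs = fs)
  back45 <- apply_head_motion(out45, head_pose(c(0, 1), yaw = -45), fs = fs)
  expect_lt(10 * log10(sum((back45 - ch)^2) / sum(ch^2) + 1e-300), -40)

  expect_error(apply_head_motion(ch, head_pose(c(0, 0.1), yaw = 0), fs = fs),
               "shorter")
})

test_that("turning towards a lateral source collapses the ear level difference", {
  fs <- 44100
  sig <- speech_shaped_noise(fs / 2, fs, seed = 5)
  model <- harir_model(fs)
  sp <- scene_spec(list(scene_source(90, sig, role = "noise")),
                   duration = 0.5, fs = fs)
  ch <- render_to_array(sp)$noise
  still <- to_ha_mics(ch, model)
  ild_still <- 10 * log10(mean(still$left_front^2) / mean(still$right_front^2))
  turned <- to_ha_mics(apply_head_motion(ch, head_pose(c(0, 1), yaw = 90),
                                         fs = fs), model)
  ild_turned <- 10 * log10(mean(turned$left_front^2) / mean(turned$right_front^2))
  expect_gt(ild_still, 1)
  expect_lt(abs(ild_turned), 0.5)
})

test_that("parametric impulse responses carry the right delays and symmetry", {
  fs <- 44100
  d_over_c <- 0.010 / 343
  unwrap_phase <- function(p) {
    dp <- c(0, diff(p))
    dp[dp > pi] <- dp[dp > pi] - 2 * pi
    dp[dp < -pi] <- dp[dp < -pi] + 2 * pi
    cumsum(dp) + p[1]
  }
  delay_of <- function(ir) {
    # group delay from the phase slope over the speech band
    n <- 8192
    H <- fft(c(ir, numeric(n - length(ir))))
    f <- (0:(n - 1)) / n
    band <- which(f > 0.005 & f < 0.2)
    ph <- unwrap_phase(Arg(H[band]))
    as.numeric(-coef(lm(ph ~ I(2 * pi * f[band])))[2])
  }
  fr0 <- parametric_harir(0, mic = "front", side = "left", fs = fs)
  re0 <- parametric_harir(0, mic = "rear", side = "left", fs = fs)
  expect_equal(delay_of(re0) - delay_of(fr0), d_over_c * fs,
               tolerance = 0.05)
  fr180 <- parametric_harir(180, mic = "front", side = "left", fs = fs)
  re180 <- parametric_harir(180, mic = "rear", side = "left", fs = fs)
  expect_equal(delay_of(fr180) - delay_of(re180), d_over_c * fs,
               tolerance = 0.05)
  # Woodworth interaural delay for a lateral source
  fr90l <- parametric_harir(90, mic = "front", side = "left", fs = fs)
  fr90r <- parametric_harir(90, mic = "front", side = "right", fs = fs)
  expect_equal(delay_of(fr90r) - delay_of(fr90l),
               (0.0875 / 343) * (1 + pi / 2) * fs, tolerance = 0.1)
  # left/right symmetry at 0 degrees, exactly
  expect_identical(parametric_harir(0, mic = "front", side = "left", fs = fs),
                   parametric_harir(0, mic = "front", side = "right", fs = fs))
  expect_error(parametric_harir(0, mic = "front", side = "left", fs = 4000),
               "8000")
})

test_that("head shadow attenuation matches the analytic filter gain", {
  fs <- 44100
  s <- speech_shaped_noise(fs / 2, fs, seed = 6)
  ha <- plane_wave_ha(s, 90, fs)  # from the left
  ild <- 10 * log10(mean(ha$left_front^2) / mean(ha$right_front^2))
  expect_gt(ild, 1)
  # oracle: integrate the source spectrum through the one-pole/one-zero
  # shadow response H(s) = (alpha s + w0) / (s + w0)
  S2 <- Mod(fft(s))^2
  f <- (0:(length(s) - 1)) * fs / length(s)
  half <- f <= fs / 2
  w <- 2 * pi * f[half]
  alpha <- 0.05; w0 <- 343 / 0.0875
  H2 <- (alpha^2 * w^2 + w0^2) / (w^2 + w0^2)
  ild_pred <- 10 * log10(sum(S2[half]) / sum(S2[half] * H2))
  expect_equal(ild, ild_pred, tolerance = 0.3)
})

test_that("an impulse through one direction returns that direction's response", {
  fs <- 44100
  model <- harir_model(fs)
  ch <- matrix(0, 512, 29)
  ch[1, 5] <- 1
  out <- to_ha_mics(ch, model)
  expect_equal(out$left_front[1:128], model$irs$left_front[, 5],
               tolerance = 1e-9)
})

test_that("measured impulse responses load from WAV files as a model", {
  fs <- 44100
  ref <- harir_model(fs)
  d <- tempfile(); dir.create(d)
  for (j in 1:29) {
    m <- cbind(ref$irs$left_front[, j], ref$irs$left_rear[, j],
               ref$irs$right_front[, j], ref$irs$right_rear[, j])
    write_wav(m, fs, file.path(d, sprintf("dir_%03d.wav", j)))
  }
  loaded <- harir_from_files(d)
  expect_equal(loaded$irs$left_front, ref$irs$left_front, tolerance = 1e-6)
  expect_equal(loaded$fs, fs)
  expect_error(harir_from_files(tempfile()), "missing")
})

test_that("WAV files round-trip in float32 and PCM16", {
  x <- matrix(selfmotion:::with_seed(1, rnorm(600)) / 6, ncol = 3)
  p <- tempfile(fileext = ".wav")
  write_wav(x, 48000, p)
  w <- read_wav(p)
  expect_equal(w$samples, x, tolerance = 1e-6)
  expect_equal(w$fs, 48000)
  write_wav(x, 16000, p, bits = 16)
  w16 <- read_wav(p)
  expect_equal(w16$samples, x, tolerance = 1e-4)
})
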