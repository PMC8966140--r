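fs <- 44100

# plane-wave microphone pair with inter-mic delay tau*cos(theta); building the
# delayed member from the other with the package's own fractional delay keeps
# the geometry exact
plane_pair <- function(s, theta, cfg) {
  tau <- cfg$tau * fs * cos(theta * pi / 180)
  d0 <- selfmotion:::frac_delay_fir(0, cfg$delay_taps)
  if (tau >= 0) {
    front <- as.numeric(signal::fftfilt(d0, s))
    rear <- as.numeric(signal::fftfilt(
      selfmotion:::frac_delay_fir(tau, cfg$delay_taps), s))
  } else {
    rear <- as.numeric(signal::fftfilt(d0, s))
    front <- as.numeric(signal::fftfilt(
      selfmotion:::frac_delay_fir(-tau, cfg$delay_taps), s))
  }
  list(front = front, rear = rear)
}

test_that("cardioid formation nulls the opposite hemisphere", {
  cfg <- adm_config(fs)
  s <- speech_shaped_noise(fs, fs, seed = 21)
  p0 <- plane_pair(s, 0, cfg)
  cd <- form_cardioids(p0$front, p0$rear, cfg)
  expect_lt(10 * log10(mean(cd$c_back^2) / mean(cd$c_front^2)), -30)

  p180 <- plane_pair(s, 180, cfg)
  cd2 <- form_cardioids(p180$front, p180$rear, cfg)
  expect_lt(10 * log10(mean(cd2$c_front^2) / mean(cd2$c_back^2)), -30)

  z <- form_cardioids(numeric(1000), numeric(1000), cfg)
  expect_true(all(z$c_front == 0) && all(z$c_back == 0))
  expect_error(form_cardioids(numeric(10), numeric(9), cfg), "equal")
})

test_that("frozen beta = 0 reduces to the compensated front cardioid", {
  cfg0 <- adm_config(fs, mu = 0)
  s <- speech_shaped_noise(fs / 2, fs, seed = 22)
  ha <- plane_wave_ha(s, 0, fs)
  st <- adm_process(ha$left_front, ha$left_rear, cfg0)
  cd <- form_cardioids(ha$left_front, ha$left_rear, cfg0)
  ref <- as.numeric(signal::fftfilt(selfmotion:::comp_fir(cfg0), cd$c_front))
  expect_identical(st$y, ref)
  expect_true(all(st$beta == 0))

  cfg_nc <- adm_config(fs, mu = 0, compensation = FALSE)
  st2 <- adm_process(ha$left_front, ha$left_rear, cfg_nc)
  expect_identical(st2$y, form_cardioids(ha$left_front, ha$left_rear,
                                         cfg_nc)$c_front)
})

test_that("adapted beta matches the grid-search power minimizer", {
  cfg <- adm_config(fs)
  s <- speech_shaped_noise(2 * fs, fs, seed = 23)
  for (theta in c(135, 180, 225)) {
    p <- plane_pair(s, theta, cfg)
    cd <- form_cardioids(p$front, p$rear, cfg)
    st <- adapt_and_combine(cd$c_front, cd$c_back, cfg)
    tail_idx <- seq(round(length(s) * 0.8), length(s))
    grid <- seq(0, 1, by = 0.001)
    pow <- vapply(grid, function(b)
      mean((cd$c_front[tail_idx] - b * cd$c_back[tail_idx])^2), 0)
    expect_lt(abs(converged_beta(st) - grid[which.min(pow)]), 0.02)
  }
})

test_that("beta stays within bounds for arbitrary inputs", {
  cfg <- adm_config(fs, mu = 0.5)
  for (seed in 1:5) {
    x <- selfmotion:::with_seed(seed, {
      n <- 20000
      list(f = rnorm(n) * exp(rnorm(n)), r = rnorm(n) * 10)
    })
    st <- adm_process(x$f, x$r, cfg)
    expect_true(all(st$beta >= 0 & st$beta <= 1))
  }
})

test_that("a frontal broadband target passes within +/-3 dB from 200 Hz to 8 kHz", {
  s <- speech_shaped_noise(2 * fs, fs, seed = 24)
  ha <- plane_wave_ha(s, 0, fs)
  st <- adm_process(ha$left_front, ha$left_rear, adm_config(fs))
  n <- length(s)
  f <- (0:(n - 1)) * fs / n
  py <- Mod(fft(st$y))^2
  px <- Mod(fft(ha$left_front))^2
  edges <- c(200, 400, 800, 1600, 3200, 6400, 8000)
  for (k in seq_len(length(edges) - 1)) {
    i <- f >= edges[k] & f < edges[k + 1]
    expect_lt(abs(10 * log10(sum(py[i]) / sum(px[i]))), 3)
  }
})

test_that("shadow processing is exactly linear in the components", {
  cfg <- adm_config(fs)
  for (seed in 1:3) {
    v <- selfmotion:::with_seed(seed, {
      n <- fs / 2
      lapply(1:4, function(i) rnorm(n) / 3)
    })
    st <- adm_process(v[[1]] + v[[3]], v[[2]] + v[[4]], cfg)
    sh <- shadow_process(v[[1]], v[[2]], v[[3]], v[[4]], st)
    expect_lt(max(abs(sh$y_target + sh$y_noise - st$y)), 1e-6)
  }

  # silent noise: shadow output splits trivially
  s <- speech_shaped_noise(fs / 2, fs, seed = 25)
  ha <- plane_wave_ha(s, 0, fs)
  zero <- numeric(length(s))
  st <- adm_process(ha$left_front, ha$left_rear, cfg)
  sh <- shadow_process(ha$left_front, ha$left_rear, zero, zero, st)
  expect_true(all(sh$y_noise == 0))
  expect_equal(sh$y_target, st$y)

  # swapping the component labels changes labels only, not the sum
  v <- selfmotion:::with_seed(9, lapply(1:4, function(i) rnorm(fs / 4)))
  st2 <- adm_process(v[[1]] + v[[3]], v[[2]] + v[[4]], cfg)
  a <- shadow_process(v[[1]], v[[2]], v[[3]], v[[4]], st2)
  b <- shadow_process(v[[3]], v[[4]], v[[1]], v[[2]], st2)
  expect_equal(a$y_target + a$y_noise, b$y_target + b$y_noise)
  expect_equal(a$y_target, b$y_noise)

  expect_error(shadow_process(v[[1]][1:100], v[[2]][1:100], v[[3]][1:100],
                              v[[4]][1:100], st2), "match")
})

test_that("the two sides of the binaural ADM never exchange state", {
  cfg <- adm_config(fs)
  s <- speech_shaped_noise(fs / 2, fs, seed = 26)
  ha_t <- plane_wave_ha(s, 0, fs, component = "target")
  ha_n <- plane_wave_ha(speech_shaped_noise(fs / 2, fs, seed = 27), 150, fs,
                        component = "noise")
  base <- adm_binaural(ha_t, ha_n, cfg)
  ha_n2 <- ha_n
  ha_n2$right_front <- ha_n2$right_front * 3
  ha_n2$right_rear <- ha_n2$right_rear * 3
  mod <- adm_binaural(ha_t, ha_n2, cfg)
  expect_identical(base$mixture$left, mod$mixture$left)
  expect_identical(base$state$left$beta, mod$state$left$beta)
  expect_false(identical(base$mixture$right, mod$mixture$right))
})
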