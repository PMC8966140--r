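#' Configuration for the adaptive differential microphone
#'
#' A first-order ADM per side: the two omnidirectional microphones are
#' combined by delay-and-subtract into a front-facing and a back-facing
#' cardioid, which are mixed as `y = c_front - beta * c_back`. Adapting the
#' mixing weight beta steers a spatial null towards the most prominent rear
#' sound source; constraining beta to [0, 1] keeps the null in the back
#' hemisphere (the target is assumed frontal).
#'
#' @param fs sampling rate, Hz.
#' @param mic_spacing front/rear microphone distance d, metres (default
#'   0.010).
#' @param c speed of sound, m/s.
#' @param mu normalized adaptation step per block (default 0.01).
#' @param block adaptation block size in samples (default 64).
#' @param beta_bounds bounds for the mixing weight (default `c(0, 1)`).
#' @param compensation logical; equalize the +6 dB/oct differential tilt of
#'   the output so a frontal broadband target is preserved (default TRUE).
#' @param delay_taps fractional-delay FIR length (default 64; the
#'   inter-microphone delay d/c is ~1.3 samples at 44.1 kHz, so an integer
#'   delay is insufficient and null depth tracks delay accuracy).
#' @param comp_taps compensation FIR length (default 512).
#' @return object of class `adm_config`.
#' @export
adm_config <- function(fs, mic_spacing = 0.010, c = 343, mu = 0.01,
                       block = 64, beta_bounds = c(0, 1),
                       compensation = TRUE, delay_taps = 64,
                       comp_taps = 512) {
  stopifnot(fs > 0, mic_spacing > 0, block >= 8)
  if (!(beta_bounds[1] >= 0 && beta_bounds[1] < beta_bounds[2] &&
        beta_bounds[2] <= 1))
    stop("beta_bounds must satisfy 0 <= min < max <= 1")
  tau_samples <- mic_spacing * fs / c
  if (tau_samples < 1)
    stop("mic_spacing * fs / c must be >= 1 sample (got ",
         signif(tau_samples, 3), "); increase fs")
  structure(list(fs = fs, mic_spacing = mic_spacing, c = c, mu = mu,
                 block = block, beta_bounds = beta_bounds,
                 compensation = compensation, delay_taps = delay_taps,
                 comp_taps = comp_taps, tau = mic_spacing / c),
            class = "adm_config")
}

# linear-phase FIR equalizing the front-cardioid frontal response
# |1 - e^{-i w 2 tau}| = 2|sin(w tau)|; gain clipped below 150 Hz and at the
# high-frequency notch region
comp_fir <- function(cfg) {
  nyq <- cfg$fs / 2
  f <- seq(0, 1, length.out = 257)
  fhz <- f * nyq
  resp <- 2 * abs(sin(2 * pi * fhz * cfg$tau))
  gmax <- 1 / (2 * abs(sin(2 * pi * 150 * cfg$tau)))
  m <- pmin(1 / pmax(resp, 1e-9), gmax)
  signal::fir2(cfg$comp_taps, f, m)
}

apply_fir <- function(b, x) as.numeric(signal::fftfilt(b, x))

#' Form front- and back-facing cardioids from a microphone pair
#'
#' `c_front = front - delay(rear, d/c)` and
#' `c_back = rear - delay(front, d/c)`, with the delay realized as a
#' windowed-sinc fractional-delay FIR. Both outputs share the FIR's base
#' latency so they stay time-aligned.
#'
#' @param front,rear equal-length audio vectors from the front and rear
#'   microphone of one side.
#' @param cfg an [adm_config()].
#' @return list with `c_front` and `c_back`.
#' @export
form_cardioids <- function(front, rear, cfg) {
  stopifnot(inherits(cfg, "adm_config"))
  if (length(front) != length(rear))
    stop("front and rear signals must have equal length")
  tau_samp <- cfg$tau * cfg$fs
  d0 <- frac_delay_fir(0, cfg$delay_taps)
  dt <- frac_delay_fir(tau_samp, cfg$delay_taps)
  list(c_front = apply_fir(d0, front) - apply_fir(dt, rear),
       c_back = apply_fir(d0, rear) - apply_fir(dt, front))
}

# sequential block NLMS on beta; returns per-block beta (the value used for
# each block's output) and the mixed signal before compensation
adm_adapt_core <- function(cf, cb, mu, bounds, block, beta_init = 0) {
  n <- length(cf)
  nb <- ceiling(n / block)
  beta <- numeric(nb)
  y <- numeric(n)
  b <- beta_init
  eps <- 1e-12
  for (k in seq_len(nb)) {
    idx <- ((k - 1) * block + 1):min(k * block, n)
    yk <- cf[idx] - b * cb[idx]
    y[idx] <- yk
    beta[k] <- b
    p <- sum(cb[idx]^2)
    b <- b + mu * sum(yk * cb[idx]) / (p + eps)
    b <- max(bounds[1], min(bounds[2], b))
  }
  list(y = y, beta = beta)
}

#' Adapt the mixing weight and combine the cardioids
#'
#' Block-wise `y = c_front - beta * c_back` with a normalized gradient
#' (block NLMS) update of beta towards minimizing the block output power,
#' hard-clipped to `beta_bounds` after every update, followed by the
#' differential-tilt compensation filter when enabled. The per-block beta
#' trajectory is returned so the identical time-varying linear operations
#' can be re-applied to clean components ([shadow_process()]).
#'
#' @param c_front,c_back cardioid signals from [form_cardioids()].
#' @param cfg an [adm_config()].
#' @param beta_init initial mixing weight (default 0).
#' @return object of class `adm_state`: list with `y` (processed audio),
#'   `beta` (per-block trajectory), `block`, `cfg`.
#' @export
adapt_and_combine <- function(c_front, c_back, cfg, beta_init = 0) {
  stopifnot(inherits(cfg, "adm_config"))
  res <- adm_adapt_core(c_front, c_back, cfg$mu, cfg$beta_bounds,
                        cfg$block, beta_init)
  y <- if (cfg$compensation) apply_fir(comp_fir(cfg), res$y) else res$y
  structure(list(y = y, beta = res$beta, block = cfg$block, cfg = cfg),
            class = "adm_state")
}

#' @export
print.adm_state <- function(x, ...) {
  cat(sprintf("<adm_state> %d samples, %d blocks of %d; beta: %.3f -> %.3f (mean last 20%%: %.3f)\n",
              length(x$y), length(x$beta), x$block,
              x$beta[1], x$beta[length(x$beta)], converged_beta(x)))
  invisible(x)
}

#' Converged mixing weight
#'
#' Mean beta over the last `tail_frac` of the adaptation blocks.
#' @param state an `adm_state`.
#' @param tail_frac fraction of blocks to average over (default 0.2).
#' @return scalar beta.
#' @export
converged_beta <- function(state, tail_frac = 0.2) {
  nb <- length(state$beta)
  mean(state$beta[seq(max(1, ceiling(nb * (1 - tail_frac))), nb)])
}

#' Process a microphone pair with the ADM
#'
#' Convenience wrapper: forms cardioids, adapts, combines, compensates.
#'
#' @param front,rear microphone signals of one side.
#' @param cfg an [adm_config()].
#' @param beta_init initial mixing weight.
#' @return an `adm_state`.
#' @export
adm_process <- function(front, rear, cfg, beta_init = 0) {
  cd <- form_cardioids(front, rear, cfg)
  adapt_and_combine(cd$c_front, cd$c_back, cfg, beta_init)
}

# apply a frozen beta trajectory to one component (vectorized over blocks)
apply_frozen <- function(cf, cb, beta, block, cfg) {
  n <- length(cf)
  bexp <- rep(beta, each = block)[seq_len(n)]
  y <- cf - bexp * cb
  if (cfg$compensation) apply_fir(comp_fir(cfg), y) else y
}

#' Shadow-process clean components with a recorded ADM state
#'
#' Applies the identical time-varying linear operations (fractional delays,
#' per-block beta, compensation) that were recorded while processing the
#' mixture separately to the target-only and noise-only microphone signals.
#' Because every operation is linear, `y_target + y_noise` equals the
#' processed mixture to float precision, which makes the SNR after the
#' (nonlinear, adaptive) ADM well defined.
#'
#' @param target_front,target_rear,noise_front,noise_rear clean-component
#'   microphone signals of one side.
#' @param state the `adm_state` recorded from processing the mixture.
#' @return list with `y_target` and `y_noise`.
#' @export
shadow_process <- function(target_front, target_rear,
                           noise_front, noise_rear, state) {
  stopifnot(inherits(state, "adm_state"))
  cfg <- state$cfg
  n <- length(target_front)
  if (length(noise_front) != n || length(target_rear) != n ||
      length(noise_rear) != n)
    stop("component signals must all have equal length")
  if (length(state$beta) != ceiling(n / state$block))
    stop("state trajectory length does not match the signal length")
  ct <- form_cardioids(target_front, target_rear, cfg)
  cn <- form_cardioids(noise_front, noise_rear, cfg)
  list(
    y_target = apply_frozen(ct$c_front, ct$c_back, state$beta, state$block, cfg),
    y_noise = apply_frozen(cn$c_front, cn$c_back, state$beta, state$block, cfg)
  )
}

#' Binaural ADM with shadow processing of target and noise
#'
#' Runs two fully independent ADMs (left and right side) on the
#' target-plus-noise mixtures, then shadow-filters the clean components
#' with each side's recorded state.
#'
#' @param ha_target,ha_noise `ha_mic_signals` for the target and noise
#'   components (4 channels each).
#' @param cfg an [adm_config()]; built from the signal sampling rate when
#'   `NULL`.
#' @return list with `target` and `noise` (each `list(left, right)`
#'   processed clean components), `mixture` (processed mixtures), and
#'   `state` (per-side `adm_state`).
#' @export
adm_binaural <- function(ha_target, ha_noise, cfg = NULL) {
  stopifnot(inherits(ha_target, "ha_mic_signals"),
            inherits(ha_noise, "ha_mic_signals"))
  if (is.null(cfg)) cfg <- adm_config(fs = ha_target$fs)
  out <- list(target = list(), noise = list(), mixture = list(), state = list())
  for (side in c("left", "right")) {
    fr <- paste0(side, "_front"); re <- paste0(side, "_rear")
    st <- adm_process(ha_target[[fr]] + ha_noise[[fr]],
                      ha_target[[re]] + ha_noise[[re]], cfg)
    sh <- shadow_process(ha_target[[fr]], ha_target[[re]],
                         ha_noise[[fr]], ha_noise[[re]], st)
    out$target[[side]] <- sh$y_target
    out$noise[[side]] <- sh$y_noise
    out$mixture[[side]] <- st$y
    out$state[[side]] <- st
  }
  out
}
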