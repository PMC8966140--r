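# Independent oracles and small constructors shared across the suite.

# naive per-window better-ear segmental SNR, written as an explicit loop
naive_segmental_snr <- function(tl, tr, nl, nr, fs, window_len = 0.2,
                                clamp = c(-10, 35)) {
  w <- round(window_len * fs)
  nw <- length(tl) %/% w
  be <- numeric(nw)
  for (k in seq_len(nw)) {
    idx <- ((k - 1) * w + 1):(k * w)
    ear <- function(tg, nz) {
      et <- sum(tg[idx]^2); en <- sum(nz[idx]^2)
      s <- if (en == 0) { if (et == 0) clamp[1] else clamp[2] }
      else 10 * log10(et / en)
      min(clamp[2], max(clamp[1], s))
    }
    be[k] <- max(ear(tl, nl), ear(tr, nr))
  }
  be
}

# brute-force Benjamini-Hochberg step-up adjustment
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest down
  for (i in seq(m, 1)) {
    adj[i] <- if (i == m) sorted[i] else min(adj[i + 1], sorted[i])
  }
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# between-groups F in a balanced mixed design, from scratch on subject means
brute_between_F <- function(d, dv, group, subject) {
  agg <- aggregate(d[[dv]], list(subj = d[[subject]], grp = d[[group]]), mean)
  k <- length(unique(d[[dv]])) # unused; keep simple
  n_env <- nrow(d) / nrow(agg)
  grand <- mean(agg$x)
  gm <- tapply(agg$x, agg$grp, mean)
  ng <- tapply(agg$x, agg$grp, length)
  ssa <- n_env * sum(ng * (gm - grand)^2)
  sse <- n_env * sum((agg$x - gm[as.character(agg$grp)])^2)
  dfa <- length(gm) - 1
  dfe <- nrow(agg) - length(gm)
  (ssa / dfa) / (sse / dfe)
}

# minimal gaze decomposition built directly (bypassing the sensor path)
make_gd <- function(t, head, gaze, torso = 0, mask = NULL,
                    saccades_gaze = NULL) {
  fs <- if (length(t) > 1) 1 / (t[2] - t[1]) else 120
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      effector = character(0))
  torso <- rep_len(torso, length(t))
  structure(list(
    t = t, fs = fs, head_yaw = head, eye_in_head = gaze - head, gaze = gaze,
    torso_yaw = torso, head_re_torso = head - torso,
    gaze_re_torso = gaze - torso,
    head_x = rep(0, length(t)), head_y = rep(0, length(t)),
    saccade_mask = if (is.null(mask)) rep(FALSE, length(t)) else mask,
    saccades = list(eye = empty, head = empty,
                    gaze = if (is.null(saccades_gaze)) empty else saccades_gaze),
    duration = max(t) - min(t),
    participant_id = "t", environment_id = "t", group = "NH_young"),
    class = "gaze_decomposition")
}

# constant-rate motion recording from ideal head/eye series
make_recording <- function(duration, f_head = 200, f_eog = 33,
                           head_fun = function(t) rep(0, length(t)),
                           eye_fun = function(t) rep(0, length(t))) {
  th <- seq(0, duration, by = 1 / f_head)
  te <- seq(0, duration, by = 1 / f_eog)
  motion_recording(th, head_fun(th), te, eye_fun(te))
}
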