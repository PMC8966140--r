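#' Virtual loudspeaker array layout
#'
#' @param az,el direction azimuths and elevations in degrees.
#' @param ring ring membership label per direction: `"h"` (horizontal ring),
#'   `"up"`, `"down"`, `"pole"`.
#' @return object of class `array_layout`.
#' @export
array_layout <- function(az, el, ring) {
  stopifnot(length(az) == length(el), length(az) == length(ring))
  structure(list(az = wrap_angle(az), el = el, ring = ring,
                 n = length(az)), class = "array_layout")
}

#' Default 29-direction rendering layout
#'
#' Horizontal ring of 16 directions at ear level (first at 11.25 deg, 22.5
#' deg spacing), rings of 6 at +45 deg (first at 0 deg) and -45 deg
#' elevation (first at 30 deg), 60 deg spacing, and one pole direction at
#' +90 deg elevation.
#' @return an [array_layout()] with 29 directions.
#' @export
default_layout <- function() {
  array_layout(
    az = c(11.25 + 22.5 * 0:15, 60 * 0:5, 30 + 60 * 0:5, 0),
    el = c(rep(0, 16), rep(45, 6), rep(-45, 6), 90),
    ring = c(rep("h", 16), rep("up", 6), rep("down", 6), "pole")
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat("<array_layout>", x$n, "directions:",
      sum(x$ring == "h"), "horizontal,",
      sum(x$ring == "up"), "upper,", sum(x$ring == "down"), "lower,",
      sum(x$ring == "pole"), "pole\n")
  invisible(x)
}

# constant-power pan of an azimuth onto the 16-slot horizontal ring;
# returns ring-local indices (1..16) and gains with g1^2+g2^2 = 1
pan_gains_ring <- function(az) {
  a <- az %% 360
  u <- (a - 11.25) / 22.5
  i0 <- floor(u)
  f <- u - i0
  idx <- c(i0 %% 16, (i0 + 1) %% 16) + 1
  g <- c(cos(f * pi / 2), sin(f * pi / 2))
  list(idx = idx, g = g)
}

# nearest layout direction by great-circle distance (used for elevated sources)
nearest_direction <- function(layout, az, el) {
  a1 <- deg2rad(az); e1 <- deg2rad(el)
  a2 <- deg2rad(layout$az); e2 <- deg2rad(layout$el)
  cosd <- sin(e1) * sin(e2) + cos(e1) * cos(e2) * cos(a1 - a2)
  which.max(cosd)
}

#' A single scene source
#'
#' @param azimuth constant azimuth in degrees, or a list/data.frame with
#'   elements `t` and `azimuth` describing a piecewise-constant track (e.g.
#'   the active-speaker direction of a conversation).
#' @param signal numeric audio vector, or a recipe list created by
#'   [ssn_recipe()] which is materialised lazily at render time.
#' @param role `"target"` or `"noise"`.
#' @param level_db gain applied to the signal, dB.
#' @param elevation elevation in degrees (elevated sources are snapped to
#'   the nearest layout direction; azimuth tracks are supported only at
#'   elevation 0).
#' @param distance source distance in metres (defaults to the 1.76 m ring
#'   radius; used by the translation model).
#' @return object of class `scene_source`.
#' @export
scene_source <- function(azimuth, signal, role = c("noise", "target"),
                         level_db = 0, elevation = 0, distance = 1.76) {
  role <- match.arg(role)
  if (is.numeric(azimuth) && length(azimuth) == 1 && !is.finite(azimuth))
    stop("source azimuth must be finite")
  structure(list(azimuth = azimuth, signal = signal, role = role,
                 level_db = level_db, elevation = elevation,
                 distance = distance),
            class = "scene_source")
}

#' Scene description
#'
#' @param sources list of [scene_source()] objects; at least one noise
#'   source is required, a target is optional (passive environments have
#'   none).
#' @param duration scene duration in seconds.
#' @param fs audio sampling rate, Hz (default 44100).
#' @param schedule optional data.frame `(t_start, t_end, source)` recording
#'   the active-speaker schedule (metadata; the target azimuth track already
#'   encodes it).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(sources, duration, fs = 44100, schedule = NULL) {
  stopifnot(is.list(sources), length(sources) >= 1, duration > 0)
  roles <- vapply(sources, function(s) s$role, "")
  if (!any(roles == "noise")) stop("scene must contain at least one noise source")
  if (!is.null(schedule) && nrow(schedule) > 1 &&
      any(schedule$t_start[-1] < schedule$t_end[-nrow(schedule)]))
    stop("active-speaker schedule intervals must not overlap")
  structure(list(sources = sources, duration = duration, fs = fs,
                 schedule = schedule),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  roles <- vapply(x$sources, function(s) s$role, "")
  cat(sprintf("<scene_spec> %.1f s @ %g Hz: %d target, %d noise source(s)\n",
              x$duration, x$fs, sum(roles == "target"), sum(roles == "noise")))
  invisible(x)
}

# evaluate a source's azimuth (deg) at times tq
eval_source_azimuth <- function(src, tq) {
  if (is.numeric(src$azimuth)) return(rep(src$azimuth[1], length(tq)))
  tr <- src$azimuth
  if (length(tr$t) == 1) return(rep(tr$azimuth, length(tq)))
  stats::approx(tr$t, tr$azimuth, tq, method = "constant", rule = 2)$y
}

materialize_signal <- function(sig, n, fs) {
  if (is.numeric(sig)) {
    out <- numeric(n)
    out[seq_len(min(n, length(sig)))] <- sig[seq_len(min(n, length(sig)))]
    return(out)
  }
  if (inherits(sig, "signal_recipe")) return(realize_recipe(sig, n, fs))
  stop("unsupported signal type")
}

#' Render a scene to per-direction channel signals
#'
#' Each source is amplitude-panned onto the layout: constant-power pairwise
#' panning between the two nearest horizontal-ring directions for sources at
#' ear level, nearest-direction snap for elevated sources. Moving azimuth
#' tracks are applied block-wise with a linear cross-fade of the panning
#' gains. Target and noise roles are rendered into separate channel sets so
#' the downstream SNR computation has clean components.
#'
#' @param spec a [scene_spec()].
#' @param layout an [array_layout()].
#' @param block block size in samples for motion/gain updates (default 1024).
#' @return list with elements `target` and `noise` (each a `n x layout$n`
#'   matrix or `NULL`), `fs`, `layout`.
#' @export
render_to_array <- function(spec, layout = default_layout(), block = 1024) {
  stopifnot(inherits(spec, "scene_spec"), inherits(layout, "array_layout"))
  n <- round(spec$duration * spec$fs)
  ring_cols <- which(layout$ring == "h")
  out <- list(target = NULL, noise = NULL)
  for (src in spec$sources) {
    x <- materialize_signal(src$signal, n, spec$fs) * 10^(src$level_db / 20)
    if (is.null(out[[src$role]]))
      out[[src$role]] <- matrix(0, n, layout$n)
    M <- out[[src$role]]
    if (src$elevation != 0) {
      az0 <- if (is.numeric(src$azimuth)) src$azimuth[1] else src$azimuth$azimuth[1]
      j <- nearest_direction(layout, az0, src$elevation)
      M[, j] <- M[, j] + x
    } else if (is.numeric(src$azimuth)) {
      if (!is.finite(src$azimuth[1])) stop("source azimuth must be finite")
      p <- pan_gains_ring(src$azimuth[1])
      for (k in 1:2) {
        j <- ring_cols[p$idx[k]]
        M[, j] <- M[, j] + x * p$g[k]
      }
    } else {
      # moving source: block-wise gains with linear cross-fade
      nb <- ceiling(n / block)
      tb <- (seq(0, nb) * block) / spec$fs
      azb <- eval_source_azimuth(src, pmin(tb, spec$duration))
      if (any(!is.finite(azb))) stop("source azimuth must be finite")
      for (b in seq_len(nb)) {
        i0 <- (b - 1) * block + 1
        i1 <- min(b * block, n)
        idx <- i0:i1
        r <- (seq_along(idx) - 1) / length(idx)
        p0 <- pan_gains_ring(azb[b])
        p1 <- pan_gains_ring(azb[b + 1])
        # accumulate ramped gains per ring slot
        for (k in 1:2) {
          j <- ring_cols[p0$idx[k]]
          M[idx, j] <- M[idx, j] + x[idx] * (p0$g[k] * (1 - r))
          j <- ring_cols[p1$idx[k]]
          M[idx, j] <- M[idx, j] + x[idx] * (p1$g[k] * r)
        }
      }
    }
    out[[src$role]] <- M
  }
  out$fs <- spec$fs
  out$layout <- layout
  out
}

#' Head pose track
#'
#' @param t time axis, seconds.
#' @param yaw head yaw, degrees (positive left).
#' @param x,y horizontal head translation, metres.
#' @return object of class `head_pose`.
#' @export
head_pose <- function(t, yaw = 0, x = 0, y = 0) {
  structure(list(t = as.numeric(t),
                 yaw = rep_len(as.numeric(yaw), length(t)),
                 x = rep_len(as.numeric(x), length(t)),
                 y = rep_len(as.numeric(y), length(t))),
            class = "head_pose")
}

#' Head pose from a gaze decomposition
#' @param g a `gaze_decomposition`.
#' @param translation include measured head translation (default TRUE).
#' @return a [head_pose()] with time rebased to start at 0.
#' @export
as_head_pose <- function(g, translation = TRUE) {
  stopifnot(inherits(g, "gaze_decomposition"))
  head_pose(g$t - g$t[1], g$head_yaw,
            x = if (translation) g$head_x else 0,
            y = if (translation) g$head_y else 0)
}

# 29 x 29 gain matrix mapping world-fixed channels to head-relative channels
# for one pose sample
motion_gain_matrix <- function(layout, yaw, x = 0, y = 0, radius = 1.76) {
  G <- diag(layout$n)
  ring_cols <- which(layout$ring == "h")
  ring_az <- layout$az[ring_cols]
  translated <- !(x == 0 && y == 0)
  for (k in seq_along(ring_cols)) {
    i <- ring_cols[k]
    if (translated) {
      th <- deg2rad(ring_az[k])
      px <- radius * cos(th) - x
      py <- radius * sin(th) - y
      dist <- sqrt(px^2 + py^2)
      az_rel <- (atan2(py, px) * 180 / pi) - yaw
      gain <- radius / max(dist, 0.05)
    } else {
      # pure rotation: keep slot-multiple yaws (incl. zero) bit-exact
      az_rel <- ring_az[k] - yaw
      gain <- 1
    }
    p <- pan_gains_ring(az_rel)
    G[i, ] <- 0
    G[i, ring_cols[p$idx]] <- gain * p$g
  }
  for (ring in c("up", "down")) {
    cols <- which(layout$ring == ring)
    az <- layout$az[cols]
    for (k in seq_along(cols)) {
      i <- cols[k]
      # nearest-slot snap within the same elevated ring
      j <- cols[which.min(abs(wrap_angle((az[k] - yaw) - az)))]
      G[i, ] <- 0
      G[i, j] <- 1
    }
  }
  G
}

#' Apply measured head motion to rendered channel signals
#'
#' Per processing block, each horizontal-ring channel is re-panned to its
#' head-relative direction (direction minus yaw, with the translation of the
#' listening position shifting per-channel azimuth and distance gain at the
#' 1.76 m ring radius); elevated rings are rotated by nearest-slot snap and
#' the pole is unaffected by yaw. Gains are linearly cross-faded across each
#' block to avoid clicks.
#'
#' @param channels `n x layout$n` channel matrix from [render_to_array()].
#' @param pose a [head_pose()]; must cover the audio duration.
#' @param layout the [array_layout()] the channels were rendered to.
#' @param fs audio sampling rate, Hz.
#' @param block block size in samples for pose updates (default 1024).
#' @param radius virtual loudspeaker ring radius in metres.
#' @return channel matrix of the same dimensions.
#' @export
apply_head_motion <- function(channels, pose, layout = default_layout(),
                              fs = 44100, block = 1024, radius = 1.76) {
  stopifnot(is.matrix(channels), inherits(pose, "head_pose"))
  n <- nrow(channels)
  dur <- (n - 1) / fs
  if (max(pose$t) < dur - 1 / fs)
    stop("pose track (", signif(max(pose$t), 4), " s) is shorter than the audio (",
         signif(dur, 4), " s)")
  pt <- function(v, tq) {
    if (length(pose$t) == 1) rep(v, length(tq))
    else stats::approx(pose$t, v, tq, rule = 2)$y
  }
  nb <- ceiling(n / block)
  tb <- pmin((seq(0, nb) * block) / fs, dur)
  yawb <- pt(pose$yaw, tb); xb <- pt(pose$x, tb); yb <- pt(pose$y, tb)
  static <- all(yawb == yawb[1]) && all(xb == xb[1]) && all(yb == yb[1])
  if (static)
    return(channels %*% motion_gain_matrix(layout, yawb[1], xb[1], yb[1], radius))
  out <- matrix(0, n, ncol(channels))
  G1 <- motion_gain_matrix(layout, yawb[1], xb[1], yb[1], radius)
  for (b in seq_len(nb)) {
    G0 <- G1
    G1 <- motion_gain_matrix(layout, yawb[b + 1], xb[b + 1], yb[b + 1], radius)
    idx <- ((b - 1) * block + 1):min(b * block, n)
    r <- (seq_along(idx) - 1) / length(idx)
    out[idx, ] <- (channels[idx, , drop = FALSE] %*% G0) * (1 - r) +
      (channels[idx, , drop = FALSE] %*% G1) * r
  }
  out
}

# windowed-sinc fractional-delay FIR; delay in samples, relative to a fixed
# integer latency of (n_taps - 1)/2 shared by all filters; |delay| must stay
# well inside the window for the design to hold (callers split off the
# integer part for large delays)
frac_delay_fir <- function(delay, n_taps = 32) {
  ctr <- (n_taps - 1) / 2
  k <- 0:(n_taps - 1)
  t <- k - ctr - delay
  h <- ifelse(abs(t) < 1e-12, 1, sin(pi * t) / (pi * t))
  w <- 0.5 - 0.5 * cos(2 * pi * (k + 0.5) / n_taps)  # Hann
  h <- h * w
  h / sum(h)  # unit DC gain so delay-and-subtract nulls hold at low frequency
}

# fractional delay with integer/fractional split: the sinc core stays
# centred in its window however large the delay; absolute latency =
# base + delay samples
shifted_frac_delay <- function(delay, total_len, base = 28, core = 32) {
  di <- floor(delay)
  df <- delay - di - 0.5        # in [-0.5, 0.5): core stays centred
  start0 <- base + di - core %/% 2 + 1  # 0-based start so that latency works out
  if (start0 < 0 || start0 + core > total_len)
    stop("delay out of range for the impulse-response length")
  h <- numeric(total_len)
  # group delay of the core = (core-1)/2 + df; start0 + 15.5 + df = base + delay
  h[start0 + seq_len(core)] <- frac_delay_fir(df, core)
  h
}

#' Parametric head/hearing-aid impulse response
#'
#' Synthetic stand-in for measured head- and hearing-aid-related impulse
#' responses: a windowed-sinc fractional delay carrying a Woodworth
#' interaural time difference, a first-order low-pass head-shadow filter on
#' the contralateral side (cutoff and high-frequency gain scaled by the
#' lateral incidence angle), and an axial front/rear microphone delay of
#' `d/c * cos(incidence)`. Elevation is handled by cosine weighting of the
#' horizontal projection.
#'
#' @param azimuth source azimuth, degrees (0 front, positive left).
#' @param elevation source elevation, degrees.
#' @param mic `"front"` or `"rear"`.
#' @param side `"left"` or `"right"`.
#' @param fs sampling rate, Hz; must be at least 8000 so the microphone
#'   delay is resolvable.
#' @param head_radius head radius in metres (default 0.0875).
#' @param mic_spacing front/rear microphone spacing in metres (default
#'   0.010).
#' @param c speed of sound, m/s.
#' @param n_taps impulse-response length in samples (default 128).
#' @return numeric impulse response of length `n_taps`; all responses share
#'   a common base latency so interaural and inter-microphone timing is
#'   preserved.
#' @export
parametric_harir <- function(azimuth, elevation = 0,
                             mic = c("front", "rear"),
                             side = c("left", "right"),
                             fs, head_radius = 0.0875, mic_spacing = 0.010,
                             c = 343, n_taps = 128) {
  mic <- match.arg(mic)
  side <- match.arg(side)
  if (fs < 8000)
    stop("fs must be >= 8000 Hz to resolve the microphone spacing delay")
  a <- head_radius
  az <- deg2rad(azimuth); el <- deg2rad(elevation)
  # lateral angle toward this ear, sin(theta_lat) in [-1, 1]
  s_lat <- cos(el) * sin(az) * if (side == "left") 1 else -1
  s_lat <- max(-1, min(1, s_lat))
  th_lat <- asin(s_lat)
  delay_ear <- if (th_lat >= 0) -(a / c) * sin(th_lat) else (a / c) * (-th_lat)
  cos_inc <- cos(el) * cos(az)
  delay_mic <- if (mic == "rear") (mic_spacing / c) * cos_inc else 0
  ir <- shifted_frac_delay((delay_ear + delay_mic) * fs, n_taps)
  if (s_lat < 0) {
    # head shadow: bilinear-transformed one-pole/one-zero, H(s) = (alpha*s + w0)/(s + w0)
    alpha <- max(0.05, 1 + s_lat)
    w0 <- c / a
    K <- 2 * fs
    b <- c(alpha * K + w0, -alpha * K + w0) / (K + w0)
    aa <- c(1, (-K + w0) / (K + w0))
    ir <- as.numeric(signal::filter(b, aa, ir))
  }
  ir[seq_len(n_taps)]
}

#' Parametric impulse-response model for a full layout
#'
#' Precomputes [parametric_harir()] for every layout direction and the four
#' hearing-aid microphones (left/right x front/rear).
#'
#' @param fs sampling rate, Hz.
#' @param layout an [array_layout()].
#' @param ... parameters forwarded to [parametric_harir()].
#' @return object of class `harir_model`: list of `n_taps x layout$n` IR
#'   matrices keyed `left_front`, `left_rear`, `right_front`, `right_rear`.
#' @export
harir_model <- function(fs, layout = default_layout(), ...) {
  mics <- c("left_front", "left_rear", "right_front", "right_rear")
  irs <- lapply(mics, function(m) {
    parts <- strsplit(m, "_")[[1]]
    sapply(seq_len(layout$n), function(j)
      parametric_harir(layout$az[j], layout$el[j], mic = parts[2],
                       side = parts[1], fs = fs, ...))
  })
  names(irs) <- mics
  structure(list(irs = irs, fs = fs, layout = layout), class = "harir_model")
}

#' Impulse-response model from measured WAV files
#'
#' Drop-in replacement for [harir_model()] using measured impulse responses:
#' one 4-channel WAV file per layout direction (channel order left front,
#' left rear, right front, right rear), named `dir_001.wav` ...
#' `dir_029.wav` in layout order.
#'
#' @param path directory containing the files.
#' @param layout the matching [array_layout()].
#' @return a `harir_model`.
#' @export
harir_from_files <- function(path, layout = default_layout()) {
  files <- file.path(path, sprintf("dir_%03d.wav", seq_len(layout$n)))
  missing <- !file.exists(files)
  if (any(missing))
    stop("missing impulse-response file(s): ",
         paste(basename(files[missing]), collapse = ", "))
  w1 <- read_wav(files[1])
  n_taps <- nrow(w1$samples)
  mics <- c("left_front", "left_rear", "right_front", "right_rear")
  irs <- lapply(1:4, function(ch) {
    sapply(seq_len(layout$n), function(j) {
      w <- read_wav(files[j])
      if (ncol(w$samples) < 4) stop("expected 4 channels in ", files[j])
      w$samples[seq_len(n_taps), ch]
    })
  })
  names(irs) <- mics
  structure(list(irs = irs, fs = w1$fs, layout = layout), class = "harir_model")
}

#' Convolve channel signals down to hearing-aid microphones
#'
#' For each of the four microphones, sums the per-direction channel signals
#' convolved with that direction's impulse response (FFT overlap in one
#' shot; output truncated to the input length).
#'
#' @param channels `n x layout$n` channel matrix.
#' @param model a `harir_model` (parametric or measured).
#' @param component label stored in the result (`"target"`, `"noise"`,
#'   `"mixture"`).
#' @return object of class `ha_mic_signals`: list with audio vectors
#'   `left_front`, `left_rear`, `right_front`, `right_rear`, plus `fs` and
#'   `component`.
#' @export
to_ha_mics <- function(channels, model, component = "mixture") {
  stopifnot(is.matrix(channels), inherits(model, "harir_model"))
  if (ncol(channels) != model$layout$n)
    stop("channel count does not match the model layout")
  n <- nrow(channels)
  n_taps <- nrow(model$irs[[1]])
  nfft <- stats::nextn(n + n_taps - 1, 2)
  acc <- lapply(model$irs, function(...) complex(nfft))
  for (j in seq_len(ncol(channels))) {
    if (all(channels[, j] == 0)) next
    CH <- stats::fft(c(channels[, j], numeric(nfft - n)))
    for (m in names(model$irs)) {
      IR <- stats::fft(c(model$irs[[m]][, j], numeric(nfft - n_taps)))
      acc[[m]] <- acc[[m]] + CH * IR
    }
  }
  out <- lapply(acc, function(A) Re(stats::fft(A, inverse = TRUE)) / nfft)
  out <- lapply(out, function(x) x[seq_len(n)])
  structure(c(out, list(fs = model$fs, component = component)),
            class = "ha_mic_signals")
}

#' @export
print.ha_mic_signals <- function(x, ...) {
  cat(sprintf("<ha_mic_signals> %s, %d samples @ %g Hz\n",
              x$component, length(x$left_front), x$fs))
  invisible(x)
}

#' Full scene-to-microphones simulation
#'
#' Renders a scene, applies a head-pose track, and convolves to the four
#' hearing-aid microphones, separately for the target and noise components.
#'
#' @param spec a [scene_spec()].
#' @param pose a [head_pose()] or `NULL` for the static frontal reference.
#' @param model a `harir_model`; built from `spec$fs` when `NULL`.
#' @param layout an [array_layout()].
#' @param block motion-update block size in samples.
#' @return list with `ha_mic_signals` elements `target` (or `NULL`) and
#'   `noise`.
#' @export
simulate_ha_signals <- function(spec, pose = NULL, model = NULL,
                                layout = default_layout(), block = 1024) {
  if (is.null(model)) model <- harir_model(spec$fs, layout)
  ch <- render_to_array(spec, layout, block = block)
  out <- list(target = NULL, noise = NULL)
  for (role in c("target", "noise")) {
    if (is.null(ch[[role]])) next
    M <- ch[[role]]
    if (!is.null(pose))
      M <- apply_head_motion(M, pose, layout, fs = spec$fs, block = block)
    out[[role]] <- to_ha_mics(M, model, component = role)
  }
  out
}

#' Hearing-aid microphone signals for a single anechoic plane wave
#'
#' Convolves one signal with the parametric impulse responses at an exact
#' (non-gridded) direction — the anechoic free-field path used for
#' benchmarking the ADM without the loudspeaker-array stage.
#'
#' @param signal audio vector.
#' @param azimuth source azimuth, degrees.
#' @param fs sampling rate, Hz.
#' @param ... forwarded to [parametric_harir()].
#' @param component label for the result.
#' @return a `ha_mic_signals` object.
#' @export
plane_wave_ha <- function(signal, azimuth, fs, ..., component = "mixture") {
  mics <- c("left_front", "left_rear", "right_front", "right_rear")
  out <- lapply(mics, function(m) {
    parts <- strsplit(m, "_")[[1]]
    ir <- parametric_harir(azimuth, 0, mic = parts[2], side = parts[1],
                           fs = fs, ...)
    as.numeric(signal::fftfilt(ir, signal))
  })
  names(out) <- mics
  structure(c(out, list(fs = fs, component = component)),
            class = "ha_mic_signals")
}
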