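#' Raw multi-sensor trajectory bundle for one participant and environment
#'
#' Bundles the head-tracking stream (yaw in degrees, horizontal translation
#' in metres, torso yaw; typically 200 Hz) and the EOG eye stream (horizontal
#' eye-in-head rotation in degree-equivalent units; typically 33 Hz).
#'
#' @param t_head time axis of the head/torso stream, seconds, strictly
#'   increasing.
#' @param head_yaw head yaw in degrees (0 = front, positive = left).
#' @param t_eog time axis of the EOG stream, seconds, strictly increasing.
#' @param eog calibrated horizontal EOG, degree-equivalent.
#' @param torso_yaw torso yaw in degrees; scalar or vector on `t_head`.
#' @param head_x,head_y horizontal head translation in metres; scalar or
#'   vector on `t_head`.
#' @param participant_id,environment_id opaque labels.
#' @param group participant group label, one of `"NH_young"`, `"NH_old"`,
#'   `"HI_unaided"`, `"HI_aided_noADM"`, `"HI_aided_ADM"` (free-form labels
#'   are allowed for synthetic data).
#' @return an object of class `motion_recording`.
#' @export
motion_recording <- function(t_head, head_yaw, t_eog, eog,
                             torso_yaw = 0, head_x = 0, head_y = 0,
                             participant_id = "p01", environment_id = "env",
                             group = "NH_young") {
  stopifnot(length(t_head) == length(head_yaw), length(t_eog) == length(eog))
  if (length(t_head) > 1 && any(diff(t_head) <= 0))
    stop("head time axis must be strictly increasing")
  if (length(t_eog) > 1 && any(diff(t_eog) <= 0))
    stop("EOG time axis must be strictly increasing")
  if (!all(is.finite(head_yaw)) || !all(is.finite(eog)))
    stop("angles must be finite")
  rec <- list(
    t_head = as.numeric(t_head), head_yaw = as.numeric(head_yaw),
    torso_yaw = rep_len(as.numeric(torso_yaw), length(t_head)),
    head_x = rep_len(as.numeric(head_x), length(t_head)),
    head_y = rep_len(as.numeric(head_y), length(t_head)),
    t_eog = as.numeric(t_eog), eog = as.numeric(eog),
    duration = max(t_head) - min(t_head),
    participant_id = participant_id, environment_id = environment_id,
    group = group
  )
  class(rec) <- "motion_recording"
  rec
}

#' @export
print.motion_recording <- function(x, ...) {
  cat("<motion_recording> ", x$participant_id, " / ", x$environment_id,
      " (", x$group, ")\n", sep = "")
  cat(sprintf("  head: %d samples (~%.0f Hz), EOG: %d samples (~%.0f Hz), %.1f s\n",
              length(x$t_head),
              if (length(x$t_head) > 1) 1 / stats::median(diff(x$t_head)) else NA,
              length(x$t_eog),
              if (length(x$t_eog) > 1) 1 / stats::median(diff(x$t_eog)) else NA,
              x$duration))
  invisible(x)
}

#' Read a motion recording from delimited text files
#'
#' The head file must have columns `t, head_yaw, head_x, head_y, torso_yaw`,
#' the eye file columns `t, eog`; both with a header row. Units: seconds,
#' degrees, metres.
#'
#' @param head_file,eye_file paths to the two streams.
#' @param ... labels passed to [motion_recording()].
#' @return a `motion_recording`.
#' @export
read_motion_recording <- function(head_file, eye_file, ...) {
  h <- utils::read.table(head_file, header = TRUE, sep = "", check.names = TRUE)
  e <- utils::read.table(eye_file, header = TRUE, sep = "", check.names = TRUE)
  need_h <- c("t", "head_yaw", "head_x", "head_y", "torso_yaw")
  if (!all(need_h %in% names(h)))
    stop("head file must have columns: ", paste(need_h, collapse = ", "))
  if (!all(c("t", "eog") %in% names(e)))
    stop("eye file must have columns: t, eog")
  motion_recording(h$t, h$head_yaw, e$t, e$eog,
                   torso_yaw = h$torso_yaw, head_x = h$head_x, head_y = h$head_y,
                   ...)
}

#' Write a motion recording to delimited text files
#' @param rec a `motion_recording`.
#' @param head_file,eye_file output paths.
#' @return invisibly, the two paths.
#' @export
write_motion_recording <- function(rec, head_file, eye_file) {
  utils::write.table(
    data.frame(t = rec$t_head, head_yaw = rec$head_yaw, head_x = rec$head_x,
               head_y = rec$head_y, torso_yaw = rec$torso_yaw),
    head_file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(t = rec$t_eog, eog = rec$eog),
                     eye_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(head_file, eye_file))
}

#' Remove slow drift from an EOG series
#'
#' The drift estimate is the series padded at both ends by linear
#' extrapolation (fitted to the outermost half-window of samples) and then
#' smoothed with a centred moving average of `window` samples; the estimate is
#' subtracted from the input. Saccadic steps and other fast structure pass
#' through almost unchanged while slow electrode drift is removed.
#'
#' @param eog_raw numeric EOG series, degree-equivalent units.
#' @param window moving-average length in samples (default 500, ~15 s at the
#'   native 33 Hz EOG rate).
#' @return drift-corrected series, same length.
#' @export
correct_eog_drift <- function(eog_raw, window = 500) {
  if (length(eog_raw) <= window)
    stop("EOG series must be longer than the smoothing window (",
         length(eog_raw), " <= ", window, ")")
  eog_raw - moving_average_padded(eog_raw, window)
}

#' Fuse head and eye streams into a gaze decomposition
#'
#' Drift-corrects the EOG stream, linearly interpolates all streams onto a
#' common time axis at `f_fused`, sums head and eye into gaze, derives
#' relative-to-torso series, and labels saccade samples from both the
#' eye-in-head and head velocity (union mask).
#'
#' @param rec a [motion_recording()].
#' @param f_fused fused sampling rate in Hz (default 120).
#' @param eog_window drift-correction window in samples; `NULL` or 0 skips
#'   the correction (e.g. when the input is already corrected).
#' @param eye_v_thresh,head_v_thresh saccade velocity thresholds, deg/s.
#' @param min_amp,merge_gap saccade detection parameters, see
#'   [detect_saccades()].
#' @return an object of class `gaze_decomposition` with elements `t`,
#'   `head_yaw`, `eye_in_head`, `gaze`, `torso_yaw`, `head_re_torso`,
#'   `gaze_re_torso`, `head_x`, `head_y`, `saccade_mask`, `saccades` (list of
#'   per-effector event tables), `fs`, and the recording labels.
#' @export
fuse <- function(rec, f_fused = 120, eog_window = 500,
                 eye_v_thresh = 50, head_v_thresh = 20,
                 min_amp = 3, merge_gap = 0.05) {
  stopifnot(inherits(rec, "motion_recording"))
  if (length(rec$t_eog) < 2 || length(rec$t_head) < 2)
    stop("both head and eye streams must contain at least two samples")
  t0 <- max(min(rec$t_head), min(rec$t_eog))
  t1 <- min(max(rec$t_head), max(rec$t_eog))
  if (t1 <= t0) stop("head and eye streams have no overlapping time support")
  # the drift window is capped below the series length so short recordings
  # remain fusable; correct_eog_drift itself stays strict
  eog <- if (!is.null(eog_window) && eog_window > 0)
    correct_eog_drift(rec$eog, min(eog_window, length(rec$eog) - 1))
  else rec$eog
  t <- seq(t0, t1, by = 1 / f_fused)
  head_yaw <- stats::approx(rec$t_head, rec$head_yaw, t)$y
  torso <- stats::approx(rec$t_head, rec$torso_yaw, t)$y
  head_x <- stats::approx(rec$t_head, rec$head_x, t)$y
  head_y <- stats::approx(rec$t_head, rec$head_y, t)$y
  eye <- stats::approx(rec$t_eog, eog, t)$y
  gaze <- head_yaw + eye
  sac_eye <- detect_saccades(eye, f_fused, v_thresh = eye_v_thresh,
                             min_amp = min_amp, merge_gap = merge_gap,
                             effector = "eye")
  sac_head <- detect_saccades(head_yaw, f_fused, v_thresh = head_v_thresh,
                              min_amp = min_amp, merge_gap = merge_gap,
                              effector = "head")
  sac_gaze <- detect_saccades(gaze, f_fused, v_thresh = eye_v_thresh,
                              min_amp = min_amp, merge_gap = merge_gap,
                              effector = "gaze")
  mask <- rep(FALSE, length(t))
  for (s in list(sac_eye, sac_head)) {
    if (nrow(s)) for (k in seq_len(nrow(s))) {
      i0 <- 1 + round(s$onset[k] * f_fused)
      i1 <- 1 + round(s$offset[k] * f_fused)
      mask[max(1, i0):min(length(t), i1)] <- TRUE
    }
  }
  g <- list(
    t = t, fs = f_fused, head_yaw = head_yaw, eye_in_head = eye, gaze = gaze,
    torso_yaw = torso, head_re_torso = head_yaw - torso,
    gaze_re_torso = gaze - torso, head_x = head_x, head_y = head_y,
    saccade_mask = mask,
    saccades = list(eye = sac_eye, head = sac_head, gaze = sac_gaze),
    duration = t1 - t0,
    participant_id = rec$participant_id, environment_id = rec$environment_id,
    group = rec$group
  )
  class(g) <- "gaze_decomposition"
  g
}

#' @export
print.gaze_decomposition <- function(x, ...) {
  cat("<gaze_decomposition> ", x$participant_id, " / ", x$environment_id,
      " (", x$group, ")\n", sep = "")
  cat(sprintf("  %d samples @ %g Hz (%.1f s); saccades: %d eye, %d head, %d gaze; %.1f%% samples in saccade\n",
              length(x$t), x$fs, x$duration,
              nrow(x$saccades$eye), nrow(x$saccades$head), nrow(x$saccades$gaze),
              100 * mean(x$saccade_mask)))
  invisible(x)
}

#' Detect saccades by velocity thresholding
#'
#' Angular velocity is estimated by central differences of a 50-ms
#' moving-average-smoothed copy of the series. Contiguous runs of
#' `|velocity| > v_thresh` become candidate events; events separated by less
#' than `merge_gap` are merged; events with amplitude (absolute angle change
#' from onset to offset) below `min_amp` are dropped.
#'
#' @param series uniformly sampled angle series, degrees.
#' @param fs sampling rate in Hz.
#' @param v_thresh velocity threshold, deg/s (50 for eye/gaze, 20 for head
#'   are the package defaults used by [fuse()]).
#' @param min_amp minimum amplitude, degrees.
#' @param merge_gap merge gap, seconds.
#' @param smooth_dur velocity pre-smoothing duration, seconds.
#' @param effector label stored in the result.
#' @return data.frame with columns `onset`, `offset` (seconds from the first
#'   sample), `amplitude` (deg), `peak_velocity` (deg/s), `effector`; zero
#'   rows when nothing crosses threshold.
#' @export
detect_saccades <- function(series, fs, v_thresh = 50, min_amp = 3,
                            merge_gap = 0.05, smooth_dur = 0.05,
                            effector = "gaze") {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      effector = character(0), stringsAsFactors = FALSE)
  if (length(series) < 3) return(empty)
  v <- angular_velocity(series, fs, smooth_dur)
  hot <- abs(v) > v_thresh
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than merge_gap
  gap_n <- merge_gap * fs
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[k, 1] - last[2] - 1 < gap_n) {
      merged[[length(merged)]] <- c(last[1], runs[k, 2])
    } else merged[[length(merged) + 1]] <- runs[k, ]
  }
  ev <- do.call(rbind, lapply(merged, function(m) {
    amp <- abs(ang_diff(series[m[2]], series[m[1]]))
    data.frame(onset = (m[1] - 1) / fs, offset = (m[2] - 1) / fs,
               amplitude = amp, peak_velocity = max(abs(v[m[1]:m[2]])),
               effector = effector, stringsAsFactors = FALSE)
  }))
  ev <- ev[ev$amplitude >= min_amp, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
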