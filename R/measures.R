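#' Target direction track
#'
#' Piecewise-constant azimuth of the active speaker (or lecturer) over time.
#' Environments without a defined target (e.g. passively waiting at a street
#' crossing, train station announcements) use `defined = FALSE`; target RMS
#' measures are then undefined.
#'
#' @param t breakpoint times, seconds.
#' @param azimuth target azimuth at and after each breakpoint, degrees.
#' @param defined logical; `FALSE` marks a target-less environment.
#' @return object of class `target_track`.
#' @export
target_track <- function(t = 0, azimuth = 0, defined = TRUE) {
  stopifnot(length(t) == length(azimuth))
  if (defined && !all(is.finite(azimuth))) stop("target azimuth must be finite")
  structure(list(t = as.numeric(t), azimuth = as.numeric(azimuth),
                 defined = isTRUE(defined)),
            class = "target_track")
}

# sample the piecewise-constant track at times tq
eval_target <- function(target, tq) {
  if (length(target$t) == 1) return(rep(target$azimuth, length(tq)))
  stats::approx(target$t, target$azimuth, tq, method = "constant",
                rule = 2)$y
}

#' Basic movement measures from a gaze decomposition
#'
#' `GazeStd`/`HeadStd` are the sample standard deviations of the gaze and
#' head yaw trajectories; `GazeSpeedMean`/`HeadSpeedMean` the mean absolute
#' angular velocities (same smoothed central-difference estimator as saccade
#' detection); `NGazeJumps` the number of detected gaze saccades divided by
#' the duration, reported per minute.
#'
#' @param g a `gaze_decomposition` from [fuse()].
#' @return named list with the five measures.
#' @export
basic_measures <- function(g) {
  stopifnot(inherits(g, "gaze_decomposition"))
  if (length(g$t) < 2) stop("need at least 2 fused samples")
  list(
    GazeStd = stats::sd(g$gaze),
    HeadStd = stats::sd(g$head_yaw),
    GazeSpeedMean = mean(abs(angular_velocity(g$gaze, g$fs))),
    HeadSpeedMean = mean(abs(angular_velocity(g$head_yaw, g$fs))),
    NGazeJumps = nrow(g$saccades$gaze) / g$duration * 60
  )
}

#' Head-over-gaze ratio during fixations
#'
#' Mean over included samples of `|head_re_torso| / |gaze_re_torso|`, the
#' fraction of the (torso-relative) gaze angle carried by the head. Three
#' exclusion rules: (a) samples during a head or eye saccade; (b) samples
#' where the head angle exceeds the gaze angle in magnitude or has opposite
#' sign (zero head angle counts as same sign); (c) samples where the absolute
#' gaze angle is below `min_gaze` degrees. The rules force every included
#' per-sample ratio into [0, 1].
#'
#' @param g a `gaze_decomposition`.
#' @param min_gaze minimum absolute gaze-re-torso angle, degrees (default 10).
#' @return list with `ratio` (NA when no samples survive), `excluded_fraction`
#'   and `n_included`.
#' @export
head_gaze_ratio <- function(g, min_gaze = 10) {
  stopifnot(inherits(g, "gaze_decomposition"))
  h <- g$head_re_torso
  z <- g$gaze_re_torso
  same_sign <- sign(h) == sign(z) | h == 0
  keep <- !g$saccade_mask & (abs(h) <= abs(z)) & same_sign & (abs(z) >= min_gaze)
  list(
    ratio = if (any(keep)) mean(abs(h[keep]) / abs(z[keep])) else NA_real_,
    excluded_fraction = 1 - mean(keep),
    n_included = sum(keep)
  )
}

#' RMS error between a trajectory and the target direction
#'
#' Root-mean-squared wrapped angular difference between a yaw series and the
#' piecewise-constant target azimuth, over the common support.
#'
#' @param t time axis of `series`, seconds.
#' @param series yaw series, degrees.
#' @param target a [target_track()].
#' @return RMS error in degrees, or `NA` when the target is undefined.
#' @export
target_rms <- function(t, series, target) {
  stopifnot(inherits(target, "target_track"))
  if (!target$defined) return(NA_real_)
  tgt <- eval_target(target, t)
  sqrt(mean(ang_diff(series, tgt)^2))
}

#' All movement measures for one participant and environment
#'
#' @param g a `gaze_decomposition`.
#' @param target optional [target_track()]; when missing or undefined the
#'   target RMS measures are `NA`.
#' @param min_gaze gaze-magnitude exclusion threshold for
#'   [head_gaze_ratio()], degrees.
#' @return one-row data.frame with columns `participant_id`, `group`,
#'   `environment_id`, the eight measures and `excluded_fraction`.
#' @export
movement_measures <- function(g, target = NULL, min_gaze = 10) {
  b <- basic_measures(g)
  hg <- head_gaze_ratio(g, min_gaze)
  if (is.null(target)) target <- target_track(defined = FALSE)
  data.frame(
    participant_id = g$participant_id, group = g$group,
    environment_id = g$environment_id,
    GazeStd = b$GazeStd, HeadStd = b$HeadStd,
    GazeSpeedMean = b$GazeSpeedMean, HeadSpeedMean = b$HeadSpeedMean,
    NGazeJumps = b$NGazeJumps,
    HeadGazeRatio = hg$ratio, excluded_fraction = hg$excluded_fraction,
    TargetGazeRMS = target_rms(g$t, g$gaze, target),
    TargetHeadRMS = target_rms(g$t, g$head_yaw, target),
    stringsAsFactors = FALSE
  )
}

#' Reshape a wide measures table to tidy long format
#'
#' @param wide data.frame as returned by rbinding [movement_measures()] rows.
#' @return long data.frame with columns `participant_id`, `group`,
#'   `environment_id`, `measure`, `value`, `defined`.
#' @export
measures_long <- function(wide) {
  mcols <- setdiff(names(wide), c("participant_id", "group", "environment_id"))
  out <- do.call(rbind, lapply(mcols, function(m) {
    data.frame(participant_id = wide$participant_id, group = wide$group,
               environment_id = wide$environment_id, measure = m,
               value = wide[[m]], defined = !is.na(wide[[m]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
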