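#' Run configuration
#'
#' A serializable bundle of all pipeline parameters. A run is fully
#' reproduced by its config plus seed.
#'
#' @param seed master seed.
#' @param input_dir optional directory of trajectory files (pairs
#'   `<stem>_head.tsv` / `<stem>_eye.tsv`); when `NULL` the generator
#'   settings are used instead.
#' @param output_dir where tables are written by the command-line
#'   interface.
#' @param generator list of generator settings (`n_per_group`,
#'   `duration`, `environments`, `profiles` as named gamma values).
#' @param scene list of scene settings for the acoustic stage
#'   (`duration`, `fs`, `babble_sources`, `snr_db`, `azimuths`,
#'   `turn_mean`).
#' @param fuse list: `f_fused`, `eog_window`, saccade thresholds.
#' @param measures list: `min_gaze`.
#' @param snr list: `window_len`, `clamp`.
#' @param adm list: `mu`, `block`, `mic_spacing`, `compensation`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, input_dir = NULL, output_dir = "out",
                       generator = list(n_per_group = 3, duration = 120,
                                        environments = c("cafeteria", "lecture"),
                                        profiles = list(NH_young = 0.60,
                                                        NH_old = 0.75,
                                                        HI = 0.94)),
                       scene = list(duration = 6, fs = 44100,
                                    babble_sources = 8, snr_db = 0,
                                    azimuths = c(-30, 0, 30), turn_mean = 5),
                       fuse = list(f_fused = 120, eog_window = 500,
                                   eye_v_thresh = 50, head_v_thresh = 20,
                                   min_amp = 3, merge_gap = 0.05),
                       measures = list(min_gaze = 10),
                       snr = list(window_len = 0.2, clamp = c(-10, 35)),
                       adm = list(mu = 0.01, block = 64,
                                  mic_spacing = 0.010, compensation = TRUE)) {
  structure(list(seed = seed, input_dir = input_dir, output_dir = output_dir,
                 generator = generator, scene = scene, fuse = fuse,
                 measures = measures, snr = snr, adm = adm),
            class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param cfg a [run_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path YAML file written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

fuse_with_cfg <- function(rec, fcfg) {
  fuse(rec, f_fused = fcfg$f_fused, eog_window = fcfg$eog_window,
       eye_v_thresh = fcfg$eye_v_thresh, head_v_thresh = fcfg$head_v_thresh,
       min_amp = fcfg$min_amp, merge_gap = fcfg$merge_gap)
}

#' Generate the full synthetic cohort of a run configuration
#'
#' One generated dataset per participant and environment; per-group
#' behaviour profiles, shared conversation target tracks per environment.
#'
#' @param cfg a [run_config()].
#' @return list with `datasets` (list of `generated_dataset`) and
#'   `targets` (per-environment [target_track()]).
#' @export
generate_cohort <- function(cfg) {
  gen <- cfg$generator
  targets <- list()
  for (i in seq_along(gen$environments)) {
    env <- gen$environments[i]
    sc <- generate_conversation_scene(
      n_talkers = length(cfg$scene$azimuths), azimuths = cfg$scene$azimuths,
      turn_mean = cfg$scene$turn_mean, duration = gen$duration,
      babble_sources = cfg$scene$babble_sources, snr_db = cfg$scene$snr_db,
      fs = cfg$scene$fs, seed = cfg$seed + 97L * i, calibrate = FALSE)
    targets[[env]] <- sc$target
  }
  datasets <- list()
  pid <- 0
  for (gname in names(gen$profiles)) {
    prof <- behavior_profile(gamma = gen$profiles[[gname]])
    for (k in seq_len(gen$n_per_group)) {
      pid <- pid + 1
      for (env in gen$environments) {
        ds <- generate_behavior(
          targets[[env]], prof, duration = gen$duration,
          seed = cfg$seed + 1000L * pid + match(env, gen$environments),
          participant_id = sprintf("p%02d", pid), environment_id = env,
          group = gname)
        datasets[[length(datasets) + 1]] <- ds
      }
    }
  }
  list(datasets = datasets, targets = targets)
}

#' Compute the measures table for a batch of recordings
#'
#' Each element of `datasets` is either a `generated_dataset` or a list
#' with elements `rec` (a [motion_recording()]) and optionally `target`.
#' A failure in one participant-environment cell is logged as a warning
#' and the run continues.
#'
#' @param datasets list of inputs (see above), or a directory path
#'   containing `<stem>_head.tsv` / `<stem>_eye.tsv` pairs.
#' @param cfg a [run_config()] supplying fusion and measure parameters.
#' @return wide measures data.frame, one row per successful cell, with an
#'   attribute `failures` listing failed stems.
#' @export
run_measures <- function(datasets, cfg = run_config()) {
  if (is.character(datasets)) datasets <- load_trajectory_dir(datasets)
  if (!length(datasets)) stop("no input recordings")
  rows <- list(); failures <- character(0)
  for (ds in datasets) {
    rec <- if (inherits(ds, "generated_dataset")) ds$rec else ds$rec
    target <- if (!is.null(ds$target)) ds$target else target_track(defined = FALSE)
    res <- tryCatch({
      g <- fuse_with_cfg(rec, cfg$fuse)
      movement_measures(g, target, min_gaze = cfg$measures$min_gaze)
    }, error = function(e) {
      warning("measures failed for ", rec$participant_id, "/",
              rec$environment_id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, paste0(rec$participant_id, "/", rec$environment_id))
    } else rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Load trajectory file pairs from a directory
#' @param path directory containing `<stem>_head.tsv` / `<stem>_eye.tsv`.
#' @return list of `list(rec = motion_recording)` entries.
#' @export
load_trajectory_dir <- function(path) {
  heads <- list.files(path, pattern = "_head\\.tsv$", full.names = TRUE)
  if (!length(heads)) stop("no trajectory files (*_head.tsv) found in ", path)
  lapply(heads, function(h) {
    stem <- sub("_head\\.tsv$", "", basename(h))
    e <- file.path(path, paste0(stem, "_eye.tsv"))
    if (!file.exists(e)) stop("missing eye stream for ", stem)
    list(rec = read_motion_recording(h, e, participant_id = stem))
  })
}

#' Acoustic-simulation stage: SNRrelative and SNRimprovementADM per
#' trajectory
#'
#' For each recording: fuse, build the head-pose track, render the scene,
#' apply the motion, convolve to the hearing-aid microphones, and compute
#' (a) SNRrelative — the mean window-wise better-ear segmental SNR
#' difference against the static frontal reference of the same scene, and
#' (b) SNRimprovementADM — the mean window-wise difference between the
#' shadow-filtered ADM output and the unprocessed front microphones.
#' Trajectories longer than the scene are trimmed to the overlap with a
#' warning.
#'
#' @param datasets list as in [run_measures()].
#' @param scene result of [generate_conversation_scene()] (or a list with
#'   `spec`).
#' @param cfg a [run_config()].
#' @param model optional `harir_model` (built from the scene sampling rate
#'   when `NULL`).
#' @return data.frame with one row per successful cell: `participant_id`,
#'   `group`, `environment_id`, `SNRrelative`, `SNRimprovementADM`,
#'   `reference_snr`.
#' @export
run_acoustics <- function(datasets, scene, cfg = run_config(), model = NULL) {
  if (is.character(datasets)) datasets <- load_trajectory_dir(datasets)
  spec <- scene$spec
  if (is.null(model)) model <- harir_model(spec$fs)
  layout <- default_layout()
  ch <- render_to_array(spec, layout)
  ref_t <- to_ha_mics(ch$target, model, "target")
  ref_n <- to_ha_mics(ch$noise, model, "noise")
  ref_track <- segmental_snr_front(ref_t, ref_n, cfg$snr$window_len,
                                   cfg$snr$clamp)
  adm_cfg <- adm_config(fs = spec$fs, mu = cfg$adm$mu, block = cfg$adm$block,
                        mic_spacing = cfg$adm$mic_spacing,
                        compensation = cfg$adm$compensation)
  rows <- list()
  for (ds in datasets) {
    rec <- ds$rec
    row <- tryCatch({
      g <- fuse_with_cfg(rec, cfg$fuse)
      if (g$duration < spec$duration - cfg$snr$window_len)
        stop("trajectory shorter than the scene")
      if (g$duration > spec$duration + 1e-9)
        warning("trajectory longer than scene for ", rec$participant_id,
                "; trimmed to the scene duration")
      pose <- as_head_pose(g)
      mt <- apply_head_motion(ch$target, pose, layout, fs = spec$fs)
      mn <- apply_head_motion(ch$noise, pose, layout, fs = spec$fs)
      ha_t <- to_ha_mics(mt, model, "target")
      ha_n <- to_ha_mics(mn, model, "noise")
      track <- segmental_snr_front(ha_t, ha_n, cfg$snr$window_len,
                                   cfg$snr$clamp)
      imp <- snr_improvement_adm(ha_t, ha_n, adm_cfg, cfg$snr$window_len,
                                 cfg$snr$clamp)
      data.frame(participant_id = rec$participant_id, group = rec$group,
                 environment_id = rec$environment_id,
                 SNRrelative = snr_difference(track, ref_track),
                 SNRimprovementADM = imp$improvement_db,
                 reference_snr = ref_track$mean_db,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("acoustics failed for ", rec$participant_id, "/",
              rec$environment_id, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Statistics stage over a measures table
#'
#' Grouped mixed ANOVAs (one per measure) with a joint Benjamini-Hochberg
#' adjustment, plus per-environment pairwise Bonferroni comparisons for
#' each measure.
#'
#' @param table wide table from [run_measures()] and/or [run_acoustics()].
#' @param dvs measure columns to analyse (defaults to all numeric measure
#'   columns present).
#' @return list with `anovas` (an `anova_results` table) and `pairwise`
#'   (named list of comparison tables).
#' @export
run_stats <- function(table, dvs = NULL) {
  if (is.null(dvs)) {
    cand <- c("GazeStd", "HeadStd", "GazeSpeedMean", "HeadSpeedMean",
              "NGazeJumps", "HeadGazeRatio", "TargetGazeRMS", "TargetHeadRMS",
              "SNRrelative", "SNRimprovementADM")
    dvs <- intersect(cand, names(table))
  }
  an <- grouped_anovas(table, dvs, between = "group",
                       within = "environment_id", subject = "participant_id")
  pw <- lapply(dvs, function(dv)
    pairwise_bonferroni(table, dv, group = "group", by = "environment_id"))
  names(pw) <- dvs
  list(anovas = an, pairwise = pw)
}

#' End-to-end run from a configuration
#'
#' Generates the synthetic cohort, computes the measures table, runs the
#' acoustic simulations on a short calibrated scene, and performs the
#' group statistics. Everything is reproduced exactly by the same config
#' and seed.
#'
#' @param cfg a [run_config()].
#' @param acoustics run the (audio-heavy) acoustic stage (default TRUE).
#' @return list with `measures`, `acoustics` (or `NULL`), `stats`, `cfg`.
#' @export
run_all <- function(cfg = run_config(), acoustics = TRUE) {
  cohort <- generate_cohort(cfg)
  meas <- run_measures(cohort$datasets, cfg)
  ac <- NULL
  if (acoustics) {
    sc <- generate_conversation_scene(
      n_talkers = length(cfg$scene$azimuths), azimuths = cfg$scene$azimuths,
      turn_mean = cfg$scene$turn_mean, duration = cfg$scene$duration,
      babble_sources = cfg$scene$babble_sources, snr_db = cfg$scene$snr_db,
      fs = cfg$scene$fs, seed = cfg$seed, calibrate = TRUE)
    short <- lapply(cohort$datasets, function(ds) {
      # trim trajectories to the (shorter) acoustic scene
      keep_h <- ds$rec$t_head <= cfg$scene$duration
      keep_e <- ds$rec$t_eog <= cfg$scene$duration
      list(rec = motion_recording(
        ds$rec$t_head[keep_h], ds$rec$head_yaw[keep_h],
        ds$rec$t_eog[keep_e], ds$rec$eog[keep_e],
        torso_yaw = ds$rec$torso_yaw[keep_h],
        head_x = ds$rec$head_x[keep_h], head_y = ds$rec$head_y[keep_h],
        participant_id = ds$rec$participant_id,
        environment_id = ds$rec$environment_id, group = ds$rec$group))
    })
    ac <- run_acoustics(short, sc, cfg)
  }
  st <- tryCatch(run_stats(meas), error = function(e) {
    warning("statistics stage failed: ", conditionMessage(e)); NULL
  })
  list(measures = meas, acoustics = ac, stats = st, cfg = cfg)
}
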