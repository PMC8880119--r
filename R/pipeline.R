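# End-to-end orchestration: one configuration object drives generation (or
# loading) of inputs, the signal -> calibration -> sync -> strides ->
# mechanics -> statistics chain, and the output artifacts, with an audit
# trail of every excluded stride. All randomness derives from one root seed
# via fixed per-module substreams.

#' Pipeline run configuration
#'
#' Collects every tunable of the processing chain with its default, plus
#' the synthetic-cohort dimensions for generator-driven runs. `mode`
#' selects how wave speed is obtained: `"fast"` synthesizes the wave-speed
#' series directly from the generator truth (plus measurement noise), while
#' `"full"` renders tap-level accelerometer recordings at the tensiometer
#' rate and processes them through the signal chain (practical for short
#' trials).
#'
#' @param n_participants,n_strides synthetic cohort dimensions (strides per
#'   participant, walking trial).
#' @param seed root integer seed; all stage substreams derive from it.
#' @param mode `"fast"` or `"full"` (see above).
#' @param noise_scale generator measurement-noise fraction.
#' @param sync_delay_range range the injected inter-system start delay is
#'   drawn from, s.
#' @param course list of [make_course()] arguments, or `NULL` to size a
#'   course to the trial automatically.
#' @param flat_approach_m flat lead-in added before the course, m (supplies
#'   level strides for sync and normalization).
#' @param fs_imu kinematics sample rate, Hz.
#' @param quality_floor,speed_bounds wave-speed validity thresholds
#'   (see [wave_speed_series()]).
#' @param bandpass tensiometry analysis band, Hz.
#' @param heel_band heel-strike impact band, Hz.
#' @param min_stride minimum stride time, s.
#' @param max_stride_length stride-length exclusion threshold, m.
#' @param level_tol level-stride threshold, deg.
#' @param bin_width slope bin width, deg.
#' @param soleus_frac soleus share of Achilles force.
#' @param include_boundary include 0-degree strides in both regression
#'   segments.
#' @param sway_duration calibration sway-trial length, s.
#' @param output_dir directory for [write_outputs()]; `NULL` skips writing.
#' @return a `run_config` list.
#' @export
run_config <- function(n_participants = 2, n_strides = 40, seed = 1L,
                       mode = c("fast", "full"), noise_scale = 0.005,
                       sync_delay_range = c(0.01, 0.1), course = NULL,
                       flat_approach_m = 20, fs_imu = 100,
                       quality_floor = 0.5, speed_bounds = c(2, 150),
                       bandpass = c(150, 1500), heel_band = c(10, 50),
                       min_stride = 0.4, max_stride_length = 3.0,
                       level_tol = 1, bin_width = 2, soleus_frac = 0.65,
                       include_boundary = TRUE, sway_duration = 30,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_participants >= 1, n_strides >= 10, seed == as.integer(seed),
            noise_scale >= 0, length(sync_delay_range) == 2,
            sync_delay_range[1] >= 0, sync_delay_range[2] <= 0.1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML document
#'
#' @param path YAML file whose keys are [run_config()] arguments; `seed` is
#'   mandatory.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) stop("config must set a seed")
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, x)
}

# prepend a flat approach segment to a full (out-and-back) course map
add_flat_approach <- function(map, length_m, grid_step = 0.5) {
  if (length_m <= 0) return(map)
  flat <- data.frame(position_m = seq(0, length_m - grid_step, by = grid_step),
                     incline_deg = 0)
  shifted <- data.frame(position_m = map$position_m + length_m,
                        incline_deg = map$incline_deg)
  out <- rbind(flat, shifted)
  class(out) <- class(map)
  attr(out, "one_way") <- attr(map, "one_way")
  out
}

# simulate stride-by-stride slopes from walking the course map
walk_course_slopes <- function(map, n_strides, level_len, per_deg) {
  pos <- 0
  slopes <- numeric(n_strides)
  for (i in seq_len(n_strides)) {
    s <- resample_linear(map$position_m, map$incline_deg,
                         pos + level_len / 2)
    slopes[i] <- max(-10, min(10, s))
    pos <- pos + level_len * (1 + per_deg * slopes[i])
  }
  slopes
}

process_participant <- function(cfg, pidx, course_map) {
  sub <- function(k) cfg$seed * 97L + pidx * 13L + k
  with_seed(sub(1L), {
    profile <- participant_profile(
      id = sprintf("P%02d", pidx),
      mass = max(45, rnorm(1, 76.5, 13.6)),
      calib_slope = 0.05 * exp(rnorm(1, 0, 0.05)),
      calib_intercept = -17.0 * (1 + rnorm(1, 0, 0.05)),
      level_stride_length = 1.60 * (1 + rnorm(1, 0, 0.04)),
      level_speed = 1.31 * (1 + rnorm(1, 0, 0.04)))
    sync_delay <- runif(1, cfg$sync_delay_range[1], cfg$sync_delay_range[2])
  })

  # --- calibration from a sway trial -------------------------------------
  sway <- make_sway_trial(profile, duration = cfg$sway_duration,
                          impact_time = 0.35, noise_scale = cfg$noise_scale,
                          seed = sub(2L))
  plate_offset <- align_plate_to_accel(sway$plate$fz_n,
                                       sway$wave_speed$speed_mps, fs = 1000)
  ws_cal <- apply_offset(sway$wave_speed, plate_offset)
  S <- resample_linear(ws_cal$time_s, ws_cal$speed_mps, sway$plate$time_s)
  M <- ankle_moment_from_plate(sway$plate, sway$ankle_axis_ap)
  away <- abs(sway$plate$time_s - sway$truth$impact_time) > 0.5
  calib <- fit_calibration(S[away], M[away], participant = profile$id)

  # --- walking trial ------------------------------------------------------
  pattern <- gait_pattern_default()
  slopes_true <- walk_course_slopes(
    course_map, cfg$n_strides, profile$level_stride_length,
    pattern$modulators$stride_length_per_deg)
  spec <- trial_spec(cfg$n_strides, slopes_true, sync_delay = sync_delay,
                     noise_scale = cfg$noise_scale, seed = sub(3L))
  trial <- make_trial(profile, pattern, spec, fs_imu = cfg$fs_imu)

  ws <- if (cfg$mode == "full") {
    rec <- render_tap_recording(trial$wave_speed, noise_scale = cfg$noise_scale * 1e-3,
                                seed = sub(4L))
    rec <- bandpass_filter(rec, cfg$bandpass[1], cfg$bandpass[2])
    wave_speed_series(rec, quality_floor = cfg$quality_floor,
                      speed_bounds = cfg$speed_bounds,
                      trial_id = profile$id)
  } else {
    data.frame(time_s = trial$wave_speed$time_s,
               speed_mps = trial$wave_speed$speed_mps,
               quality = 1, valid = TRUE)
  }

  # --- heel strikes on the tensiometry clock ------------------------------
  hs_true_ws <- trial$truth$heel_strikes - sync_delay
  hs_true_ws <- hs_true_ws[hs_true_ws >= 0]
  foot <- render_heel_strike_accel(hs_true_ws, fs = cfg$fs_imu,
                                   duration = max(ws$time_s),
                                   noise_sd = 5 * cfg$noise_scale,
                                   seed = sub(5L))
  hs_ws <- detect_heel_strikes(foot$accel, cfg$fs_imu, band = cfg$heel_band,
                               min_stride = cfg$min_stride)

  # --- sync correction ----------------------------------------------------
  # preliminary slope per detected stride, from pelvis displacement
  mid_x <- resample_linear(trial$kinematics$time_s,
                           trial$kinematics$pelvis_x_m,
                           (head(hs_ws, -1) + tail(hs_ws, -1)) / 2)
  slopes_prelim <- resample_linear(course_map$position_m,
                                   course_map$incline_deg, mid_x)
  sync <- estimate_sync_offset(trial$kinematics, ws, hs_ws, slopes_prelim,
                               level_tol = cfg$level_tol)
  ws_al <- apply_offset(ws, sync$mean_offset)
  hs_al <- hs_ws + sync$mean_offset
  hs_al <- hs_al[hs_al >= min(trial$kinematics$time_s) &
                   hs_al <= max(trial$kinematics$time_s)]
  if (length(hs_al) < 2) stop("sync correction left fewer than 2 heel strikes")

  # --- strides, slopes, mechanics -----------------------------------------
  strides <- stride_metrics(trial$kinematics, hs_al,
                            max_length = cfg$max_stride_length)
  strides <- assign_and_bin_slope(strides, course_map,
                                  bin_width = cfg$bin_width)
  kin <- trial$kinematics
  mech_rows <- list(); curves <- list()
  work <- data.frame()
  for (i in seq_len(nrow(strides))) {
    if (!strides$included[i]) next
    sel <- kin$time_s >= strides$start_s[i] & kin$time_s <= strides$end_s[i]
    if (sum(sel) < 10) {
      strides$included[i] <- FALSE
      strides$exclusion_reason[i] <- "too_few_samples"
      next
    }
    tt <- kin$time_s[sel]
    sp <- resample_linear(ws_al$time_s, ws_al$speed_mps, tt)
    mech <- mtu_stride_mechanics(tt, kin$ankle_deg[sel], kin$knee_deg[sel],
                                 sp, calib, profile$mass,
                                 soleus_frac = cfg$soleus_frac)
    w_grav <- work_against_gravity(strides$stride_length_m[i],
                                   strides$slope_deg[i])
    work <- rbind(work, data.frame(
      participant = profile$id, stride_id = strides$stride_id[i],
      slope_deg = strides$slope_deg[i], slope_bin = strides$slope_bin[i],
      ws_net = mech$work$soleus$net, ws_pos = mech$work$soleus$pos,
      ws_neg = mech$work$soleus$neg,
      wg_net = mech$work$gastroc$net, wg_pos = mech$work$gastroc$pos,
      wg_neg = mech$work$gastroc$neg, w_gravity = w_grav))
    st <- mech$streams
    st$participant <- profile$id
    st$stride_id <- strides$stride_id[i]
    mech_rows[[length(mech_rows) + 1L]] <- st
    curves[[length(curves) + 1L]] <- sp
  }
  strides$participant <- profile$id
  list(profile = profile, calibration = calib, sync = sync,
       sync_delay_true = sync_delay, strides = strides, work = work,
       mechanics = do.call(rbind, mech_rows), curves = curves)
}

#' Run the full processing pipeline
#'
#' Executes the stages in order -- signal (or fast-mode synthesis),
#' calibration, sync correction, stride segmentation and slope assignment,
#' MTU mechanics, slope statistics -- for a synthetic cohort described by
#' the configuration, and assembles a run report with an audit trail of
#' excluded strides. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` list: `report` (totals, exclusions by
#'   reason, per-bin counts, sync offsets, calibrations, regressions),
#'   `strides`, `work`, `mechanics`, `bin_curves`, `regressions`. When
#'   `config$output_dir` is set, artifacts are written via
#'   [write_outputs()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  course_args <- config$course
  if (is.null(course_args)) {
    # size the course so the trial walks out and back over the whole hill
    walk_m <- config$n_strides * 1.65 - config$flat_approach_m
    one_way <- max(30, floor(walk_m / 2) - 10)
    course_args <- list(total_length = 2 * one_way, max_slope = 10,
                        section_length = max(8, one_way / 8))
  }
  course_args$seed <- config$seed * 31L + 7L
  course <- do.call(make_course, course_args)
  course_map <- add_flat_approach(course$map, config$flat_approach_m)

  parts <- lapply(seq_len(config$n_participants), function(p) {
    tryCatch(process_participant(config, p, course_map),
             error = function(e) {
               stop("pipeline failed for participant P",
                    sprintf("%02d", p), ": ", conditionMessage(e),
                    call. = FALSE)
             })
  })

  strides <- do.call(rbind, lapply(parts, `[[`, "strides"))
  work <- do.call(rbind, lapply(parts, `[[`, "work"))
  mechanics <- do.call(rbind, lapply(parts, `[[`, "mechanics"))

  # cohort statistics
  curves <- do.call(c, lapply(parts, `[[`, "curves"))
  inc_str <- strides[strides$included, ]
  regressions <- list()
  bin_curves <- NULL
  if (!is.null(work) && nrow(work)) {
    level_mask <- abs(work$slope_deg) < config$level_tol
    norm_curves <- tryCatch(
      normalize_wave_speed_curves(curves, inc_str$slope_deg,
                                  inc_str$participant,
                                  level_tol = config$level_tol),
      error = function(e) NULL)
    if (!is.null(norm_curves)) {
      bin_curves <- bin_average_curves(norm_curves, inc_str$slope_bin)
    }
    for (m in c("soleus", "gastroc")) {
      wcol <- if (m == "soleus") work$ws_net else work$wg_net
      regressions[[m]] <- tryCatch({
        dw <- zero_reference_work(wcol, work$participant, level_mask)
        fit_slope_sensitivity(dw, work$slope_deg, muscle = m,
                              include_boundary = config$include_boundary)
      }, error = function(e) conditionMessage(e))
    }
  }

  excl <- table(strides$exclusion_reason[!strides$included])
  bins <- table(factor(inc_str$slope_bin, levels = seq(-10, 10, 2)))
  report <- structure(list(
    strides_total = nrow(strides),
    strides_included = sum(strides$included),
    exclusions = as.list(excl),
    per_bin_counts = as.list(bins),
    sync = lapply(parts, function(p) list(
      participant = p$profile$id,
      mean_offset_s = p$sync$mean_offset,
      true_delay_s = p$sync_delay_true,
      n_strides_used = p$sync$n_strides_used)),
    calibrations = lapply(parts, function(p) unclass(p$calibration)),
    regressions = lapply(regressions, function(r) {
      if (is.character(r)) r else lapply(r, unclass)
    }),
    seed = config$seed, mode = config$mode), class = "run_report")

  result <- structure(list(report = report, strides = strides, work = work,
                           mechanics = mechanics, bin_curves = bin_curves,
                           regressions = regressions,
                           course_map = course_map),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_outputs(result, config$output_dir)
  result
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run report: %d strides, %d included, %d excluded>\n",
              x$strides_total, x$strides_included,
              x$strides_total - x$strides_included))
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes the stride table (with exclusion reasons), per-stride mechanics
#' streams, bin-averaged wave-speed curves, regression records and the run
#' report to `dir` as CSV/JSON.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  paths <- c(strides = file.path(dir, "strides.csv"),
             work = file.path(dir, "stride_work.csv"),
             mechanics = file.path(dir, "mechanics.csv"),
             curves = file.path(dir, "bin_curves.csv"),
             regressions = file.path(dir, "regressions.json"),
             report = file.path(dir, "report.json"))
  write.csv(as.data.frame(result$strides), paths["strides"], row.names = FALSE)
  write.csv(result$work, paths["work"], row.names = FALSE)
  write.csv(result$mechanics, paths["mechanics"], row.names = FALSE)
  if (!is.null(result$bin_curves)) {
    write.csv(result$bin_curves, paths["curves"], row.names = FALSE)
  }
  jsonlite::write_json(result$report$regressions, paths["regressions"],
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(result$report), paths["report"],
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
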