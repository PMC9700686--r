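# Synthetic VR-session generator.
#
# Produces ground-truth-annotated gaze sessions with the statistical
# structure the downstream analysis assumes: two groups of participants, a
# fixed number of task scenarios per participant, each scenario split into an
# instruction phase (gaze parked near a speaker location) and an execution
# phase (free scanning), alternating fixation/saccade events with
# main-sequence kinematics, tracker noise, sinusoidal head motion and bursty
# data loss. Event durations and saccade amplitudes are drawn from truncated
# normals whose locations are calibrated so that the mean of events surviving
# the physiological filters equals the requested group target.

PERFORMANCE_MEASURES <- c("total_score", "task_efficacy", "navigation_efficacy",
                          "controller_motion", "total_actions")

#' Group-level generative parameters
#'
#' Defines one group of the synthetic cohort: targets for the three eye
#' movement features (group mean and between-participant SD of participant
#' means, plus a within-participant SD), the gaze data-loss rate, and the
#' five task-performance measures (total score, task efficacy, navigation
#' efficacy, controller motion, total actions).
#'
#' @param fixation_mean_ms,fixation_between_sd_ms,fixation_within_sd_ms
#'   fixation-duration target mean, between- and within-participant SD (ms).
#' @param saccade_amp_mean_deg,saccade_amp_between_sd_deg,saccade_amp_within_sd_deg
#'   saccade amplitude mean and SDs (degrees).
#' @param saccade_dur_mean_ms,saccade_dur_between_sd_ms,saccade_dur_within_sd_ms
#'   saccade duration mean and SDs (ms).
#' @param invalid_rate expected fraction of invalid gaze samples, in
#'   `[0, 0.3)` (participants with >= 30% loss are excluded from analysis).
#' @param performance_means,performance_sds length-5 vectors for the five
#'   performance measures, in the order of `vrgaze:::PERFORMANCE_MEASURES`.
#' @param relevance_offset_ms mean fixation-duration surplus on task-relevant
#'   versus task-irrelevant objects (ms); applied with weights that leave the
#'   overall fixation-duration mean unchanged.
#' @param main_sequence_slope_ms_deg slope of the affine amplitude-duration
#'   main sequence (ms per degree); the intercept is recalibrated per
#'   participant to hit the group saccade-duration target.
#' @param filter the [filter_params()] windows the means must lie inside.
#' @return object of class `vrgaze_group_params`.
#' @export
group_params <- function(fixation_mean_ms, fixation_between_sd_ms,
                         fixation_within_sd_ms = 80,
                         saccade_amp_mean_deg, saccade_amp_between_sd_deg,
                         saccade_amp_within_sd_deg = 2,
                         saccade_dur_mean_ms, saccade_dur_between_sd_ms,
                         saccade_dur_within_sd_ms = 8,
                         invalid_rate = 0,
                         performance_means = c(65, 69, 1.0, 21, 86),
                         performance_sds = c(13, 10, 0.25, 5, 18),
                         relevance_offset_ms = 40,
                         main_sequence_slope_ms_deg = 2.2,
                         filter = filter_params()) {
  assert_scalar_num(fixation_mean_ms, "fixation_mean_ms",
                    filter$fixation_dur_ms[1], filter$fixation_dur_ms[2])
  if (fixation_mean_ms <= filter$fixation_dur_ms[1] ||
      fixation_mean_ms >= filter$fixation_dur_ms[2]) {
    stop_vrgaze("fixation_mean_ms must lie strictly inside the fixation filter window",
                class = "vrgaze_validation_error")
  }
  assert_scalar_num(saccade_dur_mean_ms, "saccade_dur_mean_ms",
                    filter$saccade_dur_ms[1], filter$saccade_dur_ms[2])
  if (saccade_dur_mean_ms <= filter$saccade_dur_ms[1] ||
      saccade_dur_mean_ms >= filter$saccade_dur_ms[2]) {
    stop_vrgaze("saccade_dur_mean_ms must lie strictly inside the saccade duration window",
                class = "vrgaze_validation_error")
  }
  if (saccade_amp_mean_deg <= filter$saccade_min_amp_deg) {
    stop_vrgaze("saccade_amp_mean_deg must exceed the minimum amplitude %g deg",
                filter$saccade_min_amp_deg, class = "vrgaze_validation_error")
  }
  assert_scalar_num(invalid_rate, "invalid_rate", 0, 0.3 - 1e-12)
  for (nm in c("fixation_between_sd_ms", "fixation_within_sd_ms",
               "saccade_amp_between_sd_deg", "saccade_amp_within_sd_deg",
               "saccade_dur_between_sd_ms", "saccade_dur_within_sd_ms")) {
    assert_scalar_num(get(nm), nm, 0)
  }
  stopifnot(length(performance_means) == 5L, length(performance_sds) == 5L,
            all(performance_sds >= 0))
  structure(list(
    fixation_mean_ms = fixation_mean_ms,
    fixation_between_sd_ms = fixation_between_sd_ms,
    fixation_within_sd_ms = fixation_within_sd_ms,
    saccade_amp_mean_deg = saccade_amp_mean_deg,
    saccade_amp_between_sd_deg = saccade_amp_between_sd_deg,
    saccade_amp_within_sd_deg = saccade_amp_within_sd_deg,
    saccade_dur_mean_ms = saccade_dur_mean_ms,
    saccade_dur_between_sd_ms = saccade_dur_between_sd_ms,
    saccade_dur_within_sd_ms = saccade_dur_within_sd_ms,
    invalid_rate = invalid_rate,
    performance_means = stats::setNames(as.numeric(performance_means),
                                        PERFORMANCE_MEASURES),
    performance_sds = stats::setNames(as.numeric(performance_sds),
                                      PERFORMANCE_MEASURES),
    relevance_offset_ms = relevance_offset_ms,
    main_sequence_slope_ms_deg = main_sequence_slope_ms_deg,
    filter = filter
  ), class = "vrgaze_group_params")
}

#' Default group parameters for the two study groups
#'
#' Group means and between-participant SDs of the three eye-movement
#' features follow the published group summaries (ADHD: fixation 317 (36) ms,
#' saccade duration 57 (8.3) ms, amplitude 5.44 (1.4) deg; control: 309 (30)
#' ms, 67 (10.1) ms, 6.29 (1.7) deg). Within-participant SDs, data-loss
#' rates and performance separations are free generator defaults; the five
#' performance measures are separated by roughly 0.3 between-participant SD
#' in the directions reported for the clinical group (lower total score,
#' task efficacy and navigation efficacy; higher controller motion and total
#' actions).
#'
#' @param group `"adhd"` or `"control"`.
#' @return a [group_params()] object.
#' @export
default_group_params <- function(group = c("adhd", "control")) {
  group <- match.arg(tolower(group), c("adhd", "control"))
  if (group == "adhd") {
    group_params(
      fixation_mean_ms = 317, fixation_between_sd_ms = 36,
      saccade_amp_mean_deg = 5.44, saccade_amp_between_sd_deg = 1.4,
      saccade_dur_mean_ms = 57, saccade_dur_between_sd_ms = 8.3,
      invalid_rate = 0.05,
      performance_means = c(61, 66, 0.92, 22.5, 92),
      performance_sds = c(13, 10, 0.25, 5, 18))
  } else {
    group_params(
      fixation_mean_ms = 309, fixation_between_sd_ms = 30,
      saccade_amp_mean_deg = 6.29, saccade_amp_between_sd_deg = 1.7,
      saccade_dur_mean_ms = 67, saccade_dur_between_sd_ms = 10.1,
      invalid_rate = 0.03,
      performance_means = c(65, 69, 1.0, 21, 86),
      performance_sds = c(13, 10, 0.25, 5, 18))
  }
}

#' Cohort-level study design
#'
#' @param n_per_group named integer vector of group sizes; names must be
#'   exactly `ADHD` and `control`.
#' @param n_scenarios number of task scenarios per participant.
#' @param scenario_duration_s duration of each execution phase (seconds).
#' @param instruction_duration_s duration of each instruction phase (seconds).
#' @param sampling_rate_hz nominal tracker sampling rate.
#' @param seed master seed for the cohort.
#' @param group_params named list of [group_params()] per group label; the
#'   published defaults are used when omitted.
#' @return object of class `vrgaze_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ADHD = 37, control = 36),
                        n_scenarios = 13,
                        scenario_duration_s = 90,
                        instruction_duration_s = 15,
                        sampling_rate_hz = 90,
                        seed = 1L,
                        group_params = list(ADHD = default_group_params("adhd"),
                                            control = default_group_params("control"))) {
  if (!setequal(names(n_per_group), c("ADHD", "control")) ||
      !setequal(names(group_params), c("ADHD", "control"))) {
    stop_vrgaze("group labels must be exactly {ADHD, control}",
                class = "vrgaze_validation_error")
  }
  stopifnot(all(n_per_group >= 1), n_scenarios >= 1, sampling_rate_hz > 0,
            scenario_duration_s > 0, instruction_duration_s >= 0)
  structure(list(n_per_group = n_per_group[c("ADHD", "control")],
                 n_scenarios = as.integer(n_scenarios),
                 scenario_duration_s = scenario_duration_s,
                 instruction_duration_s = instruction_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed),
                 group_params = group_params[c("ADHD", "control")]),
            class = "vrgaze_cohort_spec")
}

# --- scene and saliency ----------------------------------------------------

#' Build a saliency map with Gaussian hotspots
#'
#' @param grid integer vector `c(n_el, n_az)` of grid cells (rows are
#'   elevation, columns azimuth; cell-centered registration).
#' @param hotspots data.frame with columns `az_deg`, `el_deg`, `sd_deg` and
#'   optionally `weight`; `NULL` gives a constant map.
#' @param az_range_deg,el_range_deg closed angular intervals of the domain.
#' @param noise_sd amplitude of optional nonnegative background texture.
#' @param seed seed for the background texture.
#' @return object of class `vrgaze_saliency_map` with fields `values`,
#'   `az_range_deg`, `el_range_deg`, `az_centers`, `el_centers`.
#' @export
make_saliency_map <- function(grid = c(50, 120), hotspots = NULL,
                              az_range_deg = c(-60, 60),
                              el_range_deg = c(-25, 25),
                              noise_sd = 0, seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 2))
  n_el <- grid[1]; n_az <- grid[2]
  az_step <- diff(az_range_deg) / n_az
  el_step <- diff(el_range_deg) / n_el
  az_c <- az_range_deg[1] + az_step * (seq_len(n_az) - 0.5)
  el_c <- el_range_deg[1] + el_step * (seq_len(n_el) - 0.5)
  values <- matrix(1, n_el, n_az)
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    if (any(hotspots$az_deg < az_range_deg[1] | hotspots$az_deg > az_range_deg[2] |
            hotspots$el_deg < el_range_deg[1] | hotspots$el_deg > el_range_deg[2])) {
      stop_vrgaze("hotspot outside the map's angular domain",
                  class = "vrgaze_validation_error")
    }
    w <- hotspots$weight %||% rep(1, nrow(hotspots))
    for (i in seq_len(nrow(hotspots))) {
      d2 <- outer((el_c - hotspots$el_deg[i])^2, (az_c - hotspots$az_deg[i])^2, `+`)
      values <- values + w[i] * exp(-d2 / (2 * hotspots$sd_deg[i]^2))
    }
  }
  if (noise_sd > 0) {
    values <- values + with_seed(seed, matrix(abs(rnorm(n_el * n_az, 0, noise_sd)),
                                              n_el, n_az))
  }
  structure(list(values = values, az_range_deg = az_range_deg,
                 el_range_deg = el_range_deg,
                 az_centers = az_c, el_centers = el_c),
            class = "vrgaze_saliency_map")
}

#' Scene annotation: areas of interest and a saliency map
#'
#' @param objects data.frame with columns `id`, `az_min`, `az_max`, `el_min`,
#'   `el_max`, `relevance` (one of `relevant`, `irrelevant`, `non-object`).
#' @param saliency_map a [make_saliency_map()] object.
#' @return object of class `vrgaze_scene_spec`.
#' @export
scene_spec <- function(objects, saliency_map) {
  need <- c("id", "az_min", "az_max", "el_min", "el_max", "relevance")
  if (!all(need %in% names(objects))) {
    stop_vrgaze("objects must have columns: %s", paste(need, collapse = ", "),
                class = "vrgaze_validation_error")
  }
  if (!all(objects$relevance %in% c("relevant", "irrelevant", "non-object"))) {
    stop_vrgaze("relevance labels must be relevant/irrelevant/non-object",
                class = "vrgaze_validation_error")
  }
  if (any(objects$az_min < saliency_map$az_range_deg[1] - 1e-9) ||
      any(objects$az_max > saliency_map$az_range_deg[2] + 1e-9) ||
      any(objects$el_min < saliency_map$el_range_deg[1] - 1e-9) ||
      any(objects$el_max > saliency_map$el_range_deg[2] + 1e-9)) {
    stop_vrgaze("AOI regions must lie within the saliency map's angular domain",
                class = "vrgaze_validation_error")
  }
  structure(list(objects = objects, saliency_map = saliency_map),
            class = "vrgaze_scene_spec")
}

#' Default synthetic scene
#'
#' A fixed layout over azimuth -60..60, elevation -25..25 degrees: a floor
#' band and two wall strips (non-objects, emulating surfaces that do not
#' count as objects), a handful of task-relevant object boxes and a larger
#' number of task-irrelevant ones, plus a saliency map with hotspots on a
#' subset of the objects.
#'
#' @return a [scene_spec()] object.
#' @export
default_scene <- function() {
  rel_az <- c(-40, -12, 8, 24, 38, -28)
  rel_el <- c(5, 12, -2, 8, 2, -6)
  irr_az <- c(-52, -44, -34, -20, -4, 2, 14, 20, 30, 44, 50, -8, 36, -24)
  irr_el <- c(-10, 14, 18, -12, 16, -14, 14, 2, 16, -8, 10, 4, -12, 16)
  half <- 3.2
  obj <- rbind(
    data.frame(id = sprintf("rel_%02d", seq_along(rel_az)),
               az_min = rel_az - half, az_max = rel_az + half,
               el_min = rel_el - half, el_max = rel_el + half,
               relevance = "relevant"),
    data.frame(id = sprintf("irr_%02d", seq_along(irr_az)),
               az_min = irr_az - half, az_max = irr_az + half,
               el_min = irr_el - half, el_max = irr_el + half,
               relevance = "irrelevant"),
    data.frame(id = c("floor", "wall_left", "wall_right", "waypoint"),
               az_min = c(-60, -60, 56, -2), az_max = c(60, -56, 60, 2),
               el_min = c(-25, -18, -18, -20), el_max = c(-18, 25, 25, -16),
               relevance = "non-object"))
  hs <- data.frame(az_deg = c(rel_az[1:3], irr_az[c(2, 5, 9)]),
                   el_deg = c(rel_el[1:3], irr_el[c(2, 5, 9)]),
                   sd_deg = 4, weight = c(2, 1.5, 1, 2, 1.5, 1))
  scene_spec(obj, make_saliency_map(hotspots = hs))
}

# --- participant-level simulation ------------------------------------------

# Standardized between-participant draws: marginally normal z-scores centered
# and rescaled to sample mean 0 / SD 1 so the realized cohort mean and
# between-participant SD equal the group parameters exactly.
standardized_draws <- function(n, mean, sd) {
  z <- rnorm(n)
  if (n > 1 && stats::sd(z) > 0) z <- (z - mean(z)) / stats::sd(z) else z <- rep(0, n)
  mean + sd * z
}

draw_participant_means <- function(gp, n, standardize = TRUE) {
  # trait means are winsorized at +/- 3 between-participant SDs (extreme
  # draws would demand near-degenerate truncation calibrations), then kept
  # inside the admissible filter windows with a margin
  draw <- function(n, m, s) {
    x <- if (standardize) standardized_draws(n, m, s) else rnorm(n, m, s)
    pmin(pmax(x, m - 3 * s), m + 3 * s)
  }
  f <- gp$filter
  list(
    fixation = pmin(pmax(draw(n, gp$fixation_mean_ms, gp$fixation_between_sd_ms),
                         f$fixation_dur_ms[1] + 10), f$fixation_dur_ms[2] - 10),
    amplitude = pmax(draw(n, gp$saccade_amp_mean_deg, gp$saccade_amp_between_sd_deg),
                     f$saccade_min_amp_deg + 0.4),
    sacc_dur = pmin(pmax(draw(n, gp$saccade_dur_mean_ms, gp$saccade_dur_between_sd_ms),
                         f$saccade_dur_ms[1] + 3), f$saccade_dur_ms[2] - 10),
    performance = {
      m <- sapply(seq_len(5L), function(j)
        draw(n, gp$performance_means[j], gp$performance_sds[j]))
      m <- matrix(m, nrow = n)
      m[, 1] <- pmin(pmax(m[, 1], 0), 100)   # total score %
      m[, 2] <- pmin(pmax(m[, 2], 0), 100)   # task efficacy %
      m[, 3:5] <- pmax(m[, 3:5], 0.01)
      colnames(m) <- PERFORMANCE_MEASURES
      m
    })
}

# Calibrate the main-sequence intercept so that the mean truncated saccade
# duration over the realized amplitudes equals the participant target.
calibrate_ms_intercept <- function(target, base, sd, lower, upper,
                                   max_iter = 200L) {
  cp <- target - mean(base)
  for (i in seq_len(max_iter)) {
    m <- mean(tnorm_mean(base + cp, sd, lower, upper))
    err <- target - m
    if (abs(err) <= 1e-8 * max(1, abs(target))) return(cp)
    cp <- cp + err
  }
  stop_vrgaze("main-sequence intercept calibration did not converge",
              class = "vrgaze_calibration_error")
}

# Random-walk fixation positions whose step lengths are the drawn saccade
# amplitudes; bearings are resampled when a step would leave the scene domain.
walk_positions <- function(n_fix, amps, az0, el0, az_lim, el_lim) {
  az <- numeric(n_fix); el <- numeric(n_fix)
  az[1] <- az0; el[1] <- el0
  bearings <- runif(n_fix * 3, 0, 360)  # pre-drawn pool
  bi <- 1L
  for (i in seq_len(n_fix - 1L)) {
    ok <- FALSE
    for (try in 1:40) {
      b <- if (bi <= length(bearings)) bearings[bi] else runif(1, 0, 360)
      bi <- bi + 1L
      dst <- gc_dest_num(az[i], el[i], b, amps[i])
      if (dst[[1]] >= az_lim[1] && dst[[1]] <= az_lim[2] &&
          dst[[2]] >= el_lim[1] && dst[[2]] <= el_lim[2]) {
        ok <- TRUE; break
      }
    }
    if (!ok) { # point the step straight back at the domain center
      b <- atan2(sin((0 - az[i]) * DEG), (0 - el[i]) * DEG) / DEG
      dst <- gc_dest_num(az[i], el[i], b, min(amps[i], 5))
      dst[[1]] <- pmin(pmax(dst[[1]], az_lim[1]), az_lim[2])
      dst[[2]] <- pmin(pmax(dst[[2]], el_lim[1]), el_lim[2])
    }
    az[i + 1] <- dst[[1]]; el[i + 1] <- dst[[2]]
  }
  list(az = az, el = el)
}

# Generate the alternating fixation/saccade ledger for one phase.
# Returns a data.frame of GroundTruthEvents with onset 0 at phase start.
gen_phase_events <- function(gp, means_p, duration_ms, phase, scene,
                             speaker = c(az = 0, el = 0)) {
  f <- gp$filter
  if (duration_ms <= 0) return(NULL)
  loc_fix <- calibrate_truncated_mean(means_p$fixation, gp$fixation_within_sd_ms,
                                      f$fixation_dur_ms[1], f$fixation_dur_ms[2])
  cycle <- means_p$fixation + means_p$sacc_dur
  n_fix <- ceiling(duration_ms / cycle * 1.3) + 8L

  if (phase == "instruction") {
    # gaze parked near the speaker: positions first, amplitudes follow
    az <- pmin(pmax(speaker["az"] + rnorm(n_fix, 0, 1.5), -58), 58)
    el <- pmin(pmax(speaker["el"] + rnorm(n_fix, 0, 1.2), -24), 24)
    fix_dur <- rtnorm(n_fix, loc_fix, gp$fixation_within_sd_ms,
                      f$fixation_dur_ms[1], f$fixation_dur_ms[2])
    v <- angles_to_dir(az, el)
    amps <- gc_dist_deg(v[-n_fix, , drop = FALSE], v[-1, , drop = FALSE])
    amps <- pmax(amps, 0.05)
    sacc_dur <- pmax(gp$main_sequence_slope_ms_deg * amps +
                       (means_p$sacc_dur - gp$main_sequence_slope_ms_deg * mean(amps)) +
                       rnorm(n_fix - 1L, 0, gp$saccade_dur_within_sd_ms), 12)
  } else {
    loc_amp <- calibrate_truncated_mean(means_p$amplitude, gp$saccade_amp_within_sd_deg,
                                        f$saccade_min_amp_deg, Inf)
    amps <- rtnorm(n_fix - 1L, loc_amp, gp$saccade_amp_within_sd_deg,
                   f$saccade_min_amp_deg, Inf)
    pos0 <- c(runif(1, -40, 40), runif(1, -12, 14))
    pos <- walk_positions(n_fix, amps, pos0[1], pos0[2],
                          az_lim = c(-56, 56), el_lim = c(-17, 20))
    az <- pos$az; el <- pos$el
    # recompute realized amplitudes (fallback steps may shorten a few)
    v <- angles_to_dir(az, el)
    amps <- pmax(gc_dist_deg(v[-n_fix, , drop = FALSE], v[-1, , drop = FALSE]), 1e-6)
    fix_dur <- rtnorm(n_fix, loc_fix, gp$fixation_within_sd_ms,
                      f$fixation_dur_ms[1], f$fixation_dur_ms[2])
    base <- gp$main_sequence_slope_ms_deg * amps
    cp <- calibrate_ms_intercept(means_p$sacc_dur, base, gp$saccade_dur_within_sd_ms,
                                 f$saccade_dur_ms[1], f$saccade_dur_ms[2])
    sacc_dur <- rtnorm(n_fix - 1L, base + cp, gp$saccade_dur_within_sd_ms,
                       f$saccade_dur_ms[1], f$saccade_dur_ms[2])
  }

  # relevance-dependent fixation durations, zero-mean over the realized mix
  if (phase == "execution" && gp$relevance_offset_ms != 0 && !is.null(scene)) {
    lk <- aoi_lookup(az, el, scene)
    is_rel <- !is.na(lk$relevance) & lk$relevance == "relevant"
    is_irr <- !is.na(lk$relevance) & lk$relevance == "irrelevant"
    n_r <- sum(is_rel); n_i <- sum(is_irr)
    if (n_r > 0 && n_i > 0) {
      o_r <- gp$relevance_offset_ms * n_i / (n_r + n_i)
      o_i <- -gp$relevance_offset_ms * n_r / (n_r + n_i)
      fix_dur[is_rel] <- fix_dur[is_rel] + o_r
      fix_dur[is_irr] <- fix_dur[is_irr] + o_i
      fix_dur <- pmin(pmax(fix_dur, f$fixation_dur_ms[1]), f$fixation_dur_ms[2])
    }
  }

  # interleave: fix1 sacc1 fix2 ... fix_n
  n_ev <- 2L * n_fix - 1L
  kind <- rep(c("fixation", "saccade"), length.out = n_ev)
  dur <- numeric(n_ev)
  dur[kind == "fixation"] <- fix_dur
  dur[kind == "saccade"] <- sacc_dur
  offset <- cumsum(dur)
  onset <- offset - dur
  keep <- offset <= duration_ms          # drop the partial event at the end
  if (!any(keep)) return(NULL)
  last <- max(which(keep))
  idx <- seq_len(last)
  kind <- kind[idx]; onset <- onset[idx]; offset <- offset[idx]; dur <- dur[idx]

  fi <- cumsum(kind == "fixation")       # fixation index active at each event
  az_start <- ifelse(kind == "fixation", az[fi], az[fi])
  el_start <- ifelse(kind == "fixation", el[fi], el[fi])
  az_end <- ifelse(kind == "fixation", az[fi], az[pmin(fi + 1L, n_fix)])
  el_end <- ifelse(kind == "fixation", el[fi], el[pmin(fi + 1L, n_fix)])
  amp <- ifelse(kind == "fixation", 0,
                gc_dist_deg(angles_to_dir(az_start, el_start),
                            angles_to_dir(az_end, el_end)))
  # cubic-sigmoid kinematics: peak acceleration 6 A / T^2
  pk <- ifelse(kind == "saccade", 6 * amp / (dur / 1000)^2, 0)

  ev <- data.frame(kind = kind, onset_ms = onset, offset_ms = offset,
                   duration_ms = dur, az_start = az_start, el_start = el_start,
                   az_end = az_end, el_end = el_end, amplitude_deg = amp,
                   peak_accel_deg_s2 = pk, phase = phase,
                   stringsAsFactors = FALSE)
  if (!is.null(scene)) {
    lk <- aoi_lookup(ifelse(kind == "fixation", az_start, NA_real_),
                     ifelse(kind == "fixation", el_start, NA_real_), scene)
    ev$object_id <- lk$id
    ev$relevance <- lk$relevance
  } else {
    ev$object_id <- NA_character_
    ev$relevance <- NA_character_
  }
  ev
}

#' Simulate one participant's VR session
#'
#' Draws participant-level trait means from the group's between-participant
#' distributions (unless supplied), then generates the ground-truth event
#' ledger for every scenario (instruction + execution phases), the five
#' performance measures, and optionally the rendered noisy gaze stream.
#'
#' @param gp a [group_params()] object.
#' @param spec a [cohort_spec()].
#' @param scene a [scene_spec()] (or `NULL` to skip object labels).
#' @param participant_seed integer seed; identical seeds give byte-identical
#'   output.
#' @param means optional list with elements `fixation`, `amplitude`,
#'   `sacc_dur` (participant trait means) to override the random draw.
#' @param performance optional length-5 numeric to override the random draw.
#' @param render logical; also render gaze samples via [render_gaze_trace()].
#' @param noise_sd_deg tracker noise SD used when rendering.
#' @param head_profile head-motion profile for rendering, see
#'   [head_profile_sinusoidal()].
#' @param participant,group label strings attached to the outputs.
#' @return list with `events` (ground-truth ledger), `performance` (named
#'   numeric), `scenario_order`, and `samples` (if `render = TRUE`).
#' @export
simulate_participant <- function(gp, spec, scene = default_scene(),
                                 participant_seed = 1L,
                                 means = NULL, performance = NULL,
                                 render = FALSE, noise_sd_deg = 0.1,
                                 head_profile = head_profile_sinusoidal(),
                                 participant = "P01", group = "control") {
  with_seed(participant_seed, {
    if (is.null(means)) {
      d <- draw_participant_means(gp, 1L, standardize = FALSE)
      means <- list(fixation = d$fixation, amplitude = d$amplitude,
                    sacc_dur = d$sacc_dur)
      if (is.null(performance)) performance <- d$performance[1, ]
    }
    if (is.null(performance)) {
      performance <- draw_participant_means(gp, 1L, standardize = FALSE)$performance[1, ]
    }
    scenario_order <- sample.int(spec$n_scenarios)
    instr_ms <- spec$instruction_duration_s * 1000
    exec_ms <- spec$scenario_duration_s * 1000
    ev_list <- vector("list", spec$n_scenarios)
    smp_list <- if (render) vector("list", spec$n_scenarios) else NULL
    for (s in seq_len(spec$n_scenarios)) {
      ei <- gen_phase_events(gp, means, instr_ms, "instruction", scene)
      ee <- gen_phase_events(gp, means, exec_ms, "execution", scene)
      if (!is.null(ee)) {
        ee$onset_ms <- ee$onset_ms + instr_ms
        ee$offset_ms <- ee$offset_ms + instr_ms
      }
      ev <- rbind(ei, ee)
      ev$scenario <- s
      ev$scenario_order <- scenario_order[s]
      ev$participant <- participant
      ev$group <- group
      ev_list[[s]] <- ev
      if (render) {
        smp <- render_gaze_trace(ev, rate_hz = spec$sampling_rate_hz,
                                 noise_sd_deg = noise_sd_deg,
                                 head_profile = head_profile,
                                 seed = derive_seed(participant_seed,
                                                    paste0("render_", s)),
                                 total_duration_ms = instr_ms + exec_ms)
        smp <- inject_data_loss(smp, gp$invalid_rate, mean_burst_len = 3L,
                                seed = derive_seed(participant_seed,
                                                   paste0("loss_", s)))
        smp$scenario <- s
        smp$participant <- participant
        smp$group <- group
        smp_list[[s]] <- smp
      }
    }
    out <- list(events = do.call(rbind, ev_list),
                performance = performance,
                scenario_order = scenario_order)
    if (render) out$samples <- do.call(rbind, smp_list)
    out
  })
}

#' Sinusoidal head-motion profile
#'
#' Slow sinusoidal yaw during the execution phase (head free to scan), static
#' head during the instruction phase.
#'
#' @param amplitude_deg yaw amplitude (degrees).
#' @param freq_hz yaw frequency (Hz).
#' @return function(t_ms, phase) -> yaw angle in degrees.
#' @export
head_profile_sinusoidal <- function(amplitude_deg = 20, freq_hz = 0.1) {
  force(amplitude_deg); force(freq_hz)
  function(t_ms, phase) {
    yaw <- amplitude_deg * sin(2 * pi * freq_hz * t_ms / 1000)
    yaw[phase != "execution"] <- 0
    yaw
  }
}

#' Static head profile
#' @return function(t_ms, phase) -> 0 yaw.
#' @export
head_profile_static <- function() function(t_ms, phase) rep(0, length(t_ms))

#' Render a ground-truth event ledger to a gaze sample stream
#'
#' Fixations are rendered as a stationary world direction plus isotropic
#' angular noise; saccades as a smooth monotone (cubic sigmoid) great-circle
#' sweep over the stated duration. The rendered world direction is then
#' re-expressed in the (possibly moving) head frame, so downstream head
#' compensation is genuinely exercised.
#'
#' @param events ground-truth ledger for one scenario (alternating,
#'   non-overlapping events).
#' @param rate_hz sampling rate; the stream has
#'   `floor(total_duration * rate)` samples.
#' @param noise_sd_deg isotropic angular tracker noise SD (degrees).
#' @param head_profile function(t_ms, phase) -> head yaw in degrees.
#' @param seed RNG seed for the noise.
#' @param total_duration_ms stream duration; defaults to the ledger's span.
#' @return data.frame of gaze samples (`t_ms`, head-frame gaze vector,
#'   head quaternion, `valid`, `phase`).
#' @export
render_gaze_trace <- function(events, rate_hz, noise_sd_deg = 0.1,
                              head_profile = head_profile_static(),
                              seed = 1L, total_duration_ms = NULL) {
  stopifnot(rate_hz > 0, nrow(events) >= 1)
  ev <- events[order(events$onset_ms), , drop = FALSE]
  if (any(diff(ev$onset_ms) < 0) ||
      any(ev$onset_ms[-1] < ev$offset_ms[-nrow(ev)] - 1e-9)) {
    stop_vrgaze("events overlap", class = "vrgaze_validation_error")
  }
  total <- total_duration_ms %||% (max(ev$offset_ms) - min(ev$onset_ms))
  n <- floor(total * rate_hz / 1000)
  dt <- 1000 / rate_hz
  t <- min(ev$onset_ms) + (seq_len(n) - 1L) * dt

  idx <- findInterval(t, ev$onset_ms)
  idx[idx < 1L] <- 1L
  kind <- ev$kind[idx]
  in_event <- t < ev$offset_ms[idx]
  # samples in inter-event gaps (phase boundary remainders) hold position
  phase <- ev$phase[idx]

  v_start <- angles_to_dir(ev$az_start, ev$el_start)
  v_end <- angles_to_dir(ev$az_end, ev$el_end)
  world <- v_end[idx, , drop = FALSE]            # default: hold event end
  fix_rows <- which(kind == "fixation" & in_event)
  world[fix_rows, ] <- v_start[idx[fix_rows], , drop = FALSE]
  sac_rows <- which(kind == "saccade" & in_event)
  if (length(sac_rows)) {
    u <- (t[sac_rows] - ev$onset_ms[idx[sac_rows]]) / ev$duration_ms[idx[sac_rows]]
    f <- u * u * (3 - 2 * u)                     # cubic sigmoid (smoothstep)
    a <- v_start[idx[sac_rows], , drop = FALSE]
    b <- v_end[idx[sac_rows], , drop = FALSE]
    dot <- pmin(1, pmax(-1, rowSums(a * b)))
    om <- acos(dot)
    sa <- ifelse(om < 1e-9, 1 - f, sin((1 - f) * om) / sin(om))
    sb <- ifelse(om < 1e-9, f, sin(f * om) / sin(om))
    world[sac_rows, ] <- a * sa + b * sb
  }

  ang <- dir_to_angles(world)
  if (noise_sd_deg > 0) {
    noise <- with_seed(seed, matrix(rnorm(2L * n, 0, noise_sd_deg), ncol = 2))
    ang$az_deg <- ang$az_deg + noise[, 1] / pmax(cos(ang$el_deg * DEG), 0.2)
    ang$el_deg <- ang$el_deg + noise[, 2]
  }
  world_noisy <- angles_to_dir(ang$az_deg, ang$el_deg)

  yaw <- head_profile(t, phase)
  q <- quat_axis_angle(c(0, 1, 0), yaw)
  gaze_head <- quat_rotate(quat_conj(q), world_noisy)

  data.frame(t_ms = t,
             gaze_x = gaze_head[, 1], gaze_y = gaze_head[, 2],
             gaze_z = gaze_head[, 3],
             head_qw = q[, 1], head_qx = q[, 2], head_qy = q[, 3],
             head_qz = q[, 4],
             valid = TRUE, phase = phase, stringsAsFactors = FALSE)
}

#' Clear validity flags in geometrically distributed bursts
#'
#' Alternates valid and invalid runs with geometric lengths so that the
#' expected invalid fraction equals `invalid_rate` (a renewal process with
#' mean invalid run `mean_burst_len` and mean valid run
#' `mean_burst_len * (1 - rate) / rate`).
#'
#' @param samples gaze sample data.frame with a `valid` column.
#' @param invalid_rate target invalid fraction in `[0, 1)`.
#' @param mean_burst_len mean invalid burst length in samples.
#' @param seed RNG seed.
#' @return `samples` with updated `valid` flags.
#' @export
inject_data_loss <- function(samples, invalid_rate, mean_burst_len = 3L,
                             seed = 1L) {
  assert_scalar_num(invalid_rate, "invalid_rate", 0, 1 - 1e-12)
  n <- nrow(samples)
  if (invalid_rate == 0 || n == 0L) return(samples)
  mean_gap <- mean_burst_len * (1 - invalid_rate) / invalid_rate
  invalid <- with_seed(seed, {
    flags <- logical(n)
    pos <- 1L + rgeom(1L, 1 / (1 + mean_gap))  # random phase into first gap
    while (pos <= n) {
      burst <- 1L + rgeom(1L, 1 / mean_burst_len)
      flags[pos:min(n, pos + burst - 1L)] <- TRUE
      gap <- 1L + rgeom(1L, 1 / mean_gap)
      pos <- pos + burst + gap
    }
    flags
  })
  samples$valid <- samples$valid & !invalid
  samples
}

#' Simulate a full two-group cohort
#'
#' Participant trait means are drawn from the between-participant
#' distributions with the realized sample standardized per group, so the
#' cohort-level mean and between-participant SD of each trait equal the
#' group parameters exactly (see the methods vignette).
#'
#' @param spec a [cohort_spec()].
#' @param scene a [scene_spec()].
#' @param render logical; render noisy gaze sample streams.
#' @param noise_sd_deg tracker noise when rendering.
#' @param head_profile head-motion profile when rendering.
#' @param sample_handler optional `function(samples, participant, group)`
#'   applied to each participant's rendered stream; when supplied the raw
#'   samples are discarded after processing (keeps memory flat at cohort
#'   scale) and the results are returned in `handler_results`.
#' @param groups which group labels to generate (default: both). A group's
#'   output is identical whether or not the other group is generated (seeds
#'   are derived per group and participant).
#' @return list with `events` (all ground-truth events), `performance`
#'   (data.frame, one row per participant), `participants` (labels, group,
#'   seeds), plus `samples` or `handler_results` when rendering.
#' @export
simulate_cohort <- function(spec, scene = default_scene(), render = FALSE,
                            noise_sd_deg = 0.1,
                            head_profile = head_profile_sinusoidal(),
                            sample_handler = NULL,
                            groups = names(spec$n_per_group)) {
  stopifnot(inherits(spec, "vrgaze_cohort_spec"),
            all(groups %in% names(spec$n_per_group)))
  ev_all <- list(); perf_all <- list(); part_all <- list()
  smp_all <- list(); hres <- list()
  for (g in groups) {
    n <- spec$n_per_group[[g]]
    gp <- spec$group_params[[g]]
    draws <- with_seed(derive_seed(spec$seed, paste0("means_", g)),
                       draw_participant_means(gp, n, standardize = TRUE))
    for (i in seq_len(n)) {
      pid <- sprintf("%s_%02d", g, i)
      pseed <- derive_seed(spec$seed, paste0("participant_", pid))
      res <- simulate_participant(
        gp, spec, scene, participant_seed = pseed,
        means = list(fixation = draws$fixation[i],
                     amplitude = draws$amplitude[i],
                     sacc_dur = draws$sacc_dur[i]),
        performance = draws$performance[i, ],
        render = render, noise_sd_deg = noise_sd_deg,
        head_profile = head_profile, participant = pid, group = g)
      ev_all[[pid]] <- res$events
      perf_all[[pid]] <- data.frame(participant = pid, group = g,
                                    t(res$performance))
      part_all[[pid]] <- data.frame(participant = pid, group = g, seed = pseed)
      if (render) {
        if (is.null(sample_handler)) {
          smp_all[[pid]] <- res$samples
        } else {
          hres[[pid]] <- sample_handler(res$samples, pid, g)
        }
      }
    }
  }
  out <- list(events = do.call(rbind, ev_all),
              performance = do.call(rbind, perf_all),
              participants = do.call(rbind, part_all),
              spec = spec)
  rownames(out$events) <- NULL
  rownames(out$performance) <- NULL
  rownames(out$participants) <- NULL
  if (render && is.null(sample_handler)) out$samples <- do.call(rbind, smp_all)
  if (render && !is.null(sample_handler)) out$handler_results <- hres
  out
}
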