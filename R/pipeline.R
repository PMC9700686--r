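# End-to-end orchestration: simulate -> screen -> detect -> filter ->
# features -> stats -> classify -> report, driven by one configuration and
# writing a provenance manifest.

cohort_spec_from_config <- function(cfg) {
  adhd <- default_group_params("adhd")
  ctrl <- default_group_params("control")
  adhd$invalid_rate <- cfg$invalid_rate_adhd
  ctrl$invalid_rate <- cfg$invalid_rate_control
  adhd$relevance_offset_ms <- cfg$relevance_offset_ms
  ctrl$relevance_offset_ms <- cfg$relevance_offset_ms
  fp <- filter_params(
    saccade_dur_ms = c(cfg$min_sacc_ms, cfg$max_sacc_ms),
    saccade_min_amp_deg = cfg$min_sacc_amp_deg,
    saccade_max_accel_deg_s2 = cfg$max_sacc_accel_deg_s2,
    fixation_dur_ms = c(cfg$min_fix_ms, cfg$max_fix_ms))
  adhd$filter <- fp
  ctrl$filter <- fp
  cohort_spec(n_per_group = c(ADHD = cfg$n_adhd, control = cfg$n_control),
              n_scenarios = cfg$n_scenarios,
              scenario_duration_s = cfg$scenario_duration_s,
              instruction_duration_s = cfg$instruction_duration_s,
              sampling_rate_hz = cfg$sampling_rate_hz,
              seed = derive_seed(cfg$seed, "simulate"),
              group_params = list(ADHD = adhd, control = ctrl))
}

detection_params_from_config <- function(cfg) {
  detection_params(lambda = cfg$lambda,
                   velocity_window = cfg$velocity_window,
                   min_saccade_samples = cfg$min_saccade_samples,
                   gap_interpolation_max_samples = cfg$gap_interpolation_max_samples,
                   min_intersaccadic_ms = cfg$min_intersaccadic_ms)
}

filter_params_from_config <- function(cfg) {
  filter_params(saccade_dur_ms = c(cfg$min_sacc_ms, cfg$max_sacc_ms),
                saccade_min_amp_deg = cfg$min_sacc_amp_deg,
                saccade_max_accel_deg_s2 = cfg$max_sacc_accel_deg_s2,
                fixation_dur_ms = c(cfg$min_fix_ms, cfg$max_fix_ms))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from the configuration, screens participants by
#' invalid-sample rate, detects and filters eye movement events from the
#' rendered gaze streams, aggregates per-scenario features, runs the group
#' statistics (rank-sum Z tests on the five performance measures, mixed-model
#' likelihood-ratio contrasts on the three eye features, FDR correction per
#' family), trains and evaluates the performance-measure and eye-feature
#' classifiers, and writes all artifacts plus a provenance manifest (written
#' even on failure) into `outdir`.
#'
#' @param config path to a YAML configuration, a configuration list, or
#'   `NULL` for the defaults.
#' @param outdir output directory (created if needed).
#' @param seed optional override of the configuration seed.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the manifest and the in-memory results.
#' @export
run_pipeline <- function(config = NULL, outdir = "vrgaze_run", seed = NULL,
                         quiet = FALSE) {
  cfg <- if (is.list(config)) {
    base <- default_config()
    unknown <- setdiff(names(config), names(base))
    if (length(unknown)) {
      stop_vrgaze("unknown config key(s): %s", paste(unknown, collapse = ", "),
                  class = "vrgaze_config_error")
    }
    validate_config(modifyList(base, config))
  } else {
    load_config(config)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  manifest <- list(package_version = as.character(utils::packageVersion("vrgaze")),
                   config = cfg, stages = list(), outputs = list(),
                   status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  on.exit(write_manifest(), add = TRUE)

  result <- tryCatch({
    scene <- default_scene()
    spec <- cohort_spec_from_config(cfg)
    dpar <- detection_params_from_config(cfg)
    fpar <- filter_params_from_config(cfg)

    say("simulating cohort (%d + %d participants, %d scenarios)",
        cfg$n_adhd, cfg$n_control, cfg$n_scenarios)
    cohort <- simulate_cohort(
      spec, scene, render = TRUE, noise_sd_deg = cfg$noise_sd_deg,
      head_profile = head_profile_sinusoidal(cfg$head_yaw_amplitude_deg,
                                             cfg$head_yaw_freq_hz))
    manifest$stages$simulate <- list(
      participants = nrow(cohort$participants),
      samples = nrow(cohort$samples),
      samples_invalid = sum(!cohort$samples$valid),
      ground_truth_events = nrow(cohort$events))

    write_gaze(cohort$samples, file.path(outdir, "gaze.tsv"))
    write_aoi(scene$objects, file.path(outdir, "aoi.tsv"))
    write_salmap(scene$saliency_map, file.path(outdir, "salmap.txt"))

    say("screening participants")
    scr <- screen_participants(cohort$samples, cfg$exclusion_threshold)
    manifest$stages$screen <- list(
      input_participants = nrow(scr$report),
      excluded = sum(scr$report$excluded),
      report = scr$report)

    say("detecting events")
    kept_ids <- unique(scr$kept$participant)
    det_list <- lapply(kept_ids, function(pid) {
      smp <- scr$kept[scr$kept$participant == pid, , drop = FALSE]
      tr <- to_world_angles(smp, dpar)
      ev <- detect_events(tr, dpar)
      if (nrow(ev)) {
        ev$participant <- pid
        ev$group <- smp$group[1]
      }
      ev
    })
    detected <- do.call(rbind, det_list)
    detected <- merge(detected,
                      unique(cohort$events[, c("participant", "scenario",
                                               "scenario_order")]),
                      by = c("participant", "scenario"), sort = FALSE)
    filtered <- filter_events(detected, fpar)
    filtered <- assign_objects(filtered, scene)
    manifest$stages$detect <- list(
      events_detected = nrow(detected),
      events_removed = as.list(attr(filtered, "removed")),
      events_kept = nrow(filtered))
    write_events(filtered, file.path(outdir, "events.tsv"))

    say("aggregating features")
    features <- feature_table(filtered, scr$kept, scene$saliency_map,
                              n_scenarios = cfg$n_scenarios)
    write_tsv_hash(features, file.path(outdir, "features.tsv"))
    bins <- bin_table(filtered, cfg$bin_s)
    write_tsv_hash(bins, file.path(outdir, "bins.tsv"))
    manifest$stages$features <- list(rows = nrow(features),
                                      bin_rows = nrow(bins))

    say("group statistics")
    stats_tab <- pipeline_stats(cohort$performance, features,
                                kept = kept_ids)
    write_tsv_hash(stats_tab, file.path(outdir, "stats.tsv"))
    manifest$stages$stats <- list(tests = nrow(stats_tab))

    say("classification")
    class_res <- pipeline_classify(cohort$performance, features, cfg,
                                   kept = kept_ids)
    jsonlite::write_json(class_res, file.path(outdir, "auc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    manifest$stages$classify <- list(
      mean_auc = lapply(class_res, function(x) x$mean_auc))

    outs <- c("gaze.tsv", "aoi.tsv", "salmap.txt", "events.tsv",
              "features.tsv", "bins.tsv", "stats.tsv", "auc_report.json")
    manifest$outputs <- as.list(tools::md5sum(file.path(outdir, outs)))
    manifest$status <- "ok"
    list(cohort = cohort, features = features, stats = stats_tab,
         classification = class_res, screen = scr$report)
  }, error = function(e) {
    manifest$status <<- "error"
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(e)
  })
  write_manifest()
  say("done: %s", outdir)
  invisible(list(manifest = manifest, result = result))
}

validate_config <- function(cfg) {
  checks <- config_checks()
  bad <- names(cfg)[!vapply(names(cfg), function(k) isTRUE(checks[[k]](cfg[[k]])),
                            logical(1))]
  if (length(bad)) {
    stop_vrgaze("config value(s) out of range: %s", paste(bad, collapse = ", "),
                class = "vrgaze_config_error")
  }
  if (is.na(cfg$min_sacc_ms)) {
    cfg$min_sacc_ms <- min_saccade_duration_ms(cfg$sampling_rate_hz)
  }
  cfg
}

# time-course bins for every participant-scenario execution phase
bin_table <- function(events, bin_s = 1) {
  keys <- unique(events[, c("participant", "scenario")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    ev <- events[events$participant == keys$participant[k] &
                   events$scenario == keys$scenario[k] &
                   events$phase == "execution", , drop = FALSE]
    if (!nrow(ev)) next
    b <- bin_time_course(ev, bin_s)
    b$participant <- keys$participant[k]
    b$scenario <- keys$scenario[k]
    rows[[length(rows) + 1L]] <- b
  }
  if (!length(rows)) {
    return(data.frame(bin_index = integer(), mean_fix_dur_ms = numeric(),
                      n_fixations = integer(), mean_sacc_amp_deg = numeric(),
                      prop_same_object_saccades = numeric(),
                      participant = character(), scenario = integer()))
  }
  do.call(rbind, rows)
}

pipeline_stats <- function(performance, features, kept = NULL) {
  if (!is.null(kept)) {
    performance <- performance[performance$participant %in% kept, , drop = FALSE]
  }
  rows <- list()
  # family 1: rank-sum tests on the five performance measures
  for (m in PERFORMANCE_MEASURES) {
    a <- performance[[m]][performance$group == "ADHD"]
    b <- performance[[m]][performance$group == "control"]
    r <- ranksum_z(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      family = "performance", test = m, statistic_name = "Z",
      statistic = r$statistic, df = NA_integer_, p_raw = r$p_raw,
      effect_phi = NA_real_, singular = NA)
  }
  # family 2: mixed-model group contrasts on the three eye features
  for (m in c("mean_fix_dur_ms", "mean_sacc_dur_ms", "mean_sacc_amp_deg")) {
    r <- suppressWarnings(lmm_group_contrast(features, m, term = "group"))
    rows[[length(rows) + 1L]] <- data.frame(
      family = "eye_features", test = m, statistic_name = "chi2",
      statistic = r$statistic, df = r$df, p_raw = r$p_raw,
      effect_phi = r$effect_phi, singular = r$singular)
  }
  tab <- do.call(rbind, rows)
  tab$p_fdr <- NA_real_
  for (fam in unique(tab$family)) {
    sel <- tab$family == fam
    tab$p_fdr[sel] <- bh_fdr(tab$p_raw[sel])
  }
  tab
}

pipeline_classify <- function(performance, features, cfg, kept = NULL) {
  if (!is.null(kept)) {
    performance <- performance[performance$participant %in% kept, , drop = FALSE]
    features <- features[features$participant %in% kept, , drop = FALSE]
  }
  n <- length(unique(performance$participant))
  outer <- min(cfg$outer_folds, floor(n / 2))
  mk_spec <- function(fs) classifier_spec(
    feature_set = fs, outer_folds = outer, inner_folds = cfg$inner_folds,
    seed = derive_seed(cfg$seed, paste0("svm_", fs)))
  perf <- performance_matrix(performance)
  eye <- eye_feature_matrix(features)
  stopifnot(identical(as.character(perf$participants),
                      as.character(eye$participants)))
  res <- list(
    performance5 = nested_cv(perf$X, perf$y, mk_spec("performance5")),
    epeli_eye39 = nested_cv(eye$X, eye$y, mk_spec("epeli_eye39")))
  res
}
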