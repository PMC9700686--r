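# Readers and writers for the on-disk artifacts, participant screening and
# run configuration. All tabular formats are plain UTF-8 tab-separated text
# with a '#'-prefixed header line; saliency maps are a plain-text matrix
# with a 4-line angular-domain header. Deliberately diff-able and
# language-agnostic.

GAZE_COLUMNS <- c("t_ms", "gaze_x", "gaze_y", "gaze_z",
                  "head_qw", "head_qx", "head_qy", "head_qz",
                  "valid", "participant", "group", "scenario", "phase")

write_tsv_hash <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(header, con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, append = TRUE,
                     quote = FALSE, logical01 = FALSE)
  invisible(path)
}

read_tsv_hash <- function(path, required) {
  if (!file.exists(path)) {
    stop_vrgaze("file not found: %s", path, class = "vrgaze_io_error")
  }
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    stop_vrgaze("%s line 1: expected '#'-prefixed header", path,
                class = "vrgaze_parse_error")
  }
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, cols)
  if (length(missing)) {
    stop_vrgaze("%s line 1: missing column(s): %s", path,
                paste(missing, collapse = ", "), class = "vrgaze_parse_error")
  }
  n_lines <- length(readLines(path))
  if (n_lines <= 1L) {
    df <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  df <- data.table::fread(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, data.table = FALSE,
                          na.strings = c("NA", ""))
  df
}

#' Write / read a gaze sample stream
#'
#' Tab-separated text with a fixed column set and a `#`-prefixed header.
#' `read_gaze()` validates the schema: timestamps strictly increasing within
#' each participant-scenario, unit gaze vectors and unit quaternions (within
#' 1e-6) on valid samples; violations raise typed parse errors naming the
#' offending line.
#'
#' @param samples gaze sample data.frame with the columns listed in
#'   `vrgaze:::GAZE_COLUMNS`.
#' @param path file path.
#' @return `write_gaze` returns the path invisibly; `read_gaze` returns the
#'   validated data.frame.
#' @export
write_gaze <- function(samples, path) {
  missing <- setdiff(GAZE_COLUMNS, names(samples))
  if (length(missing)) {
    stop_vrgaze("samples lack column(s): %s", paste(missing, collapse = ", "),
                class = "vrgaze_validation_error")
  }
  write_tsv_hash(samples[, GAZE_COLUMNS], path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  df <- read_tsv_hash(path, GAZE_COLUMNS)
  if (!nrow(df)) return(df)
  df$valid <- as.logical(df$valid)
  line_of <- function(i) i + 1L  # header occupies line 1

  key <- paste(df$participant, df$scenario)
  ord_bad <- which(c(FALSE, diff(df$t_ms) <= 0) & key == c("", head(key, -1)))
  if (length(ord_bad)) {
    stop_vrgaze("%s line %d: timestamps not strictly increasing within scenario",
                path, line_of(ord_bad[1]), class = "vrgaze_parse_error")
  }
  gn <- sqrt(df$gaze_x^2 + df$gaze_y^2 + df$gaze_z^2)
  bad <- which(df$valid & abs(gn - 1) > 1e-6)
  if (length(bad)) {
    stop_vrgaze("%s line %d: gaze vector norm %.8f outside 1 +/- 1e-6",
                path, line_of(bad[1]), gn[bad[1]], class = "vrgaze_parse_error")
  }
  qn <- sqrt(df$head_qw^2 + df$head_qx^2 + df$head_qy^2 + df$head_qz^2)
  bad <- which(df$valid & abs(qn - 1) > 1e-6)
  if (length(bad)) {
    stop_vrgaze("%s line %d: quaternion norm %.8f outside 1 +/- 1e-6",
                path, line_of(bad[1]), qn[bad[1]], class = "vrgaze_parse_error")
  }
  df
}

#' Write / read an event table
#'
#' @param events event data.frame (detected or ground truth).
#' @param path file path.
#' @return `write_events` returns the path invisibly; `read_events` the
#'   validated data.frame.
#' @export
write_events <- function(events, path) {
  write_tsv_hash(events, path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  core <- c("kind", "onset_ms", "offset_ms", "duration_ms", "az_start",
            "el_start", "az_end", "el_end", "amplitude_deg",
            "peak_accel_deg_s2")
  df <- read_tsv_hash(path, core)
  if (!nrow(df)) return(df)
  if ("complete" %in% names(df)) df$complete <- as.logical(df$complete)
  bad <- which(!df$kind %in% c("fixation", "saccade"))
  if (length(bad)) {
    stop_vrgaze("%s line %d: unknown event kind '%s'", path, bad[1] + 1L,
                df$kind[bad[1]], class = "vrgaze_parse_error")
  }
  bad <- which(df$offset_ms <= df$onset_ms)
  if (length(bad)) {
    stop_vrgaze("%s line %d: event offset not after onset", path, bad[1] + 1L,
                class = "vrgaze_parse_error")
  }
  df
}

#' Write / read AOI annotations
#'
#' @param objects AOI data.frame (`id`, `az_min`, `az_max`, `el_min`,
#'   `el_max`, `relevance`).
#' @param path file path.
#' @return path (write) / data.frame (read).
#' @export
write_aoi <- function(objects, path) {
  write_tsv_hash(objects, path)
}

#' @rdname write_aoi
#' @export
read_aoi <- function(path) {
  df <- read_tsv_hash(path, c("id", "az_min", "az_max", "el_min", "el_max",
                              "relevance"))
  bad <- which(!df$relevance %in% c("relevant", "irrelevant", "non-object"))
  if (length(bad)) {
    stop_vrgaze("%s line %d: bad relevance label '%s'", path, bad[1] + 1L,
                df$relevance[bad[1]], class = "vrgaze_parse_error")
  }
  df
}

#' Write / read a saliency map
#'
#' Plain-text matrix preceded by a 4-line angular-domain header
#' (azimuth range, elevation range, grid dimensions, registration).
#'
#' @param map a [make_saliency_map()] object.
#' @param path file path.
#' @return path (write) / saliency-map object (read).
#' @export
write_salmap <- function(map, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(c(
    sprintf("# az_range_deg %.9g %.9g", map$az_range_deg[1], map$az_range_deg[2]),
    sprintf("# el_range_deg %.9g %.9g", map$el_range_deg[1], map$el_range_deg[2]),
    sprintf("# dims %d %d", nrow(map$values), ncol(map$values)),
    "# registration cell-centered"), con)
  close(con)
  data.table::fwrite(as.data.frame(map$values), path, sep = " ",
                     col.names = FALSE, append = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_salmap
#' @export
read_salmap <- function(path) {
  hdr <- readLines(path, n = 4L)
  parse_range <- function(line, tag, lineno) {
    parts <- strsplit(trimws(sub(paste0("# *", tag), "", line)), " +")[[1]]
    if (!grepl(tag, line, fixed = TRUE) || length(parts) != 2L) {
      stop_vrgaze("%s line %d: expected '# %s <min> <max>'", path, lineno, tag,
                  class = "vrgaze_parse_error")
    }
    as.numeric(parts)
  }
  az <- parse_range(hdr[1], "az_range_deg", 1L)
  el <- parse_range(hdr[2], "el_range_deg", 2L)
  dims <- as.integer(strsplit(trimws(sub("# *dims", "", hdr[3])), " +")[[1]])
  vals <- as.matrix(data.table::fread(path, skip = 4L, header = FALSE,
                                      sep = " ", data.table = FALSE))
  dimnames(vals) <- NULL
  if (!all(dim(vals) == dims)) {
    stop_vrgaze("%s: matrix is %dx%d but header declares %dx%d", path,
                nrow(vals), ncol(vals), dims[1], dims[2],
                class = "vrgaze_parse_error")
  }
  if (any(!is.finite(vals))) {
    stop_vrgaze("%s: non-finite saliency values", path,
                class = "vrgaze_parse_error")
  }
  n_el <- dims[1]; n_az <- dims[2]
  az_step <- diff(az) / n_az; el_step <- diff(el) / n_el
  structure(list(values = vals, az_range_deg = az, el_range_deg = el,
                 az_centers = az[1] + az_step * (seq_len(n_az) - 0.5),
                 el_centers = el[1] + el_step * (seq_len(n_el) - 0.5)),
            class = "vrgaze_saliency_map")
}

#' Screen participants by invalid-sample rate
#'
#' Participants whose fraction of invalid gaze samples is at or above the
#' exclusion threshold (default 30%) are excluded from analysis, mirroring
#' the published screening (participants with 30% and 80% loss excluded;
#' 16% was the maximum retained). The operator is idempotent.
#'
#' @param samples gaze samples with `participant` and `valid` columns.
#' @param threshold exclusion threshold as a fraction (default 0.30).
#' @return list with `kept` (samples of retained participants) and `report`
#'   (per-participant invalid percentage and exclusion flag).
#' @export
screen_participants <- function(samples, threshold = 0.30) {
  inv <- tapply(!samples$valid, samples$participant, mean)
  report <- data.frame(participant = names(inv),
                       invalid_pct = 100 * as.numeric(inv),
                       excluded = as.numeric(inv) >= threshold,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep_ids <- report$participant[!report$excluded]
  list(kept = samples[samples$participant %in% keep_ids, , drop = FALSE],
       report = report)
}

# --- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' Every analysis constant in one place: cohort design, detection and filter
#' thresholds, feature and classification settings. `load_config()` starts
#' from these defaults and overlays a YAML file.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_adhd = 37L, n_control = 36L,
    n_scenarios = 13L,
    scenario_duration_s = 90,
    instruction_duration_s = 15,
    sampling_rate_hz = 90,
    noise_sd_deg = 0.1,
    head_yaw_amplitude_deg = 20,
    head_yaw_freq_hz = 0.1,
    invalid_rate_adhd = 0.05,
    invalid_rate_control = 0.03,
    relevance_offset_ms = 40,
    lambda = 6,
    velocity_window = 5L,
    min_saccade_samples = 2L,
    gap_interpolation_max_samples = 2L,
    min_intersaccadic_ms = 40,
    min_sacc_ms = NA,        # NA: derived from the sampling rate
    max_sacc_ms = 300,
    min_sacc_amp_deg = 0.75,
    max_sacc_accel_deg_s2 = 36000,
    min_fix_ms = 100,
    max_fix_ms = 1000,
    exclusion_threshold = 0.30,
    bin_s = 1,
    outer_folds = 10L,
    inner_folds = 5L,
    boot_iterations = 30L
  )
}

config_checks <- function() {
  pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  nonneg <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0
  frac <- function(x) nonneg(x) && x < 1
  int2 <- function(x) pos(x) && x >= 2
  list(
    seed = pos, n_adhd = pos, n_control = pos, n_scenarios = pos,
    scenario_duration_s = pos, instruction_duration_s = nonneg,
    sampling_rate_hz = pos, noise_sd_deg = nonneg,
    head_yaw_amplitude_deg = nonneg, head_yaw_freq_hz = nonneg,
    invalid_rate_adhd = frac, invalid_rate_control = frac,
    relevance_offset_ms = function(x) is.numeric(x) && is.finite(x),
    lambda = pos,
    velocity_window = function(x) pos(x) && x >= 3 && x %% 2 == 1,
    min_saccade_samples = pos, gap_interpolation_max_samples = nonneg,
    min_intersaccadic_ms = nonneg,
    min_sacc_ms = function(x) is.na(x) || pos(x),
    max_sacc_ms = pos, min_sacc_amp_deg = nonneg,
    max_sacc_accel_deg_s2 = pos, min_fix_ms = pos, max_fix_ms = pos,
    exclusion_threshold = frac, bin_s = pos,
    outer_folds = int2, inner_folds = int2, boot_iterations = int2
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()], and validates every
#' key. Unknown keys and out-of-range values raise a config error listing
#' the offenders. An empty (or missing-content) file yields the full default
#' set.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list, with the derived saccade-duration
#'   floor filled in.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop_vrgaze("unknown config key(s): %s", paste(unknown, collapse = ", "),
                  class = "vrgaze_config_error")
    }
    cfg <- modifyList(cfg, user)
  }
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
  if (cfg$min_fix_ms >= cfg$max_fix_ms || cfg$min_sacc_ms >= cfg$max_sacc_ms) {
    stop_vrgaze("config value(s) out of range: duration windows inverted",
                class = "vrgaze_config_error")
  }
  cfg
}
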