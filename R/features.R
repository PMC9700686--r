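# Per-scenario scanpath features: event aggregates, object-relevance
# statistics, normalized scanpath saliency, ambient/focal time-course bins
# and head-motion metrics.

#' Look up the area of interest containing gaze positions
#'
#' A position is assigned to the AOI whose angular bounding box contains it;
#' when boxes nest or overlap the smallest box (by solid angle) wins.
#'
#' @param az_deg,el_deg gaze positions (degrees), vectorized.
#' @param scene a [scene_spec()].
#' @return data.frame with `id` and `relevance` (`NA` where the position is
#'   outside every AOI).
#' @export
aoi_lookup <- function(az_deg, el_deg, scene) {
  obj <- scene$objects
  # solid-angle area of an az/el box (rad^2), for smallest-AOI tie-breaking
  area <- (obj$az_max - obj$az_min) * DEG *
    (sin(obj$el_max * DEG) - sin(obj$el_min * DEG))
  ord <- order(area)
  id <- rep(NA_character_, length(az_deg))
  rel <- rep(NA_character_, length(az_deg))
  unset <- !is.na(az_deg)
  for (k in ord) {
    if (!any(unset)) break
    hit <- unset & az_deg >= obj$az_min[k] & az_deg <= obj$az_max[k] &
      el_deg >= obj$el_min[k] & el_deg <= obj$el_max[k]
    id[hit] <- obj$id[k]
    rel[hit] <- obj$relevance[k]
    unset <- unset & !hit
  }
  data.frame(id = id, relevance = rel, stringsAsFactors = FALSE)
}

#' Assign detected fixations to scene objects
#'
#' Fixations are assigned by their centroid direction; teleport waypoints,
#' walls and floor are labelled `non-object` and excluded from the
#' relevance analyses.
#'
#' @param events event data.frame (fixations get labels; saccades pass
#'   through with `NA`).
#' @param scene a [scene_spec()].
#' @return `events` with `object_id` and `relevance` columns.
#' @export
assign_objects <- function(events, scene) {
  if (nrow(events) == 0L) {
    events$object_id <- character(0)
    events$relevance <- character(0)
    return(events)
  }
  fix <- events$kind == "fixation"
  lk <- aoi_lookup(ifelse(fix, events$az_start, NA_real_),
                   ifelse(fix, events$el_start, NA_real_), scene)
  events$object_id <- lk$id
  events$relevance <- lk$relevance
  events
}

#' Mean fixation duration on relevant versus irrelevant objects
#'
#' @param fixations fixation rows with `participant`, `duration_ms` and
#'   `relevance` labels (non-object and unassigned fixations are ignored).
#' @return data.frame per participant: mean duration and count for
#'   task-relevant and task-irrelevant objects (`NA` means when a class is
#'   empty).
#' @export
relevance_stats <- function(fixations) {
  fixations <- fixations[fixations$kind == "fixation", , drop = FALSE]
  parts <- unique(fixations$participant)
  out <- lapply(parts, function(p) {
    fp <- fixations[fixations$participant == p, , drop = FALSE]
    rel <- fp$duration_ms[!is.na(fp$relevance) & fp$relevance == "relevant"]
    irr <- fp$duration_ms[!is.na(fp$relevance) & fp$relevance == "irrelevant"]
    data.frame(participant = p,
               mean_relevant_ms = if (length(rel)) mean(rel) else NA_real_,
               mean_irrelevant_ms = if (length(irr)) mean(irr) else NA_real_,
               n_relevant = length(rel), n_irrelevant = length(irr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalized scanpath saliency
#'
#' The saliency map is z-normalized over all cells (mean 0, population SD 1)
#' and the z-value is sampled by bilinear interpolation at each fixation
#' centroid; NSS is the mean of those samples. Fixations outside the map
#' domain are skipped (count attached as `attr(, "skipped")`). NSS is 0 when
#' fixations cover the map uniformly and is invariant to affine rescaling of
#' the map.
#'
#' @param map a [make_saliency_map()] object (or anything with `values`,
#'   `az_centers`, `el_centers`, `az_range_deg`, `el_range_deg`).
#' @param fixations fixation rows with `az_start`, `el_start`; saccade rows
#'   are ignored. Alternatively a data.frame with `az_deg`/`el_deg` columns
#'   (e.g. raw samples, for the all-samples mode).
#' @return NSS value (scalar); `NA` when no usable fixation remains.
#' @export
nss <- function(map, fixations) {
  vals <- map$values
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))   # population SD
  if (!is.finite(sigma) || sigma <= 0) {
    stop_vrgaze("NSS undefined for a constant saliency map",
                class = "vrgaze_nss_error")
  }
  z <- (vals - mu) / sigma
  if (all(c("az_deg", "el_deg") %in% names(fixations))) {
    az <- fixations$az_deg; el <- fixations$el_deg
  } else {
    fx <- fixations[fixations$kind == "fixation", , drop = FALSE]
    az <- fx$az_start; el <- fx$el_start
  }
  ok <- is.finite(az) & is.finite(el) &
    az >= map$az_range_deg[1] & az <= map$az_range_deg[2] &
    el >= map$el_range_deg[1] & el <= map$el_range_deg[2]
  skipped <- sum(!ok)
  az <- az[ok]; el <- el[ok]
  if (!length(az)) {
    out <- NA_real_
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- mean(bilinear_at(z, map$az_centers, map$el_centers, az, el))
  attr(out, "skipped") <- skipped
  out
}

# bilinear interpolation on a cell-centered grid; queries beyond the outer
# cell centers (but inside the domain) clamp to the edge cells
bilinear_at <- function(z, az_c, el_c, az, el) {
  nr <- length(el_c); nc <- length(az_c)
  ci <- findInterval(az, az_c, all.inside = TRUE)
  ri <- findInterval(el, el_c, all.inside = TRUE)
  fx <- (az - az_c[ci]) / (az_c[ci + 1L] - az_c[ci])
  fy <- (el - el_c[ri]) / (el_c[ri + 1L] - el_c[ri])
  fx <- pmin(1, pmax(0, fx))
  fy <- pmin(1, pmax(0, fy))
  z00 <- z[cbind(ri, ci)];      z01 <- z[cbind(ri, ci + 1L)]
  z10 <- z[cbind(ri + 1L, ci)]; z11 <- z[cbind(ri + 1L, ci + 1L)]
  (1 - fy) * ((1 - fx) * z00 + fx * z01) + fy * ((1 - fx) * z10 + fx * z11)
}

#' Aggregate one participant-scenario into scenario-level features
#'
#' Arithmetic means of the filtered execution-phase events (fixation
#' duration, saccade duration, saccade amplitude), event counts, NSS against
#' the scenario's saliency map, and the invalid-sample percentage. Means
#' over empty sets are `NA`, never zero.
#'
#' @param events filtered events of one participant and scenario.
#' @param samples that participant-scenario's raw gaze samples (for the
#'   invalid percentage); `NULL` gives `NA`.
#' @param map optional saliency map for NSS.
#' @param phase which phase to aggregate (default `execution`, the published
#'   analysis grain).
#' @return one-row data.frame of scenario features.
#' @export
aggregate_scenario <- function(events, samples = NULL, map = NULL,
                               phase = "execution") {
  ev <- events
  if (!is.null(phase) && "phase" %in% names(ev)) {
    ev <- ev[ev$phase == phase, , drop = FALSE]
  }
  fix <- ev[ev$kind == "fixation", , drop = FALSE]
  sac <- ev[ev$kind == "saccade", , drop = FALSE]
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(
    participant = if (nrow(ev)) ev$participant[1] else NA_character_,
    group = if (nrow(ev) && "group" %in% names(ev)) ev$group[1] else NA_character_,
    scenario = if (nrow(ev) && "scenario" %in% names(ev)) ev$scenario[1] else NA_integer_,
    scenario_order = if (nrow(ev) && "scenario_order" %in% names(ev))
      ev$scenario_order[1] else NA_integer_,
    mean_fix_dur_ms = mean_or_na(fix$duration_ms),
    mean_sacc_dur_ms = mean_or_na(sac$duration_ms),
    mean_sacc_amp_deg = mean_or_na(sac$amplitude_deg),
    nss = if (!is.null(map) && nrow(fix)) as.numeric(nss(map, fix)) else NA_real_,
    invalid_pct = if (!is.null(samples) && nrow(samples))
      100 * mean(!samples$valid) else NA_real_,
    n_fix = nrow(fix), n_sacc = nrow(sac),
    stringsAsFactors = FALSE)
}

#' Build the full participant-by-scenario feature table
#'
#' One row per participant and scenario (exactly), aggregating filtered
#' execution-phase events.
#'
#' @param events filtered event table with `participant` and `scenario`.
#' @param samples optional raw samples (invalid percentages).
#' @param map optional saliency map for NSS.
#' @param n_scenarios total scenarios per participant; rows with no events
#'   are emitted with missing means.
#' @return data.frame of scenario features.
#' @export
feature_table <- function(events, samples = NULL, map = NULL,
                          n_scenarios = max(events$scenario)) {
  parts <- unique(events$participant)
  rows <- list()
  for (p in parts) {
    evp <- events[events$participant == p, , drop = FALSE]
    smp <- if (!is.null(samples))
      samples[samples$participant == p, , drop = FALSE] else NULL
    for (s in seq_len(n_scenarios)) {
      evs <- evp[evp$scenario == s, , drop = FALSE]
      sms <- if (!is.null(smp)) smp[smp$scenario == s, , drop = FALSE] else NULL
      row <- aggregate_scenario(evs, sms, map)
      row$participant <- p
      row$scenario <- s
      if (!nrow(evs)) {
        row$group <- evp$group[1]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ambient/focal time-course features in 1-s bins
#'
#' The execution phase is divided into fixed-width bins from the moment the
#' instruction phase ended (time zero). Events are assigned by onset; the
#' partial final bin is kept. Per bin: mean fixation duration, number of
#' fixations, mean saccade amplitude and the proportion of saccades landing
#' within the same object (saccades whose two flanking fixations carry the
#' same object label; fixations on non-objects or outside every AOI are
#' excluded from both numerator and denominator).
#'
#' @param events one execution phase of one participant-scenario, sorted or
#'   not, with `object_id` and `relevance` labels on fixations.
#' @param bin_s bin width in seconds.
#' @param t0_ms execution start (default: onset of the earliest event).
#' @return data.frame, one row per bin.
#' @export
bin_time_course <- function(events, bin_s = 1, t0_ms = NULL) {
  ev <- events[order(events$onset_ms), , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(bin_index = integer(), mean_fix_dur_ms = numeric(),
                      n_fixations = integer(), mean_sacc_amp_deg = numeric(),
                      prop_same_object_saccades = numeric()))
  }
  t0 <- t0_ms %||% min(ev$onset_ms)
  ev$bin <- floor((ev$onset_ms - t0) / (bin_s * 1000)) + 1L

  # same-object flag per saccade from flanking fixations
  is_sac <- ev$kind == "saccade"
  same <- rep(NA, nrow(ev))          # NA: not in denominator
  obj <- ev$object_id
  usable_fix <- ev$kind == "fixation" & !is.na(ev$relevance) &
    ev$relevance %in% c("relevant", "irrelevant")
  sac_idx <- which(is_sac)
  for (k in sac_idx) {
    if (k == 1L || k == nrow(ev)) next
    if (usable_fix[k - 1L] && usable_fix[k + 1L]) {
      same[k] <- identical(obj[k - 1L], obj[k + 1L])
    }
  }
  ev$same_object <- same

  bins <- sort(unique(ev$bin))
  out <- lapply(bins, function(b) {
    eb <- ev[ev$bin == b, , drop = FALSE]
    fx <- eb[eb$kind == "fixation", , drop = FALSE]
    sc <- eb[eb$kind == "saccade", , drop = FALSE]
    denom <- sum(!is.na(sc$same_object))
    data.frame(bin_index = b,
               mean_fix_dur_ms = if (nrow(fx)) mean(fx$duration_ms) else NA_real_,
               n_fixations = nrow(fx),
               mean_sacc_amp_deg = if (nrow(sc)) mean(sc$amplitude_deg) else NA_real_,
               prop_same_object_saccades = if (denom)
                 sum(sc$same_object, na.rm = TRUE) / denom else NA_real_)
  })
  do.call(rbind, out)
}

#' Head rotation angle and speed
#'
#' Sum of successive quaternion geodesic angles (total head rotation, in
#' degrees) and the mean per-step angular speed (deg/s).
#'
#' @param q quaternion matrix (columns w, x, y, z), one row per sample.
#' @param t_ms sample timestamps (ms).
#' @return named numeric: `rotation_angle_sum_deg`, `mean_rotation_speed_deg_s`.
#' @export
head_motion_metrics <- function(q, t_ms) {
  q <- as_quat_matrix(q)
  if (nrow(q) < 2L) {
    stop_vrgaze("head-motion metrics need at least 2 samples",
                class = "vrgaze_validation_error")
  }
  ang <- quat_angle_deg(q[-nrow(q), , drop = FALSE], q[-1, , drop = FALSE])
  dt_s <- diff(t_ms) / 1000
  c(rotation_angle_sum_deg = sum(ang),
    mean_rotation_speed_deg_s = mean(ang / dt_s))
}
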