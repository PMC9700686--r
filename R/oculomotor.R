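# Head compensation, adaptive velocity-threshold event detection
# (Engbert-Kliegl) and physiological event filters.

#' Detection parameters
#'
#' @param lambda threshold multiplier on the median-based velocity SD
#'   (standard Engbert-Kliegl value 6).
#' @param velocity_window odd moving-window length (samples) of the velocity
#'   estimator.
#' @param min_saccade_samples minimum consecutive suprathreshold samples.
#' @param gap_interpolation_max_samples invalid gaps up to this length are
#'   interpolated on the sphere; longer gaps split the trace into segments.
#' @param min_intersaccadic_ms saccade candidates closer than this are merged.
#' @return object of class `vrgaze_detection_params`.
#' @export
detection_params <- function(lambda = 6, velocity_window = 5L,
                             min_saccade_samples = 2L,
                             gap_interpolation_max_samples = 2L,
                             min_intersaccadic_ms = 40) {
  stopifnot(lambda > 0, velocity_window >= 3L, velocity_window %% 2L == 1L,
            min_saccade_samples >= 1L, gap_interpolation_max_samples >= 0L,
            min_intersaccadic_ms >= 0)
  structure(list(lambda = lambda, velocity_window = as.integer(velocity_window),
                 min_saccade_samples = as.integer(min_saccade_samples),
                 gap_interpolation_max_samples = as.integer(gap_interpolation_max_samples),
                 min_intersaccadic_ms = min_intersaccadic_ms),
            class = "vrgaze_detection_params")
}

#' Physiological event filter windows
#'
#' Defaults follow the published cleaning procedure: saccades are accepted
#' with duration 22-300 ms (lower bound = 2 sample intervals at 90 Hz),
#' amplitude >= 0.75 degrees and peak acceleration <= 36000 deg/s^2;
#' fixations with duration 100-1000 ms.
#'
#' @param saccade_dur_ms closed duration interval for saccades (ms).
#' @param saccade_min_amp_deg minimum saccade amplitude (degrees).
#' @param saccade_max_accel_deg_s2 maximum saccade acceleration (deg/s^2).
#' @param fixation_dur_ms closed duration interval for fixations (ms).
#' @return object of class `vrgaze_filter_params`.
#' @export
filter_params <- function(saccade_dur_ms = c(22, 300),
                          saccade_min_amp_deg = 0.75,
                          saccade_max_accel_deg_s2 = 36000,
                          fixation_dur_ms = c(100, 1000)) {
  stopifnot(saccade_dur_ms[1] < saccade_dur_ms[2],
            fixation_dur_ms[1] < fixation_dur_ms[2],
            saccade_min_amp_deg >= 0, saccade_max_accel_deg_s2 > 0)
  structure(list(saccade_dur_ms = saccade_dur_ms,
                 saccade_min_amp_deg = saccade_min_amp_deg,
                 saccade_max_accel_deg_s2 = saccade_max_accel_deg_s2,
                 fixation_dur_ms = fixation_dur_ms),
            class = "vrgaze_filter_params")
}

#' Minimum saccade duration implied by the sampling rate
#'
#' Two sample intervals, floored to whole milliseconds: `floor(2 * 1000 /
#' rate)`. At 90 Hz this gives the published 22 ms bound.
#'
#' @param rate_hz sampling rate (> 0).
#' @return minimum saccade duration in ms.
#' @export
min_saccade_duration_ms <- function(rate_hz) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop_vrgaze("`rate_hz` must be a positive number",
                class = "vrgaze_validation_error")
  }
  floor(2 * 1000 / rate_hz)
}

#' Map head-frame gaze samples to a world-frame angular trace
#'
#' World gaze direction = head quaternion applied to the head-frame gaze
#' vector; angles are azimuth/elevation of that direction. Invalid samples
#' propagate; invalid gaps of at most `gap_interpolation_max_samples` with
#' valid neighbours are interpolated along the great circle, longer gaps
#' split the trace into segments. Segments are maximal runs of usable
#' samples within one scenario.
#'
#' @param samples gaze sample data.frame (see [read_gaze()] for the schema).
#' @param params a [detection_params()] (only the gap policy is used here).
#' @return data.frame with `t_ms`, `az_deg`, `el_deg`, `valid` (usable after
#'   interpolation), `interpolated`, `segment_id`, plus any of `scenario`,
#'   `phase`, `participant`, `group` present in the input.
#' @export
to_world_angles <- function(samples, params = detection_params()) {
  n <- nrow(samples)
  gaze <- as.matrix(samples[, c("gaze_x", "gaze_y", "gaze_z")])
  q <- as.matrix(samples[, c("head_qw", "head_qx", "head_qy", "head_qz")])
  gn <- sqrt(rowSums(gaze^2)); qn <- sqrt(rowSums(q^2))
  valid <- samples$valid
  if (any(gn[valid] < 1e-9) || any(qn[valid] < 1e-9)) {
    stop_vrgaze("zero-norm gaze vector or quaternion among valid samples",
                class = "vrgaze_validation_error")
  }
  world <- matrix(NA_real_, n, 3)
  if (any(valid)) {
    world[valid, ] <- quat_rotate(q[valid, , drop = FALSE],
                                  gaze[valid, , drop = FALSE] / gn[valid])
  }

  scen <- if ("scenario" %in% names(samples)) samples$scenario else rep(1L, n)
  usable <- valid
  interpolated <- logical(n)
  gmax <- params$gap_interpolation_max_samples

  # interpolate short invalid gaps within each scenario
  if (gmax > 0 && any(!valid)) {
    r <- rle(paste0(scen, "_", valid))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (valid[starts[k]]) next
      i0 <- starts[k]; i1 <- ends[k]
      if ((i1 - i0 + 1L) > gmax) next
      if (i0 == 1L || i1 == n) next
      if (scen[i0 - 1L] != scen[i0] || scen[i1 + 1L] != scen[i1]) next
      if (!valid[i0 - 1L] || !valid[i1 + 1L]) next
      u <- world[i0 - 1L, ]; v <- world[i1 + 1L, ]
      f <- (samples$t_ms[i0:i1] - samples$t_ms[i0 - 1L]) /
        (samples$t_ms[i1 + 1L] - samples$t_ms[i0 - 1L])
      world[i0:i1, ] <- slerp_dir(u, v, f)
      usable[i0:i1] <- TRUE
      interpolated[i0:i1] <- TRUE
    }
  }

  ang <- data.frame(az_deg = rep(NA_real_, n), el_deg = rep(NA_real_, n))
  if (any(usable)) ang[usable, ] <- dir_to_angles(world[usable, , drop = FALSE])

  # maximal runs of usable samples within a scenario
  run_key <- paste0(scen, "_", usable)
  r <- rle(run_key)
  seg <- rep.int(seq_along(r$lengths), r$lengths)
  seg[!usable] <- NA_integer_
  seg <- match(seg, sort(unique(seg[!is.na(seg)])))

  out <- data.frame(t_ms = samples$t_ms, az_deg = ang$az_deg,
                    el_deg = ang$el_deg, valid = usable,
                    interpolated = interpolated, segment_id = seg)
  for (col in c("scenario", "phase", "participant", "group")) {
    if (col %in% names(samples)) out[[col]] <- samples[[col]]
  }
  out
}

# moving-window velocity for one coordinate; m = (window-1)/2.
# v_n = sum_{k=1..m} (x_{n+k} - x_{n-k}) / (2 * sum(k) * dt); edge samples
# use the largest stencil that fits (shortened symmetric stencils).
stencil_velocity <- function(x, t, m) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n < 2L) return(v)
  dt <- stats::median(diff(t)) / 1000  # seconds
  S <- numeric(n)
  for (mm in seq_len(m)) {
    lead <- c(x[(1L + mm):n], rep(NA_real_, mm))
    lag <- c(rep(NA_real_, mm), x[1L:(n - mm)])
    S_new <- S + (lead - lag)
    denom <- 2 * sum(seq_len(mm)) * dt
    inner <- !is.na(S_new)
    v[inner] <- S_new[inner] / denom
    S <- ifelse(is.na(S_new), S, S_new)
  }
  # widening loop: interior samples end up with the full stencil, samples
  # nearer an edge keep the widest symmetric stencil that fit; the two
  # outermost samples have none and stay NA
  v
}

#' Engbert-Kliegl moving-window velocity estimate
#'
#' For the default 5-sample window,
#' `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)` per component,
#' computed within segments only; samples nearer the segment edge than the
#' half-window get the widest symmetric stencil that fits. Azimuth velocity
#' is scaled by `cos(elevation)` so both components are true angular rates.
#'
#' @param trace angular trace from [to_world_angles()].
#' @param window odd window length in samples.
#' @return `trace` with columns `v_az`, `v_el` (deg/s; `NA` outside
#'   segments or in segments shorter than `window`, which are skipped).
#' @export
ek_velocity <- function(trace, window = 5L) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  m <- (window - 1L) %/% 2L
  n <- nrow(trace)
  v_az <- rep(NA_real_, n); v_el <- rep(NA_real_, n)
  skipped <- 0L
  for (s in unique(trace$segment_id[!is.na(trace$segment_id)])) {
    idx <- which(!is.na(trace$segment_id) & trace$segment_id == s)
    if (length(idx) < window) { skipped <- skipped + 1L; next }
    az <- unwrap_deg(trace$az_deg[idx])
    el <- trace$el_deg[idx]
    t <- trace$t_ms[idx]
    v_az[idx] <- stencil_velocity(az, t, m) * cos(el * DEG)
    v_el[idx] <- stencil_velocity(el, t, m)
  }
  trace$v_az <- v_az
  trace$v_el <- v_el
  attr(trace, "segments_skipped") <- skipped
  trace
}

unwrap_deg <- function(az) {
  d <- diff(az)
  jump <- cumsum(c(0, ifelse(d > 180, -360, ifelse(d < -180, 360, 0))))
  az + jump
}

#' Adaptive per-component velocity thresholds
#'
#' Median-based SD estimator: `sigma_c = sqrt(median(v_c^2) - median(v_c)^2)`
#' per component; threshold `eta_c = lambda * sigma_c`. Computed over all
#' valid velocity samples handed in (one scenario, in the standard pipeline).
#'
#' @param v_az,v_el component velocities in deg/s (`NA`s ignored).
#' @param lambda threshold multiplier.
#' @return named numeric `c(az = eta_az, el = eta_el)`.
#' @export
adaptive_threshold <- function(v_az, v_el, lambda = 6) {
  stopifnot(lambda > 0)
  eta <- vapply(list(az = v_az, el = v_el), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 10L) {
      stop_vrgaze("need at least 10 valid velocity samples per scenario",
                  class = "vrgaze_validation_error")
    }
    s2 <- stats::median(v^2) - stats::median(v)^2
    if (!is.finite(s2) || s2 <= 0) {
      stop_vrgaze(paste("degenerate velocity distribution (sigma = 0);",
                        "add a noise floor to the trace"),
                  class = "vrgaze_threshold_error")
    }
    lambda * sqrt(s2)
  }, numeric(1))
  eta
}

# 10% / 90% points of the cubic sigmoid s(u) = 3u^2 - 2u^3
SIGMOID_U10 <- uniroot(function(u) 3 * u^2 - 2 * u^3 - 0.1, c(0, 0.5),
                       tol = 1e-12)$root
SIGMOID_RISE_FRACTION <- 1 - 2 * SIGMOID_U10

# refine saccade boundaries from the displacement profile: time from 10% to
# 90% of the traversed amplitude, rescaled by the sigmoid shape factor.
refine_saccade <- function(t, dirs, i, j, seg_lo, seg_hi, dt) {
  pre <- max(seg_lo, i - 3L):(i - 1L)
  post <- (j + 1L):min(seg_hi, j + 3L)
  pre <- pre[pre >= seg_lo & pre < i]
  post <- post[post <= seg_hi & post > j]
  mean_dir <- function(rows, fallback) {
    if (!length(rows)) return(dirs[fallback, ])
    m <- colMeans(dirs[rows, , drop = FALSE])
    m / sqrt(sum(m^2))
  }
  d0 <- mean_dir(pre, i)
  d1 <- mean_dir(post, j)
  amp <- gc_dist_deg(matrix(d0, ncol = 3), matrix(d1, ncol = 3))
  fallback <- list(onset = t[i] - dt / 2, offset = t[j] + dt / 2, amp = amp,
                   az_el = rbind(dir_to_angles(matrix(d0, ncol = 3)),
                                 dir_to_angles(matrix(d1, ncol = 3))))
  if (amp < 0.2) return(fallback)
  w0 <- max(seg_lo, i - 2L); w1 <- min(seg_hi, j + 2L)
  rows <- w0:w1
  f <- gc_dist_deg(matrix(d0, ncol = 3, nrow = length(rows), byrow = TRUE),
                   dirs[rows, , drop = FALSE]) / amp
  cross_time <- function(level) {
    k <- which(f >= level)
    if (!length(k) || k[1] == 1L) return(NA_real_)
    k <- k[1]
    t0 <- t[rows[k - 1L]]; t1 <- t[rows[k]]
    f0 <- f[k - 1L]; f1 <- f[k]
    if (f1 <= f0) return(t0)
    t0 + (level - f0) / (f1 - f0) * (t1 - t0)
  }
  t10 <- cross_time(0.1); t90 <- cross_time(0.9)
  if (!is.finite(t10) || !is.finite(t90) || t90 <= t10) return(fallback)
  T_est <- (t90 - t10) / SIGMOID_RISE_FRACTION
  run_span <- t[j] - t[i] + dt
  if (T_est < dt / 2 || T_est > run_span + 4 * dt) return(fallback)
  onset <- t10 - SIGMOID_U10 * T_est
  list(onset = onset, offset = onset + T_est, amp = amp,
       az_el = rbind(dir_to_angles(matrix(d0, ncol = 3)),
                     dir_to_angles(matrix(d1, ncol = 3))))
}

#' Detect saccades and fixations with the adaptive velocity threshold
#'
#' Per scenario: the Engbert-Kliegl velocity estimate and median-based
#' thresholds are computed, a sample is a saccade candidate when
#' `(v_az/eta_az)^2 + (v_el/eta_el)^2 > 1` for at least
#' `min_saccade_samples` consecutive samples, and candidates separated by
#' less than `min_intersaccadic_ms` are merged. Saccade on/offsets are then
#' refined from the displacement profile (10-90% rise time of the traversed
#' arc, rescaled by the cubic-sigmoid shape factor), which removes the
#' boundary smear of the moving-window velocity estimator at low sampling
#' rates. Fixations are the complementary intervals inside each segment;
#' fixations and saccades touching a segment edge are flagged
#' `complete = FALSE` (their durations are censored).
#'
#' @param trace angular trace from [to_world_angles()].
#' @param params a [detection_params()].
#' @return data.frame of gaze events (one row per event) with kind,
#'   boundaries, duration, endpoint angles, amplitude (saccades: great-circle
#'   angle; fixations: dispersion radius), peak acceleration, `complete`,
#'   plus scenario/phase/participant/group labels carried over. Empty trace
#'   gives an empty data.frame.
#' @export
detect_events <- function(trace, params = detection_params()) {
  empty <- data.frame(kind = character(), onset_ms = numeric(),
                      offset_ms = numeric(), duration_ms = numeric(),
                      az_start = numeric(), el_start = numeric(),
                      az_end = numeric(), el_end = numeric(),
                      amplitude_deg = numeric(), peak_accel_deg_s2 = numeric(),
                      complete = logical(), stringsAsFactors = FALSE)
  if (is.null(trace) || nrow(trace) == 0L) return(empty)
  trace <- ek_velocity(trace, params$velocity_window)
  scen <- if ("scenario" %in% names(trace)) trace$scenario else rep(1L, nrow(trace))
  out <- list()
  for (sc in unique(scen)) {
    rows <- which(scen == sc)
    v_az <- trace$v_az[rows]; v_el <- trace$v_el[rows]
    if (sum(is.finite(v_az)) < 10L) next
    eta <- adaptive_threshold(v_az, v_el, params$lambda)
    crit <- (v_az / eta["az"])^2 + (v_el / eta["el"])^2 > 1
    crit[is.na(crit)] <- FALSE
    for (sg in unique(trace$segment_id[rows])) {
      if (is.na(sg)) next
      seg_rows <- rows[which(!is.na(trace$segment_id[rows]) &
                               trace$segment_id[rows] == sg)]
      ev <- segment_events(trace, seg_rows, crit[match(seg_rows, rows)], params)
      if (!is.null(ev) && nrow(ev)) out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

segment_events <- function(trace, seg_rows, crit, params) {
  n <- length(seg_rows)
  if (n < 3L) return(NULL)
  t <- trace$t_ms[seg_rows]
  dt <- stats::median(diff(t))
  dirs <- angles_to_dir(trace$az_deg[seg_rows], trace$el_deg[seg_rows])
  speed <- sqrt(trace$v_az[seg_rows]^2 + trace$v_el[seg_rows]^2)

  r <- rle(crit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(i = starts[r$values], j = ends[r$values])
  runs <- runs[runs$j - runs$i + 1L >= params$min_saccade_samples, , drop = FALSE]
  # merge runs separated by less than the minimum intersaccadic interval
  if (nrow(runs) > 1L) {
    keep_i <- runs$i[1]; keep_j <- runs$j[1]
    mi <- c(); mj <- c()
    for (k in 2:nrow(runs)) {
      if (t[runs$i[k]] - t[keep_j] < params$min_intersaccadic_ms) {
        keep_j <- runs$j[k]
      } else {
        mi <- c(mi, keep_i); mj <- c(mj, keep_j)
        keep_i <- runs$i[k]; keep_j <- runs$j[k]
      }
    }
    runs <- data.frame(i = c(mi, keep_i), j = c(mj, keep_j))
  }

  # vector accumulators; one data.frame is built at the end
  acc <- new.env(parent = emptyenv())
  acc$kind <- character(); acc$on <- numeric(); acc$off <- numeric()
  acc$az0 <- numeric(); acc$el0 <- numeric(); acc$az1 <- numeric()
  acc$el1 <- numeric(); acc$amp <- numeric(); acc$pk <- numeric()
  acc$complete <- logical(); acc$row <- integer()
  push <- function(kind, on, off, az0, el0, az1, el1, amp, pk, complete, row) {
    acc$kind <- c(acc$kind, kind); acc$on <- c(acc$on, on)
    acc$off <- c(acc$off, off); acc$az0 <- c(acc$az0, az0)
    acc$el0 <- c(acc$el0, el0); acc$az1 <- c(acc$az1, az1)
    acc$el1 <- c(acc$el1, el1); acc$amp <- c(acc$amp, amp)
    acc$pk <- c(acc$pk, pk); acc$complete <- c(acc$complete, complete)
    acc$row <- c(acc$row, row)
  }
  add_fixation <- function(t_on, t_off, row_lo, row_hi, complete) {
    if (t_off <= t_on || row_hi < row_lo) return(invisible())
    rows_in <- row_lo:row_hi
    m <- colMeans(dirs[rows_in, , drop = FALSE])
    m <- m / sqrt(sum(m^2))
    disp <- max(gc_dist_deg(matrix(m, ncol = 3, nrow = length(rows_in),
                                   byrow = TRUE), dirs[rows_in, , drop = FALSE]))
    aa <- dir_to_angles(matrix(m, ncol = 3))
    push("fixation", t_on, t_off, aa$az_deg, aa$el_deg, aa$az_deg, aa$el_deg,
         disp, 0, complete, row_lo)
  }

  if (nrow(runs) == 0L) {
    add_fixation(t[1], t[n], 1L, n, complete = FALSE)
  } else {
    prev_off <- t[1]; prev_row <- 1L; first <- TRUE
    for (k in seq_len(nrow(runs))) {
      i <- runs$i[k]; j <- runs$j[k]
      rf <- refine_saccade(t, dirs, i, j, 1L, n, dt)
      onset <- max(rf$onset, t[1]); offset <- min(rf$offset, t[n])
      add_fixation(prev_off, onset, prev_row, max(prev_row, i - 1L),
                   complete = !first)
      ext <- max(1L, i - 1L):min(n, j + 1L)
      sp <- speed[ext]
      sp <- sp[is.finite(sp)]
      pk <- if (length(sp) >= 2L) max(abs(diff(sp))) / (dt / 1000) else 0
      push("saccade", onset, offset, rf$az_el$az_deg[1], rf$az_el$el_deg[1],
           rf$az_el$az_deg[2], rf$az_el$el_deg[2], rf$amp, pk,
           i > 1L && j < n, i)
      prev_off <- offset; prev_row <- min(n, j + 1L); first <- FALSE
    }
    add_fixation(prev_off, t[n], prev_row, n, complete = FALSE)
  }
  if (!length(acc$kind)) return(NULL)
  out <- data.frame(kind = acc$kind, onset_ms = acc$on, offset_ms = acc$off,
                    duration_ms = acc$off - acc$on, az_start = acc$az0,
                    el_start = acc$el0, az_end = acc$az1, el_end = acc$el1,
                    amplitude_deg = acc$amp, peak_accel_deg_s2 = acc$pk,
                    complete = acc$complete, stringsAsFactors = FALSE)
  for (col in c("scenario", "phase", "participant", "group")) {
    if (col %in% names(trace)) out[[col]] <- trace[[col]][seg_rows[acc$row]]
  }
  out
}

#' Apply the physiological event filters
#'
#' An event survives iff every applicable bound holds: saccade duration
#' within the accepted window, amplitude at or above the minimum, peak
#' acceleration at or below the maximum; fixation duration within the
#' accepted window. Incomplete (boundary-censored) events are dropped by
#' default. Removal counts per rule are attached as `attr(, "removed")`.
#'
#' @param events event data.frame from [detect_events()] or a ground-truth
#'   ledger.
#' @param filter a [filter_params()].
#' @param drop_incomplete drop events flagged `complete = FALSE`.
#' @return the surviving events.
#' @export
filter_events <- function(events, filter = filter_params(),
                          drop_incomplete = TRUE) {
  if (nrow(events) == 0L) {
    attr(events, "removed") <- c(incomplete = 0L, saccade_duration = 0L,
                                 saccade_amplitude = 0L, saccade_acceleration = 0L,
                                 fixation_duration = 0L)
    return(events)
  }
  keep <- rep(TRUE, nrow(events))
  removed <- c(incomplete = 0L, saccade_duration = 0L, saccade_amplitude = 0L,
               saccade_acceleration = 0L, fixation_duration = 0L)
  if (drop_incomplete && "complete" %in% names(events)) {
    bad <- !events$complete
    removed["incomplete"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  sac <- events$kind == "saccade"
  fix <- events$kind == "fixation"
  bad <- sac & (events$duration_ms < filter$saccade_dur_ms[1] |
                  events$duration_ms > filter$saccade_dur_ms[2])
  removed["saccade_duration"] <- sum(bad & keep)
  keep <- keep & !bad
  bad <- sac & events$amplitude_deg < filter$saccade_min_amp_deg
  removed["saccade_amplitude"] <- sum(bad & keep)
  keep <- keep & !bad
  bad <- sac & events$peak_accel_deg_s2 > filter$saccade_max_accel_deg_s2
  removed["saccade_acceleration"] <- sum(bad & keep)
  keep <- keep & !bad
  bad <- fix & (events$duration_ms < filter$fixation_dur_ms[1] |
                  events$duration_ms > filter$fixation_dur_ms[2])
  removed["fixation_duration"] <- sum(bad & keep)
  keep <- keep & !bad
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
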