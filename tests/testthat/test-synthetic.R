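test_that("identical seeds give byte-identical participants", {
  gp <- default_group_params("control")
  spec <- small_spec(seed = 5)
  a <- simulate_participant(gp, spec, default_scene(), participant_seed = 21,
                            render = TRUE, noise_sd_deg = 0.1)
  b <- simulate_participant(gp, spec, default_scene(), participant_seed = 21,
                            render = TRUE, noise_sd_deg = 0.1)
  expect_identical(a, b)
})

test_that("ground-truth ledger alternates and amplitudes equal endpoint arcs", {
  gp <- default_group_params("adhd")
  p <- simulate_participant(gp, small_spec(seed = 2), default_scene(),
                            participant_seed = 3)
  for (s in unique(p$events$scenario)) {
    for (ph in c("instruction", "execution")) {
      ev <- p$events[p$events$scenario == s & p$events$phase == ph, ]
      expect_true(all(ev$offset_ms > ev$onset_ms))
      expect_true(all(diff(ev$onset_ms) > 0))
      expect_true(all(ev$onset_ms[-1] >= ev$offset_ms[-nrow(ev)] - 1e-9))
      expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))  # alternating
    }
  }
  sac <- p$events[p$events$kind == "saccade", ]
  arc <- gc_dist_deg(angles_to_dir(sac$az_start, sac$el_start),
                     angles_to_dir(sac$az_end, sac$el_end))
  expect_lt(max(abs(arc - sac$amplitude_deg)), 1e-6)
})

test_that("rendering honors sample count, noise level and the identity round trip", {
  fix <- data.frame(kind = "fixation", onset_ms = 0, offset_ms = 500,
                    duration_ms = 500, az_start = 10, el_start = -5,
                    az_end = 10, el_end = -5, amplitude_deg = 0,
                    peak_accel_deg_s2 = 0, phase = "execution",
                    stringsAsFactors = FALSE)
  smp <- render_gaze_trace(fix, rate_hz = 90, noise_sd_deg = 0.1, seed = 7)
  expect_identical(nrow(smp), 45L)   # floor(0.5 s * 90 Hz)
  smp$scenario <- 1L
  tr <- to_world_angles(smp)
  d <- gc_dist_deg(angles_to_dir(tr$az_deg, tr$el_deg), angles_to_dir(10, -5))
  expect_true(all(d < 4 * 0.1 * sqrt(2)))   # 4 sigma of 2-d isotropic noise

  # noiseless, static head: exact round trip
  smp0 <- render_gaze_trace(fix, rate_hz = 90, noise_sd_deg = 0, seed = 7)
  smp0$scenario <- 1L
  tr0 <- to_world_angles(smp0)
  expect_lt(max(abs(tr0$az_deg - 10)), 1e-9)
  expect_lt(max(abs(tr0$el_deg + 5)), 1e-9)

  # overlapping events are rejected
  bad <- rbind(fix, transform(fix, onset_ms = 400, offset_ms = 900))
  expect_error(render_gaze_trace(bad, 90, 0, seed = 1), "overlap")
})

test_that("a rendered saccade has peak speed above its mean speed", {
  ev <- ledger_fix_sacc(n_fix = 2, fix_ms = 400, sacc_ms = 44, amp_deg = 5)
  smp <- render_gaze_trace(ev, rate_hz = 900, noise_sd_deg = 0, seed = 1)
  v <- angles_to_dir(rep(0, nrow(smp)), rep(0, nrow(smp)))
  dirs <- angles_to_dir(dir_to_angles(as.matrix(
    smp[, c("gaze_x", "gaze_y", "gaze_z")]))$az_deg,
    dir_to_angles(as.matrix(smp[, c("gaze_x", "gaze_y", "gaze_z")]))$el_deg)
  step <- gc_dist_deg(dirs[-nrow(dirs), ], dirs[-1, ])
  speed <- step / diff(smp$t_ms) * 1000
  mean_speed <- 5 / 0.044
  expect_gt(max(speed), mean_speed)           # ~114 deg/s mean, ~170 peak
  expect_lt(max(speed), 3 * mean_speed)
})

test_that("noiseless threshold-free segmentation matches the ledger within a sample", {
  gp <- default_group_params("control")
  spec <- small_spec(seed = 31, n_scenarios = 1, scenario_duration_s = 15,
                     instruction_duration_s = 0)
  p <- simulate_participant(gp, spec, default_scene(), participant_seed = 8)
  ev <- p$events[p$events$scenario == 1, ]
  smp <- render_gaze_trace(ev, rate_hz = 90, noise_sd_deg = 0, seed = 1)
  dirs <- as.matrix(smp[, c("gaze_x", "gaze_y", "gaze_z")])
  step <- gc_dist_deg(dirs[-nrow(dirs), ], dirs[-1, ])
  moving <- step > 1e-9                      # motion between samples k, k+1
  r <- rle(moving)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  onsets <- smp$t_ms[starts[r$values]]
  truth <- ev$onset_ms[ev$kind == "saccade"]
  # every ground-truth saccade onset has a detected onset within one sample
  truth <- truth[truth < max(smp$t_ms) - 100]
  expect_true(all(vapply(truth, function(x) min(abs(onsets - x)),
                         numeric(1)) <= 1000 / 90 + 1e-9))
})

test_that("data-loss injection realizes the requested rate in bursts", {
  smp <- data.frame(valid = rep(TRUE, 105300))
  expect_identical(inject_data_loss(smp, 0, seed = 1), smp)
  out <- inject_data_loss(smp, 0.05, mean_burst_len = 3L, seed = 2)
  frac <- mean(!out$valid)
  expect_gt(frac, 0.04); expect_lt(frac, 0.06)
  # bursts, not isolated samples: mean invalid run length well above 1
  r <- rle(!out$valid)
  expect_gt(mean(r$lengths[r$values]), 2)
  # the highest loss rate observed in the study is accepted
  out16 <- inject_data_loss(smp, 0.16, mean_burst_len = 3L, seed = 3)
  expect_lt(abs(mean(!out16$valid) - 0.16), 0.01)
  expect_error(group_params(fixation_mean_ms = 317, fixation_between_sd_ms = 36,
                            saccade_amp_mean_deg = 5.44,
                            saccade_amp_between_sd_deg = 1.4,
                            saccade_dur_mean_ms = 57,
                            saccade_dur_between_sd_ms = 8.3,
                            invalid_rate = 0.35),
               "invalid_rate")
})

test_that("participants with invalid_rate zero have fully valid streams", {
  gp <- default_group_params("control")
  gp$invalid_rate <- 0
  p <- simulate_participant(gp, small_spec(seed = 4), default_scene(),
                            participant_seed = 5, render = TRUE)
  expect_true(all(p$samples$valid))
})

test_that("saliency maps expose their hotspots", {
  m0 <- make_saliency_map(grid = c(10, 20))
  expect_true(all(m0$values == m0$values[1, 1]))   # constant
  m1 <- make_saliency_map(grid = c(50, 120),
                          hotspots = data.frame(az_deg = 12, el_deg = -4,
                                                sd_deg = 5))
  idx <- which(m1$values == max(m1$values), arr.ind = TRUE)
  expect_lt(abs(m1$az_centers[idx[1, 2]] - 12), diff(m1$az_range_deg) / 120)
  expect_lt(abs(m1$el_centers[idx[1, 1]] - (-4)), diff(m1$el_range_deg) / 50)
  # two equal hotspots: two equal local maxima
  m2 <- make_saliency_map(grid = c(50, 120),
                          hotspots = data.frame(az_deg = c(-30, 30),
                                                el_deg = 0, sd_deg = 4))
  peak_left <- max(m2$values[, m2$az_centers < 0])
  peak_right <- max(m2$values[, m2$az_centers > 0])
  expect_lt(abs(peak_left - peak_right), 1e-9)
  expect_error(make_saliency_map(hotspots = data.frame(az_deg = 200, el_deg = 0,
                                                       sd_deg = 2)),
               "domain")
})

test_that("cohort specs enforce their invariants", {
  expect_error(cohort_spec(n_per_group = c(A = 3, B = 3)), "group labels")
  expect_error(group_params(fixation_mean_ms = 50, fixation_between_sd_ms = 10,
                            saccade_amp_mean_deg = 5,
                            saccade_amp_between_sd_deg = 1,
                            saccade_dur_mean_ms = 60,
                            saccade_dur_between_sd_ms = 8))
})

test_that("cohort-level trait means are realized exactly (standardized draws)", {
  gp <- default_group_params("control")
  d <- vrgaze:::with_seed(9, vrgaze:::draw_participant_means(gp, 36, standardize = TRUE))
  expect_equal(mean(d$fixation), gp$fixation_mean_ms, tolerance = 1e-9)
  expect_equal(sd(d$fixation), gp$fixation_between_sd_ms, tolerance = 1e-9)
  expect_equal(mean(d$sacc_dur), gp$saccade_dur_mean_ms, tolerance = 1e-9)
  expect_equal(mean(d$amplitude), gp$saccade_amp_mean_deg, tolerance = 1e-9)
  expect_equal(colMeans(d$performance), gp$performance_means, tolerance = 1e-9)
})
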