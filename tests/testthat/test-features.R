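fix_row <- function(dur, az = 0, el = 0, onset = 0, phase = "execution",
                    object_id = NA, relevance = NA) {
  data.frame(kind = "fixation", onset_ms = onset, offset_ms = onset + dur,
             duration_ms = dur, az_start = az, el_start = el, az_end = az,
             el_end = el, amplitude_deg = 0, peak_accel_deg_s2 = 0,
             phase = phase, participant = "P01", group = "control",
             scenario = 1L, object_id = object_id, relevance = relevance,
             stringsAsFactors = FALSE)
}

sac_row <- function(onset, dur = 50, amp = 5) {
  data.frame(kind = "saccade", onset_ms = onset, offset_ms = onset + dur,
             duration_ms = dur, az_start = 0, el_start = 0, az_end = amp,
             el_end = 0, amplitude_deg = amp, peak_accel_deg_s2 = 100,
             phase = "execution", participant = "P01", group = "control",
             scenario = 1L, object_id = NA, relevance = NA,
             stringsAsFactors = FALSE)
}

test_that("scenario aggregation takes execution-phase means, missing when empty", {
  ev <- rbind(fix_row(300), fix_row(340, onset = 400),
              fix_row(999, onset = 900, phase = "instruction"))
  agg <- aggregate_scenario(ev)
  expect_equal(agg$mean_fix_dur_ms, 320)
  expect_identical(agg$n_fix, 2L)
  expect_identical(agg$n_sacc, 0L)
  expect_true(is.na(agg$mean_sacc_dur_ms))     # missing, never zero
  expect_true(is.na(agg$mean_sacc_amp_deg))
})

test_that("fixations are assigned to AOIs with smallest-box tie-breaking", {
  scene <- default_scene()
  obj <- scene$objects
  rel1 <- obj[obj$relevance == "relevant", ][1, ]
  center <- c((rel1$az_min + rel1$az_max) / 2, (rel1$el_min + rel1$el_max) / 2)
  ev <- rbind(fix_row(300, az = center[1], el = center[2]),
              fix_row(300, az = 0, el = -20))         # on the floor band
  out <- assign_objects(ev, scene)
  expect_identical(out$object_id[1], rel1$id)
  expect_identical(out$relevance[1], "relevant")
  expect_identical(out$relevance[2], "non-object")

  # nested AOIs: the smaller box wins
  nested <- scene_spec(data.frame(id = c("outer", "inner"),
                                  az_min = c(-10, -2), az_max = c(10, 2),
                                  el_min = c(-10, -2), el_max = c(10, 2),
                                  relevance = "irrelevant"),
                       make_saliency_map(grid = c(10, 10),
                                         az_range_deg = c(-20, 20),
                                         el_range_deg = c(-20, 20)))
  out2 <- assign_objects(fix_row(300, az = 0.5, el = 0.5), nested)
  expect_identical(out2$object_id, "inner")
  # outside every AOI: labelled none (NA)
  out3 <- assign_objects(fix_row(300, az = -15, el = 5), nested)
  expect_true(is.na(out3$object_id))
})

test_that("relevance statistics average per participant and flag empty classes", {
  ev <- rbind(fix_row(200, relevance = "relevant", object_id = "a"),
              fix_row(400, relevance = "relevant", object_id = "b"),
              fix_row(300, relevance = "irrelevant", object_id = "c"))
  rs <- relevance_stats(ev)
  expect_equal(rs$mean_relevant_ms, 300)
  expect_equal(rs$mean_irrelevant_ms, 300)
  rs2 <- relevance_stats(ev[1:2, ])
  expect_true(is.na(rs2$mean_irrelevant_ms))
  expect_identical(rs2$n_irrelevant, 0L)
})

test_that("relevance offset configured in the generator is recovered", {
  gp <- default_group_params("control")
  gp$relevance_offset_ms <- 40
  spec <- small_spec(seed = 17, n_adhd = 1, n_control = 12,
                     n_scenarios = 6, scenario_duration_s = 60)
  co <- simulate_cohort(spec, default_scene(), groups = "control")
  fx <- co$events[co$events$kind == "fixation" & co$events$phase == "execution", ]
  rs <- relevance_stats(fx)
  offs <- rs$mean_relevant_ms - rs$mean_irrelevant_ms
  expect_lt(abs(mean(offs) - 40), 5)
})

test_that("NSS is zero under exhaustive coverage and affine-invariant", {
  m <- make_saliency_map(grid = c(8, 12),
                         hotspots = data.frame(az_deg = 10, el_deg = 3,
                                               sd_deg = 8))
  grid_fix <- expand.grid(az_deg = m$az_centers, el_deg = m$el_centers)
  expect_lt(abs(nss(m, grid_fix)), 1e-9)

  # all fixations on the hotspot cell equal that cell's z value
  idx <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  z <- (m$values - mean(m$values)) / sqrt(mean((m$values - mean(m$values))^2))
  one <- data.frame(az_deg = m$az_centers[idx[2]], el_deg = m$el_centers[idx[1]])
  expect_equal(as.numeric(nss(m, one)), z[idx[1], idx[2]], tolerance = 1e-9)

  # affine rescaling of the map leaves NSS unchanged
  m2 <- m; m2$values <- 7 * m$values + 3
  fx <- data.frame(az_deg = c(-20, 0, 15), el_deg = c(2, -1, 4))
  expect_equal(as.numeric(nss(m, fx)), as.numeric(nss(m2, fx)), tolerance = 1e-9)

  # fixations unrelated to the map: NSS distribution centred on zero
  centre <- vrgaze:::with_seed(77, mean(vapply(1:50, function(i) {
    rf <- data.frame(az_deg = runif(40, -60, 60), el_deg = runif(40, -25, 25))
    as.numeric(nss(m, rf))
  }, numeric(1))))
  expect_lt(abs(centre), 0.1)

  # constant map: undefined
  expect_error(nss(make_saliency_map(grid = c(4, 4)), fx), "constant",
               class = "vrgaze_nss_error")
  # fixations outside the domain are skipped and counted
  out <- nss(m, data.frame(az_deg = c(0, 500), el_deg = c(0, 0)))
  expect_identical(attr(out, "skipped"), 1L)
})

test_that("time bins follow onsets and same-object proportions use labeled flanks", {
  # phase shorter than 1 s: a single bin
  short <- rbind(fix_row(200), sac_row(200, dur = 50), fix_row(250, onset = 250))
  expect_identical(nrow(bin_time_course(short)), 1L)

  # fix(objA) sacc fix(objA) sacc fix(objB): same-object proportion 1/2
  ev <- rbind(fix_row(150, object_id = "A", relevance = "relevant"),
              sac_row(150, dur = 50),
              fix_row(150, onset = 200, object_id = "A", relevance = "relevant"),
              sac_row(350, dur = 50),
              fix_row(150, onset = 400, object_id = "B", relevance = "irrelevant"))
  b <- bin_time_course(ev)
  expect_equal(b$prop_same_object_saccades[1], 0.5)
  expect_identical(b$n_fixations[1], 3L)

  # a floor-fixation flank drops the saccade from the denominator
  ev2 <- ev
  ev2$relevance[3] <- "non-object"; ev2$object_id[3] <- "floor"
  b2 <- bin_time_course(ev2)
  expect_true(is.na(b2$prop_same_object_saccades[1]))

  # bin fixation counts partition the scenario's fixations
  gp <- default_group_params("control")
  p <- simulate_participant(gp, small_spec(seed = 23, n_scenarios = 1,
                                           scenario_duration_s = 30,
                                           instruction_duration_s = 0),
                            participant_seed = 4)
  ex <- p$events[p$events$phase == "execution", ]
  bb <- bin_time_course(ex)
  expect_identical(sum(bb$n_fixations), sum(ex$kind == "fixation"))
})

test_that("head-motion metrics match closed forms and a quaternion oracle", {
  n <- 901
  t_ms <- (0:900) / 90 * 1000
  static <- quat_axis_angle(c(0, 1, 0), rep(0, n))
  expect_equal(as.numeric(head_motion_metrics(static, t_ms)), c(0, 0))

  yaw <- quat_axis_angle(c(0, 1, 0), (0:900) * (10 / 90))  # 10 deg/s for 10 s
  hm <- head_motion_metrics(yaw, t_ms)
  expect_equal(as.numeric(hm["rotation_angle_sum_deg"]), 100, tolerance = 1e-6)
  expect_equal(as.numeric(hm["mean_rotation_speed_deg_s"]), 10, tolerance = 1e-6)

  # random walk vs independent pairwise-angle oracle
  set.seed(12)
  ang <- cumsum(rnorm(50, 0, 2))
  q <- quat_axis_angle(c(0, 1, 0), ang)
  t2 <- seq_len(50) * 11.1
  oracle <- sum(abs(diff(ang)))
  hm2 <- head_motion_metrics(q, t2)
  expect_equal(as.numeric(hm2["rotation_angle_sum_deg"]), oracle,
               tolerance = 1e-6)
})

test_that("the feature table has one row per participant and scenario", {
  gp <- default_group_params("control")
  spec <- small_spec(seed = 6, n_adhd = 2, n_control = 2)
  co <- simulate_cohort(spec)
  f <- filter_events(co$events, drop_incomplete = FALSE)
  ft <- feature_table(f[f$phase == "execution", ], n_scenarios = 2)
  expect_identical(nrow(ft), 4L * 2L)
  expect_false(any(duplicated(ft[, c("participant", "scenario")])))
  X <- eye_feature_matrix(ft)
  expect_identical(ncol(X$X), 3L * 2L)   # 3 features x scenarios
})
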