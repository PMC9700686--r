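test_that("gaze streams round-trip through the TSV format", {
  gp <- default_group_params("control")
  p <- simulate_participant(gp, small_spec(seed = 3, n_scenarios = 1,
                                           scenario_duration_s = 10),
                            participant_seed = 2, render = TRUE,
                            participant = "P01", group = "control")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze(p$samples, path)
  back <- read_gaze(path)
  num <- c("t_ms", "gaze_x", "gaze_y", "gaze_z", "head_qw", "head_qx",
           "head_qy", "head_qz")
  for (cn in num) expect_equal(back[[cn]], p$samples[[cn]], tolerance = 1e-9)
  expect_identical(back$valid, p$samples$valid)
  expect_identical(back$phase, p$samples$phase)
})

test_that("an empty gaze file with a header reads as an empty stream", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste0("#", paste(vrgaze:::GAZE_COLUMNS, collapse = "\t")), path)
  out <- read_gaze(path)
  expect_identical(nrow(out), 0L)
  expect_identical(names(out), vrgaze:::GAZE_COLUMNS)
})

test_that("parse errors are typed and name the offending line", {
  gp <- default_group_params("control")
  p <- simulate_participant(gp, small_spec(seed = 3, n_scenarios = 1,
                                           scenario_duration_s = 2),
                            participant_seed = 2, render = TRUE)
  s <- p$samples
  s[10, c("head_qw", "head_qx", "head_qy", "head_qz")] <- c(0.9, 0, 0, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze(s, path)
  expect_error(read_gaze(path), "line 11.*quaternion", class = "vrgaze_parse_error")

  s2 <- p$samples
  s2$t_ms[20] <- s2$t_ms[19]      # non-monotone time
  write_gaze(s2, path)
  expect_error(read_gaze(path), "line 21.*increasing", class = "vrgaze_parse_error")

  writeLines(c("#t_ms\tgaze_x", "0\t1"), path)   # missing columns
  expect_error(read_gaze(path), "missing column", class = "vrgaze_parse_error")
})

test_that("event, AOI and saliency-map formats round-trip", {
  ev <- ledger_fix_sacc(n_fix = 3)
  ev$participant <- "P01"; ev$group <- "control"; ev$object_id <- NA_character_
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$onset_ms, ev$onset_ms, tolerance = 1e-9)
  expect_identical(back$kind, ev$kind)

  scene <- default_scene()
  apath <- withr::local_tempfile(fileext = ".tsv")
  write_aoi(scene$objects, apath)
  aoi <- read_aoi(apath)
  expect_equal(aoi$az_min, scene$objects$az_min, tolerance = 1e-9)
  expect_identical(aoi$relevance, scene$objects$relevance)

  m <- make_saliency_map(grid = c(12, 30),
                         hotspots = data.frame(az_deg = 5, el_deg = 2, sd_deg = 6))
  spath <- withr::local_tempfile(fileext = ".txt")
  write_salmap(m, spath)
  m2 <- read_salmap(spath)
  expect_equal(m2$values, m$values, tolerance = 1e-9)
  expect_equal(m2$az_centers, m$az_centers, tolerance = 1e-9)
  expect_identical(dim(m2$values), dim(m$values))
})

test_that("participant screening applies the 30% threshold and is idempotent", {
  smp <- data.frame(
    participant = rep(c("heavy", "max_ok", "clean"), each = 100),
    valid = c(rep(c(FALSE, TRUE), c(30, 70)),    # exactly 30%: excluded
              rep(c(FALSE, TRUE), c(16, 84)),    # 16%: the study maximum, kept
              rep(TRUE, 100)))
  scr <- screen_participants(smp)
  expect_identical(sort(unique(scr$kept$participant)), c("clean", "max_ok"))
  rep_ <- scr$report[order(scr$report$participant), ]
  expect_equal(rep_$invalid_pct[rep_$participant == "clean"], 0)
  expect_true(rep_$excluded[rep_$participant == "heavy"])
  expect_false(rep_$excluded[rep_$participant == "max_ok"])
  # idempotent
  scr2 <- screen_participants(scr$kept)
  expect_identical(scr2$kept, scr$kept)
})

test_that("configuration loading fills defaults and rejects bad input", {
  cfg <- load_config(NULL)
  expect_identical(cfg$min_sacc_ms, 22)        # derived from 90 Hz
  expect_identical(cfg$lambda, 6)

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", path)
  expect_identical(load_config(path)$n_scenarios, 13L)   # empty file: defaults

  writeLines("min_fix_ms: 50", path)
  expect_identical(load_config(path)$min_fix_ms, 50L)

  writeLines("invalid_rate_adhd: 1.5", path)
  expect_error(load_config(path), "out of range", class = "vrgaze_config_error")

  writeLines("no_such_key: 1", path)
  expect_error(load_config(path), "unknown config key",
               class = "vrgaze_config_error")
})
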