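# Shared fixtures, built in code at test time.

# a small, fast cohort design for unit tests
small_spec <- function(seed = 1L, n_adhd = 3L, n_control = 3L,
                       n_scenarios = 2L, scenario_duration_s = 20,
                       instruction_duration_s = 4) {
  cohort_spec(n_per_group = c(ADHD = n_adhd, control = n_control),
              n_scenarios = n_scenarios,
              scenario_duration_s = scenario_duration_s,
              instruction_duration_s = instruction_duration_s,
              seed = seed)
}

# a hand-built ground-truth ledger: n_fix fixations of fix_ms, separated by
# saccades of sacc_ms jumping amp_deg along the azimuth
ledger_fix_sacc <- function(n_fix = 3, fix_ms = 400, sacc_ms = 44,
                            amp_deg = 5, el = 0, phase = "execution") {
  az <- (seq_len(n_fix) - 1) * amp_deg
  kind <- rep(c("fixation", "saccade"), length.out = 2 * n_fix - 1)
  dur <- ifelse(kind == "fixation", fix_ms, sacc_ms)
  off <- cumsum(dur)
  on <- off - dur
  fi <- cumsum(kind == "fixation")
  data.frame(kind = kind, onset_ms = on, offset_ms = off, duration_ms = dur,
             az_start = az[fi], el_start = el,
             az_end = ifelse(kind == "fixation", az[fi], az[pmin(fi + 1, n_fix)]),
             el_end = el,
             amplitude_deg = ifelse(kind == "fixation", 0, amp_deg),
             peak_accel_deg_s2 = ifelse(kind == "fixation", 0,
                                        6 * amp_deg / (sacc_ms / 1000)^2),
             phase = phase, scenario = 1L,
             stringsAsFactors = FALSE)
}

# render a ledger and map it back to a world angular trace
trace_from_ledger <- function(events, noise_sd_deg = 0.05, seed = 1L,
                              head_profile = head_profile_static(),
                              rate_hz = 90) {
  smp <- render_gaze_trace(events, rate_hz = rate_hz,
                           noise_sd_deg = noise_sd_deg,
                           head_profile = head_profile, seed = seed)
  smp$scenario <- 1L
  to_world_angles(smp)
}

# exhaustive two-sample permutation p value for |U - n1 n2 / 2|
perm_ranksum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  x <- c(a, b)
  obs <- abs(ranksum_z(a, b)$U - n1 * length(b) / 2)
  combs <- utils::combn(n, n1)
  stat <- apply(combs, 2, function(idx) {
    abs(ranksum_z(x[idx], x[-idx])$U - n1 * length(b) / 2)
  })
  mean(stat >= obs - 1e-12)
}
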