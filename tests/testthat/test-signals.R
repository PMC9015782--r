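test_that("position signals track quiet stance and injected drift", {
  poco <- simulate_recording(quick_cfg("POCO", seed = 1))$recording
  z <- extract_position_signals(poco)$signals$position_z$value
  expect_lt(max(abs(z - z[1]), na.rm = TRUE), 0.05)

  sim <- simulate_recording(quick_cfg("SIP", seed = 2),
                            list(defect("forward_drift", 0.6)))
  z <- extract_position_signals(sim$recording)$signals$position_z$value
  expect_equal(z[length(z)] - z[1], -0.60, tolerance = 0.02)
})

test_that("walk position slope matches the injected speed", {
  cfg <- quick_cfg("SCSW", seed = 3)
  sim <- simulate_recording(cfg)
  s <- extract_position_signals(sim$recording)$signals$position_z
  walk_end <- (cfg$start_z_m - 1.5) / cfg$walk_speed_mps
  sel <- s$t <= walk_end
  slope <- stats::coef(stats::lm(s$value[sel] ~ s$t[sel]))[2]
  expect_equal(unname(slope), -1.2, tolerance = 0.05)
})

test_that("low-confidence pelvis gaps are interpolated up to 0.5 s only", {
  rec <- toy_recording(seq(0, 5, by = 1 / 30), z = 2.5)
  i <- mocapqc:::LM[["SpineBase"]]
  rec$skeleton$conf[20:25, i] <- 0.1    # 0.2 s gap -> interpolated
  rec$skeleton$conf[60:95, i] <- 0.1    # 1.2 s gap -> left missing
  z <- extract_position_signals(rec)$signals$position_z$value
  expect_false(anyNA(z[20:25]))
  expect_true(anyNA(z[70:80]))
})

test_that("knee amplitude recovers injected lift height per cycle", {
  sim <- simulate_recording(quick_cfg("SIP", seed = 4))
  ka <- extract_knee_amplitude(sim$recording)
  for (side in c("left", "right")) {
    v <- ka$signals[[paste0("knee_amplitude_", side)]]$value
    regions <- mocapqc:::gate_regions(v, 0.05, 8L)
    peaks <- vapply(seq_len(nrow(regions)), function(i)
      max(v[regions$start[i]:regions$end[i]]), numeric(1))
    expect_equal(length(peaks), 20)
    expect_true(all(abs(peaks - 0.15) < 0.015))
  }
  expect_error(extract_knee_amplitude(
    simulate_recording(quick_cfg("POCO", seed = 1, duration_s = 2))$recording),
    "not applicable")
})

test_that("one-sided stepping only elevates that side's amplitude", {
  sim <- simulate_recording(quick_cfg("SIP", seed = 12))
  rec <- sim$recording
  # flatten the right knee: copy its quiet baseline forward
  i <- mocapqc:::LM[["KneeRight"]]
  rec$skeleton$xyz[, i, 2] <- rec$skeleton$xyz[1, i, 2] +
    stats::rnorm(length(rec$skeleton$t), 0, 0.003)
  ka <- extract_knee_amplitude(rec)
  noise_sd <- 0.003
  expect_gt(max(ka$signals$knee_amplitude_left$value), 3 * noise_sd)
  expect_lt(max(ka$signals$knee_amplitude_right$value), 10 * noise_sd)
})

test_that("arm sway stays in the noise band without gestures and flags them", {
  still <- simulate_recording(quick_cfg("POCO", seed = 5))$recording
  sw <- extract_arm_sway(still)
  expect_lt(max(sw$signals$arm_sway_left$value, na.rm = TRUE), 0.03)

  sim <- simulate_recording(quick_cfg("POCO", seed = 6),
                            list(defect("arm_movement", 0.2, onset_s = 22)))
  sw <- extract_arm_sway(sim$recording)$signals$arm_sway_left
  inwin <- sw$value[sw$t >= 20 & sw$t <= 24]
  expect_gte(max(inwin, na.rm = TRUE), 0.15)
  outwin <- sw$value[sw$t < 19 | sw$t > 26]
  expect_lt(max(outwin, na.rm = TRUE), 0.05)
})

test_that("arm sway is invariant to whole-body walking translation", {
  walk <- simulate_recording(quick_cfg("SCSW", seed = 7))$recording
  sw <- extract_arm_sway(walk)
  expect_lt(max(sw$signals$arm_sway_left$value, na.rm = TRUE), 0.05)
  expect_lt(max(sw$signals$arm_sway_right$value, na.rm = TRUE), 0.05)
})

test_that("knee amplitude, arm sway and stance width are translation invariant", {
  sim <- simulate_recording(quick_cfg("POCO", seed = 8, duration_s = 5))
  rec <- sim$recording
  shifted <- rec
  shifted$skeleton$xyz[, , 1] <- shifted$skeleton$xyz[, , 1] + 1.3
  shifted$skeleton$xyz[, , 3] <- shifted$skeleton$xyz[, , 3] + 0.9

  a <- extract_arm_sway(rec)$signals$arm_sway_left$value
  b <- extract_arm_sway(shifted)$signals$arm_sway_left$value
  expect_lt(max(abs(a - b), na.rm = TRUE), 1e-9)

  wa <- compute_stance_width(rec)$signals$stance_width$value
  wb <- compute_stance_width(shifted)$signals$stance_width$value
  expect_lt(max(abs(wa - wb), na.rm = TRUE), 1e-9)
})

test_that("step detection equals a brute-force gate count on clean input", {
  for (task in c("SIP", "SCSW", "SLW")) {
    sim <- simulate_recording(quick_cfg(task, seed = 9))
    rec <- sim$recording
    st <- detect_steps(rec)
    # oracle: count super-gate excursions of each side's raw lift signal
    src <- if (task == "SIP") "Knee" else "Ankle"
    count <- 0L
    for (side in c("Left", "Right")) {
      y <- rec$skeleton$xyz[, mocapqc:::LM[[paste0(src, side)]], 2]
      sgl <- y - stats::quantile(y, 0.10, names = FALSE)
      count <- count + nrow(mocapqc:::gate_regions(sgl, 0.05, 8L))
    }
    expect_equal(nrow(st), count)
    expect_equal(nrow(st), nrow(sim$ground_truth$true_step_times))
  }
})

test_that("clean SIP yields 40 alternating contacts near ground truth", {
  sim <- simulate_recording(quick_cfg("SIP", seed = 10))
  st <- detect_steps(sim$recording)
  expect_equal(nrow(st), 40)
  expect_true(all(st$side[-1] != st$side[-nrow(st)]))
  gt <- sim$ground_truth$true_step_times
  expect_lt(max(abs(st$t_contact - gt$t)), 0.25)
})

test_that("a flat signal contains no steps", {
  rec <- toy_recording(seq(0, 5, by = 1 / 30), z = 2.5, task = "SIP")
  expect_equal(nrow(detect_steps(rec)), 0)
  expect_error(detect_steps(toy_recording(c(0, 0.1), z = 2, task = "POCO")),
               "not applicable")
})

test_that("heavy clothing noise corrupts the detected step count", {
  clean <- simulate_recording(quick_cfg("SCSW", seed = 11))
  noisy <- simulate_recording(quick_cfg("SCSW", seed = 11),
                              list(defect("clothing_noise", 0.5)))
  n_true <- nrow(clean$ground_truth$true_step_times)
  n_noisy <- nrow(detect_steps(noisy$recording))
  expect_false(n_noisy == n_true)
})

test_that("SAS segmentation finds three alternating cycles", {
  sim <- simulate_recording(quick_cfg("SAS", seed = 12))
  ph <- detect_sas_phases(sim$recording)
  expect_equal(sum(ph$kind == "stand_up"), 3)
  expect_equal(sum(ph$kind == "sit_down"), 3)
  expect_true(all(ph$kind[-1] != ph$kind[-nrow(ph)]))
  expect_true(all(ph$complete))
  expect_true(all(ph$start < ph$end))
  expect_true(all(ph$start[-1] >= ph$end[-nrow(ph)]))  # non-overlapping
  gt <- sim$ground_truth$true_phase_bounds
  expect_lt(max(abs(ph$start - gt$start)), 0.6)
})

test_that("a truncation mid-transition leaves an incomplete final phase", {
  sim <- simulate_recording(quick_cfg("SAS", seed = 13),
                            list(defect("truncated_duration", 3)))
  ph <- detect_sas_phases(sim$recording)
  expect_false(ph$complete[nrow(ph)])
  expect_equal(ph$end[nrow(ph)], sim$recording$duration_s)
})

test_that("constant pelvis height yields no phases", {
  rec <- toy_recording(seq(0, 10, by = 1 / 30), z = 2.5, task = "SAS")
  expect_equal(nrow(detect_sas_phases(rec)), 0)
})

test_that("stance width recovers closed and open stances", {
  closed <- simulate_recording(quick_cfg("POCO", seed = 14, duration_s = 6))
  w <- compute_stance_width(closed$recording)$signals$stance_width$value
  expect_equal(median(w, na.rm = TRUE), 0.08, tolerance = 0.01)

  open <- simulate_recording(quick_cfg("POCO", seed = 15, duration_s = 6),
                             list(defect("open_feet", 0.30)))
  w <- compute_stance_width(open$recording)$signals$stance_width$value
  expect_equal(median(w, na.rm = TRUE), 0.30, tolerance = 0.02)
  expect_true(all(w >= 0, na.rm = TRUE))
})

test_that("the task dispatcher returns the documented closed vocabulary", {
  sip <- simulate_recording(quick_cfg("SIP", seed = 16, duration_s = 5))
  s <- extract_task_signals(sip$recording)
  expect_true(all(c("knee_amplitude_left", "knee_amplitude_right",
                    "arm_sway_left", "arm_sway_right", "position_z")
                  %in% names(s$signals)))

  poco <- simulate_recording(quick_cfg("POCO", seed = 17, duration_s = 5))
  s <- extract_task_signals(poco$recording)
  expect_true("stance_width" %in% names(s$signals))
  expect_false(any(grepl("knee_amplitude", names(s$signals))))

  allowed <- c("position_z", "position_x", "position_y", "stance_width",
               "arm_sway_left", "arm_sway_right",
               "knee_amplitude_left", "knee_amplitude_right")
  for (task in task_codes()) {
    sim <- simulate_recording(quick_cfg(task, seed = 18,
      duration_s = if (task %in% c("SCSW", "SMSW")) NULL else 6))
    s <- extract_task_signals(sim$recording)
    expect_true(all(names(s$signals) %in% allowed))
  }
})

test_that("signals export to tidy CSV", {
  sim <- simulate_recording(quick_cfg("POCO", seed = 19, duration_s = 2))
  s <- extract_position_signals(sim$recording)
  f <- withr::local_tempfile(fileext = ".csv")
  export_signals_csv(s, "rec-1", f)
  df <- utils::read.csv(f)
  expect_setequal(unique(df$signal),
                  c("position_z", "position_x", "position_y"))
  expect_true(all(df$unit == "m"))
})
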