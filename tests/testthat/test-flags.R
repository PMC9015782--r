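noiseless <- function(task, seed = 1, ...) {
  simulation_config(task, seed = seed, skeleton_noise_m = 0, ...)
}

test_that("duration flag uses the strict 40 s +/- 1 s rule", {
  exact <- simulate_recording(noiseless("POCO", duration_s = 40))$recording
  expect_false(flag_duration(exact)$raised)

  at_tol <- simulate_recording(noiseless("POCO_DUAL", duration_s = 41))$recording
  fl <- flag_duration(at_tol)
  expect_false(fl$raised)                       # deviation exactly 1 s
  expect_equal(fl$evidence, 1)

  short <- simulate_recording(noiseless("SIP", duration_s = 38.5))$recording
  fl <- flag_duration(short)
  expect_true(fl$raised)
  expect_equal(fl$evidence, 1.5)

  walk <- simulate_recording(noiseless("SCSW"))$recording
  expect_error(flag_duration(walk), "not applicable")
})

test_that("forward flag raises strictly above 50 cm and honors the tolerant preset", {
  drift06 <- simulate_recording(noiseless("SIP"),
                                list(defect("forward_drift", 0.6)))$recording
  expect_true(flag_forward(drift06)$raised)

  none <- simulate_recording(noiseless("SIP"))$recording
  expect_false(flag_forward(none)$raised)

  at05 <- simulate_recording(noiseless("SIP"),
                             list(defect("forward_drift", 0.5)))$recording
  fl <- flag_forward(at05)
  expect_equal(fl$evidence, 0.5, tolerance = 1e-9)
  expect_false(fl$raised)                       # strict >

  tolerant <- flag_config(preset = "tolerant_forward")
  expect_equal(tolerant$forward_m, 0.80)
  expect_false(flag_forward(drift06, tolerant)$raised)
})

test_that("backward flag covers drift and deliberate corrections", {
  back <- simulate_recording(noiseless("SIP"),
                             list(defect("backward_drift", 0.6)))$recording
  expect_true(flag_backward(back)$raised)

  still <- simulate_recording(noiseless("SIP"))$recording
  expect_false(flag_backward(still)$raised)

  # forward 0.4 m, then a return to the start: a correction, not a drift
  t <- seq(0, 40, by = 1 / 30)
  z <- 2.5 - 0.4 * mocapqc:::ramp01(t, 5, 15) + 0.4 * mocapqc:::ramp01(t, 25, 35)
  rec <- toy_recording(t, z = z, task = "SIP")
  fl <- flag_backward(rec)
  expect_true(fl$raised)
  expect_equal(fl$note, "correction")
  expect_lt(fl$evidence, 0.5)                   # net backward never above 50 cm
})

test_that("feet flag separates closed and open stances with a strict bound", {
  open <- simulate_recording(noiseless("POCO"),
                             list(defect("open_feet", 0.30)))$recording
  expect_true(flag_feet(open)$raised)

  closed <- simulate_recording(noiseless("POCO"))$recording
  expect_false(flag_feet(closed)$raised)

  at <- simulate_recording(noiseless("POCO"),
                           list(defect("open_feet", 0.15)))$recording
  fl <- flag_feet(at)
  expect_equal(fl$evidence, 0.15, tolerance = 1e-6)
  expect_false(fl$raised)
})

test_that("movements flag detects gestures and carries the dual-task caveat", {
  poco <- simulate_recording(noiseless("POCO"),
                             list(defect("arm_movement", 0.2)))$recording
  expect_true(flag_movements(poco)$raised)

  clean <- simulate_recording(noiseless("POCO"))$recording
  expect_false(flag_movements(clean)$raised)

  dual <- simulate_recording(noiseless("POCO_DUAL"),
                             list(defect("arm_movement", 0.2)))$recording
  fl <- flag_movements(dual)
  expect_true(fl$raised)
  expect_match(fl$note, "task-associated")
})

test_that("sidestep flag is rate-limited: a slow lean does not raise", {
  side <- simulate_recording(noiseless("POCO"),
                             list(defect("sidestep", 0.25)))$recording
  expect_true(flag_sidestep(side)$raised)

  quiet <- simulate_recording(noiseless("POCO"))$recording
  expect_false(flag_sidestep(quiet)$raised)

  t <- seq(0, 40, by = 1 / 30)
  lean <- toy_recording(t, z = 2.5, x = 0.25 * mocapqc:::ramp01(t, 10, 20),
                        task = "POCO")
  fl <- flag_sidestep(lean)
  expect_false(fl$raised)
  expect_lt(fl$evidence, 0.05)
})

test_that("arms flag checks the starting hand height, max over sides", {
  up <- simulate_recording(noiseless("SAS"),
                           list(defect("arms_not_down_at_start", 0.10)))$recording
  expect_true(flag_arms_start(up)$raised)

  down <- simulate_recording(noiseless("SAS"))$recording
  expect_false(flag_arms_start(down)$raised)

  # one raised hand suffices
  rec <- simulate_recording(noiseless("SAS"))$recording
  i_hand <- mocapqc:::LM[["HandLeft"]]
  i_hip <- mocapqc:::LM[["HipLeft"]]
  sel <- rec$skeleton$t <= 2.5
  rec$skeleton$xyz[sel, i_hand, 2] <-
    rec$skeleton$xyz[sel, i_hip, 2] + 0.2
  expect_true(flag_arms_start(rec)$raised)
})

test_that("disturbance evidence grows monotonically with injected noise", {
  ev <- vapply(c(0.05, 0.15, 0.30), function(m) {
    sim <- simulate_recording(depth_cfg("POCO", seed = 30, duration_s = 6),
                              list(defect("clothing_noise", m)))
    flag_disturbances(sim$recording)$evidence
  }, numeric(1))
  expect_true(all(diff(ev) > 0))
  expect_false(ev[1] > flag_config()$noise_fraction)
  expect_true(ev[3] > flag_config()$noise_fraction)

  clean <- simulate_recording(depth_cfg("POCO", seed = 31,
                                        duration_s = 6))$recording
  expect_false(flag_disturbances(clean)$raised)
  expect_error(flag_disturbances(toy_recording(c(0, 0.1), 2.5)), "depth")
})

test_that("step plausibility flag catches broken alternation and short walks", {
  clean <- simulate_recording(noiseless("SCSW"))$recording
  expect_false(flag_step_detection(clean)$raised)

  missing <- simulate_recording(noiseless("SIP"),
                                list(defect("missing_steps", 10)))$recording
  fl <- flag_step_detection(missing)
  expect_true(fl$raised)
  expect_match(fl$note, "alternation")

  shortwalk <- simulate_recording(
    noiseless("SMSW"),
    list(defect("truncated_duration",
                simulation_config("SMSW")$duration_s - 0.9)))$recording
  fl <- flag_step_detection(shortwalk)
  expect_true(fl$raised)
  expect_match(fl$note, "no full gait cycle")
})

test_that("up/down phase flag checks count, alternation and completeness", {
  clean <- simulate_recording(noiseless("SAS"))$recording
  expect_false(flag_updown_phase(clean)$raised)

  cut <- simulate_recording(noiseless("SAS"),
                            list(defect("truncated_duration", 3)))$recording
  fl <- flag_updown_phase(cut)
  expect_true(fl$raised)

  two <- simulate_recording(noiseless("SAS", duration_s = 12.5))$recording
  fl <- flag_updown_phase(two)   # third cycle does not fit
  expect_true(fl$raised)
})

test_that("run_autoflag emits exactly the applicable criteria, in fixed order", {
  for (task in task_codes()) {
    sim <- simulate_recording(quick_cfg(task, seed = 33))
    fdf <- as.data.frame(run_autoflag(sim$recording))
    expected <- setdiff(applicable_criteria(task), "DISTURBANCES")
    expect_identical(fdf$criterion, expected)   # no depth stream here
    expect_false(any(fdf$criterion == "FORWARD" & task != "SIP"))
  }
  # SUPPORT/OTHER are always present, never raised
  sim <- simulate_recording(quick_cfg("POCO", seed = 34, duration_s = 3))
  fdf <- as.data.frame(run_autoflag(sim$recording))
  man <- fdf[fdf$criterion %in% c("SUPPORT", "OTHER"), ]
  expect_false(any(man$raised))
  expect_true(all(man$note == "manual-only"))
})

test_that("combined defects raise exactly their criteria", {
  sim <- simulate_recording(
    depth_cfg("SIP", seed = 35),
    list(defect("forward_drift", 0.6), defect("clothing_noise", 0.3)))
  fdf <- as.data.frame(run_autoflag(sim$recording))
  raised <- fdf$criterion[fdf$raised]
  expect_true(all(c("FORWARD", "DISTURBANCES") %in% raised))
  expect_true(all(raised %in% c("FORWARD", "DISTURBANCES",
                                "STEP_DETECTION")))
})

test_that("raising a threshold never converts not-raised into raised", {
  sim <- simulate_recording(quick_cfg("SIP", seed = 36),
                            list(defect("forward_drift", 0.6)))
  rec <- sim$recording
  for (mult in c(1, 1.5, 3)) {
    cfg <- flag_config(forward_m = 0.5 * mult, backward_m = 0.5 * mult,
                       movement_excursion_m = 0.1 * mult)
    fdf <- as.data.frame(run_autoflag(rec, cfg))
    if (mult == 1) base <- fdf$raised
    expect_true(all(fdf$raised <= base))
    base <- fdf$raised
  }
})

test_that("flag configuration rejects nonpositive thresholds and unknown keys", {
  expect_error(flag_config(forward_m = 0), "> 0")
  expect_error(flag_config(frobnicate = 1), "unknown")
})
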