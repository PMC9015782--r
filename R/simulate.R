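#' Simulation configuration
#'
#' Parameters of the synthetic recording generator. Defaults emulate the
#' study conditions of a Kinect-v2-class setup: 30 Hz skeleton stream,
#' subject between 1.5 and 4.5 m from the camera, 512 x 424 depth
#' resolution, and task kinematics matching the protocol (40 s quiet
#' stance and stepping in place, short walks toward the camera, three
#' stand-up/sit-down cycles).
#'
#' @param task Task code (see [task_table()]).
#' @param duration_s Recording duration in seconds. `NULL` uses the task
#'   default: 40 for POCO/POCO_DUAL/SIP, 18 for SAS, walk time plus 1 s
#'   for walks.
#' @param cadence_hz Step rate in steps per second, both legs counted
#'   (SIP and walk tasks). `NULL` uses the task default (SIP 1.0,
#'   SCSW 1.8, SMSW 2.4, SLW 0.8).
#' @param walk_speed_mps Walking speed toward the camera in m/s (walk
#'   tasks). `NULL` uses the task default (SCSW 1.2, SMSW 1.8, SLW 0.3).
#' @param start_z_m Initial subject distance from the camera in meters,
#'   must lie within the sensor's working range of 1.5 to 4.5 m. `NULL`
#'   uses 2.5 for static tasks/SIP/SAS and 4.4 (4.5 for SMSW) for walks.
#' @param body_height_m Subject stature in meters (scales the skeleton
#'   template).
#' @param shoulder_width_m Shoulder span in meters (scales lateral
#'   offsets).
#' @param knee_lift_m Peak knee lift during stepping in place (m).
#' @param noise_sd_mm Depth sensor noise standard deviation (mm).
#' @param skeleton_noise_m Landmark measurement noise SD (m).
#' @param frame_rate_hz Skeleton stream rate (Hz).
#' @param render_depth If `TRUE`, a depth stream is rendered from the
#'   skeleton (required for depth-based defects and detectors).
#' @param depth_width,depth_height Depth image resolution in pixels.
#' @param depth_fps Depth stream rate (Hz); depth timestamps are a subset
#'   of skeleton timestamps.
#' @param cam_height_m Camera height above the floor (m).
#' @param render_floor If `TRUE`, the floor plane is rendered into depth
#'   frames.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   seed.
#' @return A list of class `qc_sim_config`.
#' @export
simulation_config <- function(task, duration_s = NULL, cadence_hz = NULL,
                              walk_speed_mps = NULL, start_z_m = NULL,
                              body_height_m = 1.75, shoulder_width_m = 0.40,
                              knee_lift_m = 0.15,
                              noise_sd_mm = 8, skeleton_noise_m = 0.003,
                              frame_rate_hz = 30, render_depth = FALSE,
                              depth_width = 512, depth_height = 424,
                              depth_fps = 30, cam_height_m = 0.8,
                              render_floor = TRUE, seed = 1L) {
  assert_task(task)
  walk_speed_mps <- walk_speed_mps %||%
    switch(task, SCSW = 1.2, SMSW = 1.8, SLW = 0.3, NA_real_)
  cadence_hz <- cadence_hz %||%
    switch(task, SIP = 1.0, SCSW = 1.8, SMSW = 2.4, SLW = 0.8, NA_real_)
  start_z_m <- start_z_m %||%
    switch(task, SCSW = 4.4, SMSW = 4.5, SLW = 3.5, 2.5)
  if (start_z_m < 1.5 || start_z_m > 4.5)
    stop("start_z_m must lie in [1.5, 4.5] m", call. = FALSE)
  if (is.null(duration_s)) {
    duration_s <- switch(task,
      POCO = 40, POCO_DUAL = 40, SIP = 40, SAS = 18,
      SLW = 10,
      (start_z_m - 1.5) / walk_speed_mps + 1)
  }
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  structure(list(
    task = task, duration_s = duration_s, cadence_hz = cadence_hz,
    walk_speed_mps = walk_speed_mps, start_z_m = start_z_m,
    body_height_m = body_height_m, shoulder_width_m = shoulder_width_m,
    knee_lift_m = knee_lift_m,
    noise_sd_mm = noise_sd_mm, skeleton_noise_m = skeleton_noise_m,
    frame_rate_hz = frame_rate_hz, render_depth = render_depth,
    depth_width = depth_width, depth_height = depth_height,
    depth_fps = depth_fps, cam_height_m = cam_height_m,
    render_floor = render_floor, seed = as.integer(seed)),
    class = "qc_sim_config")
}

#' Quality-defect specification
#'
#' Describes one quality defect to superimpose on a simulated recording.
#' Each kind maps onto one rating criterion of [criterion_table()]:
#'
#' | kind | unit of `magnitude` | criterion |
#' |------|---------------------|-----------|
#' | `forward_drift` | net anterior displacement (m) | FORWARD |
#' | `backward_drift` | net posterior displacement (m) | BACKWARD |
#' | `sidestep` | lateral shift (m) | SIDESTEP |
#' | `open_feet` | ankle separation (m) | FEET |
#' | `arm_movement` | hand excursion (m) | MOVEMENTS |
#' | `arms_not_down_at_start` | hand height above hip (m) | ARMS |
#' | `support_object` | object height (m) | SUPPORT (manual only) |
#' | `clothing_noise` | fraction of silhouette pixels corrupted | DISTURBANCES |
#' | `floor_noise` | fraction of static-background pixels corrupted | DISTURBANCES |
#' | `truncated_duration` | seconds cut from the end | DURATION / UP_DOWN_PHASE / STEP_DETECTION |
#' | `extra_steps` | count of extra same-side lifts | STEP_DETECTION |
#' | `missing_steps` | count of suppressed lifts | STEP_DETECTION |
#'
#' @param kind One of the kinds above.
#' @param magnitude Non-negative, kind-specific unit (see table).
#' @param onset_s Onset time in seconds, or `NULL` for a kind- and
#'   task-appropriate default.
#' @return A list of class `qc_defect`.
#' @export
defect <- function(kind, magnitude, onset_s = NULL) {
  kinds <- names(defect_applicability())
  if (!kind %in% kinds)
    stop("unknown defect kind: ", kind, call. = FALSE)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0)
    stop("defect magnitude must be a non-negative number", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, onset_s = onset_s),
            class = "qc_defect")
}

#' @rdname defect
#' @return `defect_applicability()` returns a named list mapping each
#'   defect kind to the tasks it may be injected into.
#' @export
defect_applicability <- function() {
  all_tasks <- task_codes()
  walkish <- c("SCSW", "SMSW", "SLW", "SIP")
  list(
    forward_drift = "SIP",
    backward_drift = "SIP",
    sidestep = c("POCO", "POCO_DUAL", "SLW"),
    open_feet = c("POCO", "POCO_DUAL"),
    arm_movement = c("POCO", "POCO_DUAL", "SLW", "SIP", "SAS"),
    arms_not_down_at_start = "SAS",
    support_object = all_tasks,
    clothing_noise = all_tasks,
    floor_noise = all_tasks,
    truncated_duration = all_tasks,
    extra_steps = walkish,
    missing_steps = walkish
  )
}

# criterion a defect kind is expected to raise on a given task (NA for
# manual-only kinds)
defect_criterion <- function(kind, task) {
  switch(kind,
    forward_drift = "FORWARD", backward_drift = "BACKWARD",
    sidestep = "SIDESTEP", open_feet = "FEET",
    arm_movement = "MOVEMENTS", arms_not_down_at_start = "ARMS",
    clothing_noise = "DISTURBANCES", floor_noise = "DISTURBANCES",
    extra_steps = "STEP_DETECTION", missing_steps = "STEP_DETECTION",
    truncated_duration =
      if (task %in% c("POCO", "POCO_DUAL", "SIP")) "DURATION"
      else if (task == "SAS") "UP_DOWN_PHASE"
      else "STEP_DETECTION",
    support_object = NA_character_,
    NA_character_)
}

# standing body template in world coordinates (floor at y = 0), subject
# centered at x = 0, facing the camera; z offsets relative to the pelvis
body_template <- function(height_m = 1.75, shoulder_width_m = 0.40) {
  s <- height_m / 1.75
  w <- shoulder_width_m / 0.40
  tmpl <- matrix(0, 25, 3, dimnames = list(landmark_names(),
                                           c("x", "y", "z")))
  set <- function(name, x, y, z = 0) tmpl[name, ] <<- c(x * w, y * s, z)
  set("SpineBase", 0, 0.95); set("SpineMid", 0, 1.18)
  set("SpineShoulder", 0, 1.38); set("Neck", 0, 1.46); set("Head", 0, 1.62)
  set("ShoulderLeft", 0.20, 1.40); set("ElbowLeft", 0.23, 1.12)
  set("WristLeft", 0.24, 0.88); set("HandLeft", 0.24, 0.82)
  set("HandTipLeft", 0.24, 0.74); set("ThumbLeft", 0.21, 0.80, -0.02)
  set("ShoulderRight", -0.20, 1.40); set("ElbowRight", -0.23, 1.12)
  set("WristRight", -0.24, 0.88); set("HandRight", -0.24, 0.82)
  set("HandTipRight", -0.24, 0.74); set("ThumbRight", -0.21, 0.80, -0.02)
  set("HipLeft", 0.09, 0.92); set("HipRight", -0.09, 0.92)
  set("KneeLeft", 0.10, 0.48); set("KneeRight", -0.10, 0.48)
  set("AnkleLeft", 0.04, 0.08); set("AnkleRight", -0.04, 0.08)
  set("FootLeft", 0.05, 0.03, -0.12); set("FootRight", -0.05, 0.03, -0.12)
  tmpl
}

# raised-cosine bump of unit peak over [t0, t0 + dur]
bump <- function(t, t0, dur) {
  u <- (t - t0) / dur
  ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

# linear ramp from 0 at t0 to 1 at t1
ramp01 <- function(t, t0, t1) pmin(1, pmax(0, (t - t0) / (t1 - t0)))

# lift schedule: one row per leg lift; contact time = start + dur
make_lift_schedule <- function(task, cfg, walk_end) {
  if (!task %in% c("SIP", "SCSW", "SMSW", "SLW")) return(NULL)
  interval <- 1 / cfg$cadence_hz
  dur <- 0.6 * interval
  t0 <- if (task == "SIP") 0.1 else 0.2
  starts <- seq(t0, cfg$duration_s, by = interval)
  contacts <- starts + dur
  limit <- if (task == "SIP") cfg$duration_s else walk_end
  keep <- contacts <= limit
  starts <- starts[keep]
  if (!length(starts)) return(data.frame(side = character(), start = numeric(),
                                         dur = numeric(), amp = numeric()))
  side <- rep(c("left", "right"), length.out = length(starts))
  amp <- if (task == "SIP") cfg$knee_lift_m else 0.07
  data.frame(side = side, start = starts, dur = dur, amp = amp,
             stringsAsFactors = FALSE)
}

# stand-up/sit-down schedule for SAS: data.frame(kind, start, end)
make_sas_schedule <- function(cfg) {
  rise <- 1.2; stand <- 1.5; sit <- 1.2; seated <- 1.5
  t <- 1.0
  rows <- list()
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(kind = "stand_up", start = t,
                                            end = t + rise)
    t <- t + rise + stand
    rows[[length(rows) + 1L]] <- data.frame(kind = "sit_down", start = t,
                                            end = t + sit)
    t <- t + sit + seated
  }
  do.call(rbind, rows)
}

#' Simulate a recording with ground-truth-labeled defects
#'
#' Generates a skeleton time series (and optionally a rendered depth
#' stream) for one motor-task trial, with zero or more quality defects
#' superimposed. The kinematic model is deliberately simple — sinusoidal
#' lifts, linear translation, raised-cosine transitions — because every
#' detector in the pipeline operates on displacement and periodicity
#' features, not on biomechanical realism:
#'
#' * POCO / POCO_DUAL: quiet stance with low-amplitude mediolateral and
#'   anterior-posterior sway.
#' * SIP: in-place stepping with alternating sinusoidal knee lifts at
#'   `cadence_hz` (both legs counted).
#' * SCSW / SMSW: straight walk toward the camera at `walk_speed_mps`
#'   from `start_z_m`, stopping at 1.5 m.
#' * SLW: slow narrow-base (tandem-style) walk toward the camera.
#' * SAS: three stand-up/sit-down cycles of the pelvis between a standing
#'   and a seated height.
#'
#' The only stochastic elements are the landmark measurement noise and
#' the depth sensor noise; given the same `cfg` (including `seed`) the
#' output is bit-identical.
#'
#' @param cfg A [simulation_config()].
#' @param defects List of [defect()] objects applicable to `cfg$task`.
#' @return A list with elements `recording` (a `qc_recording`) and
#'   `ground_truth` (class `qc_ground_truth`: `defects`,
#'   `true_step_times` — data frame `t`, `side` — `true_phase_bounds` —
#'   data frame `kind`, `start`, `end` — and `clean`).
#' @export
simulate_recording <- function(cfg, defects = list()) {
  stopifnot(inherits(cfg, "qc_sim_config"))
  if (inherits(defects, "qc_defect")) defects <- list(defects)
  task <- cfg$task
  app <- defect_applicability()
  for (d in defects) {
    if (!task %in% app[[d$kind]])
      stop(sprintf("defect '%s' is not applicable to task %s (applies to: %s)",
                   d$kind, task, paste(app[[d$kind]], collapse = ", ")),
           call. = FALSE)
  }
  withr::with_seed(cfg$seed, simulate_recording_impl(cfg, defects))
}

get_defect <- function(defects, kind) {
  for (d in defects) if (d$kind == kind) return(d)
  NULL
}

simulate_recording_impl <- function(cfg, defects) {
  task <- cfg$task
  fs <- cfg$frame_rate_hz
  t <- seq(0, cfg$duration_s, by = 1 / fs)
  n <- length(t)
  s <- cfg$body_height_m / 1.75
  tmpl <- body_template(cfg$body_height_m, cfg$shoulder_width_m)

  walking <- task %in% c("SCSW", "SMSW", "SLW")
  walk_end <- if (walking)
    min(cfg$duration_s, (cfg$start_z_m - 1.5) / cfg$walk_speed_mps)
  else cfg$duration_s

  # --- defect-aware lift schedule -----------------------------------------
  lifts <- make_lift_schedule(task, cfg, walk_end)
  if (!is.null(lifts)) {
    # extra_steps: k same-side double-steps — the subject lifts the left
    # leg again where the right one was due, breaking alternation
    d_extra <- get_defect(defects, "extra_steps")
    if (!is.null(d_extra) && d_extra$magnitude >= 1) {
      right <- which(lifts$side == "right")
      k <- min(round(d_extra$magnitude), length(right))
      lifts$side[right[seq_len(k)]] <- "left"
    }
    # missing_steps: suppress k left-leg lifts (skipping the very first
    # one, so every suppression leaves a same-side right-right pair)
    d_miss <- get_defect(defects, "missing_steps")
    if (!is.null(d_miss) && d_miss$magnitude >= 1) {
      left <- which(lifts$side == "left")
      k <- min(round(d_miss$magnitude), max(0L, length(left) - 1L))
      if (k > 0L) {
        drop <- left[seq(2L, by = 2L,
                         length.out = min(k, floor(length(left) / 2)))]
        if (length(drop) < k)
          drop <- c(drop, setdiff(left[-1], drop)[seq_len(k - length(drop))])
        lifts <- lifts[-drop, ]
      }
    }
    rownames(lifts) <- NULL
  }

  # --- global translation --------------------------------------------------
  x_g <- numeric(n)
  z_g <- rep(cfg$start_z_m, n)
  if (walking) z_g <- cfg$start_z_m - cfg$walk_speed_mps * pmin(t, walk_end)
  if (task %in% c("POCO", "POCO_DUAL")) {
    x_g <- x_g + 0.006 * sin(2 * pi * 0.25 * t) + 0.002 * sin(2 * pi * 0.9 * t)
    z_g <- z_g + 0.008 * sin(2 * pi * 0.18 * t + 1)
  }
  d <- get_defect(defects, "forward_drift")
  if (!is.null(d))
    z_g <- z_g - d$magnitude * ramp01(t, d$onset_s %||% 4, cfg$duration_s)
  d <- get_defect(defects, "backward_drift")
  if (!is.null(d))
    z_g <- z_g + d$magnitude * ramp01(t, d$onset_s %||% 4, cfg$duration_s)
  d <- get_defect(defects, "sidestep")
  if (!is.null(d)) {
    o <- d$onset_s %||% (cfg$duration_s / 2)
    x_g <- x_g + d$magnitude * ramp01(t, o, o + 0.4)
  }

  # --- per-frame joint matrices -------------------------------------------
  xyz <- array(rep(t(tmpl), n), dim = c(3, 25, n))
  xyz <- aperm(xyz, c(3, 2, 1))  # n x 25 x 3
  dimnames(xyz) <- list(NULL, landmark_names(), c("x", "y", "z"))

  d <- get_defect(defects, "open_feet")
  if (!is.null(d)) {
    half <- d$magnitude / 2
    for (side in c("Left", "Right")) {
      sgn <- if (side == "Left") 1 else -1
      xyz[, LM[[paste0("Ankle", side)]], 1] <- sgn * half
      xyz[, LM[[paste0("Foot", side)]], 1] <- sgn * (half + 0.01)
      xyz[, LM[[paste0("Knee", side)]], 1] <- sgn * (0.02 + 0.9 * half)
    }
  }

  # leg lifts (knee- or ankle-led)
  if (!is.null(lifts) && nrow(lifts)) {
    knee_led <- task == "SIP"
    for (side in c("left", "right")) {
      rows <- lifts[lifts$side == side, ]
      if (!nrow(rows)) next
      lift <- numeric(n)
      for (i in seq_len(nrow(rows)))
        lift <- lift + rows$amp[i] * bump(t, rows$start[i], rows$dur[i])
      Side <- if (side == "left") "Left" else "Right"
      if (knee_led) {
        xyz[, LM[[paste0("Knee", Side)]], 2] <-
          xyz[, LM[[paste0("Knee", Side)]], 2] + lift
        xyz[, LM[[paste0("Ankle", Side)]], 2] <-
          xyz[, LM[[paste0("Ankle", Side)]], 2] + 0.8 * lift
        xyz[, LM[[paste0("Foot", Side)]], 2] <-
          xyz[, LM[[paste0("Foot", Side)]], 2] + 0.8 * lift
      } else {
        xyz[, LM[[paste0("Ankle", Side)]], 2] <-
          xyz[, LM[[paste0("Ankle", Side)]], 2] + lift
        xyz[, LM[[paste0("Foot", Side)]], 2] <-
          xyz[, LM[[paste0("Foot", Side)]], 2] + lift
        xyz[, LM[[paste0("Knee", Side)]], 2] <-
          xyz[, LM[[paste0("Knee", Side)]], 2] + 0.7 * lift
      }
    }
  }

  # SAS vertical cycles
  phases <- NULL
  if (task == "SAS") {
    phases <- make_sas_schedule(cfg)
    # seated fraction: 1 seated, 0 standing; smooth cosine transitions
    sitfrac <- rep(1, n)  # starts seated
    for (i in seq_len(nrow(phases))) {
      p <- phases[i, ]
      u <- 0.5 * (1 - cos(pi * ramp01(t, p$start, p$end)))
      if (p$kind == "stand_up") {
        w <- t >= p$start
        sitfrac[w] <- 1 - u[w]
      } else {
        w <- t >= p$start
        sitfrac[w] <- u[w]
      }
    }
    dy <- -0.45 * s * sitfrac
    upper <- c("SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
               "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
               "HandTipLeft", "ThumbLeft", "ShoulderRight", "ElbowRight",
               "WristRight", "HandRight", "HandTipRight", "ThumbRight",
               "HipLeft", "HipRight")
    for (nm in upper) xyz[, LM[[nm]], 2] <- xyz[, LM[[nm]], 2] + dy
    for (nm in c("KneeLeft", "KneeRight")) {
      xyz[, LM[[nm]], 2] <- xyz[, LM[[nm]], 2] + 0.25 * dy
      xyz[, LM[[nm]], 3] <- xyz[, LM[[nm]], 3] - 0.20 * sitfrac
    }
  }

  # arms-not-down: hands held at hip height + magnitude for the first 3 s
  d <- get_defect(defects, "arms_not_down_at_start")
  if (!is.null(d)) {
    hold <- 3; release <- 1
    w <- ifelse(t <= hold, 1, pmax(0, 1 - (t - hold) / release))
    for (side in c("Left", "Right")) {
      hip_y <- xyz[, LM[[paste0("Hip", side)]], 2]
      for (nm in paste0(c("Hand", "Wrist", "HandTip", "Thumb"), side)) {
        target <- hip_y + d$magnitude
        xyz[, LM[[nm]], 2] <- xyz[, LM[[nm]], 2] +
          w * (target - xyz[, LM[[nm]], 2])
        xyz[, LM[[nm]], 3] <- xyz[, LM[[nm]], 3] - w * 0.15  # in front of body
      }
      enm <- paste0("Elbow", side)
      xyz[, LM[[enm]], 2] <- xyz[, LM[[enm]], 2] + w * 0.05
    }
  }

  # task-unassociated arm movement: two short (0.8 s) hand excursions
  d <- get_defect(defects, "arm_movement")
  if (!is.null(d)) {
    o <- d$onset_s %||% switch(task, SAS = 7.8, SLW = 5,
                               min(22, cfg$duration_s * 0.55))
    exc <- d$magnitude * (bump(t, o, 0.8) + bump(t, o + 1.2, 0.8))
    for (nm in c("HandLeft", "WristLeft", "HandTipLeft", "ThumbLeft")) {
      xyz[, LM[[nm]], 1] <- xyz[, LM[[nm]], 1] + exc
      xyz[, LM[[nm]], 2] <- xyz[, LM[[nm]], 2] + 0.5 * exc
    }
    xyz[, LM[["ElbowLeft"]], 1] <- xyz[, LM[["ElbowLeft"]], 1] + 0.4 * exc
  }

  # apply global translation and convert world y to camera frame
  xyz[, , 1] <- xyz[, , 1] + x_g
  xyz[, , 3] <- xyz[, , 3] + z_g
  xyz[, , 2] <- xyz[, , 2] - cfg$cam_height_m

  # measurement noise
  conf <- matrix(0.95, n, 25, dimnames = list(NULL, landmark_names()))
  if (cfg$skeleton_noise_m > 0)
    xyz <- xyz + array(stats::rnorm(length(xyz), 0, cfg$skeleton_noise_m),
                       dim = dim(xyz))

  # clothing noise corrupts lower-leg landmark tracking as well
  d_cloth <- get_defect(defects, "clothing_noise")
  if (!is.null(d_cloth) && d_cloth$magnitude > 0) {
    sd_lm <- 0.08 * d_cloth$magnitude
    legs <- c("KneeLeft", "AnkleLeft", "FootLeft",
              "KneeRight", "AnkleRight", "FootRight")
    for (nm in legs) {
      i <- LM[[nm]]
      xyz[, i, ] <- xyz[, i, ] + matrix(stats::rnorm(3 * n, 0, sd_lm), n, 3)
      conf[, i] <- pmax(0.05, 0.95 - 1.2 * d_cloth$magnitude)
    }
  }

  # --- truncation ----------------------------------------------------------
  d_trunc <- get_defect(defects, "truncated_duration")
  if (!is.null(d_trunc) && d_trunc$magnitude > 0) {
    keep <- t <= cfg$duration_s - d_trunc$magnitude
    if (!any(keep)) stop("truncation removes the whole recording",
                         call. = FALSE)
    t <- t[keep]
    xyz <- xyz[keep, , , drop = FALSE]
    conf <- conf[keep, , drop = FALSE]
    n <- length(t)
  }

  # --- depth stream --------------------------------------------------------
  depth <- NULL
  if (isTRUE(cfg$render_depth)) {
    intr <- camera_intrinsics(cfg$depth_width, cfg$depth_height)
    stride <- max(1L, round(fs / cfg$depth_fps))
    di <- seq(1L, n, by = stride)
    floor_rows <- if (isTRUE(cfg$render_floor))
      floor_depth_rows(intr, cfg$cam_height_m) else NULL
    d_floor <- get_defect(defects, "floor_noise")
    d_supp <- get_defect(defects, "support_object")
    frames <- vector("list", length(di))
    for (k in seq_along(di)) {
      J <- xyz[di[k], , , drop = TRUE]
      body <- raster_body(J, intr)
      if (!is.null(d_supp)) {
        hx <- J[LM[["SpineBase"]], 1] + 0.5
        hz <- J[LM[["SpineBase"]], 3]
        pole <- matrix(c(hx, -cfg$cam_height_m, hz,
                         hx, -cfg$cam_height_m + (d_supp$magnitude %||% 1), hz),
                       2, 3, byrow = TRUE)
        pd <- .raster_capsules(pole, matrix(c(1L, 2L), 1), 0.04,
                               intr$width, intr$height, intr$fx, intr$fy,
                               intr$cx, intr$cy)
        body <- ifelse(body > 0L & pd > 0L, pmin(body, pd),
                       pmax(body, pd))
        storage.mode(body) <- "integer"
      }
      frame <- if (is.null(floor_rows)) body else
        compose_floor(body, floor_rows)
      valid <- frame > 0L
      if (cfg$noise_sd_mm > 0) {
        nz <- sum(valid)
        frame[valid] <- pmax(1L, frame[valid] +
          as.integer(round(stats::rnorm(nz, 0, cfg$noise_sd_mm))))
      }
      # clothing noise: zero silhouette pixels below the knees so that an
      # expected `magnitude` fraction of the whole silhouette is lost
      if (!is.null(d_cloth) && d_cloth$magnitude > 0) {
        mask <- body > 0L
        knee_y <- min(J[LM[["KneeLeft"]], 2], J[LM[["KneeRight"]], 2])
        knee_z <- J[LM[["SpineBase"]], 3]
        v_knee <- intr$cy - intr$fy * knee_y / knee_z
        legs <- mask & (row(frame) > v_knee)
        n_mask <- sum(mask); n_legs <- sum(legs)
        if (n_legs > 0) {
          p <- min(1, d_cloth$magnitude * n_mask / n_legs)
          hit <- legs & matrix(stats::runif(length(frame)) < p,
                               nrow(frame))
          frame[hit] <- 0L
        }
      }
      if (!is.null(d_floor) && d_floor$magnitude > 0 && !is.null(floor_rows)) {
        fl <- matrix(floor_rows, nrow(frame), ncol(frame)) > 0L &
          !(body > 0L)
        n_fl <- sum(fl)
        if (n_fl > 0) {
          p <- min(1, d_floor$magnitude)
          hit <- fl & matrix(stats::runif(length(frame)) < p, nrow(frame))
          zero <- hit & matrix(stats::runif(length(frame)) < 0.5, nrow(frame))
          jit <- hit & !zero
          frame[zero] <- 0L
          nj <- sum(jit)
          if (nj) frame[jit] <- pmax(1L, frame[jit] +
            as.integer(round(sample(c(-1, 1), nj, replace = TRUE) *
                             stats::runif(nj, 250, 600))))
        }
      }
      frames[[k]] <- frame
    }
    depth <- list(t = t[di], frames = frames)
  }

  md <- recording_metadata(
    recording_id = sprintf("sim-%s-%06d", task, cfg$seed),
    subject_id = sprintf("synthetic-%06d", cfg$seed),
    task = task, group = "synthetic", frame_rate_hz = fs,
    operator_comment = if (length(defects))
      paste("injected:", paste(vapply(defects, `[[`, "", "kind"),
                               collapse = ", ")) else "")
  rec <- new_recording(md, skeleton = list(t = t, xyz = xyz, conf = conf),
                       depth = depth)

  steps <- if (!is.null(lifts) && nrow(lifts)) {
    st <- data.frame(t = lifts$start + lifts$dur, side = lifts$side,
                     stringsAsFactors = FALSE)
    st[st$t <= max(t), , drop = FALSE]
  } else data.frame(t = numeric(), side = character())
  gt <- structure(list(
    defects = defects,
    true_step_times = steps,
    true_phase_bounds = if (is.null(phases))
      data.frame(kind = character(), start = numeric(), end = numeric())
      else phases,
    clean = length(defects) == 0L), class = "qc_ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' Render a depth frame from one skeleton frame
#'
#' Rasterizes a body silhouette (capsules between connected landmarks,
#' radii from the documented body model) into a depth image using the
#' fixed pinhole camera model (focal 365.6 px at 512 px width, principal
#' point at the image center). Background pixels are 0; silhouette pixel
#' values are the front-surface distance in millimeters.
#'
#' @param joints 25 x 3 matrix of camera-frame landmark coordinates
#'   (meters), rows in [landmark_names()] order.
#' @param cfg A [simulation_config()] supplying resolution and floor
#'   settings.
#' @return Integer depth matrix (`depth_height` x `depth_width`), mm.
#' @export
render_depth_from_skeleton <- function(joints, cfg) {
  stopifnot(is.matrix(joints), nrow(joints) == 25L, ncol(joints) == 3L)
  if (any(!is.finite(joints)))
    stop("landmarks must be finite", call. = FALSE)
  if (any(joints[, 3] <= 0))
    stop("geometry error: landmark behind camera (z <= 0)", call. = FALSE)
  intr <- camera_intrinsics(cfg$depth_width, cfg$depth_height)
  body <- raster_body(joints, intr)
  if (isTRUE(cfg$render_floor))
    body <- compose_floor(body, floor_depth_rows(intr, cfg$cam_height_m))
  body
}
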