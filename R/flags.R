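#' Flag configuration
#'
#' Thresholds for the automated quality-criterion detectors. Two values
#' come straight from the rating criteria: the nominal duration of
#' 40 s with a tolerated deviation of 1 s, and the 50 cm forward/backward
#' displacement bound for stepping in place (with a documented tolerant
#' alternative of 0.80 m, reflecting the view that drifts up to
#' 80-100 cm may be acceptable — select it with
#' `flag_config(preset = "tolerant_forward")`). All other thresholds are
#' explicitly heuristic package defaults, because the criteria are only
#' described qualitatively:
#'
#' * `feet_width_m = 0.15`: median stance width above which feet count
#'   as open;
#' * `movement_excursion_m = 0.10`: arm-sway excursion counting as a
#'   task-unassociated movement;
#' * `sidestep_m = 0.15`: pelvis mediolateral displacement within 1 s
#'   counting as a sidestep;
#' * `arms_height_tol_m = 0.05`: tolerated mean hand height above hip
#'   height at recording start;
#' * `noise_fraction = 0.10`: tolerated fraction of disturbed pixels in
#'   the silhouette/background evidence region;
#' * `cadence_bounds_hz = c(0.3, 3.5)` and
#'   `alternation_tol = 0.20`: step-plausibility bounds.
#'
#' Every detector uses a strict comparison: evidence exactly equal to its
#' threshold does not raise the flag (matching the "more than" wording of
#' the criteria).
#'
#' @param duration_nominal_s,duration_tol_s Nominal duration and
#'   tolerated deviation (s).
#' @param forward_m,backward_m Displacement bounds (m).
#' @param feet_width_m,movement_excursion_m,sidestep_m,arms_height_tol_m
#'   Heuristic bounds (m), see above.
#' @param noise_fraction Disturbance bound (fraction).
#' @param cadence_bounds_hz Plausible total step rate range (steps/s).
#' @param alternation_tol Tolerated fraction of non-alternating step
#'   transitions.
#' @param flicker_mm Frame-to-frame depth change counting as flicker (mm).
#' @param preset `NULL` or `"tolerant_forward"` (sets `forward_m = 0.80`).
#' @param ... Named overrides for any of the above fields.
#' @return A list of class `qc_flag_config`.
#' @export
flag_config <- function(duration_nominal_s = 40, duration_tol_s = 1,
                        forward_m = 0.50, backward_m = 0.50,
                        feet_width_m = 0.15, movement_excursion_m = 0.10,
                        sidestep_m = 0.15, arms_height_tol_m = 0.05,
                        noise_fraction = 0.10,
                        cadence_bounds_hz = c(0.3, 3.5),
                        alternation_tol = 0.20, flicker_mm = 200,
                        preset = NULL, ...) {
  cfg <- list(duration_nominal_s = duration_nominal_s,
              duration_tol_s = duration_tol_s,
              forward_m = forward_m, backward_m = backward_m,
              feet_width_m = feet_width_m,
              movement_excursion_m = movement_excursion_m,
              sidestep_m = sidestep_m,
              arms_height_tol_m = arms_height_tol_m,
              noise_fraction = noise_fraction,
              cadence_bounds_hz = cadence_bounds_hz,
              alternation_tol = alternation_tol,
              flicker_mm = flicker_mm)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tolerant_forward")
    cfg$forward_m <- 0.80
  }
  extra <- list(...)
  bad <- setdiff(names(extra), names(cfg))
  if (length(bad)) stop("unknown flag_config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(extra)] <- extra
  num <- unlist(cfg[c("duration_tol_s", "forward_m", "backward_m",
                      "feet_width_m", "movement_excursion_m", "sidestep_m",
                      "noise_fraction", "flicker_mm")])
  if (any(num <= 0)) stop("all thresholds must be > 0", call. = FALSE)
  structure(cfg, class = "qc_flag_config")
}

new_flag <- function(criterion, raised, evidence, unit, threshold,
                     note = "") {
  cat_tab <- criterion_table()
  structure(list(criterion = criterion,
                 category = cat_tab$category[cat_tab$code == criterion],
                 raised = raised, evidence = evidence, unit = unit,
                 threshold = threshold, note = note),
            class = "qc_flag")
}

#' @export
print.qc_flag <- function(x, ...) {
  cat(sprintf("%-14s %-7s evidence=%.4g %s threshold=%.4g%s\n",
              x$criterion, if (x$raised) "RAISED" else "ok",
              x$evidence, x$unit, x$threshold,
              if (nzchar(x$note)) paste0("  (", x$note, ")") else ""))
  invisible(x)
}

check_flag_task <- function(rec, criterion) {
  task <- rec$metadata$task
  tab <- criterion_table()
  allowed <- tab$applicable_tasks[[match(criterion, tab$code)]]
  if (!task %in% allowed)
    stop_applicability(paste0("criterion ", criterion), task, allowed)
  task
}

#' Duration flag
#'
#' Raised when the recording duration deviates from the nominal 40 s by
#' strictly more than the tolerated 1 s. Evidence is the absolute
#' deviation in seconds. Applies to POCO, POCO_DUAL and SIP.
#'
#' @param rec A `qc_recording`.
#' @param cfg A [flag_config()].
#' @return A `qc_flag`.
#' @export
flag_duration <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "DURATION")
  dev <- abs(rec$duration_s - cfg$duration_nominal_s)
  new_flag("DURATION", dev > cfg$duration_tol_s, dev, "s",
           cfg$duration_tol_s)
}

#' Forward-displacement flag (stepping in place)
#'
#' Evidence is the maximum anterior displacement of the pelvis from its
#' starting position, `max(z(0) - z(t))`; raised when it strictly
#' exceeds `forward_m` (default 0.50 m; tolerant preset 0.80 m).
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_forward <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "FORWARD")
  z <- signal_values(extract_position_signals(rec), "position_z")
  z0 <- first_valid(z)
  ev <- max(z0 - z, na.rm = TRUE)
  new_flag("FORWARD", ev > cfg$forward_m, ev, "m", cfg$forward_m)
}

#' Backward-displacement flag (stepping in place)
#'
#' Evidence is the maximum posterior displacement `max(z(t) - z(0))`;
#' raised when it strictly exceeds `backward_m`, or — independently of
#' the threshold — when a deliberate backward correction is detected: a
#' backward excursion of at least 0.25 m following a forward excursion of
#' at least 0.25 m (note `"correction"`). The correction rule is this
#' package's heuristic operationalization of a deliberate correction.
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_backward <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "BACKWARD")
  z <- signal_values(extract_position_signals(rec), "position_z")
  z <- z[!is.na(z)]
  z0 <- z[1]
  ev <- max(z - z0)
  note <- ""
  raised <- ev > cfg$backward_m
  fwd <- z0 - z           # forward displacement, positive toward camera
  if (length(fwd) > 2) {
    i_max <- which.max(fwd)
    if (fwd[i_max] >= 0.25 &&
        i_max < length(fwd) &&
        max(fwd[i_max] - fwd[i_max:length(fwd)]) >= 0.25) {
      raised <- TRUE
      note <- "correction"
    }
  }
  new_flag("BACKWARD", raised, ev, "m", cfg$backward_m, note)
}

#' Feet-position flag (postural control)
#'
#' Evidence is the median stance width over the first 5 s; raised when
#' it strictly exceeds `feet_width_m` (heuristic default 0.15 m, since
#' the criterion only demands "closed" feet).
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_feet <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "FEET")
  ss <- compute_stance_width(rec)
  s <- ss$signals$stance_width
  sel <- s$t <= s$t[1] + 5
  ev <- stats::median(s$value[sel], na.rm = TRUE)
  new_flag("FEET", ev > cfg$feet_width_m, ev, "m", cfg$feet_width_m)
}

#' Task-unassociated-movement flag
#'
#' Evidence is the maximum arm-sway value outside task-expected windows;
#' raised when it strictly exceeds `movement_excursion_m`. Task-expected
#' windows: for SAS, the detected stand-up/sit-down transitions (padded
#' by 0.5 s) and the first 5 s (start positioning is judged by the ARMS
#' criterion); other tasks have no expected arm movement. For POCO_DUAL
#' the note records that gesturing may accompany the concurrent cognitive
#' task, so the flag is decision support rather than a verdict.
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_movements <- function(rec, cfg = flag_config()) {
  task <- check_flag_task(rec, "MOVEMENTS")
  ss <- extract_arm_sway(rec)
  t <- ss$signals$arm_sway_left$t
  sway <- pmax(ss$signals$arm_sway_left$value,
               ss$signals$arm_sway_right$value)
  keep <- rep(TRUE, length(t))
  if (task == "SAS") {
    keep <- keep & t > 5
    ph <- detect_sas_phases(rec)
    for (i in seq_len(nrow(ph)))
      keep <- keep & !(t >= ph$start[i] - 0.5 & t <= ph$end[i] + 0.5)
  }
  ev <- if (any(keep)) max(sway[keep], na.rm = TRUE) else 0
  if (!is.finite(ev)) ev <- 0
  note <- if (task == "POCO_DUAL")
    "dual-task gesturing may be task-associated" else ""
  new_flag("MOVEMENTS", ev > cfg$movement_excursion_m, ev, "m",
           cfg$movement_excursion_m, note)
}

#' Sidestep flag
#'
#' Evidence is the maximum mediolateral pelvis displacement within any
#' 1 s window (a rate-limited excursion, so a slow lean does not count);
#' raised when it strictly exceeds `sidestep_m` (heuristic default
#' 0.15 m).
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_sidestep <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "SIDESTEP")
  ss <- extract_position_signals(rec)
  s <- ss$signals$position_x
  ok <- !is.na(s$value)
  ev <- windowed_range_max(s$t[ok], s$value[ok], 1)
  new_flag("SIDESTEP", ev > cfg$sidestep_m, ev, "m", cfg$sidestep_m)
}

#' Arms-at-start flag (stand up and sit down)
#'
#' Evidence is the larger of the two sides' mean hand height minus hip
#' height over the first 2 s (meters); raised when it strictly exceeds
#' `arms_height_tol_m` (default 0.05 m) — hands hanging loosely rest
#' below hip height.
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_arms_start <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "ARMS")
  t <- rec$skeleton$t
  sel <- t <= t[1] + 2
  ev <- -Inf
  for (side in c("Left", "Right")) {
    hand <- landmark_xyz(rec, paste0("Hand", side))[, 2]
    hip <- landmark_xyz(rec, paste0("Hip", side))[, 2]
    ev <- max(ev, mean(hand[sel] - hip[sel], na.rm = TRUE))
  }
  new_flag("ARMS", ev > cfg$arms_height_tol_m, ev, "m",
           cfg$arms_height_tol_m)
}

#' Signal-disturbance flag
#'
#' Evidence is the average (over frames) of the disturbed-pixel fraction
#' in the worse of two evidence regions: the body silhouette —
#' reprojected from the recording's own skeleton through the package's
#' documented camera/body model — and the persistent static background
#' (pixels valid in at least 60% of frames, e.g. the floor). A pixel is
#' disturbed when it is invalid (0) inside its region, or when its depth
#' changes by more than `flicker_mm` between consecutive frames (body
#' flicker is only counted while the skeleton is quasi-static, so
#' ordinary locomotion does not register). Raised when the evidence
#' strictly exceeds `noise_fraction`.
#'
#' @inheritParams flag_duration
#' @param sim_cfg Optional [simulation_config()] supplying the camera and
#'   body-model parameters for silhouette reprojection; defaults to the
#'   package's standard model at the recording's depth resolution.
#' @return A `qc_flag`.
#' @export
flag_disturbances <- function(rec, cfg = flag_config(), sim_cfg = NULL) {
  if (is.null(rec$depth) || !length(rec$depth$t))
    stop("flag_disturbances requires a non-empty depth stream",
         call. = FALSE)
  dp <- rec$depth
  h <- nrow(dp$frames[[1]]); w <- ncol(dp$frames[[1]])
  intr <- camera_intrinsics(w, h)
  nf <- length(dp$frames)

  # persistent static background: valid in >= 60% of frames
  cnt <- matrix(0L, h, w)
  for (f in dp$frames) cnt <- cnt + (f > 0L)
  static_bg <- cnt >= 0.6 * nf

  has_skel <- !is.null(rec$skeleton) && length(rec$skeleton$t)
  pelvis_speed <- NULL
  if (has_skel) {
    z <- landmark_xyz(rec, "SpineBase")
    tt <- rec$skeleton$t
    v <- sqrt(rowSums(rbind(0, apply(z, 2, diff))^2)) /
      c(1, pmax(diff(tt), 1e-6))
  }
  frac <- numeric(nf)
  prev <- NULL
  for (k in seq_len(nf)) {
    f <- dp$frames[[k]]
    if (has_skel) {
      i_sk <- which.min(abs(rec$skeleton$t - dp$t[k]))
      J <- rec$skeleton$xyz[i_sk, , , drop = TRUE]
      body <- raster_body(J, intr) > 0L
      quasi_static <- v[i_sk] < 0.25
    } else {
      body <- f > 0L & !static_bg
      quasi_static <- FALSE
    }
    bg <- static_bg & !body
    ch <- matrix(FALSE, h, w)
    if (!is.null(prev))
      ch <- f > 0L & prev > 0L & abs(f - prev) > cfg$flicker_mm
    body_bad <- (body & f == 0L) |
      (ch & body & isTRUE(quasi_static))
    bg_bad <- bg & (f == 0L | ch)
    f_body <- if (sum(body) > 0L) sum(body_bad) / sum(body) else 0
    f_bg <- if (sum(bg) > 0L) sum(bg_bad) / sum(bg) else 0
    frac[k] <- max(f_body, f_bg)
    prev <- f
  }
  ev <- mean(frac)
  new_flag("DISTURBANCES", ev > cfg$noise_fraction, ev, "fraction",
           cfg$noise_fraction)
}

#' Step-detection plausibility flag
#'
#' Runs [detect_steps()] and raises the flag when the result is
#' implausible: overall cadence outside `cadence_bounds_hz`, sides
#' failing to alternate in more than `alternation_tol` of transitions,
#' or — for the walk tasks — no full gait cycle captured (fewer than two
#' steps on either side; note `"no full gait cycle"`).
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_step_detection <- function(rec, cfg = flag_config()) {
  task <- check_flag_task(rec, "STEP_DETECTION")
  st <- detect_steps(rec)
  n <- nrow(st)
  raised <- FALSE; note <- ""; ev <- 0
  walkish <- task %in% c("SCSW", "SMSW", "SLW")
  if (n < 2) {
    raised <- TRUE
    note <- if (walkish) "no full gait cycle" else "too few steps"
    ev <- n
  } else {
    span <- st$t_contact[n] - st$t_contact[1]
    cadence <- if (span > 0) (n - 1) / span else Inf
    alt_fail <- mean(st$side[-1] == st$side[-n])
    if (cadence < cfg$cadence_bounds_hz[1] ||
        cadence > cfg$cadence_bounds_hz[2]) {
      raised <- TRUE; note <- "implausible cadence"; ev <- cadence
    }
    if (alt_fail > cfg$alternation_tol) {
      raised <- TRUE
      note <- if (nzchar(note)) paste(note, "+ alternation failure")
              else "alternation failure"
      ev <- alt_fail
    }
    if (walkish && (sum(st$side == "left") < 2 &&
                    sum(st$side == "right") < 2)) {
      raised <- TRUE; note <- "no full gait cycle"; ev <- n
    }
  }
  new_flag("STEP_DETECTION", raised, ev, "plausibility",
           cfg$alternation_tol, note)
}

#' Stand-up/sit-down phase flag
#'
#' Runs [detect_sas_phases()] and raises the flag when the segmentation
#' is incomplete or implausible: phase counts differing from the
#' expected 3 stand-up + 3 sit-down, non-alternating phases, or a final
#' phase cut off by the end of the recording.
#'
#' @inheritParams flag_duration
#' @return A `qc_flag`.
#' @export
flag_updown_phase <- function(rec, cfg = flag_config()) {
  check_flag_task(rec, "UP_DOWN_PHASE")
  ph <- detect_sas_phases(rec)
  n_up <- sum(ph$kind == "stand_up")
  n_down <- sum(ph$kind == "sit_down")
  incomplete <- nrow(ph) > 0 && any(!ph$complete)
  alt_ok <- nrow(ph) < 2 ||
    all(ph$kind[-1] != ph$kind[-nrow(ph)])
  raised <- n_up != 3 || n_down != 3 || incomplete || !alt_ok
  note <- c(if (n_up != 3 || n_down != 3)
              sprintf("expected 3+3 phases, got %d up + %d down", n_up, n_down),
            if (incomplete) "final phase incomplete",
            if (!alt_ok) "phases do not alternate")
  new_flag("UP_DOWN_PHASE", raised, n_up + n_down, "count", 6,
           paste(note, collapse = "; "))
}

#' Run every applicable automated detector
#'
#' Applies all detectors applicable to the recording's task, in the fixed
#' order of [criterion_table()]. `SUPPORT` and `OTHER` have no automated
#' detector (support-object recognition is out of scope); they are always
#' returned unraised with note `"manual-only"` so rating sheets stay
#' complete. `DISTURBANCES` is skipped when the recording has no depth
#' stream.
#'
#' @inheritParams flag_duration
#' @return A list of `qc_flag` objects, class `qc_flags`.
#' @export
run_autoflag <- function(rec, cfg = flag_config()) {
  task <- rec$metadata$task
  out <- list()
  for (crit in criterion_codes()) {
    if (!criterion_applies(crit, task)) next
    fl <- switch(crit,
      DISTURBANCES = if (!is.null(rec$depth) && length(rec$depth$t))
        flag_disturbances(rec, cfg) else NULL,
      DURATION = flag_duration(rec, cfg),
      STEP_DETECTION = flag_step_detection(rec, cfg),
      UP_DOWN_PHASE = flag_updown_phase(rec, cfg),
      ARMS = flag_arms_start(rec, cfg),
      BACKWARD = flag_backward(rec, cfg),
      FEET = flag_feet(rec, cfg),
      FORWARD = flag_forward(rec, cfg),
      MOVEMENTS = flag_movements(rec, cfg),
      SIDESTEP = flag_sidestep(rec, cfg),
      SUPPORT = new_flag("SUPPORT", FALSE, NA_real_, "", NA_real_,
                         "manual-only"),
      OTHER = new_flag("OTHER", FALSE, NA_real_, "", NA_real_,
                       "manual-only"))
    if (!is.null(fl)) out[[length(out) + 1L]] <- fl
  }
  structure(out, class = "qc_flags")
}

#' @export
print.qc_flags <- function(x, ...) {
  for (fl in x) print(fl)
  invisible(x)
}

#' Convert flags to a data frame
#'
#' @param x A `qc_flags` list.
#' @param recording_id Optional identifier column.
#' @param ... Unused.
#' @return Data frame with columns `recording_id` (if given), `criterion`,
#'   `category`, `raised`, `evidence`, `unit`, `threshold`, `note`.
#' @export
as.data.frame.qc_flags <- function(x, recording_id = NULL, ...) {
  df <- do.call(rbind, lapply(x, function(fl)
    data.frame(criterion = fl$criterion, category = fl$category,
               raised = fl$raised, evidence = fl$evidence, unit = fl$unit,
               threshold = fl$threshold, note = fl$note,
               stringsAsFactors = FALSE)))
  if (!is.null(recording_id))
    df <- cbind(recording_id = recording_id, df)
  df
}

signal_values <- function(ss, name) ss$signals[[name]]$value

first_valid <- function(x) x[which(!is.na(x))[1]]
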