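# Characteristic per-task signals.
#
# All signal definitions here are landmark-based quantities chosen to be
# the simplest ones consistent with what the QC figures display: the
# pelvis landmark is SpineBase, hands are HandLeft/HandRight, knees
# KneeLeft/KneeRight, ankles AnkleLeft/AnkleRight. Gaps where the source
# landmark's tracking confidence falls below `conf_threshold` are linearly
# interpolated up to `interp_max_s`, else left missing.

new_signal_set <- function(task, signals = list(), units = character(),
                           provenance = character()) {
  structure(list(task = task, signals = signals, units = units,
                 provenance = provenance), class = "qc_signal_set")
}

add_signal <- function(ss, name, t, value, unit, provenance) {
  ss$signals[[name]] <- data.frame(t = t, value = value)
  ss$units[[name]] <- unit
  ss$provenance[[name]] <- provenance
  ss
}

#' @export
print.qc_signal_set <- function(x, ...) {
  cat(sprintf("<qc_signal_set task=%s>\n", x$task))
  for (nm in names(x$signals))
    cat(sprintf("  %s [%s] (%d samples, from %s)\n", nm, x$units[[nm]],
                nrow(x$signals[[nm]]), x$provenance[[nm]]))
  invisible(x)
}

require_skeleton <- function(rec) {
  if (is.null(rec$skeleton) || !length(rec$skeleton$t))
    stop("this operation requires a non-empty skeleton stream",
         call. = FALSE)
}

# confidence-gated landmark coordinate with bounded interpolation
gated_series <- function(rec, name, axis, conf_threshold = 0.5,
                         interp_max_s = 0.5) {
  x <- landmark_xyz(rec, name)[, axis]
  conf <- landmark_conf(rec, name)
  x[conf < conf_threshold] <- NA_real_
  dt <- median_dt(rec$skeleton$t)
  if (is.na(dt)) return(x)
  fill_gaps(x, maxgap = max(1L, round(interp_max_s / dt)))
}

#' Subject position signals
#'
#' Overall subject positioning over time, from the pelvis landmark
#' (SpineBase): anterior-posterior distance from the camera `position_z`,
#' mediolateral position `position_x`, and vertical pelvis height
#' `position_y` (camera-frame, meters).
#'
#' @param rec A `qc_recording` with a non-empty skeleton stream.
#' @param conf_threshold Confidence below which samples are treated as
#'   missing (default 0.5).
#' @return A `qc_signal_set` with signals `position_z`, `position_x`,
#'   `position_y`.
#' @export
extract_position_signals <- function(rec, conf_threshold = 0.5) {
  require_skeleton(rec)
  t <- rec$skeleton$t
  ss <- new_signal_set(rec$metadata$task)
  for (ax in c(z = 3, x = 1, y = 2)) {
    nm <- paste0("position_", names(which(c(z = 3, x = 1, y = 2) == ax)))
    ss <- add_signal(ss, nm, t,
                     gated_series(rec, "SpineBase", ax, conf_threshold),
                     "m", "SpineBase")
  }
  ss
}

#' Knee-lift amplitude signals (stepping in place)
#'
#' Per-side knee lift: knee landmark height minus its 10th-percentile
#' baseline, in meters (non-negative up to noise).
#'
#' @inheritParams extract_position_signals
#' @return A `qc_signal_set` with `knee_amplitude_left` and
#'   `knee_amplitude_right`.
#' @export
extract_knee_amplitude <- function(rec, conf_threshold = 0.5) {
  require_skeleton(rec)
  if (rec$metadata$task != "SIP")
    stop_applicability("extract_knee_amplitude", rec$metadata$task, "SIP")
  t <- rec$skeleton$t
  ss <- new_signal_set("SIP")
  for (side in c("left", "right")) {
    nm <- paste0("Knee", if (side == "left") "Left" else "Right")
    y <- gated_series(rec, nm, 2, conf_threshold)
    base <- stats::quantile(y, 0.10, na.rm = TRUE, names = FALSE)
    ss <- add_signal(ss, paste0("knee_amplitude_", side), t, y - base,
                     "m", nm)
  }
  ss
}

#' Arm-sway signals
#'
#' Per-side hand displacement magnitude from its centered rolling 2 s
#' median (meters). The hand position is taken relative to the
#' SpineShoulder landmark, so the signal is exactly invariant to
#' whole-body translation (walking, sidesteps, chair transfers) and the
#' rolling median removes slow postural adjustment — what remains are
#' transient gestures.
#'
#' @inheritParams extract_position_signals
#' @param window_s Rolling-median window (seconds, default 2).
#' @return A `qc_signal_set` with `arm_sway_left` and `arm_sway_right`.
#' @export
extract_arm_sway <- function(rec, conf_threshold = 0.5, window_s = 2) {
  require_skeleton(rec)
  t <- rec$skeleton$t
  dt <- median_dt(t)
  k <- if (is.na(dt)) 1L else odd_window(window_s, dt, length(t))
  ref <- landmark_xyz(rec, "SpineShoulder")
  ss <- new_signal_set(rec$metadata$task)
  for (side in c("left", "right")) {
    nm <- paste0("Hand", if (side == "left") "Left" else "Right")
    xyz <- landmark_xyz(rec, nm)
    conf <- landmark_conf(rec, nm)
    dev2 <- 0
    for (ax in 1:3) {
      x <- xyz[, ax] - ref[, ax]
      x[conf < conf_threshold] <- NA_real_
      x <- fill_gaps(x, maxgap = max(1L, round(0.5 / max(dt, 1e-6))))
      med <- roll_median(ifelse(is.na(x), stats::median(x, na.rm = TRUE), x), k)
      dev2 <- dev2 + (x - med)^2
    }
    ss <- add_signal(ss, paste0("arm_sway_", side), t, sqrt(dev2), "m", nm)
  }
  ss
}

#' Detect steps from per-side leg lifts
#'
#' Peak-based step detection: for each side, the lift signal (ankle
#' height for walks, knee height for stepping in place, relative to its
#' 10th-percentile baseline) is scanned for excursions above the
#' amplitude gate `gate_m`; excursions closer than `min_interval_s` are
#' merged into one lift. Each lift's peak is its maximum; the contact is
#' placed at the downward crossing to 20% of the peak height following
#' the lift; the stance phase extends from a contact to the same side's
#' next lift onset.
#'
#' @inheritParams extract_position_signals
#' @param gate_m Minimum lift amplitude (m, default 0.05).
#' @param min_interval_s Minimum interval between same-side lifts
#'   (s, default 0.25).
#' @return Data frame of class `qc_steps`: `t_contact`, `side`,
#'   `stance_start`, `stance_end` (NA where no stance bound exists),
#'   time-ordered.
#' @export
detect_steps <- function(rec, gate_m = 0.05, min_interval_s = 0.25,
                         conf_threshold = 0.5) {
  require_skeleton(rec)
  task <- rec$metadata$task
  ok <- c("SCSW", "SMSW", "SLW", "SIP")
  if (!task %in% ok) stop_applicability("detect_steps", task, ok)
  src <- if (task == "SIP") "Knee" else "Ankle"
  t <- rec$skeleton$t
  dt <- median_dt(t)
  if (is.na(dt)) return(empty_steps())
  out <- list()
  for (side in c("left", "right")) {
    nm <- paste0(src, if (side == "left") "Left" else "Right")
    y <- gated_series(rec, nm, 2, conf_threshold)
    if (!any(is.finite(y))) next   # tracking fully lost on this side
    y[is.na(y)] <- stats::median(y, na.rm = TRUE)
    sgl <- y - stats::quantile(y, 0.10, names = FALSE)
    regions <- gate_regions(sgl, gate_m,
                            max(1L, round(min_interval_s / dt)))
    if (!nrow(regions)) next
    for (i in seq_len(nrow(regions))) {
      i0 <- regions$start[i]; i1 <- regions$end[i]
      ip <- i0 + which.max(sgl[i0:i1]) - 1L
      height <- sgl[ip]
      # contact: first drop below 20% of the lift height after the peak
      after <- which(sgl[ip:length(sgl)] < 0.2 * height)
      ic <- if (length(after)) ip + after[1] - 1L else length(sgl)
      # stance lasts until the same side's next lift onset
      onset <- if (i < nrow(regions)) t[regions$start[i + 1]] else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        t_contact = t[ic], side = side,
        stance_start = t[ic], stance_end = onset,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_steps())
  res <- do.call(rbind, out)
  res <- res[order(res$t_contact), ]
  rownames(res) <- NULL
  class(res) <- c("qc_steps", "data.frame")
  res
}

empty_steps <- function() {
  res <- data.frame(t_contact = numeric(), side = character(),
                    stance_start = numeric(), stance_end = numeric(),
                    stringsAsFactors = FALSE)
  class(res) <- c("qc_steps", "data.frame")
  res
}

#' Segment stand-up / sit-down phases
#'
#' Threshold-crossing segmentation of the pelvis height signal: the
#' seated and standing plateaus are estimated as the lower and upper 25%
#' of the per-recording height range; a `stand_up` phase is a rise from
#' below the seated bound to above the standing bound (`sit_down`
#' symmetric). A transition still in progress when the recording ends is
#' returned with `end` at the recording end and `complete = FALSE`. A
#' near-constant height signal (range below `min_range_m`) yields zero
#' segments.
#'
#' @inheritParams extract_position_signals
#' @param min_range_m Minimum height range for segmentation (m).
#' @return Data frame of class `qc_phases`: `kind` (`stand_up` /
#'   `sit_down`), `start`, `end`, `complete`; non-overlapping and
#'   time-ordered.
#' @export
detect_sas_phases <- function(rec, min_range_m = 0.15,
                              conf_threshold = 0.5) {
  require_skeleton(rec)
  task <- rec$metadata$task
  if (task != "SAS") stop_applicability("detect_sas_phases", task, "SAS")
  t <- rec$skeleton$t
  dt <- median_dt(t)
  y <- gated_series(rec, "SpineBase", 2, conf_threshold)
  y[is.na(y)] <- stats::median(y, na.rm = TRUE)
  y <- roll_median(y, odd_window(0.3, dt, length(y)))
  r <- max(y) - min(y)
  empty <- data.frame(kind = character(), start = numeric(),
                      end = numeric(), complete = logical())
  class(empty) <- c("qc_phases", "data.frame")
  if (!is.finite(r) || r < min_range_m) return(empty)
  lo <- min(y) + 0.25 * r
  hi <- max(y) - 0.25 * r
  # state: -1 seated (below lo), +1 standing (above hi), 0 in transit
  segs <- list()
  state <- if (y[1] <= lo) -1L else if (y[1] >= hi) 1L else 0L
  t_leave <- t[1]
  for (i in seq_along(y)[-1]) {
    cur <- if (y[i] <= lo) -1L else if (y[i] >= hi) 1L else 0L
    if (cur == state) next
    if (state != 0L && cur == 0L) {
      from <- state; t_leave <- t[i - 1]
      state <- 0L
      attr(t_leave, "from") <- from
    } else if (cur != 0L) {
      from <- attr(t_leave, "from") %||% (-cur)
      if (cur != from) {  # completed a transition
        segs[[length(segs) + 1L]] <- data.frame(
          kind = if (cur == 1L) "stand_up" else "sit_down",
          start = as.numeric(t_leave), end = t[i], complete = TRUE,
          stringsAsFactors = FALSE)
      }
      state <- cur
    }
  }
  if (state == 0L) {  # recording ends mid-transition
    from <- attr(t_leave, "from") %||% -1L
    segs[[length(segs) + 1L]] <- data.frame(
      kind = if (from == -1L) "stand_up" else "sit_down",
      start = as.numeric(t_leave), end = t[length(t)], complete = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(segs)) return(empty)
  res <- do.call(rbind, segs)
  class(res) <- c("qc_phases", "data.frame")
  res
}

#' Stance-width time series
#'
#' Horizontal (x-z plane) separation of the two ankle landmarks over
#' time, in meters. Used to check the closed-feet requirement of the
#' postural-control tasks.
#'
#' @inheritParams extract_position_signals
#' @return A `qc_signal_set` with one signal `stance_width`.
#' @export
compute_stance_width <- function(rec, conf_threshold = 0.5) {
  require_skeleton(rec)
  task <- rec$metadata$task
  ok <- c("POCO", "POCO_DUAL")
  if (!task %in% ok) stop_applicability("compute_stance_width", task, ok)
  t <- rec$skeleton$t
  xl <- gated_series(rec, "AnkleLeft", 1, conf_threshold)
  zl <- gated_series(rec, "AnkleLeft", 3, conf_threshold)
  xr <- gated_series(rec, "AnkleRight", 1, conf_threshold)
  zr <- gated_series(rec, "AnkleRight", 3, conf_threshold)
  w <- sqrt((xl - xr)^2 + (zl - zr)^2)
  ss <- new_signal_set(task)
  add_signal(ss, "stance_width", t, w, "m", "AnkleLeft, AnkleRight")
}

#' Extract all characteristic signals for a recording's task
#'
#' Dispatcher returning the union of signals applicable to the task:
#' * POCO / POCO_DUAL: positions, stance width, arm sway;
#' * SIP: knee amplitudes, arm sway, positions;
#' * SCSW / SMSW / SLW: positions, with detected step events attached as
#'   attribute `"steps"`;
#' * SAS: positions (pelvis height), arm sway, with detected phases
#'   attached as attribute `"phases"`.
#'
#' @inheritParams extract_position_signals
#' @return A `qc_signal_set`.
#' @export
extract_task_signals <- function(rec, conf_threshold = 0.5) {
  require_skeleton(rec)
  task <- rec$metadata$task
  pos <- extract_position_signals(rec, conf_threshold)
  merge_ss <- function(a, b) {
    for (nm in names(b$signals)) {
      a$signals[[nm]] <- b$signals[[nm]]
      a$units[[nm]] <- b$units[[nm]]
      a$provenance[[nm]] <- b$provenance[[nm]]
    }
    a
  }
  ss <- pos
  if (task %in% c("POCO", "POCO_DUAL")) {
    ss <- merge_ss(ss, compute_stance_width(rec, conf_threshold))
    ss <- merge_ss(ss, extract_arm_sway(rec, conf_threshold))
  } else if (task == "SIP") {
    ss <- merge_ss(ss, extract_knee_amplitude(rec, conf_threshold))
    ss <- merge_ss(ss, extract_arm_sway(rec, conf_threshold))
  } else if (task %in% c("SCSW", "SMSW", "SLW")) {
    attr(ss, "steps") <- detect_steps(rec, conf_threshold = conf_threshold)
  } else if (task == "SAS") {
    ss <- merge_ss(ss, extract_arm_sway(rec, conf_threshold))
    attr(ss, "phases") <- detect_sas_phases(rec,
                                            conf_threshold = conf_threshold)
  }
  ss
}

#' Export a signal set as tidy CSV
#'
#' One row per sample: `recording_id`, `signal`, `t`, `value`, `unit`.
#'
#' @param ss A `qc_signal_set`.
#' @param recording_id Identifier written to every row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_signals_csv <- function(ss, recording_id, path) {
  rows <- lapply(names(ss$signals), function(nm) {
    s <- ss$signals[[nm]]
    data.frame(recording_id = recording_id, signal = nm, t = s$t,
               value = s$value, unit = ss$units[[nm]],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
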