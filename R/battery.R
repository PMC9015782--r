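#' Defect-battery specification
#'
#' The validation battery pairs every automatically detectable defect
#' kind with every task it applies to, at a magnitude of twice the
#' corresponding detector threshold (count- and time-valued defects use
#' the equivalent super-threshold dose documented per row). Depth-based
#' defects (clothing/floor noise) are simulated with a rendered depth
#' stream; all others are skeleton-only.
#'
#' @param cfg A [flag_config()] supplying the thresholds the doses are
#'   derived from.
#' @return Data frame: `task`, `kind`, `magnitude`, `criterion` (the
#'   criterion the defect must raise), `needs_depth`.
#' @export
battery_spec <- function(cfg = flag_config()) {
  rows <- list()
  add <- function(task, kind, magnitude) {
    rows[[length(rows) + 1L]] <<- data.frame(
      task = task, kind = kind, magnitude = magnitude,
      criterion = defect_criterion(kind, task),
      needs_depth = kind %in% c("clothing_noise", "floor_noise"),
      stringsAsFactors = FALSE)
  }
  add("SIP", "forward_drift", 2 * cfg$forward_m)
  add("SIP", "backward_drift", 2 * cfg$backward_m)
  for (task in c("POCO", "POCO_DUAL", "SLW"))
    add(task, "sidestep", 2 * cfg$sidestep_m)
  for (task in c("POCO", "POCO_DUAL"))
    add(task, "open_feet", 2 * cfg$feet_width_m)
  for (task in c("POCO", "POCO_DUAL", "SLW", "SIP", "SAS"))
    add(task, "arm_movement", 2 * cfg$movement_excursion_m)
  add("SAS", "arms_not_down_at_start", 2 * cfg$arms_height_tol_m)
  for (task in task_codes()) {
    add(task, "clothing_noise", 2 * cfg$noise_fraction)
    add(task, "floor_noise", 2 * cfg$noise_fraction)
  }
  for (task in c("POCO", "POCO_DUAL", "SIP"))
    add(task, "truncated_duration", 2 * cfg$duration_tol_s)
  add("SAS", "truncated_duration", 3)        # cuts the final sit-down
  for (task in c("SCSW", "SMSW", "SLW")) {
    dur <- simulation_config(task)$duration_s
    add(task, "truncated_duration", dur - 0.9)  # leaves < 1 gait cycle
  }
  add("SIP", "extra_steps", 6)               # ~30% broken transitions
  for (task in c("SCSW", "SMSW", "SLW")) add(task, "extra_steps", 1)
  add("SIP", "missing_steps", 10)            # ~35% broken transitions
  for (task in c("SCSW", "SMSW", "SLW")) add(task, "missing_steps", 2)
  do.call(rbind, rows)
}

battery_sim_config <- function(task, seed, render_depth,
                               depth_width = 96, depth_height = 80,
                               depth_fps = 3) {
  simulation_config(task, seed = seed, render_depth = render_depth,
                    depth_width = depth_width, depth_height = depth_height,
                    depth_fps = depth_fps)
}

#' Run the defect-recovery battery
#'
#' End-to-end validation of the automated detectors on simulated ground
#' truth: for every (task, defect) pair of [battery_spec()], `n_seeds`
#' recordings are simulated with the defect at its super-threshold dose
#' and flagged with the default configuration; `n_clean` clean
#' recordings per task measure the false-positive rate. Per criterion:
#'
#' * recall — fraction of defect recordings whose expected criterion was
#'   raised;
#' * precision — raised flags that correspond to an injected defect,
#'   over all raised flags of that criterion (a step-detection flag on a
#'   clothing-noise recording is treated as the documented
#'   noise-to-step-detection coupling, not a false positive);
#' * false-positive rate — raised flags per applicable criterion
#'   evaluation on clean recordings.
#'
#' Depth-dependent cases use a reduced depth resolution (96 x 80 at
#' 3 Hz); the disturbance statistic is a resolution-independent pixel
#' fraction.
#'
#' @param n_seeds Defect recordings per (task, defect) pair.
#' @param n_clean Clean recordings per task.
#' @param seed Base seed; each simulation derives its own deterministic
#'   seed below 2^31.
#' @param cfg A [flag_config()].
#' @param progress Print one line per battery row?
#' @return List with `per_criterion` (data frame: criterion, tp, fn, fp,
#'   recall, precision), `clean` (data frame: task-level false-positive
#'   counts), `fp_rate` (overall clean false-positive rate), and the raw
#'   `results` rows.
#' @export
run_defect_battery <- function(n_seeds = 50, n_clean = 20, seed = 20260101,
                               cfg = flag_config(), progress = FALSE) {
  spec <- battery_spec(cfg)
  results <- list()
  rid <- 0L
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    if (progress)
      message(sprintf("battery: %s + %s (n=%d)", row$task, row$kind, n_seeds))
    for (s in seq_len(n_seeds)) {
      rid <- rid + 1L
      sim_seed <- (seed + 7919L * rid) %% .Machine$integer.max
      sim <- simulate_recording(
        battery_sim_config(row$task, sim_seed, row$needs_depth),
        list(defect(row$kind, row$magnitude)))
      flags <- run_autoflag(sim$recording, cfg)
      fdf <- as.data.frame(flags)
      results[[rid]] <- data.frame(
        task = row$task, kind = row$kind, expected = row$criterion,
        criterion = fdf$criterion, raised = fdf$raised,
        stringsAsFactors = FALSE)
    }
  }
  clean_rows <- list()
  for (task in task_codes()) {
    for (s in seq_len(n_clean)) {
      rid <- rid + 1L
      sim_seed <- (seed + 7919L * rid) %% .Machine$integer.max
      sim <- simulate_recording(
        battery_sim_config(task, sim_seed, render_depth = TRUE), list())
      fdf <- as.data.frame(run_autoflag(sim$recording, cfg))
      clean_rows[[length(clean_rows) + 1L]] <- data.frame(
        task = task, criterion = fdf$criterion, raised = fdf$raised,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, results)
  clean <- if (length(clean_rows)) do.call(rbind, clean_rows) else
    data.frame(task = character(), criterion = character(),
               raised = logical())

  detectable <- setdiff(criterion_codes(), c("SUPPORT", "OTHER"))
  per <- lapply(detectable, function(cc) {
    pos <- res[res$expected == cc & res$criterion == cc, ]
    tp <- sum(pos$raised); fn <- sum(!pos$raised)
    # false positives: criterion raised where its defect was not injected
    # and no documented coupling explains it
    oth <- res[res$expected != cc & res$criterion == cc, ]
    coupled <- cc == "STEP_DETECTION" &
      oth$kind %in% c("clothing_noise", "floor_noise")
    fp <- sum(oth$raised & !coupled) +
      sum(clean$raised[clean$criterion == cc])
    data.frame(criterion = cc, tp = tp, fn = fn, fp = fp,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  fp_rate <- if (nrow(clean)) mean(clean$raised) else NA_real_
  list(per_criterion = per,
       clean = if (nrow(clean))
         stats::aggregate(raised ~ task, clean, mean)
       else clean,
       fp_rate = fp_rate, results = res)
}
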