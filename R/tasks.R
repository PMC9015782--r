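#' Motor task definitions
#'
#' The QC pipeline covers seven short structured motor tasks recorded with a
#' consumer depth camera: two quiet-stance postural-control tasks (POCO and
#' its dual-task variant POCO_DUAL), three short walks toward the camera
#' (comfortable speed SCSW, maximum speed SMSW, and the slow line walk SLW),
#' stepping in place (SIP) and repeated stand-up-and-sit-down cycles (SAS).
#' POCO, POCO_DUAL and SIP have a nominal recording duration of 40 seconds;
#' walks and SAS run until the task is completed.
#'
#' @return A data frame with one row per task: `code`, `nominal_duration_s`
#'   (`NA` where no nominal duration exists) and `is_static`.
#' @export
#' @examples
#' task_table()
task_table <- function() {
  data.frame(
    code = c("POCO", "POCO_DUAL", "SCSW", "SMSW", "SLW", "SIP", "SAS"),
    nominal_duration_s = c(40, 40, NA, NA, NA, 40, NA),
    is_static = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname task_table
#' @export
task_codes <- function() task_table()$code

assert_task <- function(task) {
  if (!is.character(task) || length(task) != 1L || !task %in% task_codes())
    stop("unknown task code: ", paste(task, collapse = ", "),
         " (expected one of ", paste(task_codes(), collapse = ", "), ")",
         call. = FALSE)
  task
}

#' Canonical landmark names
#'
#' The 25 skeleton landmarks tracked by Kinect-v2-class sensors, in the
#' fixed order used throughout the package (index 1 = SpineBase). All
#' skeleton arrays and the on-disk `skeleton.csv` follow this order.
#'
#' @return Character vector of length 25.
#' @export
landmark_names <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft",
    "HandTipRight", "ThumbRight")
}

LM <- local({
  n <- c("SpineBase", "SpineMid", "Neck", "Head",
         "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
         "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
         "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
         "HipRight", "KneeRight", "AnkleRight", "FootRight",
         "SpineShoulder", "HandTipLeft", "ThumbLeft",
         "HandTipRight", "ThumbRight")
  stats::setNames(seq_along(n), n)
})

#' Quality-criterion taxonomy
#'
#' The twelve-criterion quality taxonomy used for rating and automated
#' flagging. Each criterion is either a technical issue (sensor/signal
#' problems), a performance issue (subject or operator behaviour), or
#' either, and applies to a fixed subset of tasks:
#'
#' * `DISTURBANCES` (technical, all tasks): noisy background/floor/clothing
#'   signals.
#' * `DURATION` (technical; POCO, POCO_DUAL, SIP): recording duration
#'   deviating from the nominal 40 s by more than 1 s.
#' * `STEP_DETECTION` (technical; SCSW, SMSW, SIP, SLW): implausible step
#'   detection.
#' * `UP_DOWN_PHASE` (technical; SAS): incomplete or implausible
#'   stand-up/sit-down phase segmentation.
#' * `ARMS` (performance; SAS): arms not hanging down at recording start.
#' * `BACKWARD` (performance; SIP): moving backward by more than 50 cm or a
#'   deliberate backward correction.
#' * `FEET` (performance; POCO, POCO_DUAL): open or V-shaped feet position.
#' * `FORWARD` (performance; SIP): moving forward by more than 50 cm.
#' * `MOVEMENTS` (performance; POCO, POCO_DUAL, SLW, SIP, SAS):
#'   task-unassociated movements such as gesturing.
#' * `SIDESTEP` (performance; POCO, POCO_DUAL, SLW): one or more sidesteps.
#' * `SUPPORT` (performance, all tasks): use of a support object
#'   (manual rating only).
#' * `OTHER` (either, all tasks): anything not covered above
#'   (manual rating only).
#'
#' @return Data frame with columns `code`, `category` and `applicable_tasks`
#'   (list column of task codes).
#' @export
#' @examples
#' criterion_table()
criterion_table <- function() {
  all_tasks <- task_codes()
  tab <- list(
    DISTURBANCES   = list("technical",   all_tasks),
    DURATION       = list("technical",   c("POCO", "POCO_DUAL", "SIP")),
    STEP_DETECTION = list("technical",   c("SCSW", "SMSW", "SIP", "SLW")),
    UP_DOWN_PHASE  = list("technical",   "SAS"),
    ARMS           = list("performance", "SAS"),
    BACKWARD       = list("performance", "SIP"),
    FEET           = list("performance", c("POCO", "POCO_DUAL")),
    FORWARD        = list("performance", "SIP"),
    MOVEMENTS      = list("performance", c("POCO", "POCO_DUAL", "SLW", "SIP", "SAS")),
    SIDESTEP       = list("performance", c("POCO", "POCO_DUAL", "SLW")),
    SUPPORT        = list("performance", all_tasks),
    OTHER          = list("either",      all_tasks)
  )
  data.frame(
    code = names(tab),
    category = vapply(tab, function(x) x[[1]], ""),
    applicable_tasks = I(lapply(tab, function(x) x[[2]])),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname criterion_table
#' @export
criterion_codes <- function() criterion_table()$code

#' Criteria applicable to a task
#'
#' @param task Task code (see [task_table()]).
#' @return Character vector of criterion codes applicable to `task`, in
#'   taxonomy order.
#' @export
applicable_criteria <- function(task) {
  assert_task(task)
  tab <- criterion_table()
  tab$code[vapply(tab$applicable_tasks, function(ts) task %in% ts, TRUE)]
}

criterion_applies <- function(criterion, task) {
  tab <- criterion_table()
  i <- match(criterion, tab$code)
  if (is.na(i)) stop("unknown criterion code: ", criterion, call. = FALSE)
  task %in% tab$applicable_tasks[[i]]
}
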