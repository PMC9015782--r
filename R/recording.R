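#' Construct a recording object
#'
#' A recording bundles the metadata of one motor-task trial with up to two
#' synchronized streams: a 25-landmark skeleton time series and a stack of
#' 16-bit depth frames (millimeters, 0 = invalid/no return). At least one
#' stream must be non-empty. Coordinates follow a right-handed camera frame:
#' x lateral (subject's left positive as seen by the camera), y up (origin
#' at the camera's optical center), z distance from the camera; skeleton in
#' meters, depth pixels in millimeters.
#'
#' @param metadata List as returned by [recording_metadata()].
#' @param skeleton `NULL`, or a list with `t` (numeric timestamps, seconds,
#'   strictly increasing), `xyz` (array `n x 25 x 3`, dimnames
#'   `landmark_names()` and `c("x","y","z")`), and `conf` (matrix `n x 25`
#'   of tracking confidences in `[0, 1]`).
#' @param depth `NULL`, or a list with `t` (numeric timestamps) and `frames`
#'   (list of integer matrices of constant dimensions, values >= 0 in mm).
#' @return An object of class `qc_recording` with fields `metadata`,
#'   `skeleton`, `depth` and `duration_s` (last timestamp of the longer
#'   stream).
#' @seealso [validate_recording()], [write_recording()], [read_recording()]
#' @export
new_recording <- function(metadata, skeleton = NULL, depth = NULL) {
  dur <- suppressWarnings(max(
    if (!is.null(skeleton) && length(skeleton$t)) max(skeleton$t) else -Inf,
    if (!is.null(depth) && length(depth$t)) max(depth$t) else -Inf))
  rec <- structure(
    list(metadata = metadata, skeleton = skeleton, depth = depth,
         duration_s = if (is.finite(dur)) dur else NA_real_),
    class = "qc_recording")
  issues <- validate_recording(rec)
  if (length(issues))
    stop("invalid recording: ", paste(issues, collapse = "; "), call. = FALSE)
  rec
}

#' @rdname new_recording
#' @param recording_id,subject_id Identifier strings.
#' @param task Task code, see [task_table()].
#' @param group Subject group: `"HC"`, `"PwMS"` or `"synthetic"`.
#' @param frame_rate_hz Nominal sensor frame rate (Hz), must be positive.
#' @param operator_comment,study_site Free text (may be empty).
#' @export
recording_metadata <- function(recording_id, subject_id, task,
                               group = "synthetic", frame_rate_hz = 30,
                               operator_comment = "", study_site = "") {
  list(recording_id = as.character(recording_id),
       subject_id = as.character(subject_id),
       group = group, task = task,
       frame_rate_hz = frame_rate_hz,
       operator_comment = as.character(operator_comment),
       study_site = as.character(study_site))
}

#' Validate a recording against its invariants
#'
#' Total function: returns a character vector of human-readable issues, one
#' per violated invariant, or an empty vector when the recording is valid.
#' Checked invariants: known task code and valid group; positive frame rate;
#' at least one non-empty stream; strictly increasing timestamps per stream;
#' exactly 25 landmarks with finite coordinates; tracked-landmark z within
#' (0, 8) m; confidences in `[0, 1]`; non-negative depth values of constant
#' dimensions.
#'
#' @param rec A `qc_recording` (or structurally similar list).
#' @return Character vector of issues (empty when valid).
#' @export
validate_recording <- function(rec) {
  issues <- character()
  add <- function(msg) issues <<- c(issues, msg)

  md <- rec$metadata
  if (is.null(md)) {
    add("metadata: missing")
  } else {
    if (!is.character(md$recording_id) || !nzchar(md$recording_id))
      add("metadata.recording_id: must be a non-empty string")
    if (!isTRUE(md$task %in% task_codes()))
      add(sprintf("metadata.task: unknown code '%s'", md$task))
    if (!isTRUE(md$group %in% c("HC", "PwMS", "synthetic")))
      add(sprintf("metadata.group: '%s' not in {HC, PwMS, synthetic}", md$group))
    if (!is.numeric(md$frame_rate_hz) || length(md$frame_rate_hz) != 1L ||
        !is.finite(md$frame_rate_hz) || md$frame_rate_hz <= 0)
      add("metadata.frame_rate_hz: must be > 0")
  }

  sk <- rec$skeleton
  dp <- rec$depth
  n_sk <- if (is.null(sk)) 0L else length(sk$t)
  n_dp <- if (is.null(dp)) 0L else length(dp$t)
  if (n_sk == 0L && n_dp == 0L)
    add("streams: at least one of skeleton/depth must be non-empty")

  if (n_sk > 0L) {
    if (any(sk$t < 0)) add("skeleton.t: timestamps must be non-negative")
    if (n_sk > 1L && any(diff(sk$t) <= 0))
      add(sprintf("skeleton.t: timestamps not strictly increasing at row %d",
                  which(diff(sk$t) <= 0)[1] + 1L))
    d <- dim(sk$xyz)
    if (length(d) != 3L || d[1] != n_sk || d[2] != 25L || d[3] != 3L) {
      add(sprintf("landmarks: expected n x 25 x 3 array, got %s",
                  paste(d, collapse = " x ")))
    } else {
      bad <- which(!apply(is.finite(sk$xyz), 1, all))
      if (length(bad))
        add(sprintf("landmarks: non-finite coordinates at t=%.3f", sk$t[bad[1]]))
      z <- sk$xyz[, , 3, drop = FALSE]
      conf <- sk$conf
      if (is.null(conf) || !all(dim(conf) == c(n_sk, 25L))) {
        add("confidence: expected n x 25 matrix")
      } else {
        if (any(conf < 0 | conf > 1, na.rm = TRUE))
          add("confidence: values outside [0, 1]")
        tracked <- conf > 0
        zt <- z[cbind(which(tracked, arr.ind = TRUE),
                      rep(1L, sum(tracked)))]
        if (length(zt) && (any(zt <= 0) || any(zt >= 8)))
          add("landmarks: tracked landmark z outside (0, 8) m")
      }
    }
  }

  if (n_dp > 0L) {
    if (any(dp$t < 0)) add("depth.t: timestamps must be non-negative")
    if (n_dp > 1L && any(diff(dp$t) <= 0))
      add(sprintf("depth.t: timestamps not strictly increasing at frame %d",
                  which(diff(dp$t) <= 0)[1] + 1L))
    if (length(dp$frames) != n_dp) {
      add("depth: frame count does not match timestamp count")
    } else {
      dims <- vapply(dp$frames, dim, integer(2))
      if (n_dp > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
        add("depth: frame dimensions not constant within the recording")
      neg <- vapply(dp$frames, function(f) any(f < 0), TRUE)
      if (any(neg))
        add(sprintf("depth: negative depth value in frame %d", which(neg)[1]))
      big <- vapply(dp$frames, function(f) any(f > 65535), TRUE)
      if (any(big))
        add(sprintf("depth: value above 16-bit range in frame %d", which(big)[1]))
    }
  }

  issues
}

#' @export
print.qc_recording <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<qc_recording %s> task=%s group=%s duration=%.2fs\n",
              md$recording_id, md$task, md$group, x$duration_s))
  cat(sprintf("  skeleton: %d frames; depth: %d frames%s\n",
              if (is.null(x$skeleton)) 0L else length(x$skeleton$t),
              if (is.null(x$depth)) 0L else length(x$depth$t),
              if (is.null(x$depth) || !length(x$depth$t)) "" else
                sprintf(" (%d x %d)", nrow(x$depth$frames[[1]]),
                        ncol(x$depth$frames[[1]]))))
  invisible(x)
}

# pull a named landmark's coordinate series: returns matrix n x 3
landmark_xyz <- function(rec, name) {
  stopifnot(!is.null(rec$skeleton))
  rec$skeleton$xyz[, LM[[name]], , drop = TRUE]
}

landmark_conf <- function(rec, name) rec$skeleton$conf[, LM[[name]]]
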