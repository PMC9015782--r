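#' Write a recording to its on-disk container
#'
#' The container is a directory of plain-text/PNG files:
#' * `metadata.json` — UTF-8 JSON with the [recording_metadata()] fields
#'   plus `duration_s`.
#' * `skeleton.csv` — wide CSV, header row, '.' decimal: column `t`
#'   followed by `<Landmark>_x`, `_y`, `_z`, `_conf` for each of the 25
#'   landmarks in [landmark_names()] order. Omitted when the skeleton
#'   stream is empty.
#' * `depth/frame_%06d.png` — one 16-bit grayscale PNG per depth frame,
#'   pixel value = millimeters, 0 = invalid — plus `depth_index.csv`
#'   (`frame,timestamp_s`) mapping file to timestamp. Omitted when the
#'   depth stream is empty.
#'
#' The round trip [read_recording()]`(`[write_recording()]`(rec))` is the
#' identity: depth values bit-exact, skeleton values to better than 1e-6 m.
#'
#' @param rec A valid `qc_recording`.
#' @param path Directory to create (must be creatable; existing files are
#'   overwritten).
#' @return The path of `metadata.json`, invisibly.
#' @export
write_recording <- function(rec, path) {
  issues <- validate_recording(rec)
  if (length(issues))
    stop("refusing to write invalid recording: ",
         paste(issues, collapse = "; "), call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)

  md <- rec$metadata
  md$duration_s <- rec$duration_s
  meta_path <- file.path(path, "metadata.json")
  jsonlite::write_json(md, meta_path, auto_unbox = TRUE, digits = NA)

  sk <- rec$skeleton
  if (!is.null(sk) && length(sk$t)) {
    nm <- landmark_names()
    cols <- list(t = sk$t)
    for (i in seq_along(nm)) {
      cols[[paste0(nm[i], "_x")]] <- sk$xyz[, i, 1]
      cols[[paste0(nm[i], "_y")]] <- sk$xyz[, i, 2]
      cols[[paste0(nm[i], "_z")]] <- sk$xyz[, i, 3]
      cols[[paste0(nm[i], "_conf")]] <- sk$conf[, i]
    }
    df <- as.data.frame(cols, check.names = FALSE)
    utils::write.csv(df, file.path(path, "skeleton.csv"), row.names = FALSE)
  }

  dp <- rec$depth
  if (!is.null(dp) && length(dp$t)) {
    ddir <- file.path(path, "depth")
    dir.create(ddir, showWarnings = FALSE)
    files <- sprintf("frame_%06d.png", seq_along(dp$t))
    for (i in seq_along(dp$t))
      write_depth_png(dp$frames[[i]], file.path(ddir, files[i]))
    utils::write.csv(
      data.frame(frame = files, timestamp_s = dp$t),
      file.path(path, "depth_index.csv"), row.names = FALSE)
  }
  invisible(meta_path)
}

#' Read a recording from its on-disk container
#'
#' Inverse of [write_recording()]. A missing optional stream yields an
#' empty stream; format violations (missing `metadata.json`, wrong PNG bit
#' depth, non-monotone timestamps, malformed rows) raise errors naming the
#' offending file and row.
#'
#' @param path Container directory.
#' @return A `qc_recording`.
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("not a recording container (missing metadata.json): ", path,
         call. = FALSE)
  md <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  skeleton <- NULL
  sk_path <- file.path(path, "skeleton.csv")
  if (file.exists(sk_path)) {
    df <- utils::read.csv(sk_path, check.names = FALSE)
    nm <- landmark_names()
    want <- c("t", as.vector(t(outer(nm, c("_x", "_y", "_z", "_conf"),
                                     paste0))))
    missing <- setdiff(want, names(df))
    if (length(missing))
      stop("skeleton.csv: missing columns: ",
           paste(utils::head(missing, 4), collapse = ", "), call. = FALSE)
    t <- df$t
    if (length(t) > 1L && any(diff(t) <= 0))
      stop(sprintf("skeleton.csv: non-monotone timestamp at row %d",
                   which(diff(t) <= 0)[1] + 1L), call. = FALSE)
    n <- length(t)
    xyz <- array(NA_real_, c(n, 25L, 3L),
                 dimnames = list(NULL, nm, c("x", "y", "z")))
    conf <- matrix(NA_real_, n, 25L, dimnames = list(NULL, nm))
    for (i in seq_along(nm)) {
      xyz[, i, 1] <- df[[paste0(nm[i], "_x")]]
      xyz[, i, 2] <- df[[paste0(nm[i], "_y")]]
      xyz[, i, 3] <- df[[paste0(nm[i], "_z")]]
      conf[, i] <- df[[paste0(nm[i], "_conf")]]
    }
    skeleton <- list(t = t, xyz = xyz, conf = conf)
  }

  depth <- NULL
  idx_path <- file.path(path, "depth_index.csv")
  if (file.exists(idx_path)) {
    idx <- utils::read.csv(idx_path)
    if (!all(c("frame", "timestamp_s") %in% names(idx)))
      stop("depth_index.csv: expected columns frame, timestamp_s",
           call. = FALSE)
    t <- idx$timestamp_s
    if (length(t) > 1L && any(diff(t) <= 0))
      stop(sprintf("depth_index.csv: non-monotone timestamp at row %d",
                   which(diff(t) <= 0)[1] + 1L), call. = FALSE)
    frames <- lapply(file.path(path, "depth", idx$frame), read_depth_png)
    depth <- list(t = t, frames = frames)
  }

  new_recording(
    recording_metadata(
      recording_id = md$recording_id, subject_id = md$subject_id,
      task = md$task, group = md$group, frame_rate_hz = md$frame_rate_hz,
      operator_comment = md$operator_comment %||% "",
      study_site = md$study_site %||% ""),
    skeleton = skeleton, depth = depth)
}
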