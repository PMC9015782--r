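#' Condensed motion-profile images of a depth stream
#'
#' Condenses a recording's depth stack into three 2-D images:
#'
#' * `frontal` (height x width): per-pixel average over time — the
#'   time-collapsed silhouette;
#' * `top` (frames x width): per-frame average over the vertical image
#'   axis — a bird's-eye view of lateral position and distance over time
#'   (rows = time, increasing downward);
#' * `side` (frames x height): per-frame average over the horizontal
#'   image axis — a lateral view of vertical extent over time.
#'
#' Averages are arithmetic means over *valid* (nonzero) pixels only; a
#' pixel with no valid contributor is 0. `valid_fraction` gives, per
#' frontal pixel, the fraction of frames in which it was valid. With
#' `aggregate = "sum"` raw sums over valid pixels are returned instead of
#' means (the mean is the default because it is stable across recordings
#' of different length).
#'
#' @param rec A `qc_recording` with a non-empty depth stream.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Object of class `qc_motion_profile` with fields `frontal`,
#'   `top`, `side`, `valid_fraction`, `t` (frame timestamps) and
#'   `aggregate`. Units: millimeters (mean) or millimeter-sums.
#' @export
compute_motion_profiles <- function(rec, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  dp <- rec$depth
  if (is.null(dp) || !length(dp$t))
    stop("motion profiles require a non-empty depth stream", call. = FALSE)
  frames <- dp$frames
  nf <- length(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])

  sum_img <- matrix(0, h, w)
  cnt_img <- matrix(0L, h, w)
  top <- matrix(0, nf, w)
  side <- matrix(0, nf, h)
  for (k in seq_len(nf)) {
    f <- frames[[k]]
    v <- f > 0L
    sum_img <- sum_img + ifelse(v, as.numeric(f), 0)
    cnt_img <- cnt_img + v
    cs <- colSums(f * v); cn <- colSums(v)
    rs <- rowSums(f * v); rn <- rowSums(v)
    if (aggregate == "mean") {
      top[k, ] <- ifelse(cn > 0, cs / cn, 0)
      side[k, ] <- ifelse(rn > 0, rs / rn, 0)
    } else {
      top[k, ] <- cs
      side[k, ] <- rs
    }
  }
  frontal <- if (aggregate == "mean")
    ifelse(cnt_img > 0, sum_img / cnt_img, 0) else sum_img
  structure(list(frontal = frontal, top = top, side = side,
                 valid_fraction = cnt_img / nf, t = dp$t,
                 aggregate = aggregate),
            class = "qc_motion_profile")
}

# 1st-99th percentile contrast stretch of nonzero values, for display only
stretch01 <- function(m) {
  v <- m[m > 0]
  if (!length(v)) return(matrix(0, nrow(m), ncol(m)))
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  out <- (m - q[1]) / (q[2] - q[1])
  out[m == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

panel_image <- function(m, main, xlab = "", ylab = "") {
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  graphics::title(main = main, cex.main = 0.9)
  graphics::mtext(xlab, side = 1, line = 0.4, cex = 0.6)
  graphics::mtext(ylab, side = 2, line = 0.4, cex = 0.6)
  graphics::box()
}

#' Render the QC figure for one recording
#'
#' Writes a single PNG with the three motion-profile panels plus one
#' panel per characteristic signal. Styling is fixed and the file embeds
#' no timestamps, so rendering the same inputs twice yields byte-identical
#' files.
#'
#' @param mp A `qc_motion_profile` (or `NULL` if the recording has no
#'   depth stream; profile panels are then left blank).
#' @param sig A `qc_signal_set` (may contain zero signals).
#' @param meta Recording metadata (for the figure title).
#' @param out Output PNG path.
#' @param width,height Figure size in pixels.
#' @return `out`, invisibly.
#' @export
render_profile_figure <- function(mp, sig, meta, out,
                                  width = 1200, height = 800) {
  sig_names <- if (is.null(sig)) character() else names(sig$signals)
  n_panels <- 3L + length(sig_names)
  ncol <- 3L
  nrow <- ceiling(n_panels / ncol)
  grDevices::png(out, width = width, height = height * nrow / 2,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(nrow, ncol), mar = c(2.5, 2.5, 2, 0.8),
                oma = c(0, 0, 2.2, 0), mgp = c(1.4, 0.4, 0))
  if (!is.null(mp)) {
    panel_image(stretch01(mp$frontal), "frontal (time-averaged depth)",
                "x [px]", "y [px]")
    panel_image(stretch01(mp$top), "top (vertical average)",
                "x [px]", "time (down)")
    panel_image(stretch01(mp$side), "side (horizontal average)",
                "y [px]", "time (down)")
  } else {
    for (ttl in c("frontal", "top", "side")) {
      graphics::plot.new(); graphics::title(main = paste(ttl, "(no depth)"))
      graphics::box()
    }
  }
  for (nm in sig_names) {
    s <- sig$signals[[nm]]
    graphics::plot(s$t, s$value, type = "l", col = "steelblue4",
                   xlab = "t [s]",
                   ylab = sprintf("%s [%s]", nm, sig$units[[nm]]),
                   main = nm, cex.main = 0.9)
    ev <- attr(sig, "steps")
    if (!is.null(ev) && nrow(ev) && startsWith(nm, "position")) {
      graphics::abline(v = ev$t_contact, col = "tomato3", lty = 3)
    }
  }
  graphics::mtext(sprintf("%s  |  task %s", meta$recording_id, meta$task),
                  outer = TRUE, cex = 1.1, font = 2)
  invisible(out)
}

#' Export motion-profile arrays
#'
#' Writes each profile image as a 16-bit grayscale PNG plus a sidecar
#' JSON giving the value scale, so the raw arrays can be recovered.
#'
#' @param mp A `qc_motion_profile`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisible character vector of files written.
#' @export
export_profiles <- function(mp, dir, prefix = "profile") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  scales <- list()
  for (nm in c("frontal", "top", "side")) {
    m <- mp[[nm]]
    mx <- max(m)
    scale <- if (mx > 0) 65535 / mx else 1
    img <- matrix(as.integer(round(m * scale)), nrow(m), ncol(m))
    f <- file.path(dir, sprintf("%s_%s.png", prefix, nm))
    write_depth_png(img, f)
    files <- c(files, f)
    scales[[nm]] <- list(value_per_count = 1 / scale, unit =
      if (mp$aggregate == "mean") "mm" else "mm-sum")
  }
  jf <- file.path(dir, sprintf("%s_scale.json", prefix))
  jsonlite::write_json(scales, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}
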