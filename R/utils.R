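# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# odd window length (samples) covering `seconds` at sampling interval dt
odd_window <- function(seconds, dt, n) {
  k <- max(1L, round(seconds / dt))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (n %% 2L == 0L) n - 1L else n)
}

# median sampling interval of a timestamp vector
median_dt <- function(t) {
  if (length(t) < 2L) return(NA_real_)
  stats::median(diff(t))
}

# centered rolling median, endpoints handled by stats::runmed
roll_median <- function(x, k) {
  if (k <= 1L || length(x) < 3L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# linear interpolation of NAs up to maxgap samples; leading/trailing NAs kept
fill_gaps <- function(x, maxgap) {
  if (!anyNA(x)) return(x)
  as.numeric(zoo::na.approx(x, maxgap = maxgap, na.rm = FALSE))
}

# max range of x within any time window of w seconds (rate-limited excursion)
windowed_range_max <- function(t, x, w) {
  n <- length(t)
  if (n < 2L) return(0)
  out <- 0
  j <- 1L
  for (i in seq_len(n)) {
    while (t[i] - t[j] > w) j <- j + 1L
    seg <- x[j:i]
    r <- max(seg) - min(seg)
    if (r > out) out <- r
  }
  out
}

# contiguous runs where x > gate, merged when separated by < min_gap samples;
# returns data.frame(start, end) of sample indices
gate_regions <- function(x, gate, min_gap) {
  above <- x > gate
  if (!any(above)) return(data.frame(start = integer(), end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(reg) > 1L) {
    keep <- logical(nrow(reg)); keep[1] <- TRUE
    cur <- 1L
    for (i in 2:nrow(reg)) {
      if (reg$start[i] - reg$end[cur] < min_gap) {
        reg$end[cur] <- reg$end[i]
      } else {
        cur <- i
        keep[i] <- TRUE
      }
    }
    reg <- reg[keep, , drop = FALSE]
    reg$end <- pmin(reg$end, length(x))
    rownames(reg) <- NULL
  }
  reg
}

stop_applicability <- function(op, task, allowed) {
  stop(sprintf("%s is not applicable to task %s (applies to: %s)",
               op, task, paste(allowed, collapse = ", ")), call. = FALSE)
}
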