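#' Rating records
#'
#' One rating is a rater's overall usability decision for one recording —
#' `keep`, `discard` or `undecided` — plus any number of selected quality
#' criteria (multiselect), an optional free-text comment and an optional
#' rating duration. Ratings are kept in a plain data frame with columns
#' `recording_id`, `rater_id`, `task`, `decision`, `criteria`
#' (semicolon-joined criterion codes, may be empty), `comment`,
#' `rating_duration_s`.
#'
#' @param recording_id,rater_id Identifier strings.
#' @param task Task code of the rated recording.
#' @param decision `"keep"`, `"discard"` or `"undecided"`.
#' @param criteria Character vector of criterion codes applicable to the
#'   task (may be empty).
#' @param comment Free text.
#' @param rating_duration_s Seconds spent rating, or `NA`.
#' @return One-row ratings data frame.
#' @export
rating_record <- function(recording_id, rater_id, task, decision,
                          criteria = character(), comment = "",
                          rating_duration_s = NA_real_) {
  assert_task(task)
  if (!decision %in% c("keep", "discard", "undecided"))
    stop("decision must be keep, discard or undecided (got '",
         decision, "')", call. = FALSE)
  bad <- setdiff(criteria, criterion_codes())
  if (length(bad))
    stop("unknown criterion codes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  inapp <- criteria[!vapply(criteria, criterion_applies, TRUE, task = task)]
  if (length(inapp))
    stop(sprintf("criteria not applicable to task %s: %s", task,
                 paste(inapp, collapse = ", ")), call. = FALSE)
  data.frame(recording_id = as.character(recording_id),
             rater_id = as.character(rater_id), task = task,
             decision = decision,
             criteria = paste(criteria, collapse = ";"),
             comment = as.character(comment),
             rating_duration_s = rating_duration_s,
             stringsAsFactors = FALSE)
}

rating_columns <- c("recording_id", "rater_id", "task", "decision",
                    "criteria", "comment", "rating_duration_s")

validate_ratings <- function(df) {
  missing <- setdiff(rating_columns, names(df))
  if (length(missing))
    stop("rating sheet: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$task %in% task_codes())
      stop(sprintf("rating sheet row %d: unknown task '%s'", i, r$task),
           call. = FALSE)
    if (!r$decision %in% c("keep", "discard", "undecided"))
      stop(sprintf("rating sheet row %d: unknown decision '%s'", i,
                   r$decision), call. = FALSE)
    crits <- split_criteria(r$criteria)
    bad <- setdiff(crits, criterion_codes())
    if (length(bad))
      stop(sprintf("rating sheet row %d: unknown criterion '%s'", i,
                   bad[1]), call. = FALSE)
    inapp <- crits[!vapply(crits, criterion_applies, TRUE, task = r$task)]
    if (length(inapp))
      stop(sprintf("rating sheet row %d: criterion %s not applicable to task %s",
                   i, inapp[1], r$task), call. = FALSE)
  }
  invisible(df)
}

split_criteria <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Read and write rating sheets
#'
#' CSV with the documented header (see [rating_record()]). Loading
#' validates every row: unknown decisions or criterion codes, and
#' criteria not applicable to the row's task, are rejected with the row
#' number. Saving then loading reproduces the table.
#'
#' @param path CSV path.
#' @return `load_ratings()` returns the validated ratings data frame.
#' @export
load_ratings <- function(path) {
  if (!file.exists(path))
    stop("rating sheet not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rating_duration_s = "numeric"))
  df$criteria[is.na(df$criteria)] <- ""
  df$comment[is.na(df$comment)] <- ""
  validate_ratings(df)
  df[rating_columns]
}

#' @rdname load_ratings
#' @param records Ratings data frame.
#' @export
save_ratings <- function(records, path) {
  validate_ratings(records)
  utils::write.csv(records[rating_columns], path, row.names = FALSE)
  invisible(path)
}

#' Pair the ratings of two raters
#'
#' Inner-joins two raters' rating tables on `recording_id`. Recordings
#' rated by only one rater are excluded from concordance analysis and
#' reported in the `"unpaired"` attribute. A recording rated more than
#' once by the same rater is an error.
#'
#' @param a,b Ratings data frames (one rater each, or mixed tables
#'   containing exactly one rater each).
#' @return Data frame with `recording_id`, `task`, `decision_a`,
#'   `decision_b`, `criteria_a`, `criteria_b`; attribute `unpaired` lists
#'   ids seen on one side only.
#' @export
merge_rater_pair <- function(a, b) {
  for (side in list(a, b)) {
    key <- paste(side$recording_id, side$rater_id)
    if (anyDuplicated(key))
      stop("duplicate rating for recording ",
           side$recording_id[duplicated(key)][1], " by rater ",
           side$rater_id[duplicated(key)][1], call. = FALSE)
  }
  common <- intersect(a$recording_id, b$recording_id)
  ia <- match(common, a$recording_id)
  ib <- match(common, b$recording_id)
  out <- data.frame(recording_id = common,
                    task = a$task[ia],
                    decision_a = a$decision[ia],
                    decision_b = b$decision[ib],
                    criteria_a = a$criteria[ia],
                    criteria_b = b$criteria[ib],
                    stringsAsFactors = FALSE)
  attr(out, "unpaired") <- list(
    a_only = setdiff(a$recording_id, common),
    b_only = setdiff(b$recording_id, common))
  out
}

decision_levels <- c("keep", "discard", "undecided")

#' Rater-concordance summary for one task
#'
#' Builds the 3x3 confusion matrix of the two raters' usability
#' decisions and derives the headline rates. By default the raters are
#' treated as interchangeable, so the off-diagonal cells pool the two
#' orders (`ordered = TRUE` keeps them separate). All rates are
#' percentages of the paired recordings `n`:
#'
#' * `concordance_pct` — identical decisions (matrix trace / n);
#' * `unanimous_keep_pct`, `unanimous_discard_pct`,
#'   `unanimous_undecided_pct` — the diagonal cells (they sum to the
#'   concordance);
#' * `strict_disagreement_pct` — keep-vs-discard pairs only;
#' * `undecided_involved_pct` — discordant pairs in which at least one
#'   decision is undecided (with `strict_disagreement_pct` this accounts
#'   for all discordance).
#'
#' @param paired Output of [merge_rater_pair()].
#' @param task Task code to summarize.
#' @param ordered Keep rater order in the confusion matrix?
#' @return A list of class `qc_concordance` with fields `task`, `n`,
#'   `confusion` and the rates above (exact fractions internally;
#'   percentages unrounded).
#' @export
concordance_summary <- function(paired, task, ordered = FALSE) {
  assert_task(task)
  p <- paired[paired$task == task, , drop = FALSE]
  n <- nrow(p)
  if (n == 0L)
    stop("no paired ratings for task ", task, call. = FALSE)
  da <- factor(p$decision_a, decision_levels)
  db <- factor(p$decision_b, decision_levels)
  conf <- table(rater_a = da, rater_b = db)
  if (!ordered) {
    m <- matrix(0L, 3, 3, dimnames = dimnames(conf))
    for (i in 1:3) for (j in 1:3) {
      if (i <= j) m[i, j] <- conf[i, j] + if (i < j) conf[j, i] else 0L
    }
    conf <- m
  }
  trace <- sum(diag(conf))
  strict <- if (ordered) conf["keep", "discard"] + conf["discard", "keep"]
            else conf["keep", "discard"]
  undec_inv <- n - trace - strict
  structure(list(
    task = task, n = n, confusion = conf, ordered = ordered,
    concordance_pct = 100 * trace / n,
    unanimous_keep_pct = 100 * conf["keep", "keep"] / n,
    unanimous_discard_pct = 100 * conf["discard", "discard"] / n,
    unanimous_undecided_pct = 100 * conf["undecided", "undecided"] / n,
    strict_disagreement_pct = 100 * strict / n,
    undecided_involved_pct = 100 * undec_inv / n),
    class = "qc_concordance")
}

#' @export
print.qc_concordance <- function(x, ...) {
  cat(sprintf("<qc_concordance task=%s n=%d>\n", x$task, x$n))
  print(x$confusion)
  cat(sprintf(
    "  concordance %.1f%% (keep %.1f%%, discard %.1f%%, undecided %.1f%%)\n",
    x$concordance_pct, x$unanimous_keep_pct, x$unanimous_discard_pct,
    x$unanimous_undecided_pct))
  cat(sprintf("  strict disagreement %.1f%%, undecided-involved %.1f%%\n",
              x$strict_disagreement_pct, x$undecided_involved_pct))
  invisible(x)
}

#' Criterion selection frequencies
#'
#' Per task and criterion: the percentage of ratings of that task in
#' which the criterion was selected (the denominator is the number of
#' ratings, since selections are multiselect their frequencies may sum
#' to more than 100%). Optionally split by a `group` column in the
#' ratings table; the pooled frequency is then the denominator-weighted
#' mean of the group frequencies.
#'
#' @param ratings Ratings data frame (optionally with a `group` column).
#' @param by_group Split by `ratings$group`?
#' @return Data frame `task`, `criterion`, `group` (`"all"` for the
#'   pooled rows), `n_ratings`, `n_selected`, `frequency_pct`.
#' @export
criterion_frequencies <- function(ratings, by_group = FALSE) {
  if (by_group && is.null(ratings$group))
    stop("by_group = TRUE requires a 'group' column", call. = FALSE)
  groups <- if (by_group) unique(ratings$group) else character()
  out <- list()
  tally <- function(sub, task, group) {
    rows <- sub[sub$task == task, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    crits <- applicable_criteria(task)
    sel <- vapply(crits, function(cc)
      sum(vapply(rows$criteria, function(s) cc %in% split_criteria(s), TRUE)),
      integer(1))
    data.frame(task = task, criterion = crits, group = group,
               n_ratings = nrow(rows), n_selected = as.integer(sel),
               frequency_pct = 100 * sel / nrow(rows),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  for (task in intersect(task_codes(), unique(ratings$task))) {
    out[[length(out) + 1L]] <- tally(ratings, task, "all")
    for (g in groups)
      out[[length(out) + 1L]] <-
        tally(ratings[ratings$group == g, , drop = FALSE], task, g)
  }
  do.call(rbind, out)
}

#' Median rating duration
#'
#' Median over all records carrying a rating duration; with an even
#' count, the mean of the central pair. Errors when no record has a
#' duration.
#'
#' @param ratings Ratings data frame.
#' @return Median duration in seconds.
#' @export
median_rating_duration <- function(ratings) {
  d <- ratings$rating_duration_s
  d <- d[!is.na(d)]
  if (!length(d))
    stop("no rating records carry a duration", call. = FALSE)
  stats::median(d)
}

#' Rating-sheet template for a set of recordings
#'
#' One empty row per recording, listing the applicable criteria codes in
#' the comment-style `applicable_criteria` column so raters know the
#' closed vocabulary for the task.
#'
#' @param ids Character vector of recording ids.
#' @param tasks Character vector of task codes, recycled against `ids`.
#' @return Data frame ready to be filled and saved with [save_ratings()]
#'   (extra column `applicable_criteria` is ignored by the loader).
#' @export
rating_template <- function(ids, tasks) {
  tasks <- rep_len(tasks, length(ids))
  data.frame(recording_id = ids, rater_id = "", task = tasks,
             decision = "undecided", criteria = "", comment = "",
             rating_duration_s = NA_real_,
             applicable_criteria = vapply(
               tasks, function(tk) paste(applicable_criteria(tk),
                                         collapse = ";"), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Confusion-matrix figure
#'
#' Renders the per-task 3x3 decision confusion matrix as a PNG tile plot
#' with counts, mirroring the layout used for rater-agreement reporting.
#'
#' @param summaries List of `qc_concordance` objects.
#' @param out Output PNG path.
#' @return `out`, invisibly.
#' @export
render_confusion_figure <- function(summaries, out) {
  n <- length(summaries)
  ncol <- min(4L, n)
  nrow <- ceiling(n / ncol)
  grDevices::png(out, width = 300 * ncol, height = 320 * nrow,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(nrow, ncol), mar = c(3, 3.5, 2.5, 0.8))
  for (sm in summaries) {
    m <- sm$confusion
    graphics::image(1:3, 1:3, t(m[3:1, ]),
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("%s (n=%d, %.1f%%)", sm$task, sm$n,
                                   sm$concordance_pct))
    graphics::axis(1, at = 1:3, labels = colnames(m), cex.axis = 0.8)
    graphics::axis(2, at = 3:1, labels = rownames(m), cex.axis = 0.8,
                   las = 2)
    for (i in 1:3) for (j in 1:3)
      graphics::text(j, 4 - i, m[i, j], cex = 1.1)
    graphics::box()
  }
  invisible(out)
}
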