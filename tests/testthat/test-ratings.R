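toy_pair <- function() {
  # 7 keep/keep, 1 discard/discard, 1 keep/undecided, 1 keep/discard
  a <- do.call(rbind, c(
    lapply(1:7, function(i) rating_record(paste0("r", i), "A", "POCO", "keep")),
    list(rating_record("r8", "A", "POCO", "discard"),
         rating_record("r9", "A", "POCO", "keep"),
         rating_record("r10", "A", "POCO", "keep"))))
  b <- do.call(rbind, c(
    lapply(1:7, function(i) rating_record(paste0("r", i), "B", "POCO", "keep")),
    list(rating_record("r8", "B", "POCO", "discard"),
         rating_record("r9", "B", "POCO", "undecided"),
         rating_record("r10", "B", "POCO", "discard"))))
  merge_rater_pair(a, b)
}

test_that("rating sheets round-trip through CSV", {
  recs <- rbind(
    rating_record("r1", "A", "SIP", "keep", c("FORWARD", "DISTURBANCES"),
                  comment = "drifting, 60 cm", rating_duration_s = 6.3),
    rating_record("r2", "A", "POCO", "undecided"),
    rating_record("r3", "A", "SAS", "discard", "ARMS"))
  f <- withr::local_tempfile(fileext = ".csv")
  save_ratings(recs, f)
  back <- load_ratings(f)
  expect_equal(back, recs)
})

test_that("closed vocabularies are enforced with row numbers", {
  expect_error(rating_record("r", "A", "SIP", "maybe"), "decision")
  expect_error(rating_record("r", "A", "SIP", "keep", "FEET"),
               "not applicable")  # FEET is a POCO criterion
  expect_error(rating_record("r", "A", "SIP", "keep", "BOGUS"), "unknown")

  ok <- rating_record("r1", "A", "SIP", "keep")
  f <- withr::local_tempfile(fileext = ".csv")
  save_ratings(ok, f)
  df <- utils::read.csv(f)
  df$decision <- "maybe"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(load_ratings(f), "row 1")
  df$decision <- "keep"; df$criteria <- "FEET"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(load_ratings(f), "FEET")
})

test_that("merge_rater_pair joins on recording and reports the unpaired", {
  a <- rbind(rating_record("r1", "A", "POCO", "keep"),
             rating_record("r2", "A", "POCO", "keep"))
  b <- rbind(rating_record("r2", "B", "POCO", "discard"),
             rating_record("r3", "B", "POCO", "keep"))
  p <- merge_rater_pair(a, b)
  expect_equal(p$recording_id, "r2")
  expect_equal(attr(p, "unpaired")$a_only, "r1")
  expect_equal(attr(p, "unpaired")$b_only, "r3")

  disjoint <- merge_rater_pair(
    rating_record("x", "A", "POCO", "keep"),
    rating_record("y", "B", "POCO", "keep"))
  expect_equal(nrow(disjoint), 0)

  dup <- rbind(rating_record("r1", "A", "POCO", "keep"),
               rating_record("r1", "A", "POCO", "discard"))
  expect_error(merge_rater_pair(dup, b), "duplicate")
})

test_that("the hand-countable 10-pair example gives 80/70/10/10 percent", {
  sm <- concordance_summary(toy_pair(), "POCO")
  expect_equal(sm$concordance_pct, 80)
  expect_equal(sm$unanimous_keep_pct, 70)
  expect_equal(sm$unanimous_discard_pct, 10)
  expect_equal(sm$strict_disagreement_pct, 10)
  expect_equal(sm$undecided_involved_pct, 10)
  expect_equal(sum(sm$confusion), sm$n)
})

test_that("concordance identities hold against a counting oracle", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(5:60, 1)
      da <- sample(c("keep", "discard", "undecided"), n, replace = TRUE)
      db <- sample(c("keep", "discard", "undecided"), n, replace = TRUE)
      paired <- data.frame(recording_id = paste0("r", 1:n), task = "SLW",
                           decision_a = da, decision_b = db,
                           criteria_a = "", criteria_b = "")
      sm <- concordance_summary(paired, "SLW")
      # counting oracle over raw pairs
      agree <- sum(da == db)
      strict <- sum((da == "keep" & db == "discard") |
                    (da == "discard" & db == "keep"))
      undec <- sum(da != db & (da == "undecided" | db == "undecided"))
      expect_equal(sm$concordance_pct, 100 * agree / n)
      expect_equal(sm$strict_disagreement_pct, 100 * strict / n)
      expect_equal(sm$undecided_involved_pct, 100 * undec / n)
      expect_equal(sm$unanimous_keep_pct + sm$unanimous_discard_pct +
                     sm$unanimous_undecided_pct, sm$concordance_pct)
      expect_lte(sm$strict_disagreement_pct,
                 100 - sm$concordance_pct + 1e-9)
      expect_equal(sum(sm$confusion), n)
    }
  })
})

test_that("ordered mode keeps rater order; unordered pools it", {
  paired <- data.frame(recording_id = c("a", "b"), task = "POCO",
                       decision_a = c("keep", "discard"),
                       decision_b = c("discard", "keep"),
                       criteria_a = "", criteria_b = "")
  un <- concordance_summary(paired, "POCO")
  expect_equal(un$confusion["keep", "discard"], 2)
  expect_equal(un$confusion["discard", "keep"], 0)
  or <- concordance_summary(paired, "POCO", ordered = TRUE)
  expect_equal(or$confusion["keep", "discard"], 1)
  expect_equal(or$confusion["discard", "keep"], 1)
  expect_equal(or$strict_disagreement_pct, un$strict_disagreement_pct)
})

test_that("criterion frequencies are per-rating and multiselect", {
  r <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      rating_record(paste0("p", i), "A", "POCO", "discard",
                    c("FEET", "DISTURBANCES")))),
    do.call(rbind, lapply(4:12, function(i)
      rating_record(paste0("p", i), "A", "POCO", "keep"))))
  fq <- criterion_frequencies(r)
  feet <- fq[fq$criterion == "FEET", ]
  expect_equal(feet$frequency_pct, 25)          # 3 of 12
  expect_equal(feet$n_ratings, 12)
  # multiselect: per-task sum may exceed 100
  expect_gt(sum(fq$frequency_pct[fq$task == "POCO"]), 25)
  # nothing selected -> all zero
  r0 <- rating_record("q", "A", "SLW", "keep")
  fq0 <- criterion_frequencies(r0)
  expect_true(all(fq0$frequency_pct == 0))
})

test_that("pooled frequency is the weighted mean of group frequencies", {
  r <- rbind(
    cbind(rating_record("h1", "A", "SIP", "discard", "FORWARD"),
          group = "HC"),
    cbind(rating_record("h2", "A", "SIP", "keep"), group = "HC"),
    cbind(rating_record("m1", "A", "SIP", "discard", "FORWARD"),
          group = "PwMS"),
    cbind(rating_record("m2", "A", "SIP", "discard", "FORWARD"),
          group = "PwMS"),
    cbind(rating_record("m3", "A", "SIP", "keep"), group = "PwMS"))
  fq <- criterion_frequencies(r, by_group = TRUE)
  fwd <- fq[fq$criterion == "FORWARD", ]
  pooled <- fwd$frequency_pct[fwd$group == "all"]
  groups <- fwd[fwd$group != "all", ]
  expect_equal(pooled,
               sum(groups$frequency_pct * groups$n_ratings) /
                 sum(groups$n_ratings))
})

test_that("median rating duration follows the even-count convention", {
  mk <- function(durs) do.call(rbind, lapply(seq_along(durs), function(i)
    rating_record(paste0("r", i), "A", "POCO", "keep",
                  rating_duration_s = durs[i])))
  expect_equal(median_rating_duration(mk(c(5, 6, 9))), 6)
  expect_equal(median_rating_duration(mk(c(4, 8))), 6)
  withr::with_seed(7, {
    for (rep in 1:100) {
      durs <- stats::runif(sample(1:30, 1), 1, 60)
      expect_equal(median_rating_duration(mk(durs)),
                   sort(durs)[ceiling(length(durs) / 2)] / 2 +
                     sort(durs)[floor(length(durs) / 2) + 1] / 2)
    }
  })
  expect_error(median_rating_duration(
    rating_record("r", "A", "POCO", "keep")), "duration")
})
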