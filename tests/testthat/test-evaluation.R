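mk_matched <- function(truth, predicted) {
  tibble::tibble(resident_id = "r", truth_ts = NA_real_, pred_ts = NA_real_,
                 truth = truth, predicted = predicted)
}

test_that("the confusion matrix tallies truth against predictions", {
  classes <- c("nurse1", "nurse2", "none")
  perfect <- mk_matched(rep(classes, 3), rep(classes, 3))
  m <- confusion_events(perfect, classes)
  expect_equal(unname(diag(unclass(m))), c(3, 3, 3))
  expect_equal(sum(m) - sum(diag(unclass(m))), 0)

  silent <- mk_matched(rep("nurse1", 4), rep("none", 4))
  m2 <- unclass(confusion_events(silent, classes))
  expect_equal(m2["nurse1", "none"], 4)
  expect_equal(sum(m2), 4)

  ten <- mk_matched(rep(c("nurse1", "nurse2"), 5),
                    c(rep(c("nurse1", "nurse2"), 4), "nurse2", "nurse1"))
  m3 <- unclass(confusion_events(ten, classes))
  expect_equal(m3["nurse1", "nurse2"], 1)
  expect_equal(m3["nurse2", "nurse1"], 1)
  expect_equal(sum(m3) - sum(diag(m3)), 2)

  expect_error(confusion_events(mk_matched("ghost", "none"), classes),
               "outside the declared class set")
  expect_error(confusion_events(mk_matched(character(), character())), "No events")
})

test_that("metrics reach their closed-form values", {
  classes <- c("nurse1", "nurse2", "none")
  perfect <- confusion_events(mk_matched(rep(classes, 4), rep(classes, 4)), classes)
  m <- triage_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$fpr, 0)
  expect_equal(m$fnr, 0)

  # binary tally TP=3 FP=1 FN=1 TN=5 for the positive class
  mat <- matrix(c(3, 1, 1, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m2 <- triage_metrics(mat)
  pos <- m2$per_class[m2$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.75)
  expect_equal(pos$f1, 0.75)

  # a class absent from truth and predictions scores 0 and is flagged
  with_empty <- confusion_events(mk_matched(c("nurse1", "none"), c("nurse1", "none")),
                                 classes)
  m3 <- triage_metrics(with_empty)
  empty_row <- m3$per_class[m3$per_class$class == "nurse2", ]
  expect_equal(empty_row$f1, 0)
  expect_true(empty_row$undefined)
  expect_error(triage_metrics(matrix(0, 2, 2)), "Empty")
})

test_that("metrics agree with an independent brute-force tally", {
  brute <- function(m) {
    classes <- seq_len(nrow(m))
    total <- 0
    for (i in classes) for (j in classes) total <- total + m[i, j]
    acc <- 0
    for (i in classes) acc <- acc + m[i, i]
    acc <- acc / total
    f1s <- numeric(length(classes))
    for (k in classes) {
      tp <- m[k, k]
      fp <- 0; fn <- 0
      for (i in classes) if (i != k) { fp <- fp + m[i, k]; fn <- fn + m[k, i] }
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1s[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    }
    list(accuracy = acc, macro_f1 = mean(f1s))
  }
  set.seed(99)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    m <- matrix(rpois(k * k, 4), k, k)
    dimnames(m) <- list(letters[1:k], letters[1:k])
    if (sum(m) == 0) m[1, 1] <- 1
    got <- triage_metrics(m)
    want <- brute(m)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
  }
})

test_that("event matching pairs detections with truth and exposes misses", {
  run <- structure(list(decisions = tibble::tibble(
    resident_id = c("r1", "r1", "r2"),
    ts = c(10, 50, 30),
    disposition = c("dispatched", "suppressed", "escalated"),
    nurse = c("nurse1", NA, "nurse2")
  )), class = "triage_run")
  truth <- tibble::tibble(
    resident_id = c("r1", "r1", "r2", "r3"),
    ts = c(11, 49, 31, 70),
    label = c("nurse1", "none", "nurse2", "nurse1")
  )
  m <- match_events(run, truth, match_window = 3)
  expect_equal(nrow(m), 4) # three matches plus one missed truth event
  r1a <- m[m$resident_id == "r1" & m$truth_ts == 11, ]
  expect_equal(r1a$predicted, "nurse1")
  r1b <- m[m$resident_id == "r1" & m$truth_ts == 49, ]
  expect_equal(r1b$predicted, "none") # suppressed alarm predicts the quiet class
  missed <- m[m$resident_id == "r3", ]
  expect_equal(missed$predicted, "none")
  expect_true(is.na(missed$pred_ts))

  # a spurious detection shows up with truth "none"
  m2 <- match_events(run, truth[truth$resident_id != "r2", ], match_window = 3)
  spurious <- m2[m2$resident_id == "r2", ]
  expect_equal(spurious$truth, "none")
  expect_equal(spurious$predicted, "nurse2")
})

test_that("alarm loads are ratios against the baseline with a 100% identity", {
  s <- simulate_ward(small_scenario(minutes = 5), seed = 4)
  events <- detect_events(s$frames, s$calib)
  base <- run_triage(s, strategy = "baseline", events = events)
  prop <- run_triage(s, strategy = "proposed", events = events)
  self_load <- alarm_load(base, base)
  expect_true(all(self_load$load == 1))
  expect_true(all(self_load$reduction == 0))
  ld <- alarm_load(prop, base)
  expect_true(all(ld$load <= 1, na.rm = TRUE))
  expect_equal(ld$reduction, 1 - ld$load)
  # a nurse receiving nothing has a 100% reduction
  if (any(ld$notifications == 0 & ld$baseline_notifications > 0)) {
    idle <- ld[ld$notifications == 0 & ld$baseline_notifications > 0, ]
    expect_true(all(idle$reduction == 1))
  }
})

test_that("strategy comparison is deterministic and covers rooms and days", {
  s <- simulate_ward(small_scenario(minutes = 6), seed = 5)
  cmp1 <- compare_strategies(s)
  cmp2 <- compare_strategies(s)
  expect_identical(cmp1$summary, cmp2$summary)
  expect_equal(nrow(cmp1$summary), 4)
  expect_true(all(c("baseline", "rsd", "rsdv", "proposed") %in% cmp1$summary$strategy))
  expect_true(all(cmp1$summary$accuracy >= 0 & cmp1$summary$accuracy <= 1))
  expect_equal(sort(unique(cmp1$per_day$day)), 1)
  expect_true(all(cmp1$per_room$room %in% 1:3))
  # single-room scenario gives a single per-room row per strategy
  s1 <- simulate_ward(
    small_scenario(minutes = 4, n_rooms = 1, n_stationed = 0,
                   tiers = c(high = 0, medium = 2, low = 3),
                   n_nurses = 2),
    seed = 7
  )
  cmp3 <- compare_strategies(s1, strategies = c("baseline", "proposed"))
  expect_equal(nrow(cmp3$per_room[cmp3$per_room$strategy == "proposed", ]), 1)
})

test_that("tidiers and plots expose the expected shapes", {
  s <- simulate_ward(small_scenario(minutes = 4), seed = 8)
  run <- run_triage(s, strategy = "proposed")
  expect_s3_class(tidy(run), "tbl_df")
  g <- glance(run)
  expect_equal(g$n_alarms,
               g$suppressed + g$delay_discarded + g$validation_discarded +
                 g$dispatched + g$escalated + g$unanswered)
  cmp <- compare_strategies(s, strategies = c("baseline", "proposed"))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_alarm_load(cmp), "ggplot")
  matched <- match_events(run, ground_truth_labels(s))
  mets <- triage_metrics(confusion_events(matched))
  expect_s3_class(autoplot(mets), "ggplot")
  expect_s3_class(glance(mets), "tbl_df")
})
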