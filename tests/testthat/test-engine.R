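test_that("every alarm receives exactly one disposition and A* is dispatched or escalated", {
  s <- simulate_ward(small_scenario(minutes = 5), seed = 3)
  run <- run_triage(s, strategy = "proposed")
  d <- run$decisions
  expect_equal(nrow(d), nrow(run$alarms))
  expect_true(all(d$disposition %in% c(
    "suppressed", "delay_discarded", "validation_discarded",
    "dispatched", "escalated", "unanswered"
  )))
  eff <- effective_alerts(run)
  expect_setequal(eff$alarm_id,
                  d$alarm_id[d$disposition %in% c("dispatched", "escalated")])
  expect_true(all(!is.na(eff$nurse)))
  # shadow log covers exactly the suppressed/discarded alarms
  expect_setequal(
    shadow_log(run)$alarm_id,
    d$alarm_id[d$disposition %in% c("suppressed", "delay_discarded",
                                    "validation_discarded")]
  )
})

test_that("reruns with the same seed and config are identical", {
  s1 <- simulate_ward(small_scenario(minutes = 4), seed = 9)
  s2 <- simulate_ward(small_scenario(minutes = 4), seed = 9)
  expect_identical(s1$frames, s2$frames)
  r1 <- run_triage(s1, strategy = "proposed")
  r2 <- run_triage(s2, strategy = "proposed")
  expect_identical(r1$decisions, r2$decisions)
})

test_that("unknown strategies are rejected", {
  s <- simulate_ward(small_scenario(minutes = 3), seed = 1)
  expect_error(run_triage(s, strategy = "notify_some"), "Unknown strategy")
})

test_that("the baseline notifies every nurse for every event", {
  s <- simulate_ward(small_scenario(minutes = 5), seed = 6)
  run <- run_triage(s, strategy = "baseline")
  n_events <- nrow(run$alarms)
  expect_gt(n_events, 0)
  expect_true(all(run$decisions$n_notified == nrow(s$nurses)))
  expect_equal(sum(run$decisions$n_notified), n_events * nrow(s$nurses))
  expect_true(all(run$decisions$disposition == "dispatched"))
})

test_that("a stream of only fully-dependent residents is entirely shadow-logged", {
  cfg <- small_scenario(
    minutes = 6, noise = 0,
    tiers = c(high = 4, medium = 0, low = 0),
    event_rate = c(high = 40, medium = 0, low = 0),
    n_rooms = 1, n_nurses = 2, n_stationed = 2
  )
  s <- simulate_ward(cfg, seed = 8)
  expect_gt(nrow(s$truth), 0)
  run <- run_triage(s, strategy = "proposed")
  expect_equal(nrow(effective_alerts(run)), 0)
  expect_equal(nrow(shadow_log(run)), nrow(run$alarms))
  expect_true(all(run$decisions$disposition == "suppressed"))
})

test_that("acknowledgment failures escalate and exhaust to an unanswered state", {
  cfg_all_ack <- small_scenario(minutes = 5, noise = 0, p_ack = 1)
  s <- simulate_ward(cfg_all_ack, seed = 12)
  run <- run_triage(s, strategy = "proposed")
  expect_equal(sum(run$decisions$disposition %in% c("escalated", "unanswered")), 0)

  cfg_no_ack <- small_scenario(minutes = 5, noise = 0, p_ack = 0)
  s0 <- simulate_ward(cfg_no_ack, seed = 12)
  run0 <- run_triage(s0, strategy = "proposed")
  handled <- run0$decisions$disposition %in% c("dispatched", "escalated")
  expect_equal(sum(handled), 0)
  expect_gt(sum(run0$decisions$disposition == "unanswered"), 0)
})

test_that("swapping the validation backend never changes suppression or delay outcomes", {
  s <- simulate_ward(small_scenario(minutes = 5), seed = 10)
  eager <- function(alarm, nurses, theta_x) {
    if (is.data.frame(alarm)) alarm <- c(as.list(alarm), list())
    avail <- nurses$nurse_id[as.logical(nurses$available)]
    list(priority = 1, nurse = avail[1], ranking = avail)
  }
  cfg_default <- triage_config()
  cfg_eager <- triage_config(backend = eager)
  r1 <- run_triage(s, cfg_default, strategy = "proposed")
  r2 <- run_triage(s, cfg_eager, strategy = "proposed")
  pre_gate <- c("suppressed", "delay_discarded")
  expect_identical(
    r1$decisions[r1$decisions$disposition %in% pre_gate,
                 c("alarm_id", "disposition", "reason")],
    r2$decisions[r2$decisions$disposition %in% pre_gate,
                 c("alarm_id", "disposition", "reason")]
  )
  # and the set of alarms reaching validation is identical
  expect_setequal(
    r1$decisions$alarm_id[!r1$decisions$disposition %in% pre_gate],
    r2$decisions$alarm_id[!r2$decisions$disposition %in% pre_gate]
  )
})

test_that("the proposed strategy never dispatches more than the baseline issues", {
  s <- simulate_ward(small_scenario(minutes = 5), seed = 14)
  events <- detect_events(s$frames, s$calib)
  n_prop <- nrow(effective_alerts(run_triage(s, strategy = "proposed", events = events)))
  n_rsd <- nrow(effective_alerts(run_triage(s, strategy = "rsd", events = events)))
  base <- run_triage(s, strategy = "baseline", events = events)
  expect_lte(n_prop, n_rsd)
  expect_lte(n_rsd, nrow(events))
  expect_lte(n_prop, sum(base$decisions$n_notified))
})

test_that("decision logs round-trip losslessly through JSON-lines", {
  s <- simulate_ward(small_scenario(minutes = 4), seed = 11)
  run <- run_triage(s, strategy = "proposed")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_decision_log(run, path)
  back <- read_decision_log(path)
  expect_equal(nrow(back), nrow(run$decisions))
  expect_equal(back$alarm_id, run$decisions$alarm_id)
  expect_equal(back$disposition, run$decisions$disposition)
  expect_equal(back$ts, run$decisions$ts)
})
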