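test_that("urgency weights must form a simplex", {
  expect_silent(urgency_weights())
  expect_error(urgency_weights(0.5, 0.2, 0.1, 0.1), "sum to 1")
  expect_error(urgency_weights(-0.1, 0.5, 0.3, 0.3), "\\[0, 1\\]")
})

test_that("urgency combines squashed terms with the configured weights", {
  # every term zero for a still, non-risky, unflagged resident
  expect_equal(urgency_score(0, 0, "other", 0), 0)
  # squashed terms at one half, risky activity, saturated flags:
  # 0.2*0.5 + 0.2*0.5 + 0.25 + 0.35 = 0.80
  expect_equal(
    urgency_score(speed = 0.1, accel = 0.5, activity = "stand_up_attempt",
                  flag_count = 3, v_baseline = 0.1, a_baseline = 0.5),
    0.80,
    tolerance = 1e-13
  )
  # saturated inputs cap at exactly 1 because the weights sum to 1
  expect_equal(urgency_score(1e12, 1e12, "stand_up_attempt", 100), 1,
               tolerance = 1e-9)
  expect_error(urgency_score(1, 1, "other", -1), "non-negative")
})

test_that("urgency is monotone in each argument", {
  set.seed(21)
  for (i in 1:30) {
    v <- runif(1, 0, 2); a <- runif(1, -2, 2); fc <- sample(0:5, 1)
    u0 <- urgency_score(v, a, "other", fc)
    expect_gte(urgency_score(v + 0.5, a, "other", fc), u0)
    expect_gte(urgency_score(v, a, "stand_up_attempt", fc), u0)
    expect_gte(urgency_score(v, a, "other", fc + 1), u0)
    expect_gte(urgency_score(v, abs(a) + 0.5, "other", fc), u0)
  }
})

test_that("clinical priority reproduces the care/assistance mapping", {
  expect_equal(clinical_priority(1, rep(1, 5)), "mid")
  expect_equal(clinical_priority(5, rep(5, 5)), "low")
  expect_equal(clinical_priority(4, rep(5, 5)), "low")
  expect_equal(clinical_priority(3, c(4, 4, 4, 4, 4)), "high")
  expect_equal(clinical_priority(2, rep(1, 5)), "high")
  expect_error(clinical_priority(6, rep(1, 5)), "1..5")
  expect_error(clinical_priority(1, rep(1, 4)), "5 activity scores")
})

test_that("clinical priority is a total function over the full profile grid", {
  grid <- expand.grid(cl = 1:5, a1 = 1:5, a2 = 1:5, a3 = 1:5, a4 = 1:5, a5 = 1:5)
  got <- clinical_priority(grid$cl, grid[, c("a1", "a2", "a3", "a4", "a5")])
  expect_equal(length(got), nrow(grid)) # 5^6 combinations, one class each
  expect_true(all(got %in% c("high", "mid", "low")))
  # agreement with an independently written rule using max aggregation
  al <- pmax(grid$a1, grid$a2, grid$a3, grid$a4, grid$a5)
  want <- ifelse(grid$cl >= 4 & al == 5, "low",
                 ifelse(grid$cl == 1 & al == 1, "mid", "high"))
  expect_equal(got, want)
})

test_that("ward workload equals the busy fraction (exhaustive size-4 rosters)", {
  for (bits in 0:15) {
    busy <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0)
    roster <- mk_nurses(4, busy = busy)
    expect_equal(nurse_workload(roster), sum(busy) / 4)
  }
  expect_error(nurse_workload(mk_nurses(0)), "at least one")
})

test_that("alarm assembly fills all five context parts", {
  s <- simulate_ward(small_scenario(minutes = 3, noise = 0), seed = 4)
  ev <- detect_events(s$frames, s$calib)
  expect_gt(nrow(ev), 0)
  al <- assemble_alarms(ev, s$residents, s$nurses, s$frames, s$calib)
  expect_equal(nrow(al), nrow(ev))
  expect_true(all(al$urgency >= 0 & al$urgency <= 1))
  expect_true(all(al$workload >= 0 & al$workload <= 1))
  expect_true(all(al$priority_class %in% c("high", "mid", "low")))
  expect_true(all(vapply(al$distances, function(d) all(d >= 0), logical(1))))
  expect_true(all(vapply(al$distances, length, integer(1)) == nrow(s$nurses)))

  expect_error(
    assemble_alarms(dplyr::mutate(ev, person_id = "ghost"),
                    s$residents, s$nurses, s$frames, s$calib),
    "unknown residents"
  )
  expect_error(
    assemble_alarms(ev, s$residents, s$nurses[0, ], s$frames, s$calib),
    "non-empty"
  )
})

test_that("per-nurse distances in an alarm follow the pixel scale", {
  # one resident, two nurses at 100 px and 300 px with scale 0.01 m/px
  calib <- calibration(5, 0.01)
  mk_row <- function(id, role, x) {
    tibble::tibble(
      frame = 1L, ts = 0, person_id = id, role = role,
      xmin = x - 10, ymin = 0, xmax = x + 10, ymax = 20,
      kpt_x = matrix(x, 1, 17), kpt_y = matrix(10, 1, 17),
      kpt_vis = matrix(1, 1, 17)
    )
  }
  frames <- dplyr::bind_rows(
    mk_row("res01", "resident", 0),
    mk_row("nurse1", "nurse", 100),
    mk_row("nurse2", "nurse", 300)
  )
  ev <- tibble::tibble(
    event_id = "res01-e001", person_id = "res01", ordinal = 1L, ts = 0,
    frame = 1L, score = 10, tau = 1, label = "stand_up_attempt",
    n_flagged = 3L, speed = 0.5, accel = 0, recent_flags = 0L
  )
  residents <- mk_residents("res01", 3L, 3L)
  al <- assemble_alarms(ev, residents, mk_nurses(2), frames, calib)
  expect_equal(al$distances[[1]], c(nurse1 = 1, nurse2 = 3))
  expect_equal(al$nearest_nurse, "nurse1")
  # fully dependent resident maps to the low (suppressible) class
  al_low <- assemble_alarms(ev, mk_residents("res01", 5L, 5L),
                            mk_nurses(2), frames, calib)
  expect_equal(al_low$priority_class, "low")
})
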