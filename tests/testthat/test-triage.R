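test_that("the reachable distance threshold follows stand-up time and speed", {
  expect_equal(reachable_threshold(3, 1.2, reach_window = 1), 2.4)
  expect_equal(reachable_threshold(3, 0), 0)
  expect_warning(out <- reachable_threshold(1, 1.2, reach_window = 1),
                 "no alarm is reachable")
  expect_equal(out, 0)
  expect_error(suppression_thresholds(theta_u = 1.5), "theta_u")
})

test_that("suppression applies the three clauses in order", {
  th <- suppression_thresholds(theta_x = 2.4, theta_u = 0.2)
  # nearest available nurse beyond reach
  out <- suppress_alarms(mk_alarm(min_dist_avail = 5), th)
  expect_false(out$keep)
  expect_equal(out$reason, "too_far")
  # below the urgency floor
  out <- suppress_alarms(mk_alarm(urgency = 0.1, min_dist_avail = 1), th)
  expect_equal(out$reason, "not_urgent")
  # fully dependent resident
  out <- suppress_alarms(mk_alarm(priority_class = "low", min_dist_avail = 1), th)
  expect_equal(out$reason, "low_priority")
  # actionable alarm passes
  out <- suppress_alarms(mk_alarm(urgency = 0.5, min_dist_avail = 1), th)
  expect_true(out$keep)
  expect_equal(out$reason, "none")
  # clause precedence: distance outranks urgency outranks class
  out <- suppress_alarms(mk_alarm(urgency = 0.05, priority_class = "low",
                                  min_dist_avail = 9), th)
  expect_equal(out$reason, "too_far")
})

test_that("the personalized delay reproduces the weighted combination", {
  # maximally urgent high-priority alarm: no delay
  expect_equal(compute_delay(1, 0, "high"), 0)
  # 0.5*0.6 + 0.25*0.5 + 0.25*1 = 0.675
  expect_equal(compute_delay(0.4, 0.5, "mid"), 0.675, tolerance = 1e-13)
  # zero urgency, full workload, mid class: maximum delay 1
  expect_equal(compute_delay(0, 1, "mid"), 1)
  expect_error(delay_weights(0.5, 0.5, 0.5), "sum to 1")
})

test_that("delay is monotone: non-increasing in urgency, non-decreasing in workload", {
  set.seed(13)
  for (i in 1:30) {
    u <- runif(1); r <- runif(1); cls <- sample(c("high", "mid"), 1)
    d0 <- compute_delay(u, r, cls)
    expect_lte(compute_delay(min(u + 0.2, 1), r, cls), d0 + 1e-12)
    expect_gte(compute_delay(u, min(r + 0.2, 1), cls), d0 - 1e-12)
  }
})

test_that("the delay gate discards only past the acknowledgment horizon", {
  expect_true(delay_gate(0, t_ack = 30))
  expect_false(delay_gate(0.9, t_ack = 5, delay_scale = 10))
  # boundary: exactly at the horizon is kept (strict inequality)
  expect_true(delay_gate(0.5, t_ack = 5, delay_scale = 10))
  expect_error(delay_gate(-0.1), ">= 0")
})

test_that("prompts are deterministic and complete", {
  al <- mk_alarm(urgency = 0.7, priority_class = "high")
  roster <- mk_nurses(3)
  p1 <- build_prompt(al, roster)
  p2 <- build_prompt(al, roster)
  expect_identical(p1, p2)
  for (nid in roster$nurse_id) expect_match(p1, nid, fixed = TRUE)
  expect_match(p1, "Urgency: 0.7")
  expect_match(p1, "Clinical priority: high")
  expect_match(p1, "Ward workload:")
  expect_match(p1, "Time:")
  expect_match(p1, "distance")
})

test_that("the surrogate backend scores and ranks nurses by the stated rule", {
  # all terms saturated: priority exactly 1
  al <- mk_alarm(urgency = 1, priority_class = "high", workload = 0,
                 distances = c(nurse1 = 0, nurse2 = 2), min_dist_avail = 0)
  out <- validate_alarm(al, mk_nurses(2), theta_x = 2.4)
  expect_equal(out$priority, 1)
  expect_equal(out$nurse, "nurse1")

  # zero urgency, mid class, everyone out of reach, full workload: 0.3*0.5
  al2 <- mk_alarm(urgency = 0, priority_class = "mid", workload = 1,
                  distances = c(nurse1 = 3, nurse2 = 4), min_dist_avail = 3)
  out2 <- validate_alarm(al2, mk_nurses(2), theta_x = 2.4)
  expect_equal(out2$priority, 0.15, tolerance = 1e-13)

  # equidistant nurses: the tie breaks to the lower workload index
  roster <- mk_nurses(2)
  roster$workload_index <- c(5L, 1L)
  al3 <- mk_alarm(distances = c(nurse1 = 1, nurse2 = 1), min_dist_avail = 1)
  expect_equal(validate_alarm(al3, roster, theta_x = 2.4)$nurse, "nurse2")
  # and to the lexicographically lower id when workloads tie too
  roster$workload_index <- c(1L, 1L)
  expect_equal(validate_alarm(al3, roster, theta_x = 2.4)$nurse, "nurse1")
})

test_that("backend contract violations are rejected", {
  al <- mk_alarm()
  roster <- mk_nurses(2)
  bad_priority <- function(alarm, nurses, theta_x) {
    list(priority = 1.7, nurse = "nurse1", ranking = "nurse1")
  }
  expect_error(validate_alarm(al, roster, 2.4, bad_priority), "outside")
  bad_nurse <- function(alarm, nurses, theta_x) {
    list(priority = 0.5, nurse = "dr_house", ranking = "dr_house")
  }
  expect_error(validate_alarm(al, roster, 2.4, bad_nurse), "unknown nurse")
  malformed <- function(alarm, nurses, theta_x) 0.5
  expect_error(validate_alarm(al, roster, 2.4, malformed), "contract")
})

test_that("the dynamic threshold moves with context and clamps", {
  b <- c(0.2, 0.2, 0.2)
  expect_equal(dynamic_threshold("high", 0, 0, theta_x = 2.4, beta = b), 0.1)
  expect_equal(dynamic_threshold("mid", 1, 2.4, theta_x = 2.4, beta = b), 0.7)
  expect_equal(
    dynamic_threshold("high", 0, 0, theta_x = 2.4, tau0 = 0.1, beta = c(0, 0, 0.5)),
    0
  )
  # package default: no distance term, mild workload term
  expect_equal(dynamic_threshold("mid", 0.5, 2.4, theta_x = 2.4), 0.35)
})
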