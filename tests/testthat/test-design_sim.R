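test_that("sample_enrollment covers empty, degenerate and uniform cases", {
  expect_identical(sample_enrollment(0, 0, 3), numeric(0))
  expect_equal(sample_enrollment(5, 3, 3), rep(3, 5))
  expect_error(sample_enrollment(-1, 0, 3), "non-negative")
  expect_error(sample_enrollment(2, 5, 3), "start <= end")

  set.seed(101)
  x <- sample_enrollment(10000, 0, 3)
  expect_true(all(x >= 0 & x <= 3))
  se <- 3 / sqrt(12 * 10000)
  expect_lt(abs(mean(x) - 1.5), 1.5 * se)
})

test_that("patient_scale_changepoint maps and clamps the calendar switch", {
  expect_equal(patient_scale_changepoint(1, 3), 2)
  expect_equal(patient_scale_changepoint(3, 3), 0)
  expect_equal(patient_scale_changepoint(4.5, 3), 0)
  expect_equal(patient_scale_changepoint(c(0, 2, 5), 3), c(3, 1, 0))
})

test_that("sample_event_time inverts the two-piece cumulative hazard", {
  expect_equal(sample_event_time(0.3, 0.2, 0.134, 2), 1.5)
  expect_equal(sample_event_time(0.6, 0.2, 0.134, 2), 2 + 0.2 / 0.134)
  expect_equal(sample_event_time(0.134, 0.5, 0.134, 0), 1.0)
  expect_error(sample_event_time(0, 0.2, 0.134, 2), "positive")
  expect_error(sample_event_time(0.3, -0.2, 0.134, 2), "positive")
  expect_error(sample_event_time(0.3, 0.2, 0.134, -1), ">= 0")
})

test_that("equal-rate inverse sampling reproduces the exponential law", {
  set.seed(202)
  u <- -log(runif(1e4))
  draws <- sample_event_time(u, 0.3, 0.3, changepoint = 1.7)
  ks <- suppressWarnings(ks.test(draws, pexp, rate = 0.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("administrative_censor caps follow-up at the study end", {
  expect_equal(administrative_censor(20, 2, 15),
               list(followup_time = 13, event = FALSE))
  expect_equal(administrative_censor(5, 2, 15),
               list(followup_time = 5, event = TRUE))
  # boundary counts as an observed event
  expect_equal(administrative_censor(13, 2, 15),
               list(followup_time = 13, event = TRUE))
  expect_error(administrative_censor(5, 15, 15), "strictly before")
})

test_that("simulate_trial is deterministic with labelled arms and valid rows", {
  d <- default_design(n_per_arm = c(100, 100, 100))
  s1 <- simulate_trial(d, seed = 11)
  s2 <- simulate_trial(d, seed = 11)
  s3 <- simulate_trial(d, seed = 12)
  expect_equal(s1, s2)
  expect_false(isTRUE(all.equal(s1$followup_time, s3$followup_time)))
  expect_equal(nrow(s1), 300)
  expect_equal(as.vector(table(s1$arm)[c("control_ncc", "control_cc",
                                         "treatment")]),
               c(100, 100, 100))
  expect_true(all(s1$followup_time > 0))
  expect_true(all(s1$enroll + s1$followup_time <= d$t_max + 1e-12))
  # censored exactly iff follow-up runs to the study end
  expect_equal(!s1$event,
               abs(s1$enroll + s1$followup_time - d$t_max) < 1e-12)
})

test_that("simulated survival matches the closed-form exponential tail", {
  d <- default_design(n_per_arm = c(0, 20000, 0))
  cc <- simulate_trial(d, seed = 33)
  expect_equal(unique(cc$arm), "control_cc")
  # all CC subjects are under follow-up at patient time 5 (cap >= 9)
  p_hat <- mean(cc$followup_time > 5)
  p_true <- exp(-0.2 * exp(-0.4) * 5)
  mc_se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(p_hat - p_true), 3 * mc_se)
})

test_that("piecewise-exponential MLE recovers the generative NCC rates", {
  d <- default_design(n_per_arm = c(10000, 0, 0))
  ncc <- simulate_trial(d, seed = 44)
  cp <- patient_scale_changepoint(ncc$enroll, 3)
  d1 <- sum(ncc$event & ncc$followup_time <= cp)
  e1 <- sum(pmin(ncc$followup_time, cp))
  d2 <- sum(ncc$event & ncc$followup_time > cp)
  e2 <- sum(pmax(ncc$followup_time - cp, 0))
  expect_lt(abs(d1 / e1 - 0.2) / 0.2, 0.05)
  post <- 0.2 * exp(-0.4)
  expect_lt(abs(d2 / e2 - post) / post, 0.05)
})

test_that("simulate_trial rejects multi-breakpoint hazards", {
  arm <- arm_spec("a", 5, 0, 1, hazard_spec(c(1, 2, 3), breakpoints = c(1, 2)))
  d <- trial_design(list(arm, arm_spec("treatment", 5, 0, 1,
                                       hazard_spec(0.5))),
                    t1_entry = 1, t_max = 10)
  expect_error(simulate_trial(d, 1), "at most one")
})
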