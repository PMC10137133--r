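test_that("risk_set honours exit >= t > entry", {
  rec <- km_toy()
  expect_equal(risk_set(rec, 2), 1:3)
  expect_equal(risk_set(rec, 1), c(1L, 3L))   # r2 excluded: 1 > 1 is false
  expect_equal(risk_set(rec, 0.5), c(1L, 3L)) # r2 not yet entered
  expect_equal(risk_set(rec, 3.5), 3L)  # r2 already exited at 3
  expect_error(risk_set(rec, 0))
})

test_that("delayed-entry KM reproduces the hand-computed toy", {
  fit <- km_fit(km_toy())
  expect_equal(fit$time, c(2, 3))
  expect_equal(fit$at_risk, c(3, 2))
  expect_equal(fit$survival, c(2 / 3, 1 / 3))
  expect_equal(fit$variance[2], 2 / 27)
  expect_equal(km_survival(fit, c(0, 1.9, 2, 2.5, 3, 10)),
               c(1, 1, 2 / 3, 2 / 3, 1 / 3, 1 / 3))
  expect_true(all(diff(fit$survival) <= 0))
  expect_true(all(fit$ci_lower <= fit$survival & fit$survival <= fit$ci_upper))
})

test_that("KM with no events is identically one", {
  rec <- data.frame(entry = c(0, 1), exit = c(2, 4), event = FALSE)
  fit <- km_fit(rec)
  expect_length(fit$time, 0)
  expect_equal(km_survival(fit, c(0, 1, 5)), c(1, 1, 1))
})

test_that("KM with zero entries reduces to the textbook estimator", {
  set.seed(303)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    time <- round(rexp(n, 0.3), 2) + 0.01
    event <- rbinom(n, 1, 0.7) == 1
    if (!any(event)) next
    fit <- km_fit(data.frame(entry = 0, exit = time, event = event))
    ref <- textbook_km(time, event)
    expect_equal(fit$time, ref$time)
    expect_equal(fit$survival, ref$survival)
  }
})

test_that("cox_loglik matches hand values and the brute-force oracle", {
  toy <- cox_toy()
  expect_equal(cox_loglik(toy, 0), -log(24))
  one <- data.frame(group = 1L, entry = 0, exit = 1, event = TRUE)
  expect_equal(cox_loglik(one, 0), 0)

  set.seed(404)
  for (i in 1:25) {
    rec <- random_cox_records(sample(4:20, 1))
    b <- runif(1, -2, 2)
    for (ties in c("efron", "breslow")) {
      expect_equal(cox_loglik(rec, b, ties = ties),
                   brute_force_loglik(rec, b, ties = ties),
                   tolerance = 1e-12)
    }
  }
  # tied event times engage the Efron correction
  tied <- data.frame(group = c(1L, 1L, 0L, 0L, 1L), entry = 0,
                     exit = c(2, 2, 2, 3, 4),
                     event = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(cox_loglik(tied, 0.4, ties = "efron"),
               brute_force_loglik(tied, 0.4, ties = "efron"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cox_loglik(tied, 0.4, ties = "efron"),
                                cox_loglik(tied, 0.4, ties = "breslow"))))
})

test_that("cox_fit solves the worked score equations exactly", {
  # score equation for the toy reduces to u^2 - u - 4 = 0, u = exp(beta)
  fit <- cox_fit(cox_toy())
  expect_equal(fit$beta, log((1 + sqrt(17)) / 2), tolerance = 1e-7)
  expect_equal(fit$hr, (1 + sqrt(17)) / 2, tolerance = 1e-7)
  expect_true(fit$converged)
  expect_lt(abs(fit$score), 1e-6)

  # moving one entry to 1.5 changes the equation to 2u^3 - 7u - 4 = 0
  fit2 <- cox_fit(cox_toy(entry_b = 1.5))
  u <- uniroot(function(u) 2 * u^3 - 7 * u - 4, c(1, 5), tol = 1e-12)$root
  expect_equal(fit2$beta, log(u), tolerance = 1e-7)

  # label flip negates beta, keeps the standard error
  flipped <- cox_toy()
  flipped$group <- 1L - flipped$group
  fit_f <- cox_fit(flipped)
  expect_equal(fit_f$beta, -fit$beta, tolerance = 1e-7)
  expect_equal(fit_f$se, fit$se, tolerance = 1e-9)

  const <- cox_toy(); const$group <- 1L
  expect_error(cox_fit(const), "degenerate")
})

test_that("monotone likelihood is flagged, not silently returned", {
  # perfectly separated groups: all treated events precede all control events
  rec <- data.frame(group = rep(c(1L, 0L), each = 5), entry = 0,
                    exit = c(1:5, 11:15), event = TRUE)
  expect_warning(fit <- cox_fit(rec), "monotone")
  expect_false(fit$converged)
})

test_that("wald_summary matches the published-table arithmetic", {
  w <- wald_summary(log(0.744), 0.131)
  expect_equal(w$p, 0.024, tolerance = 0.001)
  expect_equal(w$ci[2], 0.962, tolerance = 0.001)
  w2 <- wald_summary(log(0.755), 0.147)
  expect_equal(w2$ci[1], 0.566, tolerance = 0.001)
  expect_equal(w2$ci[2], 1.007, tolerance = 0.001)
  expect_true(w2$p > 0.055 && w2$p < 0.057)
  expect_equal(wald_summary(0, 0.3)$hr, 1)
  expect_equal(wald_summary(0, 0.3)$p, 1)
  expect_error(wald_summary(0.1, 0), "positive")
})

test_that("log-rank toy and degenerate cases behave", {
  rec <- data.frame(entry = 0, exit = c(1, 2), event = TRUE, group = c(0, 1))
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, 1.0)
  expect_equal(lr$p, 2 * pnorm(1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(unname(lr$observed), c(1, 1))

  none <- data.frame(entry = 0, exit = c(1, 2), event = FALSE,
                     group = c(0, 1))
  lr0 <- logrank_test(none)
  expect_false(lr0$defined)
  expect_equal(lr0$p, 1)

  # one group duplicating the other (tiny delayed entry): O - E is exactly 0
  a <- data.frame(entry = 0, exit = c(1, 2, 3), event = TRUE, group = 0L)
  b <- data.frame(entry = 1e-9, exit = c(1, 2, 3), event = TRUE, group = 1L)
  lr_sym <- logrank_test(rbind(a, b))
  expect_lt(abs(lr_sym$statistic), 1e-12)
})

test_that("log-rank equals the Cox score test at beta = 0 (untied data)", {
  set.seed(505)
  for (i in 1:10) {
    rec <- random_cox_records(sample(8:25, 1))
    rec$exit <- rec$exit + seq_len(nrow(rec)) * 1e-7  # ensure no ties
    # independent literal enumeration of the score test
    U <- I <- 0
    for (t in sort(unique(rec$exit[rec$event]))) {
      at <- which(rec$exit >= t & t > rec$entry)
      dx <- rec$group[rec$event & rec$exit == t]
      p1 <- mean(rec$group[at])
      U <- U + sum(dx) - length(dx) * p1
      I <- I + length(dx) * (p1 - p1^2)
    }
    lr <- logrank_test(rec)
    expect_equal(lr$statistic, U^2 / I, tolerance = 1e-8)
  }
})

test_that("Newton and grid-search fits agree on random small instances", {
  set.seed(606)
  for (i in 1:40) {
    rec <- random_cox_records(sample(4:10, 1))
    ties <- sample(c("efron", "breslow"), 1)
    fit <- suppressWarnings(cox_fit(rec, ties = ties))
    if (!fit$converged) next
    expect_lt(abs(fit$beta - brute_force_fit(rec, ties = ties)), 1e-4)
  }
})

test_that("estimates agree with the survival package on counting-process data", {
  set.seed(707)
  rec <- random_cox_records(80)
  fit <- cox_fit(rec, ties = "efron")
  ref <- survival::coxph(survival::Surv(entry, exit, event) ~ group,
                         data = rec, ties = "efron")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)

  km <- km_fit(rec)
  sf <- survival::survfit(survival::Surv(entry, exit, event) ~ 1, data = rec)
  at_ev <- sf$n.event > 0
  expect_equal(km$time, sf$time[at_ev])
  expect_equal(km$survival, sf$surv[at_ev], tolerance = 1e-12)

  # survdiff has no counting-process form; the coxph score test at beta = 0
  # equals the log-rank statistic when event times are untied
  lr <- logrank_test(rec)
  expect_equal(unname(lr$statistic),
               unname(summary(ref)$sctest[["test"]]), tolerance = 1e-8)
})
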