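# Shared fixtures and independent mini-oracles, all built in code.

# 3-record delayed-entry KM toy: S(2) = 2/3, S(3) = 1/3 by hand.
km_toy <- function() {
  data.frame(id = c("r1", "r2", "r3"), group = 0L,
             entry = c(0, 1, 0), exit = c(2, 3, 4),
             event = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
}

# 4-record Cox toy; with entry_b = 0 the score equation reduces to
# u^2 - u - 4 = 0 (u = exp(beta)), with entry_b = 1.5 to 2u^3 - 7u - 4 = 0.
cox_toy <- function(entry_b = 0) {
  data.frame(group = c(1L, 0L, 1L, 0L),
             entry = c(0, entry_b, 0, 0), exit = 1:4,
             event = TRUE, stringsAsFactors = FALSE)
}

# Textbook (no-truncation) Kaplan-Meier by direct counting loops; written
# independently of the package's cumulative-sum machinery.
textbook_km <- function(time, event) {
  tev <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(tev))
  for (k in seq_along(tev)) {
    n <- sum(time >= tev[k])
    d <- sum(event & time == tev[k])
    s <- s * (1 - d / n)
    out[k] <- s
  }
  list(time = tev, survival = out)
}

# Random small counting-process instances for property tests; guarantees
# events in both covariate groups so the partial likelihood is well behaved.
random_cox_records <- function(n, with_entry = TRUE) {
  repeat {
    x <- c(0L, 1L, stats::rbinom(n - 2L, 1L, 0.5))
    entry <- if (with_entry) stats::rexp(n, 2) * stats::rbinom(n, 1, 0.5)
             else rep(0, n)
    exit <- entry + stats::rexp(n, 0.5) + 1e-3
    event <- stats::rbinom(n, 1, 0.8) == 1L
    rec <- data.frame(group = x, entry = entry, exit = exit, event = event)
    if (sum(event & x == 1L) >= 1L && sum(event & x == 0L) >= 1L) return(rec)
  }
}

# Subjects table with prescribed layout, for truncation tests.
make_subjects <- function(arm, enroll, followup, event) {
  data.frame(id = paste0(arm, "-", seq_along(enroll)), arm = arm,
             enroll = enroll, followup_time = followup, event = event,
             stringsAsFactors = FALSE)
}

write_design_yaml <- function(path, n = 30, seed = NULL,
                              treatment_rate = 0.114) {
  post <- 0.2 * exp(-0.4)
  cfg <- list(
    arms = list(
      list(name = "control_ncc", n = n, accrual = c(0, 3),
           hazard = list(rates = c(0.2, post), breakpoints = c(3))),
      list(name = "control_cc", n = n, accrual = c(3, 6),
           hazard = list(rates = post)),
      list(name = "treatment", n = n, accrual = c(3, 6),
           hazard = list(rates = treatment_rate))
    ),
    t1_entry = 3, t_max = 15
  )
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path)
  path
}
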