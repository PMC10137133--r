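# Trial simulation: staggered uniform accrual, piecewise-exponential event
# times via inverse cumulative-hazard sampling, administrative censoring.

# Deterministic substream seed so arms / replicates can be regenerated
# independently of each other. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  m <- 2147483629
  s <- (as.double(master) %% m)
  as.integer((s * 48271 + as.double(index) * 1099087573) %% m)
}

#' Sample uniform enrollment times
#'
#' @param n Number of patients (non-negative).
#' @param start,end Calendar accrual window, `start <= end`.
#' @return `n` i.i.d. Uniform(`start`, `end`) calendar times (unsorted). Uses
#'   the current RNG state.
#' @export
sample_enrollment <- function(n, start, end) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be non-negative", call. = FALSE)
  if (start > end) stop("need start <= end", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (start == end) return(rep(start, n))
  stats::runif(n, start, end)
}

#' Patient-scale time of the calendar changepoint
#'
#' Maps a calendar-time hazard changepoint onto a subject's
#' time-since-randomization axis: a subject enrolled at `enroll` experiences
#' the switch at patient time `max(0, t1_entry - enroll)` (0 if enrolled after
#' the changepoint).
#'
#' @param enroll Calendar enrollment time(s).
#' @param t1_entry Calendar changepoint.
#' @return Patient-scale changepoint(s), vectorized over `enroll`.
#' @export
patient_scale_changepoint <- function(enroll, t1_entry) {
  pmax(0, t1_entry - enroll)
}

#' Invert a two-piece cumulative hazard
#'
#' Solves `Lambda(t) = cumhaz_target` for the piecewise-constant hazard that
#' equals `rate_before` on patient time `[0, changepoint)` and `rate_after`
#' afterwards, i.e. `Lambda(t) = rate_before * min(t, c) + rate_after *
#' max(0, t - c)`. With `cumhaz_target = -log(U)`, `U ~ Uniform(0,1)`, the
#' result is an event time from that hazard (inverse-transform sampling).
#'
#' @param cumhaz_target Positive cumulative-hazard target(s), e.g. `-log(runif(n))`.
#' @param rate_before,rate_after Positive hazard rates.
#' @param changepoint Non-negative patient-scale switch time(s).
#' @return Patient-scale event time(s); vectorized over the first and last
#'   arguments.
#' @export
sample_event_time <- function(cumhaz_target, rate_before, rate_after,
                              changepoint) {
  if (any(!is.finite(cumhaz_target)) || any(cumhaz_target <= 0))
    stop("cumhaz_target must be positive", call. = FALSE)
  if (!is.finite(rate_before) || rate_before <= 0 ||
      !is.finite(rate_after) || rate_after <= 0)
    stop("rates must be positive", call. = FALSE)
  if (any(changepoint < 0)) stop("changepoint must be >= 0", call. = FALSE)
  cut <- rate_before * changepoint
  ifelse(cumhaz_target < cut,
         cumhaz_target / rate_before,
         changepoint + (cumhaz_target - cut) / rate_after)
}

#' Apply administrative censoring at the calendar end of study
#'
#' @param event_time Patient-scale event time(s).
#' @param enroll Calendar enrollment time(s), strictly before `t_max`.
#' @param t_max Calendar end-of-study time.
#' @return A list with `followup_time = min(event_time, t_max - enroll)` and
#'   logical `event` (`TRUE` when the event occurred at or before the cutoff;
#'   an event landing exactly on the boundary counts as observed).
#' @export
administrative_censor <- function(event_time, enroll, t_max) {
  if (any(enroll >= t_max))
    stop("enroll must be strictly before t_max", call. = FALSE)
  cap <- t_max - enroll
  list(followup_time = pmin(event_time, cap), event = event_time <= cap)
}

#' Simulate one platform-trial dataset
#'
#' For each arm, enrollment times are drawn uniformly over the arm's accrual
#' window, event times from the arm's calendar-time hazard (mapped onto each
#' subject's own time axis through [patient_scale_changepoint()]), and
#' follow-up is administratively censored at `design$t_max`. Each arm uses a
#' substream seed derived deterministically from `seed`, so the same seed
#' always reproduces the same dataset.
#'
#' Only hazard specifications with at most one breakpoint are supported (the
#' generative model has a single standard-of-care changepoint).
#'
#' @param design A [trial_design()].
#' @param seed Integer master seed.
#' @return A data frame of subjects with columns `id`, `arm`, `enroll`
#'   (calendar), `followup_time` (patient scale), `event` (logical).
#' @examples
#' subj <- simulate_trial(default_design(n_per_arm = 20), seed = 1)
#' table(subj$arm)
#' @export
simulate_trial <- function(design, seed) {
  stopifnot(inherits(design, "trial_design"))
  out <- vector("list", length(design$arms))
  for (k in seq_along(design$arms)) {
    arm <- design$arms[[k]]
    hz <- arm$hazard
    if (length(hz$breakpoints) > 1L)
      stop("simulate_trial supports at most one hazard breakpoint per arm",
           call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(seed, k))
    enroll <- sample_enrollment(arm$n, arm$accrual_start, arm$accrual_end)
    target <- -log(stats::runif(arm$n))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    if (length(hz$breakpoints) == 1L) {
      cp <- patient_scale_changepoint(enroll, hz$breakpoints)
      tt <- sample_event_time(target, hz$rates[1], hz$rates[2], cp)
    } else {
      tt <- target / hz$rates[1]
    }
    cens <- administrative_censor(tt, enroll, design$t_max)
    out[[k]] <- data.frame(
      id = if (arm$n) paste0(arm$name, "-", seq_len(arm$n)) else character(0),
      arm = rep(arm$name, arm$n),
      enroll = enroll,
      followup_time = cens$followup_time,
      event = cens$event,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- as.integer(seed)
  res
}
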