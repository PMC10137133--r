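# Strategy comparison on one dataset, exchangeability diagnostics, and Monte
# Carlo operating characteristics across simulated replicates.

#' Design-implied hazard ratio
#'
#' The hazard ratio of treatment to control over the concurrent era, i.e. the
#' ratio of post-changepoint constant rates. Requires every arm's hazard to be
#' constant after `t1_entry` and all control arms to agree there.
#'
#' @param design A [trial_design()].
#' @return Treatment-to-control hazard ratio (a single number).
#' @examples
#' true_hazard_ratio(default_design())  # about 0.85
#' @export
true_hazard_ratio <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  post_rate <- function(arm) {
    hz <- arm$hazard
    if (any(hz$breakpoints > design$t1_entry))
      stop("unsupported design: hazard of arm '", arm$name,
           "' is not constant after t1_entry", call. = FALSE)
    hz$rates[length(hz$rates)]
  }
  trt <- post_rate(design$arms[[design$treatment_arm]])
  ctrl <- vapply(design$arms[names(design$arms) != design$treatment_arm],
                 post_rate, 0)
  if (length(ctrl) == 0L) stop("design has no control arm", call. = FALSE)
  if (diff(range(ctrl)) > 1e-12)
    stop("unsupported design: control arms disagree on the ",
         "post-changepoint rate", call. = FALSE)
  trt / ctrl[[1]]
}

#' Analyze one dataset under one control-borrowing strategy
#'
#' Builds the analysis set for `strategy`, fits the delayed-entry Cox model,
#' and reports the Wald summary in the layout of a treatment-vs-control
#' results table row.
#'
#' @inheritParams build_analysis_set
#' @param true_hr Optional design-implied hazard ratio to carry along (e.g.
#'   from [true_hazard_ratio()]).
#' @param ties Tie-handling method passed to [cox_fit()].
#' @return One-row data frame: `strategy`, `n_records`, `n_events`,
#'   `n_truncated_out`, `true_hr`, `hr`, `se` (of log HR), `ci_lower`,
#'   `ci_upper`, `p`, `beta`, `converged`.
#' @export
run_strategy <- function(subjects, t1_entry, strategy,
                         treatment_arm = "treatment", true_hr = NA_real_,
                         ties = "efron") {
  rec <- build_analysis_set(subjects, t1_entry, strategy, treatment_arm)
  fit <- cox_fit(rec, ties = ties)
  data.frame(strategy = strategy,
             n_records = nrow(rec), n_events = sum(rec$event),
             n_truncated_out = attr(rec, "n_truncated_out"),
             true_hr = true_hr, hr = fit$hr, se = fit$se,
             ci_lower = fit$ci[1], ci_upper = fit$ci[2], p = fit$p,
             beta = fit$beta, converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Strategy comparison table for one dataset
#'
#' @inheritParams run_strategy
#' @param strategies_list Strategies to run, in order (default all of
#'   [strategies()]).
#' @return Data frame with one row per strategy (see [run_strategy()]).
#' @export
comparison_table <- function(subjects, t1_entry,
                             strategies_list = strategies(),
                             treatment_arm = "treatment",
                             true_hr = NA_real_, ties = "efron") {
  if (length(strategies_list) == 0L)
    return(data.frame(strategy = character(0), n_records = integer(0),
                      n_events = integer(0), n_truncated_out = integer(0),
                      true_hr = numeric(0), hr = numeric(0), se = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p = numeric(0), beta = numeric(0),
                      converged = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(strategies_list, function(s)
    run_strategy(subjects, t1_entry, s, treatment_arm, true_hr, ties))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Exchangeability diagnostic for borrowing NCC observation time
#'
#' Delayed-entry two-sample log-rank test comparing concurrent controls
#' (entry 0) with the left-truncated concurrent observation time of
#' non-concurrent controls (entry L > 0). Under the exchangeability
#' assumption that both share one hazard after the new-arm entry, the test
#' rejects at its nominal level.
#'
#' @inheritParams build_analysis_set
#' @return A [logrank_test()] result.
#' @export
exchangeability_check <- function(subjects, t1_entry,
                                  treatment_arm = "treatment") {
  rec <- build_analysis_set(subjects, t1_entry, "pooled_cot", treatment_arm)
  rec <- rec[rec$origin %in% c("CC", "NCC_COT"), , drop = FALSE]
  if (!any(rec$origin == "CC"))
    stop("no concurrent-control records to compare", call. = FALSE)
  if (!any(rec$origin == "NCC_COT"))
    stop("no non-concurrent-control records survive truncation", call. = FALSE)
  logrank_test(rec, group = rec$origin)
}

#' Monte Carlo operating characteristics of control-borrowing strategies
#'
#' Simulates `reps` datasets from `design` (replicate seeds derived
#' deterministically from `seed`), analyzes each under every strategy, and
#' summarizes the sampling behaviour of the log hazard-ratio estimator:
#' bias against the design-implied log HR, empirical SD versus mean model SE,
#' 95% CI coverage of the true HR, and the two-sided 0.05-level rejection
#' rate. Replicates whose fit does not converge are counted and excluded from
#' the moment summaries.
#'
#' @param design A [trial_design()].
#' @param strategies_list Strategies to evaluate.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer master seed.
#' @param ties Tie-handling method for the Cox fits.
#' @return Data frame of class `mc_summary`, one row per strategy:
#'   `strategy`, `reps`, `n_converged`, `mean_beta`, `bias`, `empirical_sd`
#'   (`NA` when fewer than 2 converged replicates), `mean_model_se`,
#'   `coverage`, `rejection_rate`, `truncated_out_mean`. Attributes carry the
#'   design, master seed and true HR.
#' @examples
#' mc <- monte_carlo(default_design(n_per_arm = 40),
#'                   c("cc_only", "pooled_cot"), reps = 5, seed = 42)
#' mc[, c("strategy", "mean_model_se", "coverage")]
#' @export
monte_carlo <- function(design, strategies_list = strategies(), reps, seed,
                        ties = "efron") {
  stopifnot(inherits(design, "trial_design"), reps >= 1)
  thr <- true_hazard_ratio(design)
  log_thr <- log(thr)
  res <- array(NA_real_,
               dim = c(reps, length(strategies_list), 5L),
               dimnames = list(NULL, strategies_list,
                               c("beta", "se", "p", "cover", "ntrunc")))
  conv <- matrix(FALSE, reps, length(strategies_list))
  for (r in seq_len(reps)) {
    subj <- simulate_trial(design, derive_seed(seed, r))
    for (s in seq_along(strategies_list)) {
      row <- tryCatch(
        suppressWarnings(
          run_strategy(subj, design$t1_entry, strategies_list[s],
                       design$treatment_arm, thr, ties)),
        error = function(e) NULL)
      if (is.null(row)) next
      conv[r, s] <- isTRUE(row$converged)
      res[r, s, ] <- c(row$beta, row$se, row$p,
                       as.numeric(row$ci_lower <= thr & thr <= row$ci_upper),
                       row$n_truncated_out)
    }
  }
  summ <- lapply(seq_along(strategies_list), function(s) {
    ok <- conv[, s]
    b <- res[ok, s, "beta"]
    data.frame(
      strategy = strategies_list[s],
      reps = reps,
      n_converged = sum(ok),
      mean_beta = mean(b),
      bias = mean(b) - log_thr,
      empirical_sd = if (sum(ok) >= 2L) stats::sd(b) else NA_real_,
      mean_model_se = mean(res[ok, s, "se"]),
      coverage = mean(res[ok, s, "cover"]),
      rejection_rate = mean(res[ok, s, "p"] < 0.05),
      truncated_out_mean = mean(res[ok, s, "ntrunc"]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "true_hr") <- thr
  attr(out, "design") <- design
  class(out) <- c("mc_summary", class(out))
  out
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Monte Carlo operating characteristics:",
      x$reps[1], "replicates, true HR =",
      signif(attr(x, "true_hr"), 4), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
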