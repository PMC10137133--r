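# Control classification and extraction of the non-concurrent control's
# concurrent observation time (COT) by left truncation.

#' Analysis strategies for the control group
#'
#' * `"cc_only"` — compare treatment with concurrent controls only.
#' * `"pooled_cot"` — additionally borrow the concurrent observation time of
#'   non-concurrent controls via left truncation (the method of interest).
#' * `"pooled_full_ncc"` — naively pool the full non-concurrent control
#'   follow-up from time zero (biased comparator).
#'
#' @return Character vector of the three strategy names.
#' @export
strategies <- function() c("cc_only", "pooled_cot", "pooled_full_ncc")

#' Classify control subjects as concurrent or non-concurrent
#'
#' A control patient is non-concurrent exactly when randomized strictly before
#' the new experimental arm joined; enrollment at `t1_entry` itself counts as
#' concurrent (randomized under the new-arm era).
#'
#' @param enroll Calendar enrollment time(s).
#' @param t1_entry Calendar entry time of the new arm.
#' @return Character vector, `"concurrent"` or `"non_concurrent"`.
#' @export
classify_control <- function(enroll, t1_entry) {
  ifelse(enroll < t1_entry, "non_concurrent", "concurrent")
}

#' Left truncate non-concurrent control subjects at the new-arm entry
#'
#' Each NCC subject enters the analysis risk set at patient time
#' `L = t1_entry - enroll` (the start of their concurrent observation time).
#' Subjects whose follow-up ends at or before `L` never enter a risk set and
#' are dropped ("truncated out"); the strict boundary matches the risk-set
#' convention `t > L`.
#'
#' @param subjects Data frame of NCC subjects (columns `id`, `enroll`,
#'   `followup_time`, `event`); every `enroll` must be `< t1_entry`.
#' @param t1_entry Calendar entry time of the new arm.
#' @return Analysis records (`id`, `group`, `entry`, `exit`, `event`,
#'   `origin = "NCC_COT"`) for the surviving subjects, with attribute
#'   `n_truncated_out` giving the number dropped.
#' @export
left_truncate <- function(subjects, t1_entry) {
  if (any(subjects$enroll >= t1_entry))
    stop("left_truncate applies only to non-concurrent controls ",
         "(enroll < t1_entry)", call. = FALSE)
  L <- t1_entry - subjects$enroll
  keep <- subjects$followup_time > L
  out <- data.frame(
    id = subjects$id[keep],
    group = rep(0L, sum(keep)),
    entry = L[keep],
    exit = subjects$followup_time[keep],
    event = subjects$event[keep],
    origin = rep("NCC_COT", sum(keep)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_truncated_out") <- sum(!keep)
  out
}

#' Assemble analysis-ready records under a control-borrowing strategy
#'
#' Treatment and concurrent-control subjects enter at patient time 0. What
#' happens to non-concurrent controls depends on `strategy`: dropped
#' (`"cc_only"`), left truncated at the new-arm entry (`"pooled_cot"`), or
#' included in full from time zero (`"pooled_full_ncc"`). Subjects are
#' classified CC/NCC purely by enrollment time, via [classify_control()].
#'
#' @param subjects Subject data frame as produced by [simulate_trial()] or
#'   [read_subjects()].
#' @param t1_entry Calendar entry time of the new arm.
#' @param strategy One of [strategies()].
#' @param treatment_arm Arm label identifying treated subjects; every other
#'   arm is control.
#' @return Analysis records data frame (`id`, `group`, `entry`, `exit`,
#'   `event`, `origin` in {TREATMENT, CC, NCC_COT, NCC_FULL}) with attribute
#'   `n_truncated_out`.
#' @examples
#' subj <- simulate_trial(default_design(n_per_arm = 30), seed = 7)
#' nrow(build_analysis_set(subj, 3, "cc_only"))
#' nrow(build_analysis_set(subj, 3, "pooled_cot"))
#' @export
build_analysis_set <- function(subjects, t1_entry, strategy,
                               treatment_arm = "treatment") {
  strategy <- match.arg(strategy, strategies())
  is_trt <- subjects$arm == treatment_arm
  ctrl <- subjects[!is_trt, , drop = FALSE]
  cls <- classify_control(ctrl$enroll, t1_entry)
  cc <- ctrl[cls == "concurrent", , drop = FALSE]
  ncc <- ctrl[cls == "non_concurrent", , drop = FALSE]

  as_record <- function(df, group, origin) data.frame(
    id = df$id, group = rep(group, nrow(df)),
    entry = rep(0, nrow(df)), exit = df$followup_time, event = df$event,
    origin = rep(origin, nrow(df)), stringsAsFactors = FALSE
  )

  parts <- list(as_record(subjects[is_trt, , drop = FALSE], 1L, "TREATMENT"),
                as_record(cc, 0L, "CC"))
  n_out <- 0L
  if (strategy == "pooled_cot") {
    trunc <- left_truncate(ncc, t1_entry)
    n_out <- attr(trunc, "n_truncated_out")
    parts <- c(parts, list(trunc))
  } else if (strategy == "pooled_full_ncc") {
    parts <- c(parts, list(as_record(ncc, 0L, "NCC_FULL")))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "n_truncated_out") <- n_out
  attr(out, "strategy") <- strategy
  out
}
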