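#' Piecewise-constant hazard specification
#'
#' A hazard defined on the calendar timeline as a step function: `rates[1]`
#' applies before `breakpoints[1]`, `rates[2]` between `breakpoints[1]` and
#' `breakpoints[2]`, and so on. A spec with no breakpoints is a constant-hazard
#' (exponential) specification.
#'
#' @param rates Numeric vector of hazard rates (events per unit time), all
#'   strictly positive; one more rate than breakpoints.
#' @param breakpoints Strictly increasing calendar times at which the rate
#'   changes (possibly empty).
#' @return An object of class `hazard_spec`.
#' @examples
#' hazard_spec(0.134)                      # exponential
#' hazard_spec(c(0.2, 0.134), breakpoints = 3)
#' @export
hazard_spec <- function(rates, breakpoints = numeric(0)) {
  rates <- as.numeric(rates)
  breakpoints <- as.numeric(breakpoints)
  if (length(rates) != length(breakpoints) + 1L)
    stop("need exactly one more rate than breakpoints", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all hazard rates must be finite and > 0", call. = FALSE)
  if (length(breakpoints) && (any(!is.finite(breakpoints)) ||
                              any(diff(breakpoints) <= 0)))
    stop("breakpoints must be finite and strictly increasing", call. = FALSE)
  structure(list(rates = rates, breakpoints = breakpoints),
            class = "hazard_spec")
}

#' Hazard rate at given calendar times
#'
#' @param spec A [hazard_spec()].
#' @param t Calendar times (vectorized). The rate on `[breakpoints[k],
#'   breakpoints[k+1])` is `rates[k + 1]` (right-continuous step function).
#' @return Numeric vector of rates.
#' @export
hazard_rate <- function(spec, t) {
  stopifnot(inherits(spec, "hazard_spec"))
  spec$rates[findInterval(t, spec$breakpoints) + 1L]
}

#' @export
print.hazard_spec <- function(x, ...) {
  if (length(x$breakpoints) == 0L) {
    cat("Constant hazard:", x$rates, "per unit time\n")
  } else {
    cat("Piecewise-constant hazard:\n")
    lo <- c(-Inf, x$breakpoints)
    hi <- c(x$breakpoints, Inf)
    for (i in seq_along(x$rates))
      cat(sprintf("  [%g, %g): %g\n", lo[i], hi[i], x$rates[i]))
  }
  invisible(x)
}

#' Trial arm specification
#'
#' @param name Arm label (e.g. `"treatment"`, `"control_cc"`).
#' @param n Number of patients to enroll (non-negative integer).
#' @param accrual_start,accrual_end Calendar accrual window; enrollment times
#'   are uniform on `[accrual_start, accrual_end]`.
#' @param hazard A [hazard_spec()] on the calendar timeline.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, n, accrual_start, accrual_end, hazard) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("arm name must be a non-empty string", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative count", call. = FALSE)
  if (!is.finite(accrual_start) || !is.finite(accrual_end) ||
      accrual_start > accrual_end)
    stop("need accrual_start <= accrual_end, both finite", call. = FALSE)
  if (!inherits(hazard, "hazard_spec"))
    stop("hazard must be a hazard_spec", call. = FALSE)
  structure(list(name = name, n = n, accrual_start = accrual_start,
                 accrual_end = accrual_end, hazard = hazard),
            class = "arm_spec")
}

#' Platform-trial design
#'
#' Bundles the arms, the calendar time at which the experimental arm of
#' interest joins the platform (`t1_entry`, the non-concurrent /
#' concurrent-control boundary), and the administrative end of study `t_max`.
#'
#' @param arms List of [arm_spec()] objects with distinct names.
#' @param t1_entry Calendar entry time of the new experimental arm; must lie
#'   within the overall accrual period.
#' @param t_max Calendar end-of-study time; all follow-up is administratively
#'   censored at `t_max`. Must exceed the latest accrual time.
#' @param treatment_arm Name of the experimental arm being evaluated.
#' @return An object of class `trial_design`.
#' @seealso [default_design()] for the worked three-arm configuration.
#' @export
trial_design <- function(arms, t1_entry, t_max, treatment_arm = "treatment") {
  if (!length(arms) || !all(vapply(arms, inherits, TRUE, "arm_spec")))
    stop("arms must be a non-empty list of arm_spec objects", call. = FALSE)
  nm <- vapply(arms, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("arm names must be distinct", call. = FALSE)
  if (!treatment_arm %in% nm)
    stop("treatment_arm '", treatment_arm, "' not among arms", call. = FALSE)
  starts <- vapply(arms, `[[`, 0, "accrual_start")
  ends <- vapply(arms, `[[`, 0, "accrual_end")
  if (t1_entry < min(starts) || t1_entry > max(ends))
    stop("t1_entry must lie within the overall accrual period", call. = FALSE)
  if (t_max <= max(ends))
    stop("t_max must exceed the latest accrual time", call. = FALSE)
  names(arms) <- nm
  structure(list(arms = arms, t1_entry = t1_entry, t_max = t_max,
                 treatment_arm = treatment_arm),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Platform trial design:", length(x$arms), "arms,",
      "new-arm entry at t =", x$t1_entry, ", end of study at t =", x$t_max,
      "\n")
  for (a in x$arms)
    cat(sprintf("  %-12s n = %4d, accrual [%g, %g], rates {%s}\n",
                a$name, a$n, a$accrual_start, a$accrual_end,
                paste(signif(a$hazard$rates, 4), collapse = ", ")))
  invisible(x)
}

#' Default three-arm platform-trial design
#'
#' The worked configuration used throughout the package: non-concurrent
#' controls accrue uniformly on calendar `[0, 3]`, concurrent controls and the
#' new treatment accrue on `[3, 6]`, and everyone is administratively censored
#' at calendar time 15. The control hazard is 0.2 before the new arm joins at
#' time 3 and `0.2 * exp(-0.4) = 0.134` afterwards (a standard-of-care
#' improvement affecting all controls on study); the treatment hazard is a
#' constant 0.114, so the design-implied hazard ratio is about 0.85.
#'
#' Sample sizes are not part of the generative story and default to 100 per
#' arm; headline numbers from any single simulated dataset therefore vary
#' with `n_per_arm` and seed.
#'
#' @param n_per_arm Patients per arm (scalar, or length-3 vector in the order
#'   NCC control, CC control, treatment).
#' @param treatment_rate Constant treatment-arm hazard; override to
#'   `0.2 * exp(-0.4)` for a null (no-effect) design.
#' @return A [trial_design()].
#' @examples
#' d <- default_design(n_per_arm = 50)
#' true_hazard_ratio(d)
#' @export
default_design <- function(n_per_arm = 100, treatment_rate = 0.114) {
  n <- rep_len(n_per_arm, 3L)
  post <- 0.2 * exp(-0.4) # = 0.1340640...
  trial_design(
    arms = list(
      arm_spec("control_ncc", n[1], 0, 3,
               hazard_spec(c(0.2, post), breakpoints = 3)),
      arm_spec("control_cc", n[2], 3, 6, hazard_spec(post)),
      arm_spec("treatment", n[3], 3, 6, hazard_spec(treatment_rate))
    ),
    t1_entry = 3, t_max = 15, treatment_arm = "treatment"
  )
}
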