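# Delayed-entry survival machinery built from first principles: risk sets
# under left truncation, product-limit estimation, Cox partial likelihood with
# Newton-Raphson, and the two-sample log-rank test. The risk-set convention
# throughout is R(t) = {j : exit_j >= t > entry_j} (entry strict, exit
# inclusive).

Z975 <- 1.959964

check_records <- function(records) {
  need <- c("entry", "exit", "event")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (any(records$exit <= records$entry))
    stop("every record needs exit > entry", call. = FALSE)
  invisible(records)
}

#' Risk set under left truncation
#'
#' Indices of records at risk at analysis time `t`: those with
#' `exit >= t > entry`. A subject contributes person-time only after their
#' delayed-entry time, so late entrants are absent from earlier risk sets.
#'
#' @param records Analysis records (columns `entry`, `exit`, `event`).
#' @param t A single patient-scale time, `t > 0`.
#' @return Integer vector of row indices.
#' @export
risk_set <- function(records, t) {
  check_records(records)
  stopifnot(length(t) == 1L, t > 0)
  which(records$exit >= t & t > records$entry)
}

# Weighted number/sum at risk for a vector of times, via sorted cumulative
# sums: sum over {exit >= t > entry} w = sum_{entry < t} w - sum_{exit < t} w
# (valid because exit > entry for every record).
risk_sums <- function(times, entry, exit, w) {
  oy <- order(exit); oe <- order(entry)
  cy <- c(0, cumsum(w[oy])); ce <- c(0, cumsum(w[oe]))
  ky <- findInterval(times, exit[oy], left.open = TRUE)   # #{exit < t}
  ke <- findInterval(times, entry[oe], left.open = TRUE)  # #{entry < t}
  ce[ke + 1L] - cy[ky + 1L]
}

#' Kaplan-Meier estimate with delayed entry
#'
#' Product-limit estimator over the distinct event times, with risk sets that
#' honour left truncation: a record counts as at risk at `t` only when
#' `exit >= t > entry`. Variance by Greenwood's formula; pointwise confidence
#' intervals on the log(-log) scale by default (plain linear Greenwood
#' selectable).
#'
#' With all entry times zero this reduces to the textbook Kaplan-Meier
#' estimator. Note that with late entry the early risk sets can be small, so
#' the curve near t = 0 may be unstable; this is inherent to delayed-entry
#' estimation, not a defect.
#'
#' @param records Analysis records (columns `entry`, `exit`, `event`).
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `km_fit`: `time`, `at_risk`, `events`,
#'   `survival`, `variance` (Greenwood), `ci_lower`, `ci_upper`. With no
#'   events the estimate is identically 1 and all vectors are empty.
#' @examples
#' rec <- data.frame(entry = c(0, 1, 0), exit = c(2, 3, 4),
#'                   event = c(TRUE, TRUE, FALSE))
#' km_fit(rec)$survival  # 2/3, 1/3
#' @export
km_fit <- function(records, conf_type = c("log-log", "plain"),
                   conf_level = 0.95) {
  check_records(records)
  conf_type <- match.arg(conf_type)
  tev <- sort(unique(records$exit[records$event]))
  n_at_risk <- risk_sums(tev, records$entry, records$exit,
                         rep(1, nrow(records)))
  d <- vapply(tev, function(t) sum(records$event & records$exit == t), 0)
  surv <- cumprod(1 - d / n_at_risk)
  gw <- cumsum(d / (n_at_risk * pmax(n_at_risk - d, 0)))  # Inf when n == d
  variance <- surv^2 * gw
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "plain") {
    half <- z * sqrt(variance)
    lo <- pmax(surv - half, 0); hi <- pmin(surv + half, 1)
  } else {
    # var(log(-log S)) = gw / log(S)^2; degenerate at S = 0 or 1
    ok <- surv > 0 & surv < 1 & is.finite(gw)
    lo <- hi <- rep(NA_real_, length(surv))
    se_ll <- sqrt(gw[ok]) / abs(log(surv[ok]))
    lo[ok] <- surv[ok]^exp(z * se_ll)
    hi[ok] <- surv[ok]^exp(-z * se_ll)
    lo[surv == 0] <- 0; hi[surv == 0] <- 0
  }
  structure(list(time = tev, at_risk = n_at_risk, events = d,
                 survival = surv, variance = variance,
                 ci_lower = lo, ci_upper = hi,
                 conf_type = conf_type, conf_level = conf_level,
                 n = nrow(records)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param fit A [km_fit()].
#' @param times Patient-scale times (vectorized).
#' @return Estimated survival at each time (1 before the first event time).
#' @export
km_survival <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"))
  c(1, fit$survival)[findInterval(times, fit$time) + 1L]
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Delayed-entry Kaplan-Meier estimate:", x$n, "records,",
      sum(x$events), "events at", length(x$time), "distinct times\n")
  if (length(x$time)) {
    df <- data.frame(time = x$time, at_risk = x$at_risk, events = x$events,
                     survival = signif(x$survival, 4),
                     lower = signif(x$ci_lower, 4),
                     upper = signif(x$ci_upper, 4))
    print(utils::head(df, 10), row.names = FALSE)
    if (length(x$time) > 10) cat("  ...", length(x$time) - 10, "more rows\n")
  }
  invisible(x)
}

# ---- Cox partial likelihood (single binary covariate, delayed entry) -------

# Precompute everything beta-independent: per distinct event time, the event
# count d, the covariate sum over tied events, and the row indices of the
# events grouped by time (for Efron's tied-mass correction).
cox_prep <- function(records, ties) {
  check_records(records)
  if (!"group" %in% names(records))
    stop("records need a binary 'group' covariate column", call. = FALSE)
  x <- as.numeric(records$group)
  if (!all(x %in% c(0, 1)))
    stop("group covariate must be binary 0/1", call. = FALSE)
  ev_rows <- which(records$event)
  tev <- sort(unique(records$exit[ev_rows]))
  ev_k <- match(records$exit[ev_rows], tev)        # time index of each event
  d <- tabulate(ev_k, nbins = length(tev))
  s1d <- as.numeric(rowsum(x[ev_rows], ev_k, reorder = TRUE))
  list(x = x, entry = records$entry, exit = records$exit,
       tev = tev, d = d, s1d = s1d, ev_rows = ev_rows, ev_k = ev_k,
       ties = ties, n = nrow(records), nev = length(ev_rows))
}

# Partial log-likelihood, score and observed information at beta, using
# O(n log n) risk-set sums. For a binary covariate the second moment S2
# equals S1. Efron's correction subtracts fractions of the tied-event mass
# from the risk-set sums; with no ties it reduces to the Breslow form.
cox_quantities <- function(prep, beta) {
  w <- exp(beta * prep$x)
  wx <- w * prep$x
  S0 <- risk_sums(prep$tev, prep$entry, prep$exit, w)
  S1 <- risk_sums(prep$tev, prep$entry, prep$exit, wx)
  if (prep$ties == "efron" && any(prep$d > 1)) {
    wd <- as.numeric(rowsum(w[prep$ev_rows], prep$ev_k, reorder = TRUE))
    wxd <- as.numeric(rowsum(wx[prep$ev_rows], prep$ev_k, reorder = TRUE))
    frac <- sequence(prep$d) - 1L            # 0 .. d_k - 1 within each time
    kk <- rep.int(seq_along(prep$tev), prep$d)
    denom <- S0[kk] - (frac / prep$d[kk]) * wd[kk]
    num <- S1[kk] - (frac / prep$d[kk]) * wxd[kk]
    loglik <- sum(beta * prep$s1d) - sum(log(denom))
    score <- sum(prep$s1d) - sum(num / denom)
    info <- sum(num / denom - (num / denom)^2)
  } else {
    # Breslow form (exact when every d_k = 1)
    loglik <- sum(beta * prep$s1d - prep$d * log(S0))
    r <- S1 / S0
    score <- sum(prep$s1d - prep$d * r)
    info <- sum(prep$d * (r - r^2))
  }
  list(loglik = loglik, score = score, info = info)
}

#' Cox partial log-likelihood under left truncation
#'
#' Evaluates the partial log-likelihood of the proportional-hazards model
#' `lambda(t | x) = lambda0(t) exp(beta x)` for a single binary covariate,
#' with delayed-entry risk sets `{j : exit_j >= t > entry_j}`. Ties are
#' handled by Efron's method by default (Breslow selectable); the two
#' coincide when all event times are distinct.
#'
#' @param records Analysis records (`group`, `entry`, `exit`, `event`).
#' @param beta Log hazard ratio at which to evaluate.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return The partial log-likelihood value.
#' @export
cox_loglik <- function(records, beta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  prep <- cox_prep(records, ties)
  cox_quantities(prep, beta)$loglik
}

#' Fit the Cox proportional-hazards model with delayed entry
#'
#' Maximizes the partial likelihood for a single binary group covariate by
#' Newton-Raphson started at beta = 0, with step halving whenever a step
#' would decrease the log-likelihood. Convergence is declared when the
#' absolute score falls below `tol`; a trajectory escaping `|beta| > 15` is
#' flagged as monotone likelihood (non-convergence) with a warning. The
#' standard error is the inverse square-root of the observed information at
#' the maximum; the hazard ratio, 95% CI and p-value are Wald quantities on
#' the log scale (see [wald_summary()]).
#'
#' @inheritParams cox_loglik
#' @param tol Convergence tolerance on the absolute score.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_fit`: `beta`, `se`, `hr`, `ci`, `p`,
#'   `loglik`, `iterations`, `converged`, `n`, `events`, `ties`.
#' @examples
#' rec <- data.frame(group = c(1, 0, 1, 0), entry = 0,
#'                   exit = 1:4, event = TRUE)
#' cox_fit(rec)$hr  # (1 + sqrt(17)) / 2
#' @export
cox_fit <- function(records, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 25L) {
  ties <- match.arg(ties)
  prep <- cox_prep(records, ties)
  if (length(unique(prep$x)) < 2L)
    stop("degenerate covariate: group must take both values", call. = FALSE)
  if (length(prep$tev) == 0L)
    stop("no events: the partial likelihood is flat", call. = FALSE)

  beta <- 0; q <- cox_quantities(prep, beta)
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (abs(q$score) < tol) { converged <- TRUE; break }
    if (q$info <= 0)
      stop("degenerate covariate: no covariate variation in risk sets",
           call. = FALSE)
    step <- q$score / q$info
    new_beta <- beta + step
    q_new <- cox_quantities(prep, new_beta)
    halvings <- 0L
    while (q_new$loglik < q$loglik && halvings < 20L) {
      step <- step / 2; new_beta <- beta + step
      q_new <- cox_quantities(prep, new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta; q <- q_new
    if (abs(beta) > 15) break
  }
  if (abs(q$score) < tol) converged <- TRUE
  if (abs(beta) > 15) {
    converged <- FALSE
    warning("monotone partial likelihood: |beta| exceeded 15; ",
            "estimate unreliable", call. = FALSE)
  }
  se <- if (q$info > 0) 1 / sqrt(q$info) else NA_real_
  ws <- wald_summary(beta, max(se, .Machine$double.xmin))
  structure(list(beta = beta, se = se, hr = ws$hr, ci = ws$ci, p = ws$p,
                 loglik = q$loglik, score = q$score,
                 iterations = iter, converged = converged,
                 n = prep$n, events = prep$nev, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox fit (delayed entry, %s ties): n = %d, events = %d\n", x$ties, x$n,
    x$events))
  cat(sprintf(
    "  beta = %.4f (se %.4f)  HR = %.4f  95%% CI [%.4f, %.4f]  p = %.4g\n",
    x$beta, x$se, x$hr, x$ci[1], x$ci[2], x$p))
  if (!x$converged) cat("  WARNING: did not converge\n")
  invisible(x)
}

#' Wald inference on the log hazard-ratio scale
#'
#' @param beta Log hazard-ratio estimate.
#' @param se Its standard error (positive).
#' @return List with `hr = exp(beta)`, `ci` (95% Wald interval for the HR)
#'   and two-sided `p = 2 * (1 - pnorm(|beta| / se))`.
#' @export
wald_summary <- function(beta, se) {
  if (!is.finite(se) || se <= 0) stop("se must be positive", call. = FALSE)
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * Z975 * se),
       p = 2 * stats::pnorm(abs(beta) / se, lower.tail = FALSE))
}

#' Two-sample log-rank test with delayed entry
#'
#' Observed-minus-expected statistic with the hypergeometric variance at each
#' distinct event time, using left-truncated risk sets. Equivalent to the Cox
#' score test at beta = 0 when all event times are distinct.
#'
#' @param records Analysis records (`entry`, `exit`, `event`).
#' @param group Two-level grouping vector aligned with `records` (defaults to
#'   `records$group`).
#' @return An object of class `logrank_result`: `statistic` (chi-squared, 1
#'   df), `p`, per-group `observed` and `expected` event counts, and a
#'   `defined` flag (FALSE, with `p = 1`, when there are no events or no
#'   variance).
#' @export
logrank_test <- function(records, group = records$group) {
  check_records(records)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  g1 <- g == levels(g)[1]
  tev <- sort(unique(records$exit[records$event]))
  obs <- stats::setNames(numeric(2), levels(g))
  if (length(tev) == 0L) {
    return(structure(list(statistic = NA_real_, df = 1L, p = 1,
                          observed = obs, expected = obs, defined = FALSE),
                     class = "logrank_result"))
  }
  one <- rep(1, nrow(records))
  n_all <- risk_sums(tev, records$entry, records$exit, one)
  n_1 <- risk_sums(tev, records$entry, records$exit, as.numeric(g1))
  d <- vapply(tev, function(t) sum(records$event & records$exit == t), 0)
  d1 <- vapply(tev, function(t) sum(records$event & records$exit == t & g1), 0)
  e1 <- d * n_1 / n_all
  v <- d * (n_1 / n_all) * (1 - n_1 / n_all) *
    ifelse(n_all > 1, (n_all - d) / (n_all - 1), 0)
  obs[1] <- sum(d1); obs[2] <- sum(d) - obs[1]
  expd <- stats::setNames(c(sum(e1), sum(d) - sum(e1)), levels(g))
  V <- sum(v)
  if (V <= 0) {
    return(structure(list(statistic = NA_real_, df = 1L, p = 1,
                          observed = obs, expected = expd, defined = FALSE),
                     class = "logrank_result"))
  }
  stat <- (obs[[1]] - expd[[1]])^2 / V
  structure(list(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 observed = obs, expected = expd, defined = TRUE),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Delayed-entry log-rank test:\n")
  if (!x$defined) {
    cat("  statistic undefined (no events or no variance); p = 1\n")
  } else {
    cat(sprintf("  chi-squared = %.4f on %d df, p = %.4g\n",
                x$statistic, x$df, x$p))
    tab <- rbind(observed = x$observed, expected = signif(x$expected, 4))
    print(tab)
  }
  invisible(x)
}

# ---- Brute-force oracles ---------------------------------------------------

#' Brute-force partial log-likelihood (independent oracle)
#'
#' Literal enumeration of the risk set `{j : exit_j >= t > entry_j}` at every
#' event time, intended as an independent check of [cox_loglik()] on small
#' instances. No shared code path with the production implementation.
#'
#' @inheritParams cox_loglik
#' @export
brute_force_loglik <- function(records, beta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_records(records)
  x <- as.numeric(records$group)
  ll <- 0
  for (t in sort(unique(records$exit[records$event]))) {
    at_risk <- which(records$exit >= t & t > records$entry)
    ev <- which(records$event & records$exit == t)
    d <- length(ev)
    s0 <- sum(exp(beta * x[at_risk]))
    s1 <- sum(beta * x[ev])
    if (ties == "efron" && d > 1) {
      wd <- sum(exp(beta * x[ev]))
      ll <- ll + s1 -
        sum(vapply(seq_len(d) - 1, function(k) log(s0 - (k / d) * wd), 0))
    } else {
      ll <- ll + s1 - d * log(s0)
    }
  }
  ll
}

#' Brute-force maximum partial-likelihood estimate (independent oracle)
#'
#' Golden-section search of [brute_force_loglik()] over beta in [-15, 15]
#' (the partial likelihood is concave in beta, so unimodal). For small
#' instances only.
#'
#' @inheritParams cox_loglik
#' @param tol Bracket width at which to stop.
#' @return The maximizing beta.
#' @export
brute_force_fit <- function(records, ties = c("efron", "breslow"),
                            tol = 1e-6) {
  ties <- match.arg(ties)
  f <- function(b) brute_force_loglik(records, b, ties)
  gr <- (sqrt(5) - 1) / 2
  lo <- -15; hi <- 15
  b1 <- hi - gr * (hi - lo); b2 <- lo + gr * (hi - lo)
  f1 <- f(b1); f2 <- f(b2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- b1; b1 <- b2; f1 <- f2
      b2 <- lo + gr * (hi - lo); f2 <- f(b2)
    } else {
      hi <- b2; b2 <- b1; f2 <- f1
      b1 <- hi - gr * (hi - lo); f1 <- f(b1)
    }
  }
  (lo + hi) / 2
}
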