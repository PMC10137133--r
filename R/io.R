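# Readers and writers: subjects CSV, analysis-records CSV, YAML design
# configuration, JSON fit export, TSV result tables. Comma-separated, header
# row, '.' decimal; lines starting with '#' are comments (used to echo the
# resolved seed into data files).

#' Write simulated subjects to CSV
#'
#' Columns `id,arm,enroll,followup_time,event` with `event` coded 0/1. A
#' `# seed:` comment line records the simulation seed when present.
#'
#' @param subjects Subject data frame from [simulate_trial()].
#' @param path Output file path.
#' @param seed Seed to echo; defaults to the data frame's `seed` attribute.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path, seed = attr(subjects, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  df <- subjects
  df$event <- as.integer(df$event)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subjects CSV
#'
#' @param path File written by [write_subjects()] (comment lines ignored).
#' @return Subject data frame with logical `event`; the echoed seed, if any,
#'   is attached as attribute `seed`.
#' @export
read_subjects <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "arm", "enroll", "followup_time", "event")
  if (!all(need %in% names(df)))
    stop("subjects CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df$event <- df$event != 0
  if (grepl("^# seed:", first))
    attr(df, "seed") <- as.integer(sub("^# seed:\\s*", "", first))
  df
}

#' Write analysis records to CSV
#'
#' Counting-process layout `id,group,entry,exit,event,origin` with the
#' (entry, exit] convention and `event` coded 0/1.
#'
#' @param records Analysis records from [build_analysis_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- records
  df$event <- as.integer(df$event)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis-records CSV
#'
#' @param path File in the layout of [write_records()]. An `origin` column is
#'   optional when the records come from elsewhere.
#' @return Analysis records data frame with logical `event`.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "group", "entry", "exit", "event")
  if (!all(need %in% names(df)))
    stop("records CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df$event <- df$event != 0
  df
}

#' Read a trial-design YAML configuration
#'
#' Expected keys: `arms` (list of `{name, n, accrual: [start, end], hazard:
#' {rates: [...], breakpoints: [...]}}`), `t1_entry`, `t_max`, optional
#' `treatment_arm` (default `"treatment"`) and `seed`.
#'
#' @param path YAML file path.
#' @return List with elements `design` (a [trial_design()]) and `seed`
#'   (`NULL` when the file has none).
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("arms", "t1_entry", "t_max"))
    if (is.null(cfg[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  arms <- lapply(cfg$arms, function(a) {
    for (key in c("name", "n", "accrual", "hazard"))
      if (is.null(a[[key]]))
        stop("arm config is missing key '", key, "'", call. = FALSE)
    if (is.null(a$hazard$rates))
      stop("arm config is missing key 'hazard.rates'", call. = FALSE)
    hz <- hazard_spec(unlist(a$hazard$rates),
                      breakpoints = unlist(a$hazard$breakpoints))
    acc <- unlist(a$accrual)
    if (length(acc) != 2L)
      stop("accrual must be [start, end]", call. = FALSE)
    arm_spec(a$name, a$n, acc[1], acc[2], hz)
  })
  design <- trial_design(arms, cfg$t1_entry, cfg$t_max,
                         treatment_arm = cfg$treatment_arm %||% "treatment")
  list(design = design, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a Cox fit as JSON
#'
#' @param fit A [cox_fit()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cox_fit"))
  jsonlite::write_json(
    list(beta = fit$beta, se = fit$se, hr = fit$hr,
         ci = as.numeric(fit$ci), p = fit$p, loglik = fit$loglik,
         n = fit$n, events = fit$events, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param df Data frame (e.g. from [comparison_table()] or [monte_carlo()]).
#' @param path Output file path.
#' @param seed Optional seed echoed as a `# seed:` comment line.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
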