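#' Filter period estimates to the plausible circadian range
#'
#' Removes model-fit periods outside the plausible circadian band: values
#' above `max_period_h` or below `min_period_h` are dropped, so the bounds
#' themselves are retained (18.0 h and 32.0 h pass with the defaults).
#'
#' @param estimates A tibble with a `period_h` column (e.g. from
#'   [estimate_periods]).
#' @param min_period_h,max_period_h Inclusive retention bounds, hours
#'   (defaults 18 and 32).
#' @return A list with tibbles `retained` and `removed`; `removed` gains a
#'   `removal_reason` column. Every input row appears in exactly one of the
#'   two.
#' @examples
#' est <- tibble::tibble(period_h = c(17.9, 18, 24, 32, 32.1))
#' filter_periods(est)
#' @export
filter_periods <- function(estimates, min_period_h = 18, max_period_h = 32) {
  if (!is.data.frame(estimates) || !"period_h" %in% names(estimates)) {
    abort("`estimates` must be a data frame with a `period_h` column",
          class = "leaftrack_error_qc")
  }
  estimates <- as_tibble(estimates)
  if (nrow(estimates) == 0) {
    return(list(retained = estimates,
                removed = mutate(estimates, removal_reason = character(0))))
  }
  keep <- estimates$period_h >= min_period_h &
    estimates$period_h <= max_period_h
  removed <- estimates[!keep, , drop = FALSE]
  removed$removal_reason <- ifelse(
    removed$period_h < min_period_h,
    paste0("period below ", min_period_h, " h"),
    paste0("period above ", max_period_h, " h")
  )
  list(retained = estimates[keep, , drop = FALSE], removed = removed)
}

#' Summarize one line's retained period estimates
#'
#' Computes the mean period, sample standard deviation (n - 1 denominator),
#' and standard error of the mean (SEM = sd / sqrt(n)). A line is excluded
#' when its SEM exceeds `sem_cutoff_h` (default 0.50 h, i.e. 30 min): the
#' SEM is the precision gate for carrying a line's mean period into
#' downstream genetic analysis. Lines with a single retained estimate are
#' excluded as well, since their SEM is undefined and precision cannot be
#' certified.
#'
#' @param periods_h Numeric vector of retained period estimates, hours.
#' @param line_id Line identifier.
#' @param sem_cutoff_h SEM exclusion threshold, hours.
#' @return A one-row tibble: `line_id`, `n_retained`, `mean_period_h`,
#'   `sd_h`, `sem_h`, `excluded`, `exclusion_reason`.
#' @examples
#' summarize_line(c(24.0, 24.2, 23.8, 24.0), "line1")
#' summarize_line(c(20, 28), "noisy")  # SEM 2.83 > 0.50: excluded
#' @export
summarize_line <- function(periods_h, line_id = "line", sem_cutoff_h = 0.5) {
  n <- length(periods_h)
  if (n == 0) {
    return(tibble(line_id = line_id, n_retained = 0L,
                  mean_period_h = NA_real_, sd_h = NA_real_,
                  sem_h = NA_real_, excluded = TRUE,
                  exclusion_reason = "no estimates after period filter"))
  }
  m <- mean(periods_h)
  s <- if (n > 1) stats::sd(periods_h) else NA_real_
  sem <- if (n > 1) s / sqrt(n) else NA_real_
  excluded <- n == 1 || sem > sem_cutoff_h
  reason <- if (n == 1) {
    "single estimate: SEM undefined"
  } else if (sem > sem_cutoff_h) {
    paste0("SEM ", round(sem, 3), " h above cutoff ", sem_cutoff_h, " h")
  } else {
    NA_character_
  }
  tibble(line_id = line_id, n_retained = as.integer(n), mean_period_h = m,
         sd_h = s, sem_h = sem, excluded = excluded,
         exclusion_reason = reason)
}

#' Filter and aggregate per-plant periods to per-line summaries
#'
#' Applies the period-bounds filter ([filter_periods]) first, then
#' summarizes each line and applies the SEM gate ([summarize_line]). Both
#' removal steps are logged.
#'
#' @param estimates A tibble with columns `line_id` and `period_h` (one row
#'   per plant).
#' @inheritParams filter_periods
#' @inheritParams summarize_line
#' @return A list: `lines` (per-line summary tibble, all lines with their
#'   `excluded` flag), `removal_log` (per-plant rows removed by the period
#'   bounds, with reasons).
#' @export
summarize_lines <- function(estimates, min_period_h = 18, max_period_h = 32,
                            sem_cutoff_h = 0.5) {
  if (!all(c("line_id", "period_h") %in% names(estimates))) {
    abort("`estimates` needs columns line_id and period_h",
          class = "leaftrack_error_qc")
  }
  flt <- filter_periods(estimates, min_period_h, max_period_h)
  all_lines <- unique(estimates$line_id)
  lines <- bind_rows(lapply(all_lines, function(id) {
    p <- flt$retained$period_h[flt$retained$line_id == id]
    summarize_line(p, line_id = id, sem_cutoff_h = sem_cutoff_h)
  }))
  list(lines = lines, removal_log = flt$removed)
}
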