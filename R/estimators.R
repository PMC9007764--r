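# epoch-second interval matrix for a set of record rows
.record_intervals <- function(records, rows = seq_len(nrow(records))) {
  cbind(start = as.numeric(records$start[rows]), end = as.numeric(records$end[rows]))
}

# per-session list of normalized interval matrices for records with keep==TRUE
.session_slice_intervals <- function(dataset, keep) {
  r <- dataset$records
  out <- list()
  for (sid in dataset$sessions$session_id) {
    rows <- which(keep & r$session_id == sid)
    out[[sid]] <- if (length(rows)) normalize_intervals(.record_intervals(r, rows))
                  else matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  out
}

#' Time spent on an analysis slice, accounting for multitasking
#'
#' Total seconds during which at least one record matching the selector was
#' active — the union of the matching intervals within each session, so that
#' a second covered by two simultaneous matching tasks is counted once.
#'
#' @param dataset An `observation_dataset`.
#' @param sel A [selector()] defining the slice.
#' @return Duration in seconds.
#' @export
time_on <- function(dataset, sel = selector()) {
  ivs <- .session_slice_intervals(dataset, matches_selector(dataset, sel))
  sum(vapply(ivs, interval_length, numeric(1)))
}

.proportion_estimate <- function(num, den) {
  structure(list(numerator_seconds = num, denominator_seconds = den,
                 proportion = num / den, as_percent = 100 * num / den,
                 minutes_per_hour = 60 * num / den),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("proportion %.4f (%s%% of %.2f h; %.1f min/h)\n",
              x$proportion, format(round_half_up(x$as_percent, 1)),
              x$denominator_seconds / 3600, x$minutes_per_hour))
  invisible(x)
}

#' Proportion of time spent on a slice
#'
#' With the default denominator (`NULL`, "ALL") the denominator is the total
#' scheduled observation time — the sum of session durations, including
#' seconds with no recorded task.  With an explicit denominator selector the
#' denominator is the (overlap-deduplicated) time on that slice and the
#' numerator is the time on the intersection of the two slices, so
#' slice-specific proportions such as "share of drug-related task time" use
#' slice-specific denominators.
#'
#' A single slice proportion is always in \[0, 1\]; only *sums* of
#' proportions across slices can exceed 1, because multitasked seconds count
#' once in every slice they touch.
#'
#' @param dataset An `observation_dataset`.
#' @param numerator Selector for the numerator slice.
#' @param denominator Optional selector for the denominator slice; `NULL`
#'   means total observation time.
#' @return A `proportion_estimate` with fields `numerator_seconds`,
#'   `denominator_seconds`, `proportion`, `as_percent`, `minutes_per_hour`.
#' @export
proportion_of_time <- function(dataset, numerator, denominator = NULL) {
  if (is.null(denominator)) {
    den <- total_observation_hours(dataset) * 3600
    if (den <= 0) stop("total observation time is zero", call. = FALSE)
    num <- time_on(dataset, numerator)
  } else {
    num_ivs <- .session_slice_intervals(dataset, matches_selector(dataset, numerator))
    den_ivs <- .session_slice_intervals(dataset, matches_selector(dataset, denominator))
    den <- sum(vapply(den_ivs, interval_length, numeric(1)))
    if (den <= 0) stop("denominator slice has zero time", call. = FALSE)
    num <- sum(vapply(names(den_ivs), function(sid) {
      intersect_length(num_ivs[[sid]], den_ivs[[sid]])
    }, numeric(1)))
  }
  .proportion_estimate(num, den)
}

#' Fraction of slice time spent multitasking
#'
#' The numerator is the number of seconds, within the selector slice's time,
#' during which two or more tasks (any tasks of the session, not just
#' matching ones) were simultaneously active; the denominator is the slice
#' time itself.  "Physicians multitasked for 17%-style" statistics are
#' computed this way.
#'
#' @inheritParams time_on
#' @return A `proportion_estimate`.
#' @export
multitask_fraction <- function(dataset, sel = selector()) {
  r <- dataset$records
  keep <- matches_selector(dataset, sel)
  num <- 0; den <- 0
  for (sid in dataset$sessions$session_id) {
    rows_all <- which(r$session_id == sid)
    rows_sel <- which(keep & r$session_id == sid)
    if (length(rows_sel) == 0L) next
    sel_union <- normalize_intervals(.record_intervals(r, rows_sel))
    den <- den + interval_length(sel_union)
    prof <- concurrency_profile(.record_intervals(r, rows_all), ids = r$record_id[rows_all])
    mt <- multitask_intervals(prof)
    num <- num + intersect_length(mt, sel_union)
  }
  if (den <= 0) stop("selector slice has zero time", call. = FALSE)
  .proportion_estimate(num, den)
}

.rate_estimate <- function(count, hours) {
  structure(list(event_count = count, exposure_hours = hours,
                 rate_per_hour = count / hours),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%d events over %.2f h: %.2f per hour\n",
              x$event_count, x$exposure_hours, x$rate_per_hour))
  invisible(x)
}

#' Interruption rate per hour of exposure
#'
#' An interruption is a record flagged `is_interruption` (the physician
#' stopped the current task to respond to an external stimulus; it is linked
#' to the task it interrupts).  With `exposure = NULL` the count is all
#' interruption records and the exposure is the total observation time.
#' With an exposure selector, an interruption counts if its start second lies
#' inside the slice's active time — i.e. some record matching the selector
#' (other than the interruption itself) was ongoing at that second — and the
#' exposure is the slice time, giving slice-specific rates such as
#' "interruptions per hour of drug-related task time".
#'
#' @param dataset An `observation_dataset`.
#' @param exposure Optional [selector()]; `NULL` means overall.
#' @return A `rate_estimate` with `event_count`, `exposure_hours`,
#'   `rate_per_hour`.
#' @export
interruption_rate <- function(dataset, exposure = NULL) {
  r <- dataset$records
  ints <- which(r$is_interruption %in% TRUE)
  if (is.null(exposure)) {
    hours <- total_observation_hours(dataset)
    if (hours <= 0) stop("zero exposure", call. = FALSE)
    return(.rate_estimate(length(ints), hours))
  }
  keep <- matches_selector(dataset, exposure)
  count <- 0L; secs <- 0
  for (sid in dataset$sessions$session_id) {
    rows_sel <- which(keep & r$session_id == sid)
    if (length(rows_sel)) {
      secs <- secs + interval_length(normalize_intervals(.record_intervals(r, rows_sel)))
    }
    for (i in intersect(ints, which(r$session_id == sid))) {
      others <- setdiff(rows_sel, i)
      if (length(others) == 0L) next
      t0 <- as.numeric(r$start[i])
      if (any(as.numeric(r$start[others]) <= t0 & as.numeric(r$end[others]) > t0)) {
        count <- count + 1L
      }
    }
  }
  if (secs <= 0) stop("zero exposure for the given slice", call. = FALSE)
  .rate_estimate(count, secs / 3600)
}

#' Fraction of task instances interrupted at least once
#'
#' Instance-based (not time-based): the numerator counts matching records
#' referenced by at least one interruption's `interrupts_record_id`, the
#' denominator counts all matching records.
#'
#' @inheritParams time_on
#' @return A `proportion_estimate` (the `*_seconds` fields hold counts).
#' @export
fraction_tasks_interrupted <- function(dataset, sel = selector()) {
  r <- dataset$records
  keep <- matches_selector(dataset, sel)
  if (!any(keep)) stop("no records match the selector", call. = FALSE)
  targets <- unique(r$interrupts_record_id[r$is_interruption %in% TRUE &
                                           !is.na(r$interrupts_record_id)])
  num <- sum(r$record_id[keep] %in% targets)
  .proportion_estimate(num, sum(keep))
}

#' Task-category distribution of interrupting tasks
#'
#' For interruptions whose *target* (the interrupted task) matches
#' `target_sel`, tallies the what-category of the interrupting record.
#' Answers "what was the most common reason for interruption of <slice>".
#'
#' @param dataset An `observation_dataset`.
#' @param target_sel Selector the interrupted task must match.
#' @return Named numeric vector of fractions over what-categories, summing
#'   to 1.
#' @export
interruption_reason_breakdown <- function(dataset, target_sel = selector()) {
  r <- dataset$records
  keep_target <- matches_selector(dataset, target_sel)
  ints <- which(r$is_interruption %in% TRUE & !is.na(r$interrupts_record_id))
  tgt <- match(r$interrupts_record_id[ints], r$record_id)
  qualifying <- ints[!is.na(tgt) & keep_target[tgt]]
  if (length(qualifying) == 0L) {
    stop("no interruptions target the given slice", call. = FALSE)
  }
  tab <- table(factor(r$what[qualifying], levels = what_categories()))
  frac <- as.numeric(tab) / length(qualifying)
  names(frac) <- names(tab)
  frac[frac > 0]
}

#' Convert a time proportion to minutes per hour
#'
#' @param proportion Fraction in \[0, 1\].
#' @return `proportion * 60` minutes.
#' @examples
#' minutes_per_hour(0.129)  # 7.74 min/h
#' @export
minutes_per_hour <- function(proportion) {
  if (any(proportion < 0 | proportion > 1)) {
    stop("proportion must be in [0, 1]", call. = FALSE)
  }
  proportion * 60
}

#' Mean patients attended per session
#'
#' Session-level means of total, new (no prior medical/medication history
#' taken), and follow-up patient counts.  The total mean equals the sum of
#' the new and follow-up means exactly.
#'
#' @param dataset An `observation_dataset` with at least one session.
#' @return Named numeric vector `c(mean_total, mean_new, mean_followup)`.
#' @export
patients_per_session <- function(dataset) {
  s <- dataset$sessions
  if (nrow(s) == 0L) stop("dataset has no sessions", call. = FALSE)
  c(mean_total = mean(s$n_new_patients + s$n_followup_patients),
    mean_new = mean(s$n_new_patients),
    mean_followup = mean(s$n_followup_patients))
}

#' Round half away from zero
#'
#' Report tables round half-up (2.5 -> 3) to match conventional clinical
#' reporting, unlike base R's round-half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
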