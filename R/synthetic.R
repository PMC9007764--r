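#' Default per-category mean task durations, seconds
#'
#' Realistic mean durations for sampled task intervals, per what-category
#' (and drug-related subcategory where it applies), derived from typical
#' emergency-department task counts and hours: documentation episodes are
#' minutes long, hygiene and movement are tens of seconds.
#'
#' @return Named numeric vector; names are `"what"` or `"what|subcategory"`.
#' @export
default_mean_durations <- function() {
  c("Examination/Treatment" = 74,
    "Gather information|non-drug-related" = 58,
    "Gather information|drug-related" = 48,
    "Documentation|non-drug-related" = 107,
    "Documentation|drug-related" = 58,
    "Professional communication|non-drug-related" = 40,
    "Professional communication|drug-related" = 39,
    "Social" = 43,
    "Unknown" = 229,
    "Hygiene" = 18,
    "Movement" = 21,
    "Outside ED" = 132)
}

.duration_key <- function(what, subcategory) {
  ifelse(subcategory %in% c("drug-related", "non-drug-related"),
         paste(what, subcategory, sep = "|"), what)
}

#' A compact task time-budget for simulation
#'
#' A simple seven-cell budget used as the generator default: drug-related
#' work (gathering information + documentation) is 18\% of session time,
#' and the budget sums to 1.05 so a realistic amount of multitasking arises
#' under the generator's auto-calibration.
#'
#' @return data.frame with columns `what`, `subcategory`, `where`, `how`,
#'   `who`, `budget` (target fraction of session time).
#' @export
default_task_budget <- function() {
  data.frame(
    what = c("Gather information", "Documentation", "Gather information",
             "Documentation", "Professional communication",
             "Examination/Treatment", "Movement"),
    subcategory = c("drug-related", "drug-related", "non-drug-related",
                    "non-drug-related", "non-drug-related", "none", "none"),
    where = c("Physician desk", "Physician desk", "Patient room",
              "Physician desk", "Corridor", "Patient room", "Corridor"),
    how = c("Direct", "On computer", "Direct", "On computer", "Direct",
            "Direct", "none"),
    who = c("Patient", "none", "Patient", "none", "Nurse", "Patient", "none"),
    budget = c(0.10, 0.08, 0.25, 0.20, 0.22, 0.12, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Default distribution of interrupting tasks
#'
#' Professional communication dominates as the reason for interruption.
#'
#' @return data.frame with `what`, `subcategory`, `where`, `how`, `who`,
#'   `weight`.
#' @export
default_interrupter_budget <- function() {
  data.frame(
    what = c("Professional communication", "Gather information", "Movement",
             "Examination/Treatment", "Social"),
    subcategory = c("non-drug-related", "non-drug-related", "none", "none",
                    "non-professional"),
    where = c("Physician desk", "Physician desk", "Corridor", "Patient room",
              "Physician desk"),
    how = c("Direct", "Direct", "none", "Direct", "Direct"),
    who = c("Nurse", "Patient", "none", "Patient", "none"),
    weight = c(0.825, 0.06, 0.05, 0.04, 0.025),
    stringsAsFactors = FALSE
  )
}

#' Synthetic observation-study generator configuration
#'
#' Describes the simulated world: a roster of physicians drawn 3:1
#' medical:surgical and 1:1 experienced:inexperienced, observed for two-hour
#' sessions (at most two per physician); a target time-budget over task
#' cells; exponential (or lognormal) task durations; chained task sampling
#' with a configurable probability that a task starts before the previous
#' one ends (multitasking); homogeneous-Poisson interruption events recorded
#' as linked task records; and Poisson per-session new/follow-up patient
#' counts.
#'
#' When `multitask_probability` is `NULL` it is auto-calibrated to
#' `2 * (1 - 1/sum(budget))`: chained sampling covers each session exactly
#' once, so the total raw task time is `1/(1 - p/2)` session-times and the
#' calibration makes each cell's realized (raw) time fraction equal its
#' configured budget.
#'
#' @param n_physicians Number of physicians.
#' @param n_second_sessions How many of them are observed for a second
#'   session.
#' @param session_hours Session length in hours (default 2).
#' @param affiliation_ratio Probability weights `c(Medical, Surgical)` for
#'   the per-physician affiliation draw (default 3:1).
#' @param budget Task-cell budget table as in [default_task_budget()].
#' @param mean_durations Named per-category mean durations (seconds), as in
#'   [default_mean_durations()].
#' @param multitask_probability Probability that a task starts before the
#'   previous one ends; `NULL` (default) auto-calibrates from the budget sum.
#' @param duration_model `"exponential"` (default) or `"lognormal"`
#'   (same mean, sdlog 1).
#' @param interruption_rate_per_hour Poisson intensity of interruption
#'   events (default 4).
#' @param interruption_mean_duration_s Mean interruption duration (default
#'   30 s).
#' @param interrupter_budget Distribution of interrupting-task cells.
#' @param patient_rate Poisson means `c(new, followup)` per session
#'   (default 2.0 and 0.7).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_physicians = 31,
                             n_second_sessions = 14,
                             session_hours = 2,
                             affiliation_ratio = c(Medical = 3, Surgical = 1),
                             budget = default_task_budget(),
                             mean_durations = default_mean_durations(),
                             multitask_probability = NULL,
                             duration_model = c("exponential", "lognormal"),
                             interruption_rate_per_hour = 4,
                             interruption_mean_duration_s = 30,
                             interrupter_budget = default_interrupter_budget(),
                             patient_rate = c(new = 2.0, followup = 0.7),
                             seed = 1L) {
  duration_model <- match.arg(duration_model)
  if (any(budget$budget < 0)) stop("budgets must be non-negative", call. = FALSE)
  total_budget <- sum(budget$budget)
  if (total_budget <= 0) stop("budget must have positive total", call. = FALSE)
  if (n_second_sessions > n_physicians) {
    stop("n_second_sessions cannot exceed n_physicians", call. = FALSE)
  }
  if (is.null(multitask_probability)) {
    multitask_probability <- max(0, 2 * (1 - 1 / total_budget))
  }
  if (multitask_probability < 0 || multitask_probability > 1) {
    stop("multitask_probability must be in [0, 1]", call. = FALSE)
  }
  if (multitask_probability == 0 && total_budget > 1 + 1e-9) {
    stop("infeasible budget: cells sum to ", round(total_budget, 3),
         " > 1 with no multitasking allowed", call. = FALSE)
  }
  if (interruption_rate_per_hour < 0) stop("interruption rate must be >= 0", call. = FALSE)
  key <- .duration_key(budget$what, budget$subcategory)
  miss <- setdiff(key, names(mean_durations))
  if (length(miss)) stop("no mean duration for cell(s): ",
                         paste(unique(miss), collapse = ", "), call. = FALSE)
  structure(list(n_physicians = n_physicians, n_second_sessions = n_second_sessions,
                 session_hours = session_hours,
                 affiliation_ratio = affiliation_ratio, budget = budget,
                 mean_durations = mean_durations,
                 multitask_probability = multitask_probability,
                 duration_model = duration_model,
                 interruption_rate_per_hour = interruption_rate_per_hour,
                 interruption_mean_duration_s = interruption_mean_duration_s,
                 interrupter_budget = interrupter_budget,
                 patient_rate = patient_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$n_physicians, "physicians (",
      x$n_second_sessions, "observed twice ),", x$session_hours, "h sessions\n")
  cat("  budget cells:", nrow(x$budget), "summing to", round(sum(x$budget$budget), 3),
      "| multitask p =", round(x$multitask_probability, 3),
      "| interruptions", x$interruption_rate_per_hour, "/h\n")
  invisible(x)
}

.draw_durations <- function(n, mean_s, model) {
  if (n == 0L) return(numeric(0))
  raw <- if (model == "exponential") {
    stats::rexp(n, rate = 1 / mean_s)
  } else {
    # lognormal with the requested mean and sdlog 1
    stats::rlnorm(n, meanlog = log(mean_s) - 0.5, sdlog = 1)
  }
  pmax(1, round(raw))
}

# chained task sampling for one session on [0, n_sec): each next task starts
# at the previous task's end (plus an idle gap when the budget sum is below
# what the multitask level sustains), or (with probability p) uniformly
# inside the previous task
.sample_session_tasks <- function(config, n_sec) {
  budget <- config$budget
  mean_dur <- unname(config$mean_durations[.duration_key(budget$what, budget$subcategory)])
  cell_prob <- budget$budget / mean_dur
  p <- config$multitask_probability
  dbar <- stats::weighted.mean(mean_dur, cell_prob)
  # expected start-to-start increment must be dbar/sum(budget) for each
  # cell's realized raw-time fraction to equal its configured budget; the
  # shortfall relative to dbar*(1 - p/2) is made up by idle gaps after
  # non-overlapped tasks
  gap_mean <- max(0, (dbar / sum(budget$budget) - dbar * (1 - p / 2)) / max(1 - p, 1e-9))
  starts <- integer(0); ends <- integer(0); cells <- integer(0)
  t <- 0
  exp_inc <- dbar / sum(budget$budget)
  chunk <- max(16L, ceiling(n_sec / exp_inc * 0.5))
  while (t < n_sec) {
    cell <- sample.int(nrow(budget), chunk, replace = TRUE, prob = cell_prob)
    dur <- .draw_durations(chunk, mean_dur[cell], config$duration_model)
    overlap <- stats::runif(chunk) < p
    gap <- if (gap_mean > 0) round(stats::rexp(chunk, 1 / gap_mean)) else numeric(chunk)
    inc <- ifelse(overlap, floor(stats::runif(chunk) * dur), dur + gap)
    st <- t + c(0, cumsum(inc[-chunk]))
    keep <- st < n_sec
    starts <- c(starts, st[keep])
    ends <- c(ends, pmin(st[keep] + dur[keep], n_sec))
    cells <- c(cells, cell[keep])
    t <- st[chunk] + inc[chunk]
  }
  ok <- ends > starts
  data.frame(cell = cells[ok], start = starts[ok], end = ends[ok])
}

#' Generate a synthetic observation dataset with known ground truth
#'
#' Simulates the whole observation study described by a
#' [generator_config()]: physicians, sessions, chained (possibly
#' overlapping) task intervals drawn from the configured time-budget,
#' Poisson interruption events recorded as linked interruption records, and
#' per-session patient counts.  The realized raw time fraction of every
#' budget cell is recorded in the `"ground_truth"` attribute.
#'
#' Generated datasets always pass [validate_dataset()], and generation is
#' deterministic given `config$seed` (the caller's RNG state is untouched).
#'
#' @param config A [generator_config()].
#' @return An `observation_dataset` with attribute `ground_truth` (list with
#'   the config and the realized per-cell budget table).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(config) {
  n_sec <- round(config$session_hours * 3600)
  aff_prob <- config$affiliation_ratio / sum(config$affiliation_ratio)
  phys <- data.frame(
    physician_id = sprintf("P%03d", seq_len(config$n_physicians)),
    affiliation = sample(c("Medical", "Surgical"), config$n_physicians,
                         replace = TRUE, prob = aff_prob),
    experience = sample(c("experienced", "inexperienced"), config$n_physicians,
                        replace = TRUE),
    stringsAsFactors = FALSE
  )
  twice <- if (config$n_second_sessions > 0) {
    sample.int(config$n_physicians, config$n_second_sessions)
  } else integer(0)
  phys_per_session <- c(seq_len(config$n_physicians), twice)

  base <- as.numeric(as.POSIXct("2018-10-16 09:00:00", tz = "UTC"))
  sessions <- data.frame(
    session_id = sprintf("S%03d", seq_along(phys_per_session)),
    physician_id = phys$physician_id[phys_per_session],
    affiliation = phys$affiliation[phys_per_session],
    experience = phys$experience[phys_per_session],
    session_start = base + (seq_along(phys_per_session) - 1) * 86400 +
      ((seq_along(phys_per_session) - 1) %% 5) * 7200,
    n_new_patients = stats::rpois(length(phys_per_session), config$patient_rate[["new"]]),
    n_followup_patients = stats::rpois(length(phys_per_session),
                                       config$patient_rate[["followup"]]),
    stringsAsFactors = FALSE
  )
  sessions$session_end <- sessions$session_start + n_sec

  budget <- config$budget
  ib <- config$interrupter_budget
  rec_parts <- vector("list", nrow(sessions))
  cell_secs <- numeric(nrow(budget))
  for (k in seq_len(nrow(sessions))) {
    t0 <- sessions$session_start[k]
    tasks <- .sample_session_tasks(config, n_sec)
    n_base <- nrow(tasks)
    rid <- sprintf("%s-r%04d", sessions$session_id[k], seq_len(n_base))
    cell_secs <- cell_secs + as.numeric(tapply(tasks$end - tasks$start,
                                               factor(tasks$cell, levels = seq_len(nrow(budget))),
                                               sum, default = 0))
    rec <- data.frame(
      record_id = rid,
      session_id = sessions$session_id[k],
      what = budget$what[tasks$cell],
      subcategory = budget$subcategory[tasks$cell],
      where = budget$where[tasks$cell],
      how = budget$how[tasks$cell],
      who = budget$who[tasks$cell],
      start = t0 + tasks$start,
      end = t0 + tasks$end,
      is_interruption = FALSE,
      interrupts_record_id = NA_character_,
      stringsAsFactors = FALSE
    )
    n_int <- stats::rpois(1, config$interruption_rate_per_hour * config$session_hours)
    if (n_int > 0) {
      times <- sort(floor(stats::runif(n_int) * n_sec))
      icell <- sample.int(nrow(ib), n_int, replace = TRUE, prob = ib$weight)
      idur <- pmax(1, round(stats::rexp(n_int, 1 / config$interruption_mean_duration_s)))
      keep <- logical(n_int)
      target <- character(n_int)
      for (j in seq_len(n_int)) {
        active <- which(tasks$start <= times[j] & tasks$end > times[j])
        if (length(active) == 0L) next  # cannot happen with chained coverage, kept for safety
        keep[j] <- TRUE
        target[j] <- rid[active[which.max(tasks$start[active])]]
      }
      if (any(keep)) {
        j <- which(keep)
        irec <- data.frame(
          record_id = sprintf("%s-i%03d", sessions$session_id[k], seq_along(j)),
          session_id = sessions$session_id[k],
          what = ib$what[icell[j]],
          subcategory = ib$subcategory[icell[j]],
          where = ib$where[icell[j]],
          how = ib$how[icell[j]],
          who = ib$who[icell[j]],
          start = t0 + times[j],
          end = t0 + pmin(times[j] + idur[j], n_sec),
          is_interruption = TRUE,
          interrupts_record_id = target[j],
          stringsAsFactors = FALSE
        )
        rec <- rbind(rec, irec)
      }
    }
    rec_parts[[k]] <- rec
  }
  records <- do.call(rbind, rec_parts)
  sessions$session_start <- as.POSIXct(sessions$session_start, origin = "1970-01-01", tz = "UTC")
  sessions$session_end <- as.POSIXct(sessions$session_end, origin = "1970-01-01", tz = "UTC")
  records$start <- as.POSIXct(records$start, origin = "1970-01-01", tz = "UTC")
  records$end <- as.POSIXct(records$end, origin = "1970-01-01", tz = "UTC")

  ds <- observation_dataset(sessions[c("session_id", "physician_id", "affiliation",
                                       "experience", "session_start", "session_end",
                                       "n_new_patients", "n_followup_patients")],
                            records, check = FALSE)
  realized <- budget
  realized$realized_fraction <- cell_secs / (nrow(sessions) * n_sec)
  attr(ds, "ground_truth") <- list(config = config, realized_budget = realized)
  ds
}

#' Observer error model for paired-log simulation
#'
#' Describes how a second, imperfect observer's log differs from the true
#' log: task boundary timestamps jittered by rounded Gaussian noise, labels
#' confused (replaced by another label of the same dimension) with a
#' per-dimension probability, and whole tasks missed.
#'
#' @param boundary_jitter_sd_s SD of the boundary jitter, seconds.
#' @param label_confusion_prob Either a single probability applied to every
#'   dimension or a named vector over
#'   `c("what", "subcategory", "where", "how", "who")`.
#' @param miss_prob Probability a task is absent from the second log.
#' @return An object of class `observer_error_model`.
#' @export
observer_error_model <- function(boundary_jitter_sd_s = 2,
                                 label_confusion_prob = 0.05,
                                 miss_prob = 0.02) {
  dims <- c("what", "subcategory", "where", "how", "who")
  if (length(label_confusion_prob) == 1L && is.null(names(label_confusion_prob))) {
    label_confusion_prob <- stats::setNames(rep(label_confusion_prob, length(dims)), dims)
  } else {
    full <- stats::setNames(rep(0, length(dims)), dims)
    full[names(label_confusion_prob)] <- label_confusion_prob
    label_confusion_prob <- full
  }
  stopifnot(all(label_confusion_prob >= 0 & label_confusion_prob <= 1),
            miss_prob >= 0, miss_prob <= 1, boundary_jitter_sd_s >= 0)
  structure(list(boundary_jitter_sd_s = boundary_jitter_sd_s,
                 label_confusion_prob = label_confusion_prob,
                 miss_prob = miss_prob),
            class = "observer_error_model")
}

# keep a record's subcategory legal after its what (or subcategory) changed
.repair_subcategory <- function(what, subcategory) {
  drug <- what %in% drug_split_categories()
  soc <- what == "Social"
  out <- subcategory
  out[drug & !subcategory %in% c("drug-related", "non-drug-related")] <- "non-drug-related"
  out[soc & !subcategory %in% c("professional", "non-professional")] <- "non-professional"
  out[!drug & !soc] <- "none"
  out
}

#' Simulate a paired observer log
#'
#' Observer A is the input dataset unchanged; observer B is a copy degraded
#' by an [observer_error_model()]: whole-second boundary jitter (clamped to
#' the session window), per-dimension label confusion (with the subcategory
#' kept legal for the possibly-changed task category), and missed tasks.
#' Interruption links that no longer resolve in B are cleared.
#'
#' @param dataset The true `observation_dataset`.
#' @param error_model An [observer_error_model()].
#' @param seed Integer seed.
#' @return list with elements `a` and `b`, both `observation_dataset`s.
#' @export
generate_observer_pair <- function(dataset, error_model = observer_error_model(),
                                   seed = 1L) {
  with_local_seed(seed, {
    r <- dataset$records
    s <- dataset$sessions
    keep <- stats::runif(nrow(r)) >= error_model$miss_prob
    r <- r[keep, , drop = FALSE]
    n <- nrow(r)
    if (n > 0L) {
      sd_ <- error_model$boundary_jitter_sd_s
      idx <- match(r$session_id, s$session_id)
      lo <- as.numeric(s$session_start)[idx]
      hi <- as.numeric(s$session_end)[idx]
      st <- as.numeric(r$start) + round(stats::rnorm(n, 0, sd_))
      en <- as.numeric(r$end) + round(stats::rnorm(n, 0, sd_))
      st <- pmax(lo, pmin(st, hi - 1))
      en <- pmax(st + 1, pmin(en, hi))
      r$start <- as.POSIXct(st, origin = "1970-01-01", tz = "UTC")
      r$end <- as.POSIXct(en, origin = "1970-01-01", tz = "UTC")

      vocab <- list(what = what_categories(),
                    subcategory = subcategory_levels(),
                    where = unique(dataset$records$where),
                    how = how_categories(),
                    who = who_categories())
      for (d in names(error_model$label_confusion_prob)) {
        p <- error_model$label_confusion_prob[[d]]
        if (p <= 0) next
        flip <- which(stats::runif(n) < p)
        for (i in flip) {
          alt <- setdiff(vocab[[d]], r[[d]][i])
          if (length(alt)) r[[d]][i] <- sample(alt, 1)
        }
      }
      r$subcategory <- .repair_subcategory(r$what, r$subcategory)

      # re-check interruption linkage in the degraded log
      tgt <- match(r$interrupts_record_id, r$record_id)
      valid <- r$is_interruption %in% TRUE & !is.na(tgt) &
        !is.na(r$interrupts_record_id)
      ok <- valid
      ok[valid] <- as.numeric(r$start[valid]) >= as.numeric(r$start[tgt[valid]]) &
        as.numeric(r$start[valid]) < as.numeric(r$end[tgt[valid]]) &
        r$session_id[valid] == r$session_id[tgt[valid]]
      r$is_interruption <- r$is_interruption %in% TRUE & ok
      r$interrupts_record_id[!ok] <- NA_character_
    }
    b <- observation_dataset(s, r, check = FALSE)
    list(a = dataset, b = b)
  })
}

#' Study-emulation generator preset
#'
#' A demonstration configuration whose cell budgets mirror a published
#' emergency-department time-distribution table: drug-related work about
#' 18\% of session time (gathering information, documentation, professional
#' communication, broken down by who/how cells), an overall interruption
#' intensity of 4 per hour, two-hour sessions for 31 physicians of whom 14
#' are observed twice, a 3:1 medical:surgical draw, and mean patient counts
#' of 2.0 new and 0.7 follow-up per session.
#'
#' @param seed Integer seed stored in the config.
#' @return A [generator_config()].
#' @export
study_preset <- function(seed = 1L) {
  pc <- function(what, sub, who, how, budget, where = "Physician desk") {
    data.frame(what = what, subcategory = sub, where = where, how = how,
               who = who, budget = budget / 100, stringsAsFactors = FALSE)
  }
  budget <- rbind(
    # professional communication, drug-related
    pc("Professional communication", "drug-related", "Patient", "Direct", 1.08, "Patient room"),
    pc("Professional communication", "drug-related", "Next of kin", "Direct", 0.25, "Patient room"),
    pc("Professional communication", "drug-related", "Another physician", "Direct", 3.05),
    pc("Professional communication", "drug-related", "Nurse", "Direct", 1.07),
    pc("Professional communication", "drug-related", "Pharmacist", "Direct", 0.04),
    pc("Professional communication", "drug-related", "Other hospital", "Telephone", 0.15),
    pc("Professional communication", "drug-related", "Unknown", "Direct", 0.40),
    pc("Professional communication", "drug-related", "Others", "Direct", 0.10),
    # professional communication, non-drug-related
    pc("Professional communication", "non-drug-related", "Patient", "Direct", 2.66, "Patient room"),
    pc("Professional communication", "non-drug-related", "Next of kin", "Direct", 0.37, "Patient room"),
    pc("Professional communication", "non-drug-related", "Another physician", "Direct", 9.82),
    pc("Professional communication", "non-drug-related", "Nurse", "Direct", 3.66),
    pc("Professional communication", "non-drug-related", "Other hospital", "Telephone", 0.68),
    pc("Professional communication", "non-drug-related", "Unknown", "Direct", 1.63),
    pc("Professional communication", "non-drug-related", "Others", "Direct", 1.59),
    pc("Professional communication", "non-drug-related", "General Practitioner", "Telephone", 0.02),
    # gather information, drug-related
    pc("Gather information", "drug-related", "Patient", "Direct", 2.57, "Patient room"),
    pc("Gather information", "drug-related", "Next of kin", "Direct", 0.21, "Patient room"),
    pc("Gather information", "drug-related", "Another physician", "Direct", 0.01),
    pc("Gather information", "drug-related", "Nurse", "Direct", 0.01),
    pc("Gather information", "drug-related", "none", "On paper", 1.08),
    pc("Gather information", "drug-related", "none", "On computer", 1.80),
    pc("Gather information", "drug-related", "none", "On smartphone", 1.04),
    pc("Gather information", "drug-related", "none", "With Prescription Intermediary", 0.46),
    # gather information, non-drug-related
    pc("Gather information", "non-drug-related", "Patient", "Direct", 8.42, "Patient room"),
    pc("Gather information", "non-drug-related", "Next of kin", "Direct", 0.65, "Patient room"),
    pc("Gather information", "non-drug-related", "Another physician", "Direct", 0.05),
    pc("Gather information", "non-drug-related", "Nurse", "Direct", 0.02),
    pc("Gather information", "non-drug-related", "none", "On paper", 2.91),
    pc("Gather information", "non-drug-related", "none", "On computer", 17.22),
    pc("Gather information", "non-drug-related", "none", "On smartphone", 0.21),
    # documentation
    pc("Documentation", "drug-related", "none", "On paper", 3.19),
    pc("Documentation", "drug-related", "none", "On computer", 3.09),
    pc("Documentation", "drug-related", "none", "With dictaphone", 0.27),
    pc("Documentation", "drug-related", "none", "With Prescription Intermediary", 0.07),
    pc("Documentation", "non-drug-related", "none", "On paper", 0.67),
    pc("Documentation", "non-drug-related", "none", "On computer", 15.12),
    pc("Documentation", "non-drug-related", "none", "With dictaphone", 1.81),
    # remaining what-categories
    pc("Examination/Treatment", "none", "Patient", "Direct", 5.6, "Patient room"),
    pc("Unknown", "none", "none", "none", 0.8, "Patient room"),
    pc("Social", "professional", "none", "On computer", 3.35),
    pc("Social", "non-professional", "none", "none", 3.35),
    pc("Hygiene", "none", "none", "none", 1.0, "Patient room"),
    pc("Movement", "none", "none", "none", 5.9, "Corridor"),
    pc("Outside ED", "none", "none", "none", 2.7, "Outside ED")
  )
  generator_config(n_physicians = 31, n_second_sessions = 14, session_hours = 2,
                   budget = budget, interruption_rate_per_hour = 4,
                   patient_rate = c(new = 2.0, followup = 0.7), seed = seed)
}
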