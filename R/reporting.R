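#' Standard analysis slice definitions
#'
#' `table_what_slices()` defines the rows of the category-level
#' time-distribution table: the nine task categories, with gathering
#' information, documentation and professional communication split into
#' drug-related and non-drug-related rows, and Social reported as one row
#' (professional and non-professional collapsed).
#' `drug_list_process_cells()` defines the composite "obtaining and
#' documenting the patient's drug list" process: drug-related gathering of
#' information from the patient or next of kin, on paper, on computer or in
#' the national Prescription Intermediary database, plus drug-related
#' documentation on paper, on computer or with a dictaphone.
#'
#' @return A named list of [selector()]s (with attributes `block` marking
#'   drug-related vs non-drug-related rows).
#' @export
table_what_slices <- function() {
  nd <- c("non-drug-related", "professional", "non-professional", "none")
  slices <- list(
    "Examination" = selector(what = "Examination/Treatment"),
    "Professional communication" =
      selector(what = "Professional communication", subcategory = "non-drug-related"),
    "Gather information" =
      selector(what = "Gather information", subcategory = "non-drug-related"),
    "Documentation" = selector(what = "Documentation", subcategory = "non-drug-related"),
    "Unknown" = selector(what = "Unknown"),
    "Social (both professional and non-professional)" = selector(what = "Social"),
    "Hygiene" = selector(what = "Hygiene"),
    "Movement" = selector(what = "Movement"),
    "Outside ED" = selector(what = "Outside ED"),
    "Professional communication (drug-related)" =
      selector(what = "Professional communication", subcategory = "drug-related"),
    "Gather information (drug-related)" =
      selector(what = "Gather information", subcategory = "drug-related"),
    "Documentation (drug-related)" =
      selector(what = "Documentation", subcategory = "drug-related")
  )
  blocks <- c(rep("non-drug-related", 9L), rep("drug-related", 3L))
  for (i in seq_along(slices)) attr(slices[[i]], "block") <- blocks[i]
  slices
}

#' @rdname table_what_slices
#' @export
drug_list_process_cells <- function() {
  list(
    gather_patient = selector(what = "Gather information", subcategory = "drug-related",
                              who = "Patient", how = "Direct"),
    gather_next_of_kin = selector(what = "Gather information", subcategory = "drug-related",
                                  who = "Next of kin", how = "Direct"),
    gather_paper = selector(what = "Gather information", subcategory = "drug-related",
                            how = "On paper"),
    gather_computer = selector(what = "Gather information", subcategory = "drug-related",
                               how = "On computer"),
    gather_prescription_db = selector(what = "Gather information",
                                      subcategory = "drug-related",
                                      how = "With Prescription Intermediary"),
    doc_paper = selector(what = "Documentation", subcategory = "drug-related",
                         how = "On paper"),
    doc_computer = selector(what = "Documentation", subcategory = "drug-related",
                            how = "On computer"),
    doc_dictaphone = selector(what = "Documentation", subcategory = "drug-related",
                              how = "With dictaphone")
  )
}

# logical: records matching any selector in the list
.matches_any <- function(dataset, cells) {
  keep <- rep(FALSE, nrow(dataset$records))
  for (cell in cells) keep <- keep | matches_selector(dataset, cell)
  keep
}

#' @rdname ratio_stat
#' @param cells A list of selectors; the slice is their union (a record
#'   matching any cell counts, each second once).
#' @export
stat_union_proportion <- function(cells) {
  force(cells)
  ratio_stat(function(dataset) {
    ivs <- .session_slice_intervals(dataset, .matches_any(dataset, cells))
    data.frame(session_id = dataset$sessions$session_id,
               num = unname(vapply(ivs, interval_length, numeric(1))),
               den = .session_seconds(dataset), stringsAsFactors = FALSE)
  }, label = "proportion of time on a union of slices")
}

#' Proportion of time on the drug-list process
#'
#' Overlap-deduplicated time on the union of the configured composite cells
#' (see [drug_list_process_cells()]) divided by total observation time, with
#' the minutes-per-hour equivalent attached.
#'
#' @param dataset An `observation_dataset`.
#' @param cells Composite cell selectors (default
#'   [drug_list_process_cells()]).
#' @return A `proportion_estimate`.
#' @export
summarize_drug_list_process <- function(dataset, cells = drug_list_process_cells()) {
  if (length(cells) == 0L) stop("composite slice is empty", call. = FALSE)
  keep <- .matches_any(dataset, cells)
  ivs <- .session_slice_intervals(dataset, keep)
  num <- sum(vapply(ivs, interval_length, numeric(1)))
  den <- total_observation_hours(dataset) * 3600
  if (den <= 0) stop("total observation time is zero", call. = FALSE)
  .proportion_estimate(num, den)
}

#' Analysis pipeline configuration
#'
#' @param what_slices Category-table row selectors
#'   (default [table_what_slices()]).
#' @param composite_cells Drug-list-process cells
#'   (default [drug_list_process_cells()]).
#' @param bootstrap_replicates,level,cluster Cluster-bootstrap settings.
#' @param n_permutations Monte Carlo test permutations.
#' @param seed Global seed; per-call seeds are derived deterministically.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(what_slices = table_what_slices(),
                            composite_cells = drug_list_process_cells(),
                            bootstrap_replicates = 2000,
                            level = 0.95,
                            cluster = "physician",
                            n_permutations = 1999,
                            seed = 1L) {
  structure(list(what_slices = what_slices, composite_cells = composite_cells,
                 bootstrap_replicates = bootstrap_replicates, level = level,
                 cluster = cluster, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

.slice_counts <- function(dataset, sel) {
  keep <- matches_selector(dataset, sel)
  r <- dataset$records[keep, , drop = FALSE]
  c(n_tasks = nrow(r),
    task_hours = sum(as.numeric(r$end) - as.numeric(r$start)) / 3600)
}

#' Run the full time-motion analysis pipeline
#'
#' Computes, from one validated dataset: (a) the category-level
#' time-distribution table (task counts, raw task hours,
#' multitask-deduplicated percent of total observation time with cluster
#' bootstrap CIs, plus drug-related / non-drug-related block totals); (b)
#' the who-by-how breakdown of the three interactive categories, split
#' drug-related vs non-drug-related; (c) the composite drug-list-process
#' proportion with its minutes-per-hour equivalent; (d) interruption and
#' multitasking statistics; and (e) Monte Carlo group contrasts of
#' drug-related task time (medical vs surgical, experienced vs
#' inexperienced).  All resampling seeds are derived from `config$seed`, so
#' the report is reproducible bit-for-bit.
#'
#' @param dataset An `observation_dataset`.
#' @param config An [analysis_config()].
#' @return An object of class `analysis_report`: list with elements
#'   `what_table`, `block_table`, `who_how_table`, `drug_list_process`,
#'   `interruptions`, `multitasking`, `group_tests`, `provenance`.
#' @export
run_analysis <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  rep_check <- validate_dataset(dataset)
  if (nrow(rep_check) > 0L) {
    stop("input stage: dataset failed validation (", nrow(rep_check), " violation(s))",
         call. = FALSE)
  }
  seed_counter <- 0L
  next_seed <- function() {
    seed_counter <<- seed_counter + 1L
    (config$seed + 7919L * seed_counter) %% 2147483647L
  }
  boot <- function(statistic) {
    bootstrap_ci(dataset, statistic, level = config$level,
                 n_replicates = config$bootstrap_replicates, seed = next_seed(),
                 cluster = config$cluster)
  }

  # (a) category table
  rows <- lapply(names(config$what_slices), function(lab) {
    sel <- config$what_slices[[lab]]
    cnt <- .slice_counts(dataset, sel)
    b <- boot(stat_proportion(sel))
    data.frame(slice = lab, block = attr(sel, "block") %||% "",
               n_tasks = cnt[["n_tasks"]], task_hours = cnt[["task_hours"]],
               percent = 100 * b$point_estimate,
               ci_low = 100 * b$ci_low, ci_high = 100 * b$ci_high,
               stringsAsFactors = FALSE)
  })
  what_table <- do.call(rbind, rows)

  drug_sel <- selector(subcategory = "drug-related")
  nondrug_sel <- selector(subcategory = c("non-drug-related", "professional",
                                          "non-professional", "none"))
  block_rows <- lapply(list(`drug-related` = drug_sel, `non-drug-related` = nondrug_sel),
                       function(sel) {
    b <- boot(stat_proportion(sel))
    data.frame(percent = 100 * b$point_estimate, ci_low = 100 * b$ci_low,
               ci_high = 100 * b$ci_high, stringsAsFactors = FALSE)
  })
  block_table <- cbind(data.frame(block = names(block_rows), stringsAsFactors = FALSE),
                       do.call(rbind, block_rows))
  rownames(block_table) <- NULL

  # (b) who/how cells of the three interactive categories
  r <- dataset$records
  interactive <- r$what %in% drug_split_categories()
  combos <- unique(r[interactive, c("what", "subcategory", "who", "how")])
  combos <- combos[order(combos$what, combos$subcategory, combos$who, combos$how), ,
                   drop = FALSE]
  who_how_table <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- selector(what = combos$what[i], subcategory = combos$subcategory[i],
                    who = combos$who[i], how = combos$how[i])
    cnt <- .slice_counts(dataset, sel)
    b <- boot(stat_proportion(sel))
    data.frame(what = combos$what[i], subcategory = combos$subcategory[i],
               who = combos$who[i], how = combos$how[i],
               n_tasks = cnt[["n_tasks"]], task_hours = cnt[["task_hours"]],
               percent = 100 * b$point_estimate, ci_low = 100 * b$ci_low,
               ci_high = 100 * b$ci_high, stringsAsFactors = FALSE)
  }))

  # (c) drug-list process composite
  comp_b <- boot(stat_union_proportion(config$composite_cells))
  comp <- summarize_drug_list_process(dataset, config$composite_cells)
  drug_list_process <- data.frame(
    percent = comp$as_percent, ci_low = 100 * comp_b$ci_low,
    ci_high = 100 * comp_b$ci_high,
    minutes_per_hour = comp$minutes_per_hour,
    minutes_low = 60 * comp_b$ci_low, minutes_high = 60 * comp_b$ci_high,
    stringsAsFactors = FALSE)

  # (d) interruption + multitasking statistics
  rate_all <- boot(stat_interruption_rate(NULL))
  rate_drug <- boot(stat_interruption_rate(drug_sel))
  rate_nondrug <- boot(stat_interruption_rate(nondrug_sel))
  interruptions <- data.frame(
    exposure = c("total observation time", "drug-related task time",
                 "non-drug-related task time"),
    n_events = c(sum(r$is_interruption),
                 NA_integer_, NA_integer_),
    rate_per_hour = c(rate_all$point_estimate, rate_drug$point_estimate,
                      rate_nondrug$point_estimate),
    ci_low = c(rate_all$ci_low, rate_drug$ci_low, rate_nondrug$ci_low),
    ci_high = c(rate_all$ci_high, rate_drug$ci_high, rate_nondrug$ci_high),
    stringsAsFactors = FALSE)

  mt_drug <- boot(stat_multitask_fraction(drug_sel))
  mt_nondrug <- boot(stat_multitask_fraction(nondrug_sel))
  multitasking <- data.frame(
    slice = c("drug-related task time", "non-drug-related task time"),
    percent = 100 * c(mt_drug$point_estimate, mt_nondrug$point_estimate),
    ci_low = 100 * c(mt_drug$ci_low, mt_nondrug$ci_low),
    ci_high = 100 * c(mt_drug$ci_high, mt_nondrug$ci_high),
    stringsAsFactors = FALSE)

  # (e) group contrasts of drug-related task time
  group_tests <- do.call(rbind, lapply(c("affiliation", "experience"), function(g) {
    tst <- monte_carlo_group_test(dataset, g, stat_proportion(drug_sel),
                                  n_permutations = config$n_permutations,
                                  seed = next_seed())
    data.frame(group_field = g,
               group1 = tst$group_levels[1L], estimate1 = 100 * tst$group_estimates[1L],
               group2 = tst$group_levels[2L], estimate2 = 100 * tst$group_estimates[2L],
               difference = 100 * tst$observed_statistic, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(group_tests) <- NULL

  pat <- patients_per_session(dataset)
  structure(list(
    what_table = what_table, block_table = block_table,
    who_how_table = who_how_table, drug_list_process = drug_list_process,
    interruptions = interruptions, multitasking = multitasking,
    group_tests = group_tests,
    patients = data.frame(mean_total = pat[["mean_total"]],
                          mean_new = pat[["mean_new"]],
                          mean_followup = pat[["mean_followup"]]),
    provenance = list(seed = config$seed,
                      bootstrap_replicates = config$bootstrap_replicates,
                      level = config$level, cluster = config$cluster,
                      n_permutations = config$n_permutations,
                      n_sessions = nrow(dataset$sessions),
                      n_physicians = length(unique(dataset$sessions$physician_id)),
                      total_observation_hours = total_observation_hours(dataset))),
    class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  p <- x$provenance
  cat("Time-motion analysis report\n")
  cat(sprintf("  %d sessions, %d physicians, %.1f h observed | seed %d, B = %d, %d permutations\n\n",
              p$n_sessions, p$n_physicians, p$total_observation_hours, p$seed,
              p$bootstrap_replicates, p$n_permutations))
  fmt <- function(v, d = 1) format(round_half_up(v, d), nsmall = d)
  cat("Distribution of task time (% of total observation time):\n")
  for (i in seq_len(nrow(x$what_table))) {
    w <- x$what_table[i, ]
    cat(sprintf("  %-48s %5d tasks %7.1f h  %s (%s, %s)\n", w$slice, w$n_tasks,
                w$task_hours, fmt(w$percent), fmt(w$ci_low), fmt(w$ci_high)))
  }
  for (i in seq_len(nrow(x$block_table))) {
    b <- x$block_table[i, ]
    cat(sprintf("  %-48s %s%% (%s, %s)\n", paste(b$block, "total"), fmt(b$percent),
                fmt(b$ci_low), fmt(b$ci_high)))
  }
  d <- x$drug_list_process
  cat(sprintf("\nDrug-list process: %s%% (%s, %s) of time = %s min/h (%s, %s)\n",
              fmt(d$percent), fmt(d$ci_low), fmt(d$ci_high),
              fmt(d$minutes_per_hour), fmt(d$minutes_low), fmt(d$minutes_high)))
  cat("\nInterruptions:\n")
  for (i in seq_len(nrow(x$interruptions))) {
    it <- x$interruptions[i, ]
    cat(sprintf("  %-28s %s/h (%s, %s)\n", it$exposure, fmt(it$rate_per_hour),
                fmt(it$ci_low), fmt(it$ci_high)))
  }
  cat("\nMultitasking:\n")
  for (i in seq_len(nrow(x$multitasking))) {
    m <- x$multitasking[i, ]
    cat(sprintf("  %-28s %s%% (%s, %s)\n", m$slice, fmt(m$percent), fmt(m$ci_low),
                fmt(m$ci_high)))
  }
  cat("\nGroup contrasts (drug-related task time):\n")
  for (i in seq_len(nrow(x$group_tests))) {
    g <- x$group_tests[i, ]
    cat(sprintf("  %s: %s %s%% vs %s %s%%, p = %s\n", g$group_field, g$group1,
                fmt(g$estimate1), g$group2, fmt(g$estimate2),
                format(round(g$p_value, 4))))
  }
  cat(sprintf("\nPatients per session: %s total (%s new + %s follow-up)\n",
              fmt(x$patients$mean_total), fmt(x$patients$mean_new),
              fmt(x$patients$mean_followup)))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the machine-readable tables as CSV (full precision) plus a plain
#' text rendering (one-decimal percentages) and a JSON provenance header.
#' Output is deterministic: identical datasets, config and seed give
#' byte-identical files.
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = TRUE)
  }
  w(report$what_table, "what_table.csv")
  w(report$block_table, "block_table.csv")
  w(report$who_how_table, "who_how_table.csv")
  w(report$drug_list_process, "drug_list_process.csv")
  w(report$interruptions, "interruptions.csv")
  w(report$multitasking, "multitasking.csv")
  w(report$group_tests, "group_tests.csv")
  w(report$patients, "patients.csv")
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
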