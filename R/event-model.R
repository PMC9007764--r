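#' Controlled vocabularies for the observation dimensions
#'
#' The *what* dimension (task category) and its subcategories, plus the *how*
#' (tool/channel) and *who* (other person involved) vocabularies are fixed
#' enums.  Only three task categories carry the drug-related /
#' non-drug-related split (gathering information, documentation, professional
#' communication, i.e. any conversation, reading or writing that includes
#' information about the patient's drugs), and only Social carries the
#' professional / non-professional split.  The *where* dimension is a
#' configurable controlled vocabulary, not an enum, because location lists
#' are site-specific.
#'
#' @return Character vector of permitted labels.
#' @export
what_categories <- function() {
  c("Examination/Treatment", "Gather information", "Documentation",
    "Professional communication", "Social", "Unknown", "Hygiene",
    "Movement", "Outside ED")
}

#' @rdname what_categories
#' @export
subcategory_levels <- function() {
  c("drug-related", "non-drug-related", "professional", "non-professional", "none")
}

#' @rdname what_categories
#' @export
how_categories <- function() {
  c("Direct", "Telephone", "On paper", "On computer", "On smartphone",
    "With Prescription Intermediary", "With dictaphone", "none")
}

#' @rdname what_categories
#' @export
who_categories <- function() {
  c("Patient", "Next of kin", "Another physician", "Nurse", "Pharmacist",
    "Other hospital", "General Practitioner", "Unknown", "Others", "none")
}

# categories permitted to carry each subcategory
drug_split_categories <- function() {
  c("Gather information", "Documentation", "Professional communication")
}

.ts_parse <- function(x) {
  if (inherits(x, "POSIXct")) {
    out <- x
  } else {
    out <- as.POSIXct(as.character(x), tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  }
  attr(out, "tzone") <- "UTC"
  # truncate to whole seconds: all analyses run on a 1 s grid
  as.POSIXct(floor(as.numeric(out)), origin = "1970-01-01", tz = "UTC")
}

.ts_format <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

.na_to_empty <- function(x) ifelse(is.na(x), "", as.character(x))
.empty_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Assemble an observation dataset
#'
#' Bundles a session table and a task-record table into a validated
#' `observation_dataset`.  A session is one continuous observation period of
#' one physician (nominally two hours); records are the timestamped task
#' intervals observed during sessions, including interruption events, which
#' are themselves task records linked to the task they interrupt.
#'
#' @param sessions data.frame with columns `session_id`, `physician_id`,
#'   `affiliation` (`"Medical"`/`"Surgical"`), `experience`
#'   (`"experienced"`/`"inexperienced"`), `session_start`, `session_end`
#'   (POSIXct or ISO 8601 strings), `n_new_patients`, `n_followup_patients`.
#' @param records data.frame with columns `record_id`, `session_id`, `what`,
#'   `subcategory`, `where`, `how`, `who`, `start`, `end`, `is_interruption`,
#'   `interrupts_record_id` (NA/empty when not an interruption).
#' @param check If `TRUE` (default), stop when [validate_dataset()] reports
#'   any violation.
#' @return An object of class `observation_dataset`: a list with elements
#'   `sessions` and `records` (both data.frames with parsed timestamps).
#' @seealso [validate_dataset()], [read_event_log()], [filter_records()]
#' @export
observation_dataset <- function(sessions, records, check = TRUE) {
  sessions <- as.data.frame(sessions, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  s_cols <- c("session_id", "physician_id", "affiliation", "experience",
              "session_start", "session_end", "n_new_patients", "n_followup_patients")
  r_cols <- c("record_id", "session_id", "what", "subcategory", "where", "how",
              "who", "start", "end", "is_interruption", "interrupts_record_id")
  miss <- setdiff(s_cols, names(sessions))
  if (length(miss)) stop("sessions is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) {
    records <- data.frame(record_id = character(0), session_id = character(0),
                          what = character(0), subcategory = character(0),
                          where = character(0), how = character(0), who = character(0),
                          start = .ts_parse(character(0)), end = .ts_parse(character(0)),
                          is_interruption = logical(0),
                          interrupts_record_id = character(0),
                          stringsAsFactors = FALSE)
  }
  miss <- setdiff(r_cols, names(records))
  if (length(miss)) stop("records is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)

  sessions <- sessions[s_cols]
  records <- records[r_cols]
  for (col in c("session_id", "physician_id", "affiliation", "experience")) {
    sessions[[col]] <- as.character(sessions[[col]])
  }
  sessions$session_start <- .ts_parse(sessions$session_start)
  sessions$session_end <- .ts_parse(sessions$session_end)
  sessions$n_new_patients <- as.integer(sessions$n_new_patients)
  sessions$n_followup_patients <- as.integer(sessions$n_followup_patients)

  for (col in c("record_id", "session_id", "what", "subcategory", "where", "how", "who")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$subcategory[is.na(records$subcategory) | records$subcategory == ""] <- "none"
  for (col in c("where", "how", "who")) {
    records[[col]][is.na(records[[col]]) | records[[col]] == ""] <- "none"
  }
  records$start <- .ts_parse(records$start)
  records$end <- .ts_parse(records$end)
  records$is_interruption <- as.logical(records$is_interruption)
  records$interrupts_record_id <- .empty_to_na(records$interrupts_record_id)

  ds <- structure(list(sessions = sessions, records = records),
                  class = "observation_dataset")
  if (check) {
    rep <- validate_dataset(ds)
    if (nrow(rep) > 0L) {
      stop("invalid observation dataset (", nrow(rep), " violation(s)); first: ",
           rep$message[1L], ". Run validate_dataset() for the full report.",
           call. = FALSE)
    }
  }
  ds
}

#' @export
print.observation_dataset <- function(x, ...) {
  cat("<observation_dataset>\n")
  cat("  sessions:", nrow(x$sessions),
      sprintf("(%d physician(s))", length(unique(x$sessions$physician_id))), "\n")
  cat("  records: ", nrow(x$records),
      sprintf("(%d interruption(s))", sum(x$records$is_interruption)), "\n")
  cat("  total observation time:",
      format(round(total_observation_hours(x), 2), nsmall = 2), "h\n")
  invisible(x)
}

#' Total scheduled observation time, in hours
#'
#' Sum of session durations (the denominator for overall time proportions —
#' scheduled observer-present time, including seconds with no recorded task).
#'
#' @param dataset An `observation_dataset`.
#' @return Duration in hours.
#' @export
total_observation_hours <- function(dataset) {
  sum(as.numeric(dataset$sessions$session_end) -
      as.numeric(dataset$sessions$session_start)) / 3600
}

#' Validate an observation dataset
#'
#' Checks every structural invariant of the data model and returns a report
#' of violations rather than raising: positive durations, subcategory rules
#' (the drug-related split only on gathering information / documentation /
#' professional communication; professional split only on Social), controlled
#' vocabularies, session cross-references, records contained in their
#' session, interruption linkage (an interruption must point at a record in
#' the same session whose interval contains the interruption's start), and at
#' most two sessions per physician.
#'
#' @param dataset An `observation_dataset` (or a list with `sessions` and
#'   `records` data.frames of the same shape).
#' @return data.frame with columns `rule`, `id`, `message`; zero rows iff the
#'   dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  s <- dataset$sessions
  r <- dataset$records
  v <- list()
  add <- function(rule, id, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, id = id, message = message,
                                       stringsAsFactors = FALSE)
  }

  bad <- s$session_id[as.numeric(s$session_end) <= as.numeric(s$session_start)]
  for (id in bad) add("session_duration", id, sprintf("session %s has non-positive duration", id))

  dup <- s$session_id[duplicated(s$session_id)]
  for (id in unique(dup)) add("session_id_unique", id, sprintf("duplicated session_id %s", id))

  tab <- table(s$physician_id)
  for (p in names(tab)[tab > 2L]) {
    add("max_two_sessions", p, sprintf("physician %s has %d sessions (max 2)", p, tab[[p]]))
  }
  for (id in s$session_id[!s$affiliation %in% c("Medical", "Surgical")]) {
    add("affiliation_enum", id, sprintf("session %s: unknown affiliation", id))
  }
  for (id in s$session_id[!s$experience %in% c("experienced", "inexperienced")]) {
    add("experience_enum", id, sprintf("session %s: unknown experience level", id))
  }
  if (any(is.na(s$n_new_patients) | s$n_new_patients < 0L) ||
      any(is.na(s$n_followup_patients) | s$n_followup_patients < 0L)) {
    for (id in s$session_id[is.na(s$n_new_patients) | s$n_new_patients < 0L |
                            is.na(s$n_followup_patients) | s$n_followup_patients < 0L]) {
      add("patient_counts", id, sprintf("session %s: patient counts must be non-negative", id))
    }
  }

  if (nrow(r) > 0L) {
    dupr <- unique(r$record_id[duplicated(r$record_id)])
    for (id in dupr) add("record_id_unique", id, sprintf("duplicated record_id %s", id))

    bad <- r$record_id[as.numeric(r$end) <= as.numeric(r$start)]
    for (id in bad) add("record_duration", id, sprintf("record %s: end must be > start", id))

    for (id in r$record_id[!r$what %in% what_categories()]) {
      add("what_enum", id, sprintf("record %s: unknown what category", id))
    }
    for (id in r$record_id[!r$subcategory %in% subcategory_levels()]) {
      add("subcategory_enum", id, sprintf("record %s: unknown subcategory", id))
    }
    for (id in r$record_id[!r$how %in% how_categories()]) {
      add("how_enum", id, sprintf("record %s: unknown how label", id))
    }
    for (id in r$record_id[!r$who %in% who_categories()]) {
      add("who_enum", id, sprintf("record %s: unknown who label", id))
    }

    drug_sub <- r$subcategory %in% c("drug-related", "non-drug-related")
    bad <- r$record_id[drug_sub & !r$what %in% drug_split_categories()]
    for (id in bad) {
      add("subcategory_rule", id,
          sprintf("record %s: drug-related split only applies to %s", id,
                  paste(drug_split_categories(), collapse = ", ")))
    }
    soc_sub <- r$subcategory %in% c("professional", "non-professional")
    bad <- r$record_id[soc_sub & r$what != "Social"]
    for (id in bad) add("subcategory_rule", id,
                        sprintf("record %s: professional split only applies to Social", id))

    known <- r$session_id %in% s$session_id
    for (id in r$record_id[!known]) {
      add("session_ref", id, sprintf("record %s references unknown session", id))
    }
    if (any(known)) {
      idx <- match(r$session_id, s$session_id)
      inside <- !is.na(idx) &
        as.numeric(r$start) >= as.numeric(s$session_start)[idx] &
        as.numeric(r$end) <= as.numeric(s$session_end)[idx]
      for (id in r$record_id[known & !inside[seq_len(nrow(r))]]) {
        add("record_in_session", id,
            sprintf("record %s falls outside its session window", id))
      }
    }

    is_int <- r$is_interruption %in% TRUE
    miss_link <- is_int & is.na(r$interrupts_record_id)
    for (id in r$record_id[miss_link]) {
      add("interruption_link", id, sprintf("interruption %s has no interrupts_record_id", id))
    }
    linked <- is_int & !is.na(r$interrupts_record_id)
    if (any(linked)) {
      tgt <- match(r$interrupts_record_id, r$record_id)
      for (i in which(linked)) {
        j <- tgt[i]
        if (is.na(j)) {
          add("interruption_link", r$record_id[i],
              sprintf("interruption %s links to unknown record %s",
                      r$record_id[i], r$interrupts_record_id[i]))
        } else if (r$session_id[j] != r$session_id[i]) {
          add("interruption_link", r$record_id[i],
              sprintf("interruption %s links across sessions", r$record_id[i]))
        } else if (!(as.numeric(r$start[i]) >= as.numeric(r$start[j]) &&
                     as.numeric(r$start[i]) < as.numeric(r$end[j]))) {
          add("interruption_link", r$record_id[i],
              sprintf("interruption %s starts outside the interval of its target %s",
                      r$record_id[i], r$interrupts_record_id[i]))
        }
      }
    }
  }

  if (length(v) == 0L) {
    return(data.frame(rule = character(0), id = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Record selectors: predicates over dimensions and physician groups
#'
#' A selector is a conjunction of per-dimension membership conditions used to
#' define analysis slices (the rows and cells of the standard task-time
#' report tables).  `NULL` means "no restriction"; the empty selector matches
#' every record.  Group conditions (`affiliation`, `experience`) restrict by
#' the record's session.  `include_interruptions = FALSE` additionally drops
#' interruption records from the slice.
#'
#' @param what,subcategory,where,how,who Optional character vectors of
#'   permitted labels for the respective dimension.
#' @param affiliation,experience Optional physician-group restriction.
#' @param include_interruptions Keep interruption records in the slice
#'   (default `TRUE`: interruptions are tasks and their time counts toward
#'   their own category).
#' @return An object of class `selector`.
#' @examples
#' drug <- selector(subcategory = "drug-related")
#' drug_doc_paper <- selector(what = "Documentation",
#'                            subcategory = "drug-related", how = "On paper")
#' @export
selector <- function(what = NULL, subcategory = NULL, where = NULL, how = NULL,
                     who = NULL, affiliation = NULL, experience = NULL,
                     include_interruptions = TRUE) {
  structure(list(what = what, subcategory = subcategory, where = where,
                 how = how, who = who, affiliation = affiliation,
                 experience = experience,
                 include_interruptions = isTRUE(include_interruptions)),
            class = "selector")
}

#' @rdname selector
#' @param s1,s2 Selectors to combine; the result matches records matched by
#'   both (conjunction; set conditions intersect).
#' @export
selector_and <- function(s1, s2) {
  comb <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    intersect(a, b)
  }
  selector(what = comb(s1$what, s2$what),
           subcategory = comb(s1$subcategory, s2$subcategory),
           where = comb(s1$where, s2$where),
           how = comb(s1$how, s2$how),
           who = comb(s1$who, s2$who),
           affiliation = comb(s1$affiliation, s2$affiliation),
           experience = comb(s1$experience, s2$experience),
           include_interruptions = s1$include_interruptions && s2$include_interruptions)
}

#' @export
print.selector <- function(x, ...) {
  set <- Filter(Negate(is.null), x[c("what", "subcategory", "where", "how", "who",
                                     "affiliation", "experience")])
  if (length(set) == 0L) {
    cat("<selector> (matches everything)\n")
  } else {
    cat("<selector>\n")
    for (nm in names(set)) {
      cat(" ", nm, "in {", paste(set[[nm]], collapse = ", "), "}\n")
    }
  }
  if (!x$include_interruptions) cat("  interruption records excluded\n")
  invisible(x)
}

#' Which records match a selector
#'
#' @param dataset An `observation_dataset`.
#' @param sel A [selector()].
#' @return Logical vector over `dataset$records` rows.
#' @export
matches_selector <- function(dataset, sel) {
  r <- dataset$records
  keep <- rep(TRUE, nrow(r))
  for (dim in c("what", "subcategory", "where", "how", "who")) {
    if (!is.null(sel[[dim]])) keep <- keep & r[[dim]] %in% sel[[dim]]
  }
  if (!is.null(sel$affiliation) || !is.null(sel$experience)) {
    idx <- match(r$session_id, dataset$sessions$session_id)
    if (!is.null(sel$affiliation)) {
      keep <- keep & dataset$sessions$affiliation[idx] %in% sel$affiliation
    }
    if (!is.null(sel$experience)) {
      keep <- keep & dataset$sessions$experience[idx] %in% sel$experience
    }
  }
  if (!sel$include_interruptions) keep <- keep & !r$is_interruption
  keep
}

#' Restrict a dataset's records to a selector slice
#'
#' Sessions are kept unchanged (they define the observation time); only the
#' record table is filtered.
#'
#' @inheritParams matches_selector
#' @return An `observation_dataset` with the matching records.
#' @export
filter_records <- function(dataset, sel) {
  keep <- matches_selector(dataset, sel)
  out <- dataset
  out$records <- dataset$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Restrict a dataset to a physician group
#'
#' Unlike [filter_records()], this drops sessions (and their records) whose
#' physician is outside the group, so group-specific denominators use the
#' group's own observation time.
#'
#' @param dataset An `observation_dataset`.
#' @param affiliation,experience Optional group levels to keep.
#' @return An `observation_dataset`.
#' @export
subset_sessions <- function(dataset, affiliation = NULL, experience = NULL) {
  keep <- rep(TRUE, nrow(dataset$sessions))
  if (!is.null(affiliation)) keep <- keep & dataset$sessions$affiliation %in% affiliation
  if (!is.null(experience)) keep <- keep & dataset$sessions$experience %in% experience
  out <- dataset
  out$sessions <- dataset$sessions[keep, , drop = FALSE]
  out$records <- dataset$records[dataset$records$session_id %in% out$sessions$session_id, ,
                                 drop = FALSE]
  rownames(out$sessions) <- NULL
  rownames(out$records) <- NULL
  out
}
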