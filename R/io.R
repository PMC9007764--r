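#' Read and write observation event logs
#'
#' Two plain-text dialects are supported.  The CSV dialect uses a record file
#' with header
#' `record_id,session_id,what,subcategory,where,how,who,start,end,is_interruption,interrupts_record_id`
#' and a companion session file with header
#' `session_id,physician_id,affiliation,experience,session_start,session_end,n_new_patients,n_followup_patients`.
#' The JSON dialect is a single document `{"sessions": [...], "records":
#' [...]}` with the same field names.  Timestamps are ISO 8601 at seconds
#' precision (UTC); empty strings encode "none"/absent optionals.  Reading
#' and writing round-trip: `read_event_log(write_event_log(d)) == d`.
#'
#' @param path For CSV, the records file; for JSON, the single document.
#' @param sessions_path Companion sessions CSV (required for CSV, ignored
#'   for JSON).
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @param check Validate on read/write (default `TRUE`).
#' @return [read_event_log()] returns an `observation_dataset`;
#'   [write_event_log()] invisibly returns the main output path.
#' @export
read_event_log <- function(path, sessions_path = NULL,
                           format = c("auto", "csv", "json"), check = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!all(c("sessions", "records") %in% names(doc))) {
      stop("JSON event log must contain 'sessions' and 'records'", call. = FALSE)
    }
    sessions <- as.data.frame(doc$sessions, stringsAsFactors = FALSE)
    records <- if (length(doc$records) == 0L) data.frame() else
      as.data.frame(doc$records, stringsAsFactors = FALSE)
    if (nrow(records) > 0L) {
      records$interrupts_record_id <- .empty_to_na(records$interrupts_record_id)
    }
  } else {
    if (is.null(sessions_path)) {
      stop("CSV event logs need a companion sessions file (sessions_path)", call. = FALSE)
    }
    if (!file.exists(sessions_path)) stop("file not found: ", sessions_path, call. = FALSE)
    records <- .read_strict_csv(path,
      c("record_id", "session_id", "what", "subcategory", "where", "how", "who",
        "start", "end", "is_interruption", "interrupts_record_id"))
    sessions <- .read_strict_csv(sessions_path,
      c("session_id", "physician_id", "affiliation", "experience",
        "session_start", "session_end", "n_new_patients", "n_followup_patients"))
    if (nrow(records) > 0L) {
      records$is_interruption <- .parse_bool(records$is_interruption, path)
      records$interrupts_record_id <- .empty_to_na(records$interrupts_record_id)
    }
  }
  ds <- observation_dataset(sessions, records, check = FALSE)
  if (check) {
    rep <- validate_dataset(ds)
    if (nrow(rep) > 0L) {
      stop("event log failed validation (", nrow(rep), " violation(s)):\n",
           paste(utils::head(rep$message, 10L), collapse = "\n"), call. = FALSE)
    }
  }
  ds
}

.read_strict_csv <- function(path, expected_cols) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  miss <- setdiff(expected_cols, names(df))
  if (length(miss)) {
    stop("malformed file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df[expected_cols]
}

.parse_bool <- function(x, path) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "1", "t")] <- TRUE
  out[tolower(x) %in% c("false", "0", "f", "")] <- FALSE
  if (anyNA(out)) {
    stop("malformed file ", path, ": row ", which(is.na(out))[1L],
         ", field is_interruption: cannot parse '", x[which(is.na(out))[1L]], "'",
         call. = FALSE)
  }
  out
}

#' @rdname read_event_log
#' @param dataset An `observation_dataset` to serialize.
#' @export
write_event_log <- function(dataset, path, sessions_path = NULL,
                            format = c("auto", "csv", "json"), check = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (check) {
    rep <- validate_dataset(dataset)
    if (nrow(rep) > 0L) {
      stop("refusing to write invalid dataset (", nrow(rep), " violation(s))", call. = FALSE)
    }
  }
  s <- dataset$sessions
  r <- dataset$records
  s_out <- data.frame(session_id = s$session_id, physician_id = s$physician_id,
                      affiliation = s$affiliation, experience = s$experience,
                      session_start = .ts_format(s$session_start),
                      session_end = .ts_format(s$session_end),
                      n_new_patients = s$n_new_patients,
                      n_followup_patients = s$n_followup_patients,
                      stringsAsFactors = FALSE)
  r_out <- data.frame(record_id = r$record_id, session_id = r$session_id,
                      what = r$what, subcategory = r$subcategory, where = r$where,
                      how = r$how, who = r$who,
                      start = .ts_format(r$start), end = .ts_format(r$end),
                      is_interruption = r$is_interruption,
                      interrupts_record_id = .na_to_empty(r$interrupts_record_id),
                      stringsAsFactors = FALSE)
  if (format == "json") {
    jsonlite::write_json(list(sessions = s_out, records = r_out), path,
                         dataframe = "rows", auto_unbox = FALSE, pretty = TRUE)
  } else {
    if (is.null(sessions_path)) {
      sessions_path <- sub("(\\.[Cc][Ss][Vv])?$", "", path)
      sessions_path <- paste0(sub("_?records$", "", sessions_path), "_sessions.csv")
    }
    utils::write.csv(r_out, path, row.names = FALSE, quote = TRUE)
    utils::write.csv(s_out, sessions_path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
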