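# Brute-force per-second oracles.  Production code uses sweep lines over
# interval endpoints; these oracles materialize a boolean/count array over
# every second and are the independent reference for the interval algebra,
# the estimators and the windowing.

oracle_seconds_covered <- function(intervals, lo = NULL, hi = NULL) {
  m <- as.matrix(intervals)
  if (nrow(m) == 0L) return(logical(0))
  if (is.null(lo)) lo <- min(m[, 1L])
  if (is.null(hi)) hi <- max(m[, 2L])
  covered <- logical(hi - lo)
  for (i in seq_len(nrow(m))) {
    if (m[i, 2L] > m[i, 1L]) {
      idx <- seq.int(m[i, 1L] - lo + 1L, m[i, 2L] - lo)
      covered[idx] <- TRUE
    }
  }
  covered
}

oracle_union_length <- function(intervals) sum(oracle_seconds_covered(intervals))

oracle_intersect_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  lo <- min(a[, 1L], b[, 1L]); hi <- max(a[, 2L], b[, 2L])
  sum(oracle_seconds_covered(a, lo, hi) & oracle_seconds_covered(b, lo, hi))
}

# per-second count of active intervals on [lo, hi)
oracle_concurrency_counts <- function(intervals, lo, hi) {
  counts <- integer(hi - lo)
  m <- as.matrix(intervals)
  for (i in seq_len(nrow(m))) {
    idx <- seq.int(max(m[i, 1L], lo) - lo + 1L, min(m[i, 2L], hi) - lo)
    if (length(idx) > 0L && idx[1L] <= idx[length(idx)]) {
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

# labels of tasks active during second w (1-based over [t0, t0+n))
oracle_window_labels <- function(records, dim, t0, n) {
  lapply(seq_len(n), function(w) {
    ws <- t0 + w - 1L; we <- ws + 1L
    on <- as.numeric(records$start) < we & as.numeric(records$end) > ws
    if (!any(on)) "(idle)" else sort(unique(records[[dim]][on]))
  })
}

random_intervals <- function(n, span = 200L) {
  s <- sample.int(span, n, replace = TRUE) - 1L
  d <- sample.int(30L, n, replace = TRUE)
  cbind(start = s, end = pmin(s + d, span))
}

# exhaustive double-loop iota oracle on per-window label-set lists
oracle_iota <- function(dims_a, dims_b) {
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0L) 0 else 1 - length(intersect(x, y)) / u
  }
  n <- length(dims_a[[1L]])
  d_obs <- 0; d_exp <- 0
  for (d in seq_along(dims_a)) {
    for (i in seq_len(n)) d_obs <- d_obs + jac(dims_a[[d]][[i]], dims_b[[d]][[i]])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d_exp <- d_exp + jac(dims_a[[d]][[i]], dims_b[[d]][[j]])
    }
  }
  1 - (d_obs / n) / (d_exp / n^2)
}

# --- fixtures -------------------------------------------------------------

BASE <- as.POSIXct("2018-10-16 09:00:00", tz = "UTC")

make_session <- function(session_id = "S1", physician_id = "P1",
                         affiliation = "Medical", experience = "experienced",
                         start = BASE, hours = 2, n_new = 2L, n_follow = 1L) {
  data.frame(session_id = session_id, physician_id = physician_id,
             affiliation = affiliation, experience = experience,
             session_start = start, session_end = start + hours * 3600,
             n_new_patients = n_new, n_followup_patients = n_follow,
             stringsAsFactors = FALSE)
}

make_record <- function(record_id, session_id = "S1", what = "Documentation",
                        subcategory = "drug-related", where = "Physician desk",
                        how = "On computer", who = "none", start_s = 0, end_s = 60,
                        is_interruption = FALSE, interrupts = NA_character_,
                        base = BASE) {
  data.frame(record_id = record_id, session_id = session_id, what = what,
             subcategory = subcategory, where = where, how = how, who = who,
             start = base + start_s, end = base + end_s,
             is_interruption = is_interruption, interrupts_record_id = interrupts,
             stringsAsFactors = FALSE)
}

# one 2 h session: two sequential tasks and one interruption inside the first
tiny_dataset <- function() {
  recs <- rbind(
    make_record("r1", what = "Documentation", subcategory = "drug-related",
                start_s = 0, end_s = 600),
    make_record("r2", what = "Gather information", subcategory = "non-drug-related",
                who = "Patient", how = "Direct", start_s = 600, end_s = 1500),
    make_record("r3", what = "Professional communication",
                subcategory = "non-drug-related", who = "Nurse", how = "Direct",
                start_s = 120, end_s = 180, is_interruption = TRUE, interrupts = "r1")
  )
  observation_dataset(make_session(), recs)
}

# a dataset with several physicians generated from the compact default budget
small_synthetic <- function(n_phys = 8, seed = 1, hours = 0.5, ...) {
  generate_dataset(generator_config(n_physicians = n_phys, n_second_sessions = 0,
                                    session_hours = hours, seed = seed, ...))
}
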