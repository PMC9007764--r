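#' Exact algebra on half-open time intervals
#'
#' All task timing in this package is reduced to sets of half-open intervals
#' `[start, end)` on an integer-second axis.  The half-open convention makes
#' adjacency unambiguous: a task ending at second `t` and another starting at
#' `t` do not overlap, and the duration of `[s, e)` is exactly `e - s`
#' seconds.  Every operation below is exact integer arithmetic; no tolerances
#' are involved.
#'
#' An interval set is represented as a two-column numeric matrix with columns
#' `start` and `end`.  [normalize_intervals()] brings any such matrix into
#' canonical form: sorted, pairwise disjoint and non-adjacent.
#'
#' @param intervals A two-column matrix (or data.frame) of `start`, `end`
#'   pairs in seconds, with `end > start` row-wise.  A zero-row matrix is the
#'   empty set.
#' @return [normalize_intervals()] returns the canonical matrix.
#'   [interval_length()], [union_length()] and [intersect_length()] return a
#'   duration in seconds.
#' @examples
#' normalize_intervals(rbind(c(0, 10), c(5, 15)))   # merges to [0, 15)
#' union_length(rbind(c(0, 10), c(5, 15)))          # 15
#' intersect_length(rbind(c(0, 10)), rbind(c(5, 20)))  # 5
#' @name interval-algebra
NULL

as_interval_matrix <- function(intervals) {
  if (is.null(intervals)) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  if (is.data.frame(intervals)) intervals <- cbind(intervals$start, intervals$end)
  if (is.vector(intervals) && length(intervals) == 2L) intervals <- matrix(intervals, ncol = 2L)
  m <- unname(as.matrix(intervals))
  if (length(m) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  if (ncol(m) != 2L) stop("intervals must have two columns (start, end)", call. = FALSE)
  storage.mode(m) <- "numeric"
  colnames(m) <- c("start", "end")
  m
}

#' @rdname interval-algebra
#' @export
normalize_intervals <- function(intervals) {
  m <- as_interval_matrix(intervals)
  if (nrow(m) == 0L) return(m)
  if (any(!is.finite(m))) stop("interval endpoints must be finite", call. = FALSE)
  if (any(m[, 2L] <= m[, 1L])) {
    stop("all intervals must satisfy end > start (half-open [start, end))", call. = FALSE)
  }
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  start <- m[, 1L]; end <- m[, 2L]
  # merge runs where the next start is <= the running maximum end (adjacency
  # [a,b) + [b,c) merges too: same point set as [a,c))
  out_s <- numeric(nrow(m)); out_e <- numeric(nrow(m)); k <- 0L
  cs <- start[1L]; ce <- end[1L]
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      if (start[i] <= ce) {
        if (end[i] > ce) ce <- end[i]
      } else {
        k <- k + 1L; out_s[k] <- cs; out_e[k] <- ce
        cs <- start[i]; ce <- end[i]
      }
    }
  }
  k <- k + 1L; out_s[k] <- cs; out_e[k] <- ce
  cbind(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

#' @rdname interval-algebra
#' @export
interval_length <- function(intervals) {
  m <- normalize_intervals(intervals)
  if (nrow(m) == 0L) return(0)
  sum(m[, 2L] - m[, 1L])
}

#' @rdname interval-algebra
#' @param ... For [union_length()], any number of interval sets.
#' @export
union_length <- function(...) {
  sets <- list(...)
  interval_length(do.call(rbind, lapply(sets, as_interval_matrix)))
}

#' @rdname interval-algebra
#' @param a,b Interval sets.
#' @export
intersect_intervals <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  # two-pointer sweep over the two sorted disjoint lists
  out <- vector("list", nrow(a) + nrow(b))
  i <- 1L; j <- 1L; k <- 0L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1L], b[j, 1L])
    e <- min(a[i, 2L], b[j, 2L])
    if (s < e) {
      k <- k + 1L
      out[[k]] <- c(s, e)
    }
    if (a[i, 2L] <= b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  if (k == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  m <- do.call(rbind, out[seq_len(k)])
  colnames(m) <- c("start", "end")
  m
}

#' @rdname interval-algebra
#' @export
intersect_length <- function(a, b) {
  interval_length(intersect_intervals(a, b))
}

#' Segment a set of task intervals by concurrency
#'
#' Sweep-line segmentation of a collection of (possibly overlapping) task
#' intervals into maximal segments over which the set of active tasks is
#' constant.  Multitasking — two or more tasks performed simultaneously — is
#' exactly the union of segments with two or more active tasks.
#'
#' @param intervals Two-column matrix/data.frame of `[start, end)` pairs.
#' @param ids Optional vector of task identifiers, one per interval row;
#'   defaults to row numbers.
#' @return A data.frame with columns `start`, `end`, `n_active` and a
#'   list-column `active` holding the ids active on each segment.  Segments
#'   partition the union of the input intervals; consecutive segments differ
#'   in their active set.
#' @examples
#' concurrency_profile(rbind(c(0, 10), c(5, 15)))
#' @export
concurrency_profile <- function(intervals, ids = NULL) {
  m <- as_interval_matrix(intervals)
  if (is.null(ids)) ids <- seq_len(nrow(m))
  if (length(ids) != nrow(m)) stop("ids must have one entry per interval", call. = FALSE)
  empty <- data.frame(start = numeric(0), end = numeric(0), n_active = integer(0))
  empty$active <- list()
  if (nrow(m) == 0L) return(empty)
  if (any(m[, 2L] <= m[, 1L])) stop("all intervals must satisfy end > start", call. = FALSE)
  cuts <- sort(unique(c(m[, 1L], m[, 2L])))
  seg_s <- cuts[-length(cuts)]
  seg_e <- cuts[-1L]
  active <- vector("list", length(seg_s))
  n_active <- integer(length(seg_s))
  for (k in seq_along(seg_s)) {
    on <- m[, 1L] <= seg_s[k] & m[, 2L] >= seg_e[k]
    active[[k]] <- ids[on]
    n_active[k] <- sum(on)
  }
  keep <- n_active > 0L
  seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
  active <- active[keep]; n_active <- n_active[keep]
  # merge consecutive segments with identical active sets (cut points interior
  # to every active task leave the set unchanged)
  if (length(seg_s) > 1L) {
    same <- logical(length(seg_s))
    for (k in 2L:length(seg_s)) {
      same[k] <- seg_s[k] == seg_e[k - 1L] && identical(active[[k]], active[[k - 1L]])
    }
    grp <- cumsum(!same)
    seg_s <- tapply(seg_s, grp, min)
    seg_e <- tapply(seg_e, grp, max)
    active <- active[!same]
    n_active <- n_active[!same]
  }
  out <- data.frame(start = as.numeric(seg_s), end = as.numeric(seg_e),
                    n_active = as.integer(n_active), row.names = NULL)
  out$active <- active
  out
}

#' Multitasked subset of a concurrency profile
#'
#' @param profile A concurrency profile from [concurrency_profile()].
#' @param min_active Minimum number of simultaneously active tasks (default 2).
#' @return Normalized interval matrix covering the time with at least
#'   `min_active` concurrent tasks.
#' @export
multitask_intervals <- function(profile, min_active = 2L) {
  keep <- profile$n_active >= min_active
  if (!any(keep)) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  normalize_intervals(cbind(profile$start[keep], profile$end[keep]))
}
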