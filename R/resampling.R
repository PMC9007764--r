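# evaluate expr with a temporary RNG state; the caller's RNG is untouched
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Ratio-of-sums statistics for resampling
#'
#' All the headline estimators of this package (time proportions, multitask
#' fractions, interruption rates, per-session patient means) are ratios of
#' session-decomposable sums: the dataset-level value is
#' `sum(numerator_by_session) / sum(denominator_by_session)`.  A
#' `ratio_stat` captures that decomposition, which lets the cluster
#' bootstrap and the permutation test recompute the statistic on thousands
#' of resampled datasets from per-cluster aggregates instead of rebuilding
#' record tables.  [evaluate_stat()] applies a statistic to a dataset; for a
#' `ratio_stat` this equals the corresponding estimator function exactly.
#'
#' @param components_fn Function `dataset -> data.frame(session_id, num, den)`.
#' @param label Human-readable description.
#' @return An object of class `ratio_stat`.
#' @export
ratio_stat <- function(components_fn, label = "ratio statistic") {
  structure(list(components = components_fn, label = label), class = "ratio_stat")
}

#' @export
print.ratio_stat <- function(x, ...) {
  cat("<ratio_stat>", x$label, "\n")
  invisible(x)
}

.session_seconds <- function(dataset) {
  as.numeric(dataset$sessions$session_end) - as.numeric(dataset$sessions$session_start)
}

#' @rdname ratio_stat
#' @param numerator,denominator Selectors as in [proportion_of_time()].
#' @export
stat_proportion <- function(numerator, denominator = NULL) {
  force(numerator); force(denominator)
  ratio_stat(function(dataset) {
    num_ivs <- .session_slice_intervals(dataset, matches_selector(dataset, numerator))
    if (is.null(denominator)) {
      num <- vapply(num_ivs, interval_length, numeric(1))
      den <- .session_seconds(dataset)
    } else {
      den_ivs <- .session_slice_intervals(dataset, matches_selector(dataset, denominator))
      num <- vapply(dataset$sessions$session_id, function(sid) {
        intersect_length(num_ivs[[sid]], den_ivs[[sid]])
      }, numeric(1))
      den <- vapply(den_ivs, interval_length, numeric(1))
    }
    data.frame(session_id = dataset$sessions$session_id, num = unname(num),
               den = unname(den), stringsAsFactors = FALSE)
  }, label = "proportion of time")
}

#' @rdname ratio_stat
#' @param sel Selector defining the slice.
#' @export
stat_multitask_fraction <- function(sel = selector()) {
  force(sel)
  ratio_stat(function(dataset) {
    r <- dataset$records
    keep <- matches_selector(dataset, sel)
    num <- den <- numeric(nrow(dataset$sessions))
    for (k in seq_len(nrow(dataset$sessions))) {
      sid <- dataset$sessions$session_id[k]
      rows_sel <- which(keep & r$session_id == sid)
      if (length(rows_sel) == 0L) next
      sel_union <- normalize_intervals(.record_intervals(r, rows_sel))
      den[k] <- interval_length(sel_union)
      rows_all <- which(r$session_id == sid)
      prof <- concurrency_profile(.record_intervals(r, rows_all))
      num[k] <- intersect_length(multitask_intervals(prof), sel_union)
    }
    data.frame(session_id = dataset$sessions$session_id, num = num, den = den,
               stringsAsFactors = FALSE)
  }, label = "multitask fraction")
}

#' @rdname ratio_stat
#' @param exposure Exposure selector as in [interruption_rate()] (`NULL` =
#'   total observation time); the ratio is events per *hour*.
#' @export
stat_interruption_rate <- function(exposure = NULL) {
  force(exposure)
  ratio_stat(function(dataset) {
    r <- dataset$records
    ints <- which(r$is_interruption %in% TRUE)
    n_sess <- nrow(dataset$sessions)
    num <- den <- numeric(n_sess)
    if (is.null(exposure)) {
      for (k in seq_len(n_sess)) {
        sid <- dataset$sessions$session_id[k]
        num[k] <- sum(r$session_id[ints] == sid)
      }
      den <- .session_seconds(dataset) / 3600
    } else {
      keep <- matches_selector(dataset, exposure)
      for (k in seq_len(n_sess)) {
        sid <- dataset$sessions$session_id[k]
        rows_sel <- which(keep & r$session_id == sid)
        if (length(rows_sel)) {
          den[k] <- interval_length(normalize_intervals(.record_intervals(r, rows_sel))) / 3600
        }
        for (i in intersect(ints, which(r$session_id == sid))) {
          others <- setdiff(rows_sel, i)
          if (length(others) == 0L) next
          t0 <- as.numeric(r$start[i])
          if (any(as.numeric(r$start[others]) <= t0 & as.numeric(r$end[others]) > t0)) {
            num[k] <- num[k] + 1L
          }
        }
      }
    }
    data.frame(session_id = dataset$sessions$session_id, num = num, den = den,
               stringsAsFactors = FALSE)
  }, label = "interruption rate per hour")
}

#' @rdname ratio_stat
#' @export
stat_fraction_tasks_interrupted <- function(sel = selector()) {
  force(sel)
  ratio_stat(function(dataset) {
    r <- dataset$records
    keep <- matches_selector(dataset, sel)
    targets <- unique(r$interrupts_record_id[r$is_interruption %in% TRUE &
                                             !is.na(r$interrupts_record_id)])
    num <- den <- numeric(nrow(dataset$sessions))
    for (k in seq_len(nrow(dataset$sessions))) {
      sid <- dataset$sessions$session_id[k]
      rows <- which(keep & r$session_id == sid)
      den[k] <- length(rows)
      num[k] <- sum(r$record_id[rows] %in% targets)
    }
    data.frame(session_id = dataset$sessions$session_id, num = num, den = den,
               stringsAsFactors = FALSE)
  }, label = "fraction of tasks interrupted")
}

#' @rdname ratio_stat
#' @param type Which patient mean: `"total"`, `"new"` or `"followup"`.
#' @export
stat_patients_per_session <- function(type = c("total", "new", "followup")) {
  type <- match.arg(type)
  ratio_stat(function(dataset) {
    s <- dataset$sessions
    num <- switch(type,
                  total = s$n_new_patients + s$n_followup_patients,
                  new = s$n_new_patients,
                  followup = s$n_followup_patients)
    data.frame(session_id = s$session_id, num = as.numeric(num),
               den = rep(1, nrow(s)), stringsAsFactors = FALSE)
  }, label = paste("mean", type, "patients per session"))
}

#' @rdname ratio_stat
#' @param statistic A `ratio_stat` or a plain function `dataset -> scalar`.
#' @param dataset An `observation_dataset`.
#' @export
evaluate_stat <- function(statistic, dataset) {
  if (inherits(statistic, "ratio_stat")) {
    comp <- statistic$components(dataset)
    sum(comp$num) / sum(comp$den)
  } else {
    statistic(dataset)
  }
}

.cluster_of_sessions <- function(dataset, cluster = c("physician", "session")) {
  cluster <- match.arg(cluster)
  if (cluster == "physician") dataset$sessions$physician_id else dataset$sessions$session_id
}

# resampled copy of a dataset given drawn cluster labels (with repetition);
# ids get a copy suffix so duplicated clusters stay distinct
.resample_dataset <- function(dataset, cluster_ids, drawn) {
  s <- dataset$sessions; r <- dataset$records
  s_parts <- vector("list", length(drawn))
  r_parts <- vector("list", length(drawn))
  for (k in seq_along(drawn)) {
    srows <- which(cluster_ids == drawn[k])
    sk <- s[srows, , drop = FALSE]
    rk <- r[r$session_id %in% sk$session_id, , drop = FALSE]
    suffix <- paste0("#", k)
    rk$session_id <- paste0(rk$session_id, suffix)
    rk$record_id <- paste0(rk$record_id, suffix)
    rk$interrupts_record_id <- ifelse(is.na(rk$interrupts_record_id), NA,
                                      paste0(rk$interrupts_record_id, suffix))
    sk$session_id <- paste0(sk$session_id, suffix)
    sk$physician_id <- paste0(sk$physician_id, suffix)
    s_parts[[k]] <- sk
    r_parts[[k]] <- rk
  }
  structure(list(sessions = do.call(rbind, s_parts),
                 records = do.call(rbind, r_parts)),
            class = "observation_dataset")
}

#' Cluster bootstrap percentile confidence interval
#'
#' Resamples independence units ("clusters": physicians by default, carrying
#' all their sessions and records) with replacement to the original cluster
#' count, recomputes the statistic on each replicate, and returns the
#' percentile interval.  Nonparametric by design — proportions of continuous
#' multitasked time have no convenient parametric sampling model.
#'
#' Replicates on which the statistic is undefined (zero denominator) are
#' dropped and counted; more than 10\% dropped is an error.
#'
#' @param dataset An `observation_dataset` with at least two clusters.
#' @param statistic A `ratio_stat` (fast path, recomputed from per-cluster
#'   aggregates) or any function `dataset -> scalar`.
#' @param level Confidence level (default 0.95).
#' @param n_replicates Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param cluster `"physician"` (default) or `"session"`.
#' @return An object of class `bootstrap_result`: `point_estimate`,
#'   `ci_low`, `ci_high`, `level`, `n_replicates`, `seed`,
#'   `replicate_values`, `n_dropped`.
#' @export
bootstrap_ci <- function(dataset, statistic, level = 0.95, n_replicates = 10000,
                         seed = 1L, cluster = c("physician", "session")) {
  cluster <- match.arg(cluster)
  cluster_ids <- .cluster_of_sessions(dataset, cluster)
  clusters <- unique(cluster_ids)
  if (length(clusters) < 2L) stop("need at least two clusters to bootstrap", call. = FALSE)
  point <- evaluate_stat(statistic, dataset)

  if (inherits(statistic, "ratio_stat")) {
    comp <- statistic$components(dataset)
    idx <- match(comp$session_id, dataset$sessions$session_id)
    cnum <- tapply(comp$num, factor(cluster_ids[idx], levels = clusters), sum)
    cden <- tapply(comp$den, factor(cluster_ids[idx], levels = clusters), sum)
    cnum <- as.numeric(cnum); cden <- as.numeric(cden)
    vals <- with_local_seed(seed, {
      vapply(seq_len(n_replicates), function(b) {
        j <- sample.int(length(clusters), length(clusters), replace = TRUE)
        d <- sum(cden[j])
        if (d <= 0) NA_real_ else sum(cnum[j]) / d
      }, numeric(1))
    })
  } else {
    vals <- with_local_seed(seed, {
      vapply(seq_len(n_replicates), function(b) {
        drawn <- sample(clusters, length(clusters), replace = TRUE)
        res <- tryCatch(statistic(.resample_dataset(dataset, cluster_ids, drawn)),
                        error = function(e) NA_real_)
        if (is.null(res) || !is.finite(res)) NA_real_ else res
      }, numeric(1))
    })
  }
  n_dropped <- sum(is.na(vals))
  if (n_dropped > 0.1 * n_replicates) {
    stop("statistic undefined on more than 10% of bootstrap replicates (",
         n_dropped, "/", n_replicates, ")", call. = FALSE)
  }
  vals_ok <- vals[!is.na(vals)]
  alpha <- 1 - level
  qs <- stats::quantile(vals_ok, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  structure(list(point_estimate = point, ci_low = qs[1L], ci_high = qs[2L],
                 level = level, n_replicates = n_replicates, seed = seed,
                 replicate_values = vals_ok, n_dropped = n_dropped,
                 cluster = cluster),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.4f (%.0f%% CI %.4f, %.4f) [%d %s-cluster bootstrap replicates, seed %d]\n",
              x$point_estimate, 100 * x$level, x$ci_low, x$ci_high,
              x$n_replicates, x$cluster, x$seed))
  invisible(x)
}

#' Monte Carlo permutation test for a two-group contrast
#'
#' Tests whether a statistic (by default a time proportion with
#' group-specific denominators) differs between two physician groups
#' (medical vs surgical affiliation, or experienced vs inexperienced).  The
#' observed statistic is the group-1 minus group-2 difference.  The null
#' distribution is built by randomly reassigning group labels over
#' physicians, preserving the observed group sizes (conditioning on the
#' design, e.g. the 3:1 medical:surgical draw).  The two-sided p-value uses
#' the add-one rule `p = (1 + #{|T*| >= |T|}) / (1 + n_permutations)`, so
#' `p` is in (0, 1].
#'
#' @param dataset An `observation_dataset` whose sessions carry exactly two
#'   distinct labels in `group_field`, with at least two physicians each.
#' @param group_field `"affiliation"` or `"experience"`.
#' @param statistic A `ratio_stat` or function `dataset -> scalar`, applied
#'   to each group's sub-dataset.
#' @param n_permutations Number of random label permutations (default 9999).
#' @param seed Integer seed.
#' @return An object of class `mc_test_result`: `observed_statistic`,
#'   `p_value`, `n_permutations`, `seed`, `group_levels`, `group_estimates`.
#' @export
monte_carlo_group_test <- function(dataset, group_field = c("affiliation", "experience"),
                                   statistic, n_permutations = 9999, seed = 1L) {
  group_field <- match.arg(group_field)
  s <- dataset$sessions
  phys <- unique(s[c("physician_id", group_field)])
  if (any(duplicated(phys$physician_id))) {
    stop("a physician appears with two different ", group_field, " labels", call. = FALSE)
  }
  levels_ <- sort(unique(phys[[group_field]]))
  if (length(levels_) != 2L) stop("need exactly two group labels, found ",
                                  length(levels_), call. = FALSE)
  n_by_group <- table(factor(phys[[group_field]], levels = levels_))
  if (any(n_by_group < 2L)) stop("need at least two physicians per group", call. = FALSE)

  if (inherits(statistic, "ratio_stat")) {
    comp <- statistic$components(dataset)
    idx <- match(comp$session_id, s$session_id)
    pid <- s$physician_id[idx]
    pnum <- tapply(comp$num, factor(pid, levels = phys$physician_id), sum)
    pden <- tapply(comp$den, factor(pid, levels = phys$physician_id), sum)
    pnum <- as.numeric(pnum); pden <- as.numeric(pden)
    pnum[is.na(pnum)] <- 0; pden[is.na(pden)] <- 0
    grp_stat <- function(members) {
      d <- sum(pden[members])
      if (d <= 0) NA_real_ else sum(pnum[members]) / d
    }
    g1 <- which(phys[[group_field]] == levels_[1L])
    g2 <- which(phys[[group_field]] == levels_[2L])
    est1 <- grp_stat(g1); est2 <- grp_stat(g2)
    observed <- est1 - est2
    n1 <- length(g1)
    perm_vals <- with_local_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        p1 <- sample.int(nrow(phys), n1)
        grp_stat(p1) - grp_stat(setdiff(seq_len(nrow(phys)), p1))
      }, numeric(1))
    })
  } else {
    group_of <- function(members) {
      keep_phys <- phys$physician_id[members]
      out <- dataset
      out$sessions <- s[s$physician_id %in% keep_phys, , drop = FALSE]
      out$records <- dataset$records[dataset$records$session_id %in% out$sessions$session_id, ,
                                     drop = FALSE]
      out
    }
    g1 <- which(phys[[group_field]] == levels_[1L])
    g2 <- which(phys[[group_field]] == levels_[2L])
    est1 <- statistic(group_of(g1)); est2 <- statistic(group_of(g2))
    observed <- est1 - est2
    n1 <- length(g1)
    perm_vals <- with_local_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        p1 <- sample.int(nrow(phys), n1)
        statistic(group_of(p1)) - statistic(group_of(setdiff(seq_len(nrow(phys)), p1)))
      }, numeric(1))
    })
  }
  exceed <- sum(abs(perm_vals) >= abs(observed), na.rm = FALSE)
  if (anyNA(perm_vals)) exceed <- sum(abs(perm_vals) >= abs(observed) | is.na(perm_vals))
  p <- (1 + exceed) / (1 + n_permutations)
  structure(list(observed_statistic = observed, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 group_levels = levels_,
                 group_estimates = stats::setNames(c(est1, est2), levels_)),
            class = "mc_test_result")
}

#' @export
print.mc_test_result <- function(x, ...) {
  cat(sprintf("%s: %.4f vs %s: %.4f; difference %.4f, p = %.4f (%d permutations, seed %d)\n",
              x$group_levels[1L], x$group_estimates[1L],
              x$group_levels[2L], x$group_estimates[2L],
              x$observed_statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
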