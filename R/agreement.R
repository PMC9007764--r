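#' Discretize a session's records into aligned label windows
#'
#' Inter-rater reliability is computed on a per-window multivariate label
#' sequence: observation time is cut into fixed windows (default one second)
#' and each window is labelled, per dimension, with the *set* of labels of
#' all tasks active during any part of that window (set-valued under
#' multitasking).  Windows with no active task get the sentinel label
#' `"(idle)"`, so label sets are never empty.
#'
#' @param dataset An `observation_dataset` (one observer's log).
#' @param session_id Which session to discretize.
#' @param dims Dimensions to label, a subset of
#'   `c("what", "subcategory", "where", "how", "who")`.
#' @param window_seconds Window width in seconds (default 1).
#' @return An object of class `window_sequence`: list with `window_seconds`,
#'   `t0` (epoch seconds), `n` (number of windows) and `dims`, a named list
#'   of length-`n` lists of character label sets.
#' @export
discretize_to_windows <- function(dataset, session_id,
                                  dims = c("what", "where", "how", "who"),
                                  window_seconds = 1L) {
  stopifnot(window_seconds >= 1L)
  dims <- match.arg(dims, c("what", "subcategory", "where", "how", "who"),
                    several.ok = TRUE)
  srow <- which(dataset$sessions$session_id == session_id)
  if (length(srow) != 1L) stop("unknown session_id: ", session_id, call. = FALSE)
  t0 <- as.numeric(dataset$sessions$session_start[srow])
  t1 <- as.numeric(dataset$sessions$session_end[srow])
  n <- as.integer(ceiling((t1 - t0) / window_seconds))
  r <- dataset$records[dataset$records$session_id == session_id, , drop = FALSE]

  dim_windows <- lapply(dims, function(d) vector("list", n))
  names(dim_windows) <- dims
  if (nrow(r) > 0L) {
    rs <- as.numeric(r$start); re <- as.numeric(r$end)
    # task active in window w iff start < window end and end > window start
    w1 <- pmax(1L, as.integer(floor((rs - t0) / window_seconds)) + 1L)
    w2 <- pmin(n, as.integer(ceiling((re - t0) / window_seconds)))
    for (i in seq_len(nrow(r))) {
      if (w2[i] < w1[i]) next
      for (d in dims) {
        lab <- r[[d]][i]
        for (w in w1[i]:w2[i]) {
          dim_windows[[d]][[w]] <- c(dim_windows[[d]][[w]], lab)
        }
      }
    }
  }
  for (d in dims) {
    dim_windows[[d]] <- lapply(dim_windows[[d]], function(x) {
      if (is.null(x)) "(idle)" else sort(unique(x))
    })
  }
  structure(list(window_seconds = as.integer(window_seconds), t0 = t0, n = n,
                 dims = dim_windows),
            class = "window_sequence")
}

#' @export
print.window_sequence <- function(x, ...) {
  cat("<window_sequence>", x$n, "windows of", x$window_seconds, "s; dimensions:",
      paste(names(x$dims), collapse = ", "), "\n")
  invisible(x)
}

# align two window sequences on their common span (truncating with a warning
# when the recorded extents differ)
.align_sequences <- function(seq_a, seq_b) {
  if (seq_a$window_seconds != seq_b$window_seconds) {
    stop("window widths differ between observers", call. = FALSE)
  }
  ws <- seq_a$window_seconds
  t0 <- max(seq_a$t0, seq_b$t0)
  tend_a <- seq_a$t0 + ws * seq_a$n
  tend_b <- seq_b$t0 + ws * seq_b$n
  t1 <- min(tend_a, tend_b)
  if ((t1 - t0) / ws < 1) stop("observer sequences do not overlap in time", call. = FALSE)
  if (t0 != seq_a$t0 || t0 != seq_b$t0 || t1 != tend_a || t1 != tend_b) {
    warning("observer sequences cover different spans; truncated to the common span",
            call. = FALSE)
  }
  crop <- function(s) {
    from <- as.integer(round((t0 - s$t0) / ws)) + 1L
    to <- as.integer(round((t1 - s$t0) / ws))
    s$dims <- lapply(s$dims, function(w) w[from:to])
    s$t0 <- t0
    s$n <- to - from + 1L
    s
  }
  list(a = crop(seq_a), b = crop(seq_b))
}

.agreement_score <- function(d_obs, d_exp, method, dims) {
  structure(list(observed_disagreement = d_obs, expected_disagreement = d_exp,
                 score = 1 - d_obs / d_exp, method = method, dims = dims),
            class = "agreement_score")
}

#' @export
print.agreement_score <- function(x, ...) {
  cat(sprintf("%s = %.4f  (observed disagreement %.4f, expected %.4f; dims: %s)\n",
              x$method, x$score, x$observed_disagreement, x$expected_disagreement,
              paste(x$dims, collapse = ", ")))
  invisible(x)
}

# canonical string key for a label set, plus jaccard distance on keys
.set_keys <- function(windows) {
  vapply(windows, function(x) paste(x, collapse = "\x1f"), character(1))
}

.jaccard_dist <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0L) return(0)
  1 - length(intersect(set_a, set_b)) / u
}

# per-dimension observed/expected disagreement via distinct-set tabulation:
# D_e over all n^2 cross pairs reduces to p' D q with p, q the observers'
# distributions over distinct label sets and D the pairwise distance matrix
.dim_disagreement <- function(win_a, win_b) {
  key_a <- .set_keys(win_a)
  key_b <- .set_keys(win_b)
  keys <- unique(c(key_a, key_b))
  sets <- win_a[match(keys, key_a)]
  miss <- is.na(match(keys, key_a))
  sets[miss] <- win_b[match(keys[miss], key_b)]
  K <- length(keys)
  D <- matrix(0, K, K)
  if (K > 1L) {
    for (i in 1:(K - 1L)) {
      for (j in (i + 1L):K) {
        D[i, j] <- D[j, i] <- .jaccard_dist(sets[[i]], sets[[j]])
      }
    }
  }
  ia <- match(key_a, keys); ib <- match(key_b, keys)
  d_obs <- mean(D[cbind(ia, ib)])
  p <- tabulate(ia, K) / length(ia)
  q <- tabulate(ib, K) / length(ib)
  d_exp <- as.numeric(t(p) %*% D %*% q)
  c(d_obs = d_obs, d_exp = d_exp)
}

#' Multivariate chance-adjusted agreement (iota) on aligned windows
#'
#' Between-observer distance of window `i` is the sum over dimensions of a
#' per-dimension set distance: `1 - |A
#' intersect B| / |A union B|` (Jaccard), which reduces to a 0/1 mismatch for
#' singleton labels.  Observed disagreement is the mean distance over the
#' `n` aligned windows; expected disagreement is the mean over all `n^2`
#' cross pairs (window `i` of observer A against window `j` of observer B,
#' i.e. Cohen-style per-observer marginals).  The score is
#' `1 - observed/expected`: 1 for identical sequences, about 0 for
#' chance-level agreement, negative for worse-than-chance.
#'
#' For a single dimension with singleton labels, iota equals Cohen's kappa
#' exactly.
#'
#' @param seq_a,seq_b `window_sequence` objects from
#'   [discretize_to_windows()], one per observer, covering the same span.
#' @param dims Dimensions to include (default: all shared dimensions).
#' @return An `agreement_score` with `observed_disagreement`,
#'   `expected_disagreement` and `score`.
#' @seealso [cohens_kappa()], [mean_agreement()]
#' @export
iota <- function(seq_a, seq_b, dims = NULL) {
  if (is.null(dims)) dims <- intersect(names(seq_a$dims), names(seq_b$dims))
  if (length(dims) == 0L) stop("no shared dimensions", call. = FALSE)
  miss <- setdiff(dims, intersect(names(seq_a$dims), names(seq_b$dims)))
  if (length(miss)) stop("dimension(s) not present in both sequences: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  al <- .align_sequences(seq_a, seq_b)
  d_obs <- 0; d_exp <- 0
  for (d in dims) {
    dd <- .dim_disagreement(al$a$dims[[d]], al$b$dims[[d]])
    d_obs <- d_obs + dd[["d_obs"]]
    d_exp <- d_exp + dd[["d_exp"]]
  }
  if (d_exp == 0) {
    stop("expected disagreement is zero (both observers constant and equal); iota undefined",
         call. = FALSE)
  }
  .agreement_score(d_obs, d_exp, "iota", dims)
}

#' Cohen's kappa on one dimension of aligned windows
#'
#' The univariate base case of [iota()]: requires singleton labels in the
#' chosen dimension.  `kappa = (Po - Pe) / (1 - Pe)` with `Po` the fraction
#' of agreeing windows and `Pe` the chance agreement from the two observers'
#' label marginals.
#'
#' @inheritParams iota
#' @param dim The single dimension to score.
#' @return An `agreement_score`.
#' @export
cohens_kappa <- function(seq_a, seq_b, dim = "what") {
  if (!dim %in% names(seq_a$dims) || !dim %in% names(seq_b$dims)) {
    stop("dimension not present in both sequences: ", dim, call. = FALSE)
  }
  al <- .align_sequences(seq_a, seq_b)
  wa <- al$a$dims[[dim]]; wb <- al$b$dims[[dim]]
  if (any(lengths(wa) != 1L) || any(lengths(wb) != 1L)) {
    stop("Cohen's kappa needs singleton labels; use iota() for set-valued windows",
         call. = FALSE)
  }
  a <- unlist(wa); b <- unlist(wb)
  labs <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pe <- sum((tabulate(match(a, labs), length(labs)) / length(a)) *
            (tabulate(match(b, labs), length(labs)) / length(b)))
  if (pe == 1) {
    stop("chance agreement is 1 (both raters constant and equal); kappa undefined",
         call. = FALSE)
  }
  .agreement_score(1 - po, 1 - pe, "kappa", dim)
}

#' Average of agreement scores
#'
#' Arithmetic mean of a collection of agreement scores, as used to summarize
#' repeated inter-rater reliability sessions.
#'
#' @param scores A numeric vector of scores, or a list of `agreement_score`
#'   objects.
#' @return The mean score.
#' @export
mean_agreement <- function(scores) {
  if (is.list(scores)) {
    scores <- vapply(scores, function(s) {
      if (inherits(s, "agreement_score")) s$score else as.numeric(s)
    }, numeric(1))
  }
  if (length(scores) == 0L) stop("no scores to average", call. = FALSE)
  mean(scores)
}

#' Full agreement report for a paired-observer session
#'
#' Discretizes both observers' logs for one session and reports the joint
#' multivariate iota plus a per-dimension breakdown (each dimension scored
#' alone, handling set-valued windows), with observed/expected disagreement
#' diagnostics.
#'
#' @param obs_a,obs_b `observation_dataset`s from the two observers.
#' @param session_id Session common to both logs.
#' @param dims Dimensions to score.
#' @param window_seconds Window width in seconds.
#' @return A list with `iota` (joint `agreement_score`) and `per_dimension`
#'   (data.frame of per-dimension scores and diagnostics).
#' @export
agreement_report <- function(obs_a, obs_b, session_id,
                             dims = c("what", "where", "how", "who"),
                             window_seconds = 1L) {
  sa <- discretize_to_windows(obs_a, session_id, dims, window_seconds)
  sb <- discretize_to_windows(obs_b, session_id, dims, window_seconds)
  joint <- iota(sa, sb, dims)
  per_dim <- do.call(rbind, lapply(dims, function(d) {
    sc <- iota(sa, sb, d)
    data.frame(dim = d, score = sc$score,
               observed_disagreement = sc$observed_disagreement,
               expected_disagreement = sc$expected_disagreement,
               stringsAsFactors = FALSE)
  }))
  list(iota = joint, per_dimension = per_dim)
}
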