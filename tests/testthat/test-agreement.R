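# build a window_sequence directly from per-dim label vectors/lists
seq_from_labels <- function(..., window_seconds = 1L, t0 = 0) {
  dims <- list(...)
  dims <- lapply(dims, function(x) if (is.list(x)) x else as.list(x))
  structure(list(window_seconds = as.integer(window_seconds), t0 = t0,
                 n = length(dims[[1L]]), dims = dims),
            class = "window_sequence")
}

test_that("discretization labels each second with the active task set", {
  # one task spanning the whole session
  d <- observation_dataset(make_session(hours = 0.1),
                           make_record("r1", start_s = 0, end_s = 360))
  ws <- discretize_to_windows(d, "S1", dims = c("what", "how"))
  expect_equal(ws$n, 360L)
  expect_true(all(vapply(ws$dims$what, identical, logical(1), "Documentation")))

  # overlapping tasks -> set-valued windows; gaps -> idle sentinel
  d2 <- observation_dataset(make_session(hours = 0.1), rbind(
    make_record("a", start_s = 0, end_s = 100),
    make_record("b", what = "Gather information", subcategory = "non-drug-related",
                who = "Patient", how = "Direct", start_s = 50, end_s = 150)))
  ws2 <- discretize_to_windows(d2, "S1", dims = "what")
  expect_equal(ws2$dims$what[[75]], c("Documentation", "Gather information"))
  expect_equal(ws2$dims$what[[25]], "Documentation")
  expect_equal(ws2$dims$what[[200]], "(idle)")

  # random sessions vs the per-second scan, all four dimensions
  for (seed in 1:3) {
    d3 <- small_synthetic(n_phys = 1, seed = 200 + seed, hours = 0.1)
    sid <- d3$sessions$session_id[1]
    t0 <- as.numeric(d3$sessions$session_start[1])
    r <- d3$records[d3$records$session_id == sid, ]
    got <- discretize_to_windows(d3, sid)
    for (dim in c("what", "where", "how", "who")) {
      expect_identical(got$dims[[dim]], oracle_window_labels(r, dim, t0, got$n))
    }
  }
})

test_that("kappa matches the hand-computed confusion matrix", {
  # confusion counts [[20, 5], [10, 15]] over 50 windows:
  # Po = 35/50 = 0.7; marginals a = (0.5, 0.5), b = (0.6, 0.4);
  # Pe = 0.5*0.6 + 0.5*0.4 = 0.5; kappa = (0.7-0.5)/(1-0.5) = 0.4
  a <- c(rep("X", 25), rep("Y", 25))
  b <- c(rep("X", 20), rep("Y", 5), rep("X", 10), rep("Y", 15))
  k <- cohens_kappa(seq_from_labels(what = a), seq_from_labels(what = b), "what")
  expect_equal(k$score, 0.4)
  expect_equal(k$observed_disagreement, 0.3)
  expect_equal(k$expected_disagreement, 0.5)

  # identical sequences -> 1
  k1 <- cohens_kappa(seq_from_labels(what = a), seq_from_labels(what = a), "what")
  expect_equal(k1$score, 1)

  # both raters constant and equal -> undefined
  cc <- rep("X", 10)
  expect_error(cohens_kappa(seq_from_labels(what = cc), seq_from_labels(what = cc), "what"),
               "undefined")
})

test_that("kappa equals the brute-force mismatch-distance computation", {
  set.seed(501)
  for (rep in 1:10) {
    n <- 80
    labs <- LETTERS[1:sample(2:5, 1)]
    a <- sample(labs, n, replace = TRUE)
    b <- sample(labs, n, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    k <- cohens_kappa(seq_from_labels(what = a), seq_from_labels(what = b), "what")
    d_obs <- mean(a != b)
    d_exp <- mean(outer(a, b, "!="))
    expect_equal(k$score, 1 - d_obs / d_exp)
  }
})

test_that("iota equals the exhaustive double-loop oracle", {
  # 10-window, 2-dimension toy example with set-valued windows
  what_a <- list("Doc", "Doc", c("Doc", "Move"), "Move", "Idle",
                 "Gather", c("Gather", "Doc"), "Doc", "Idle", "Move")
  what_b <- list("Doc", "Move", c("Doc", "Move"), "Move", "Idle",
                 "Doc", c("Gather", "Doc"), "Doc", "Gather", "Move")
  how_a <- list("PC", "PC", c("PC", "none"), "none", "none",
                "Paper", "Paper", "PC", "none", "none")
  how_b <- list("PC", "none", c("PC", "none"), "none", "none",
                "PC", "Paper", "PC", "Paper", "none")
  sa <- seq_from_labels(what = what_a, how = how_a)
  sb <- seq_from_labels(what = what_b, how = how_b)
  got <- iota(sa, sb)
  expect_equal(got$score, oracle_iota(sa$dims, sb$dims))

  # identical multivariate sequences -> exactly 1
  expect_equal(iota(sa, sa)$score, 1)

  # iota <= 1 on random set-valued sequences, matching the oracle
  set.seed(502)
  for (rep in 1:5) {
    n <- 30
    mk <- function() lapply(seq_len(n), function(i) {
      sort(sample(c("A", "B", "C", "D"), sample(1:2, 1)))
    })
    sa <- seq_from_labels(what = mk(), who = mk())
    sb <- seq_from_labels(what = mk(), who = mk())
    got <- iota(sa, sb)
    expect_equal(got$score, oracle_iota(sa$dims, sb$dims))
    expect_lte(got$score, 1)
  }
})

test_that("iota reduces exactly to Cohen's kappa for one singleton dimension", {
  set.seed(503)
  for (rep in 1:10) {
    n <- 120
    labs <- c("Doc", "Gather", "Comm", "Move")
    a <- sample(labs, n, replace = TRUE)
    b <- sample(labs, n, replace = TRUE)
    sa <- seq_from_labels(what = a)
    sb <- seq_from_labels(what = b)
    expect_equal(iota(sa, sb, "what")$score, cohens_kappa(sa, sb, "what")$score)
  }
})

test_that("degrading one sequence never increases iota", {
  set.seed(504)
  n <- 200
  a <- sample(c("A", "B", "C"), n, replace = TRUE)
  sa <- seq_from_labels(what = a)
  flip_positions <- sample(n)
  scores <- vapply(c(0, 20, 60, 120, 200), function(k) {
    b <- a
    for (i in flip_positions[seq_len(k)]) {
      b[i] <- setdiff(c("A", "B", "C"), a[i])[1]
    }
    iota(sa, seq_from_labels(what = b), "what")$score
  }, numeric(1))
  expect_equal(scores[1], 1)
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("iota concentrates near zero for independent sequences", {
  set.seed(505)
  n <- 3000
  mk <- function() sample(c("A", "B", "C", "D"), n, replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1))
  sc <- iota(seq_from_labels(what = mk(), who = mk()),
             seq_from_labels(what = mk(), who = mk()))$score
  expect_lt(abs(sc), 0.05)
})

test_that("sequences of different spans are truncated with a warning", {
  d <- observation_dataset(make_session(hours = 0.1),
                           make_record("r1", start_s = 0, end_s = 300))
  d_long <- observation_dataset(make_session(hours = 0.2),
                                make_record("r1", start_s = 0, end_s = 300))
  sa <- discretize_to_windows(d, "S1", dims = "what")
  sb <- discretize_to_windows(d_long, "S1", dims = "what")
  expect_warning(sc <- iota(sa, sb, "what"), "common span")
  expect_equal(sc$score, 1)
})

test_that("mean_agreement averages scores", {
  expect_equal(mean_agreement(c(0.781, 0.622, 0.867)), mean(c(0.781, 0.622, 0.867)))
  expect_equal(mean_agreement(0.5), 0.5)
  expect_equal(mean_agreement(c(0.7, 0.7, 0.7)), 0.7)
  expect_error(mean_agreement(numeric(0)), "no scores")
})
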