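drug_sel <- selector(subcategory = "drug-related")

test_that("time_on deduplicates overlap within a slice", {
  d0 <- observation_dataset(make_session(),
                            make_record("r1", start_s = 0, end_s = 600))
  expect_equal(time_on(d0, selector(what = "Movement")), 0)
  expect_equal(time_on(d0, drug_sel), 600)

  recs <- rbind(make_record("r1", start_s = 0, end_s = 600),
                make_record("r2", start_s = 300, end_s = 900))
  d <- observation_dataset(make_session(), recs)
  expect_equal(time_on(d, drug_sel), 900)  # not 1200
  # per-second oracle agrees
  expect_equal(time_on(d, drug_sel),
               oracle_union_length(cbind(as.numeric(recs$start), as.numeric(recs$end))))
})

test_that("time is never double counted across sessions at the same wall clock", {
  # two physicians observed simultaneously: their hours both count
  s <- rbind(make_session("S1", "P1"), make_session("S2", "P2"))
  recs <- rbind(make_record("r1", "S1", start_s = 0, end_s = 600),
                make_record("r2", "S2", start_s = 0, end_s = 600))
  d <- observation_dataset(s, recs)
  expect_equal(time_on(d, drug_sel), 1200)
  expect_equal(total_observation_hours(d), 4)
})

test_that("proportion_of_time uses session time or slice-specific denominators", {
  s <- make_session(hours = 1)
  d <- observation_dataset(s, make_record("r1", start_s = 0, end_s = 1800))
  p <- proportion_of_time(d, drug_sel)
  expect_equal(p$proportion, 0.5)
  expect_equal(p$as_percent, 50)
  expect_equal(p$minutes_per_hour, 30)

  # numerator slice == denominator slice -> exactly 1
  p1 <- proportion_of_time(d, drug_sel, denominator = drug_sel)
  expect_equal(p1$proportion, 1.0)

  # numerator restricted to the denominator slice via intersection
  recs <- rbind(
    make_record("a", subcategory = "drug-related", start_s = 0, end_s = 600),
    make_record("b", what = "Gather information", subcategory = "non-drug-related",
                start_s = 300, end_s = 1200)
  )
  d2 <- observation_dataset(make_session(hours = 1), recs)
  p2 <- proportion_of_time(d2, selector(what = "Gather information"),
                           denominator = drug_sel)
  expect_equal(p2$proportion, 300 / 600)
  expect_error(proportion_of_time(d2, drug_sel, denominator = selector(what = "Hygiene")),
               "zero")
})

test_that("single-slice proportions stay within [0, 1] on random data", {
  d <- small_synthetic(n_phys = 5, seed = 21)
  for (sel in list(drug_sel, selector(what = "Documentation"), selector())) {
    p <- proportion_of_time(d, sel)
    expect_gte(p$proportion, 0)
    expect_lte(p$proportion, 1)
  }
})

test_that("multitask_fraction counts concurrent seconds within the slice", {
  # no overlap -> 0
  d0 <- observation_dataset(make_session(), rbind(
    make_record("a", start_s = 0, end_s = 100),
    make_record("b", start_s = 100, end_s = 200)))
  expect_equal(multitask_fraction(d0, drug_sel)$proportion, 0)

  # matching task fully nested inside a non-matching one -> 1
  d1 <- observation_dataset(make_session(), rbind(
    make_record("a", start_s = 0, end_s = 1000, what = "Gather information",
                subcategory = "non-drug-related"),
    make_record("b", start_s = 200, end_s = 400)))
  expect_equal(multitask_fraction(d1, drug_sel)$proportion, 1)
  expect_error(multitask_fraction(d1, selector(what = "Hygiene")), "zero")

  # random sessions vs the per-second oracle
  for (seed in 1:4) {
    d <- small_synthetic(n_phys = 2, seed = 100 + seed)
    got <- multitask_fraction(d, drug_sel)
    num <- 0; den <- 0
    for (sid in d$sessions$session_id) {
      r <- d$records[d$records$session_id == sid, ]
      srow <- d$sessions[d$sessions$session_id == sid, ]
      lo <- as.numeric(srow$session_start); hi <- as.numeric(srow$session_end)
      counts <- oracle_concurrency_counts(cbind(as.numeric(r$start), as.numeric(r$end)), lo, hi)
      rs <- r[r$subcategory == "drug-related", ]
      sel_cov <- oracle_seconds_covered(cbind(as.numeric(rs$start), as.numeric(rs$end)), lo, hi)
      num <- num + sum(sel_cov & counts >= 2)
      den <- den + sum(sel_cov)
    }
    expect_equal(got$numerator_seconds, num)
    expect_equal(got$denominator_seconds, den)
  }
})

test_that("interruption rates count events over the right exposure", {
  d <- tiny_dataset()
  r_all <- interruption_rate(d)
  expect_equal(r_all$event_count, 1L)
  expect_equal(r_all$exposure_hours, 2)
  expect_equal(r_all$rate_per_hour, 0.5)
  # conservation: overall count equals the number of interruption records
  expect_equal(r_all$event_count, sum(d$records$is_interruption))

  # the interruption starts at 120 s, inside drug-related documentation r1
  r_drug <- interruption_rate(d, drug_sel)
  expect_equal(r_drug$event_count, 1L)
  expect_equal(r_drug$exposure_hours, 600 / 3600)
  # ... but not inside any Gather information task
  r_gi <- interruption_rate(d, selector(what = "Gather information"))
  expect_equal(r_gi$event_count, 0L)

  d0 <- observation_dataset(make_session(), make_record("r1", start_s = 0, end_s = 600))
  expect_equal(interruption_rate(d0)$rate_per_hour, 0)
  expect_error(interruption_rate(d0, selector(what = "Hygiene")), "zero exposure")

  # an interruption does not qualify itself into a slice: here the
  # interrupter is itself drug-related professional communication but no
  # *other* drug-related task is active at its start
  recs <- rbind(
    make_record("t", what = "Gather information", subcategory = "non-drug-related",
                start_s = 0, end_s = 600),
    make_record("i", what = "Professional communication", subcategory = "drug-related",
                who = "Nurse", how = "Direct", start_s = 100, end_s = 160,
                is_interruption = TRUE, interrupts = "t"))
  d2 <- observation_dataset(make_session(), recs)
  expect_equal(interruption_rate(d2, drug_sel)$event_count, 0L)
  expect_equal(interruption_rate(d2, selector(subcategory = "non-drug-related"))$event_count, 1L)
})

test_that("fraction of tasks interrupted is instance based", {
  d <- tiny_dataset()
  expect_equal(fraction_tasks_interrupted(d, selector(what = "Gather information"))$proportion, 0)
  expect_equal(fraction_tasks_interrupted(d, drug_sel)$proportion, 1)
  expect_error(fraction_tasks_interrupted(d, selector(what = "Hygiene")), "no records")

  # 9 drug-related documentation tasks, 5 interrupted -> 5/9 = 55.6%
  base_tasks <- do.call(rbind, lapply(1:9, function(i) {
    make_record(sprintf("doc%d", i), start_s = (i - 1) * 400, end_s = (i - 1) * 400 + 300)
  }))
  ints <- do.call(rbind, lapply(1:5, function(i) {
    make_record(sprintf("int%d", i), what = "Professional communication",
                subcategory = "non-drug-related", who = "Nurse", how = "Direct",
                start_s = (i - 1) * 400 + 50, end_s = (i - 1) * 400 + 80,
                is_interruption = TRUE, interrupts = sprintf("doc%d", i))
  }))
  d9 <- observation_dataset(make_session(), rbind(base_tasks, ints))
  f <- fraction_tasks_interrupted(d9, selector(what = "Documentation",
                                               subcategory = "drug-related",
                                               include_interruptions = FALSE))
  expect_equal(f$proportion, 5 / 9)
  expect_equal(round_half_up(f$as_percent, 1), 55.6)
})

test_that("interruption reason breakdown tallies the interrupters' categories", {
  # 40 interruptions of drug-related documentation; 33 are professional
  # communication -> 82.5%
  target <- make_record("tgt", start_s = 0, end_s = 7000)
  whats <- c(rep("Professional communication", 33), rep("Movement", 7))
  subs <- ifelse(whats == "Movement", "none", "non-drug-related")
  hows <- ifelse(whats == "Movement", "none", "Direct")
  ints <- do.call(rbind, lapply(1:40, function(i) {
    make_record(sprintf("i%02d", i), what = whats[i], subcategory = subs[i],
                who = "none", how = hows[i], start_s = 10 + i * 100,
                end_s = 40 + i * 100, is_interruption = TRUE, interrupts = "tgt")
  }))
  d <- observation_dataset(make_session(), rbind(target, ints))
  br <- interruption_reason_breakdown(d, selector(what = "Documentation",
                                                  subcategory = "drug-related"))
  expect_equal(br[["Professional communication"]], 0.825)
  expect_equal(sum(br), 1)
  expect_error(interruption_reason_breakdown(d, selector(what = "Hygiene")),
               "no interruptions")

  # single-category case
  d1 <- tiny_dataset()
  br1 <- interruption_reason_breakdown(d1, drug_sel)
  expect_equal(br1, c("Professional communication" = 1))
})

test_that("minutes_per_hour is proportion * 60 with domain checks", {
  expect_equal(minutes_per_hour(0), 0)
  expect_equal(minutes_per_hour(0.129), 7.74)
  expect_equal(minutes_per_hour(0.143), 8.58)
  expect_equal(round_half_up(minutes_per_hour(0.143), 1), 8.6)
  expect_error(minutes_per_hour(1.2), "0, 1")
  expect_error(minutes_per_hour(-0.1), "0, 1")
})

test_that("patients_per_session means are additive", {
  s <- rbind(make_session("S1", "P1", n_new = 2L, n_follow = 1L),
             make_session("S2", "P2", n_new = 2L, n_follow = 0L),
             make_session("S3", "P3", n_new = 2L, n_follow = 1L))
  d <- observation_dataset(s, data.frame())
  m <- patients_per_session(d)
  expect_equal(unname(m), c(8 / 3, 2, 2 / 3))
  expect_equal(m[["mean_total"]], m[["mean_new"]] + m[["mean_followup"]])

  d0 <- observation_dataset(make_session(n_new = 0L, n_follow = 0L), data.frame())
  expect_equal(unname(patients_per_session(d0)), c(0, 0, 0))
})

test_that("category proportions sum to 1 + cross-category overlap share", {
  d <- small_synthetic(n_phys = 4, seed = 31)
  slices <- table_what_slices()
  total_secs <- total_observation_hours(d) * 3600
  slice_sum <- sum(vapply(slices, function(s) time_on(d, s), numeric(1)))
  # per-second accounting: overlap = multiply-counted seconds
  raw_covered <- 0; overlap_extra <- 0
  for (sid in d$sessions$session_id) {
    r <- d$records[d$records$session_id == sid, ]
    srow <- d$sessions[d$sessions$session_id == sid, ]
    lo <- as.numeric(srow$session_start); hi <- as.numeric(srow$session_end)
    # count each second once per slice it belongs to
    per_slice <- vapply(slices, function(s) {
      keep <- matches_selector(d, s) & d$records$session_id == sid
      rs <- d$records[keep, ]
      sum(oracle_seconds_covered(cbind(as.numeric(rs$start), as.numeric(rs$end)), lo, hi))
    }, numeric(1))
    raw_covered <- raw_covered + sum(per_slice)
  }
  expect_equal(slice_sum, raw_covered)
  # slices partition the record set, so the sum can exceed the session time
  # only through multitasking
  expect_gte(slice_sum / total_secs, time_on(d, selector()) / total_secs)
})
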