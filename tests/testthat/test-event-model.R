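test_that("a small event log round-trips through CSV and JSON", {
  d <- tiny_dataset()
  expect_equal(nrow(d$sessions), 1L)
  expect_equal(nrow(d$records), 3L)

  tmp <- withr::local_tempdir()
  rec_csv <- file.path(tmp, "records.csv")
  ses_csv <- file.path(tmp, "sessions.csv")
  js <- file.path(tmp, "log.json")

  write_event_log(d, rec_csv, ses_csv)
  d_csv <- read_event_log(rec_csv, ses_csv)
  expect_equal(d_csv$sessions, d$sessions)
  expect_equal(d_csv$records, d$records)

  # transitive: dataset -> JSON -> dataset -> CSV -> dataset
  write_event_log(d, js)
  d_json <- read_event_log(js)
  expect_equal(d_json$records, d$records)
  write_event_log(d_json, rec_csv, ses_csv)
  d_back <- read_event_log(rec_csv, ses_csv)
  expect_equal(d_back$sessions, d$sessions)
  expect_equal(d_back$records, d$records)
})

test_that("every enum label survives a round trip verbatim", {
  n <- max(length(what_categories()), length(how_categories()), length(who_categories()))
  subcat_for <- function(what) {
    if (what %in% c("Gather information", "Documentation", "Professional communication")) {
      "drug-related"
    } else if (what == "Social") "professional" else "none"
  }
  whats <- rep_len(what_categories(), n)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(sprintf("r%02d", i), what = whats[i],
                subcategory = subcat_for(whats[i]),
                how = rep_len(how_categories(), n)[i],
                who = rep_len(who_categories(), n)[i],
                start_s = (i - 1) * 60, end_s = i * 60)
  }))
  d <- observation_dataset(make_session(), recs)
  tmp <- withr::local_tempdir()
  write_event_log(d, file.path(tmp, "r.csv"), file.path(tmp, "s.csv"))
  back <- read_event_log(file.path(tmp, "r.csv"), file.path(tmp, "s.csv"))
  expect_identical(back$records$what, d$records$what)
  expect_identical(back$records$how, d$records$how)
  expect_identical(back$records$who, d$records$who)
  expect_identical(back$records$subcategory, d$records$subcategory)
})

test_that("random generated datasets round-trip field-by-field", {
  for (seed in 1:3) {
    d <- small_synthetic(n_phys = 3, seed = seed)
    tmp <- withr::local_tempdir()
    write_event_log(d, file.path(tmp, "r.csv"), file.path(tmp, "s.csv"))
    back <- read_event_log(file.path(tmp, "r.csv"), file.path(tmp, "s.csv"))
    expect_equal(back$sessions, d$sessions)
    expect_equal(back$records, d$records)
    write_event_log(d, file.path(tmp, "d.json"))
    back2 <- read_event_log(file.path(tmp, "d.json"))
    expect_equal(back2$records, d$records)
  }
})

test_that("the shipped example log parses to the expected dataset", {
  d <- read_event_log(system.file("extdata", "example_records.csv", package = "timemotion"),
                      system.file("extdata", "example_sessions.csv", package = "timemotion"))
  expect_equal(nrow(d$sessions), 1L)
  expect_equal(nrow(d$records), 3L)
  expect_equal(sum(d$records$is_interruption), 1L)
  expect_equal(time_on(d, selector(subcategory = "drug-related")), 600)
  expect_equal(total_observation_hours(d), 2)
})

test_that("an empty record table is a valid dataset with zero task time", {
  d <- observation_dataset(make_session(), data.frame())
  expect_equal(nrow(d$records), 0L)
  expect_equal(time_on(d, selector()), 0)
  expect_equal(total_observation_hours(d), 2)
})

test_that("malformed files raise parse errors naming the problem", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.csv")
  writeLines("record_id,session_id,what", bad)
  ses <- file.path(tmp, "s.csv")
  write_event_log(tiny_dataset(), file.path(tmp, "r.csv"), ses)
  expect_error(read_event_log(bad, ses), "missing column")
  expect_error(read_event_log(file.path(tmp, "nope.csv"), ses), "not found")
})

test_that("validation reports every broken invariant with the offending id", {
  # drug-related subcategory under a category without the drug split
  recs <- rbind(
    make_record("ok1", start_s = 0, end_s = 60),
    make_record("bad_sub", what = "Hygiene", subcategory = "drug-related",
                how = "none", start_s = 100, end_s = 160),
    # interruption starting outside its target's interval
    make_record("tgt", what = "Gather information", subcategory = "non-drug-related",
                start_s = 200, end_s = 260),
    make_record("bad_int", what = "Professional communication",
                subcategory = "non-drug-related", who = "Nurse", how = "Direct",
                start_s = 300, end_s = 330, is_interruption = TRUE, interrupts = "tgt"),
    make_record("bad_link", what = "Professional communication",
                subcategory = "non-drug-related", who = "Nurse", how = "Direct",
                start_s = 400, end_s = 430, is_interruption = TRUE,
                interrupts = "ghost")
  )
  d <- observation_dataset(make_session(), recs, check = FALSE)
  rep <- validate_dataset(d)
  expect_setequal(rep$id[rep$rule == "subcategory_rule"], "bad_sub")
  expect_setequal(rep$id[rep$rule == "interruption_link"], c("bad_int", "bad_link"))
  expect_error(observation_dataset(make_session(), recs), "violation")

  # a clean generated dataset validates
  expect_equal(nrow(validate_dataset(small_synthetic(seed = 5))), 0L)

  # three sessions for one physician
  s3 <- rbind(make_session("A", "P9"), make_session("B", "P9", start = BASE + 86400),
              make_session("C", "P9", start = BASE + 2 * 86400))
  rep <- validate_dataset(observation_dataset(s3, data.frame(), check = FALSE))
  expect_true("max_two_sessions" %in% rep$rule)
})

test_that("selector filtering matches a brute-force row scan and composes", {
  d <- small_synthetic(n_phys = 4, seed = 11)
  sel <- selector(what = "Documentation", subcategory = "drug-related",
                  how = "On computer")
  got <- filter_records(d, sel)$records
  r <- d$records
  want <- r[r$what == "Documentation" & r$subcategory == "drug-related" &
            r$how == "On computer", ]
  expect_equal(got$record_id, want$record_id)
  expect_identical(filter_records(d, selector())$records, d$records)  # identity

  # conjunction: filter(filter(d, s1), s2) == filter(d, s1 AND s2)
  s1 <- selector(what = c("Documentation", "Gather information"))
  s2 <- selector(subcategory = "drug-related")
  expect_equal(filter_records(filter_records(d, s1), s2)$records,
               filter_records(d, selector_and(s1, s2))$records)
  # sessions are untouched by record filtering
  expect_identical(filter_records(d, s2)$sessions, d$sessions)
})

test_that("counting a fixture slice works", {
  recs <- rbind(
    make_record("a", subcategory = "drug-related", start_s = 0, end_s = 50),
    make_record("b", subcategory = "drug-related", start_s = 60, end_s = 100),
    make_record("c", subcategory = "non-drug-related", start_s = 110, end_s = 150),
    make_record("d", what = "Movement", subcategory = "none", how = "none",
                start_s = 160, end_s = 200),
    make_record("e", what = "Hygiene", subcategory = "none", how = "none",
                start_s = 210, end_s = 230)
  )
  d <- observation_dataset(make_session(), recs)
  expect_equal(nrow(filter_records(d, selector(subcategory = "drug-related"))$records), 2L)
})

test_that("group subsetting drops sessions and their records", {
  d <- generate_dataset(generator_config(n_physicians = 12, n_second_sessions = 4,
                                         session_hours = 0.25, seed = 2))
  med <- subset_sessions(d, affiliation = "Medical")
  expect_true(all(med$sessions$affiliation == "Medical"))
  expect_true(all(med$records$session_id %in% med$sessions$session_id))
  expect_equal(nrow(med$sessions) + nrow(subset_sessions(d, affiliation = "Surgical")$sessions),
               nrow(d$sessions))
})
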