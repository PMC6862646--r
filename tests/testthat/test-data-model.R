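# Survey record IO, validation, and outcome harmonization.

test_that("a well-formed file reads back completely and round-trips", {
  df <- tiny_records(10)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  ds <- read_records(f)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$records), 10)
  expect_equal(nrow(attr(ds, "rejected")), 0)

  # write-then-read yields an identical dataset field by field
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(ds, f2)
  ds2 <- read_records(f2)
  expect_equal(ds2$records, ds$records)
  expect_equal(ds2$years, ds$years)
})

test_that("rows violating record invariants are rejected with diagnostics", {
  df <- tiny_records(10)
  df$age_girl[3] <- 17
  df$weight[7] <- -1
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  ds <- read_records(f)
  expect_equal(nrow(ds$records), 8)
  rej <- attr(ds, "rejected")
  expect_setequal(rej$row, c(3, 7))
  expect_match(rej$rule[rej$row == 3], "age_girl")
  expect_match(rej$rule[rej$row == 7], "weight")
})

test_that("schema mapping renames columns and errors on absent ones", {
  df <- tiny_records(5)
  names(df)[names(df) == "y"] <- "daughter_cut"
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_error(read_records(f), "absent")
  ds <- read_records(f, schema = c(y = "daughter_cut"))
  expect_equal(nrow(ds$records), 5)
  expect_error(read_records(f, schema = c(nope = "daughter_cut")),
               "unknown canonical")
})

test_that("attitude fields may be missing only in flagged years", {
  df <- tiny_records(6, year = 2003L)
  df$mother_supports_continuation <- NA_integer_
  df$mother_believes_religious_obligation <- NA_integer_
  ds <- as_survey_dataset(df)
  expect_equal(nrow(ds$records), 6)

  df14 <- tiny_records(6, year = 2014L)
  df14$mother_supports_continuation[1:2] <- NA_integer_
  ds14 <- as_survey_dataset(df14)
  expect_equal(nrow(ds14$records), 4)
  expect_true(all(grepl("attitude-flagged",
                        attr(ds14, "rejected")$rule)))
})

test_that("non-integer ages are floored with a warning", {
  df <- tiny_records(4)
  df$age_girl[2] <- 3.7
  expect_warning(ds <- as_survey_dataset(df), "floored")
  expect_equal(ds$records$age_girl[2], 3)
})

test_that("outcome rules default by wave and accept overrides", {
  r <- outcome_rules(c(1998, 2003, 2008, 2014, 2020))
  expect_equal(unname(r[c("1998", "2003")]),
               rep("ELDEST_DAUGHTER", 2))
  expect_equal(unname(r["2008"]), "MOST_RECENTLY_CUT_DAUGHTER")
  expect_equal(unname(r[c("2014", "2020")]), rep("ALL_DAUGHTERS", 2))
  r2 <- outcome_rules(2008, overrides = c("2008" = "ALL_DAUGHTERS"))
  expect_equal(unname(r2["2008"]), "ALL_DAUGHTERS")
  expect_error(outcome_rules(2008, overrides = c("2008" = "bogus")),
               "unknown outcome rule")
})

test_that("harmonize_outcome implements the year-specific rules", {
  rows <- data.frame(
    mother_id = c("m1", "m1", "m1", "m2"),
    survey_year = 1998L,
    age_girl = c(12, 7, 3, 5),
    cut = c(1L, 0L, 0L, 0L))

  # eldest-daughter rule: one record per mother, eldest's status
  eld <- harmonize_outcome(rows, "ELDEST_DAUGHTER")
  expect_equal(nrow(eld), 2)
  expect_equal(eld$y[eld$mother_id == "m1"], 1L)
  expect_equal(eld$age_girl[eld$mother_id == "m1"], 12)

  # all-daughters rule: one record per daughter, y = cut status
  all14 <- rows; all14$survey_year <- 2014L
  all_out <- harmonize_outcome(all14, "ALL_DAUGHTERS")
  expect_equal(all_out$y, c(1L, 0L, 0L, 0L))

  # most-recently-cut rule picks a cut daughter when one exists,
  # else the eldest uncut
  mrc <- rows; mrc$survey_year <- 2008L
  mrc$cut_recency <- c(2, 0, 0, 0)
  out <- harmonize_outcome(mrc, "MOST_RECENTLY_CUT_DAUGHTER")
  expect_equal(nrow(out), 2)
  expect_equal(out$y[out$mother_id == "m1"], 1L)
  expect_equal(out$y[out$mother_id == "m2"], 0L)

  # zero eligible daughters -> zero records
  empty <- rows[0, ]
  expect_equal(nrow(harmonize_outcome(empty, "ALL_DAUGHTERS")), 0)

  # daughter age outside 0..14 is an error
  bad <- rows; bad$age_girl[1] <- 16
  expect_error(harmonize_outcome(bad, "ELDEST_DAUGHTER"), "0..14")
})

test_that("harmonization is idempotent and respects count bounds", {
  set.seed(42)
  n_m <- 30
  rows <- do.call(rbind, lapply(seq_len(n_m), function(m) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(mother_id = sprintf("m%02d", m), survey_year = 1998L,
               age_girl = sample(0:14, k, replace = TRUE),
               cut = rbinom(k, 1, 0.3))
  }))
  eld <- harmonize_outcome(rows, "ELDEST_DAUGHTER")
  expect_lte(nrow(eld), n_m)
  expect_equal(nrow(harmonize_outcome(rows, "ALL_DAUGHTERS")), nrow(rows))
  # idempotence on already-harmonized records
  again <- harmonize_outcome(eld, "ELDEST_DAUGHTER")
  expect_equal(again[names(eld)], eld)
})

test_that("validate_dataset reports counts, missingness, unknown regions", {
  g <- path3_graph()
  ds <- tiny_dataset(8, regions = c("A", "B"))
  rep1 <- validate_dataset(ds, g)
  expect_length(rep1$unknown_regions, 0)
  expect_equal(sum(rep1$counts$n), 16)

  ds$records$region_id[1] <- "Zed"
  rep2 <- validate_dataset(ds, g)
  expect_equal(rep2$unknown_regions, "Zed")
})

test_that("generated data validate cleanly with configured counts", {
  sim <- simulate_survey(small_config(seed = 3))
  g <- kenya_region_graph()
  expect_equal(nrow(attr(sim$dataset, "rejected")), 0)
  rep <- validate_dataset(sim$dataset, g)
  expect_length(rep$unknown_regions, 0)
  # single-wave config: every record carries that wave's year
  expect_equal(unique(sim$dataset$records$survey_year), 2014L)
})
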