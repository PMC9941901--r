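# Lookback counts, diagnosis flags, banding, covariate assembly.

test_that("lookback window is half-open (index-1y, index]", {
  idx <- as.Date("2013-06-01")
  enc <- data.frame(date = c(idx - 10, idx - 400, idx, idx - 365),
                    channel = c("MD", "MD", "TC", "NPPA"))
  rx <- data.frame(date = idx - 30, atc_code = "A",
                   schedule_class = "prescription")
  out <- lookback_counts(enc, rx, idx)
  # idx - 400 is outside; idx itself counts (closed right end); idx - 365
  # lands exactly on the exclusive left bound 2012-06-01 and is excluded
  expect_equal(unname(out), c(1, 0, 1, 1))
})

test_that("distinct medications dedupe ATC and drop excluded schedules", {
  idx <- as.Date("2013-06-01")
  rx <- data.frame(date = rep(idx - 5, 3), atc_code = c("A", "A", "B"),
                   schedule_class = c("prescription", "prescription", "OTC"))
  out <- lookback_counts(data.frame(date = as.Date(character()),
                                    channel = character()), rx, idx)
  expect_equal(unname(out[["distinct_meds"]]), 1)
  empty <- lookback_counts(data.frame(date = as.Date(character()),
                                      channel = character()),
                           data.frame(date = as.Date(character()),
                                      atc_code = character()), idx)
  expect_equal(unname(empty), c(0, 0, 0, 0))
})

test_that("lookback counts are additive over disjoint record sets", {
  idx <- as.Date("2014-01-15")
  set.seed(42)
  enc <- data.frame(
    date = idx - sample(0:700, 40, TRUE),
    channel = sample(c("MD", "NPPA", "TC"), 40, TRUE))
  rx0 <- data.frame(date = as.Date(character()), atc_code = character(),
                    schedule_class = character())
  split1 <- enc[1:25, ]; split2 <- enc[26:40, ]
  expect_equal(
    lookback_counts(enc, rx0, idx)[1:3],
    lookback_counts(split1, rx0, idx)[1:3] +
      lookback_counts(split2, rx0, idx)[1:3])
})

test_that("undated records are a hard error", {
  idx <- as.Date("2013-06-01")
  enc <- data.frame(date = as.Date(c("2013-01-01", NA)), channel = "MD")
  expect_error(lookback_counts(enc, data.frame(date = as.Date(character()),
                                               atc_code = character()), idx),
               "undated")
})

test_that("diagnosis flags are inclusive of the index date", {
  pat <- tiny_patients()[1]
  expect_true(diagnosis_flags(pat, as.Date("2012-05-01"))[["dm"]])
  expect_false(diagnosis_flags(pat, as.Date("2012-04-30"))[["dm"]])
  expect_false(diagnosis_flags(pat, as.Date("2012-05-01"))[["cad"]])
})

test_that("categorize bands partition the nonnegative integers", {
  expect_equal(as.character(categorize(4, "md")), "3-5")
  expect_equal(as.character(categorize(0, "tc")), "0")
  expect_equal(as.character(categorize(11, "meds")), ">=11")
  expect_equal(as.character(categorize(3, "nppa")), ">=3")
  for (scheme in c("md", "nppa", "tc", "meds")) {
    bands <- categorize(0:30, scheme)
    expect_false(anyNA(bands))
    expect_true(all(table(bands) > 0))
  }
  expect_error(categorize(-1, "md"), "nonnegative")
})

test_that("covariate assembly matches a hand-computed fixture", {
  b <- tiny_bundle()
  co <- build_cohort(b)
  cv <- build_covariates(rbind(co$portal, co$control), co$patients,
                         b$encounters, b$prescriptions)
  a01 <- cv[patient_id == "A01"]
  # A01 index 2012-05-01: encounters 2012-04-21 (MD), 2011-03-27 (outside),
  # 2012-05-01 TC (index day, inside); meds: C09AA02 twice + OTC -> 1
  expect_equal(a01$md_visits_12m, 1L)
  expect_equal(a01$tc_calls_12m, 1L)
  expect_equal(a01$nppa_visits_12m, 0L)
  expect_equal(a01$distinct_meds, 1L)
  expect_true(a01$dx_dm); expect_false(a01$dx_htn)
  expect_equal(a01$age_years,
               as.numeric(lubridate::interval(
                 as.Date("1970-06-15"), as.Date("2012-05-01")) /
                   lubridate::years(1)))
  # A04 control person-year 2014: one MD and one NPPA encounter in window
  a04_2014 <- cv[patient_id == "A04" & index_year == 2014]
  expect_equal(a04_2014$md_visits_12m, 1L)
  expect_equal(a04_2014$nppa_visits_12m, 1L)
  expect_true(a04_2014$dx_cad && a04_2014$dx_htn)
  # zero-history control year
  a04_2011 <- cv[patient_id == "A04" & index_year == 2011]
  expect_equal(a04_2011$md_visits_12m + a04_2011$nppa_visits_12m +
                 a04_2011$tc_calls_12m + a04_2011$distinct_meds, 0L)
})

test_that("covariate assembly is invariant to record order", {
  b <- tiny_bundle()
  co <- build_cohort(b)
  cv1 <- build_covariates(rbind(co$portal, co$control), co$patients,
                          b$encounters, b$prescriptions)
  b2 <- tiny_bundle()
  b2$encounters <- b2$encounters[rev(seq_len(nrow(b2$encounters)))]
  b2$prescriptions <- b2$prescriptions[rev(seq_len(nrow(b2$prescriptions)))]
  cv2 <- build_covariates(rbind(co$portal, co$control), co$patients,
                          b2$encounters, b2$prescriptions)
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))
})

test_that("age is exact at an 18th-birthday index date", {
  p <- tiny_patients()[4]
  rec <- data.table::data.table(
    patient_id = "A04", arm = "control",
    index_date = lubridate::add_with_rollback(p$birth_date,
                                              lubridate::years(18)),
    index_year = 1968L)
  cv <- build_covariates(rec, p,
                         data.frame(patient_id = character(),
                                    date = as.Date(character()),
                                    channel = character()),
                         data.frame(patient_id = character(),
                                    date = as.Date(character()),
                                    atc_code = character(),
                                    schedule_class = character()))
  expect_equal(cv$age_years, 18)
})

test_that("missing sex is a hard error", {
  b <- tiny_bundle()
  co <- build_cohort(b)
  co$patients$sex[2] <- NA
  expect_error(build_covariates(rbind(co$portal, co$control), co$patients,
                                b$encounters, b$prescriptions),
               "sex")
})
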