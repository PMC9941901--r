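# In-code fixtures: a hand-sized patients table and bundles built from it.

tiny_patients <- function() {
  data.table::data.table(
    patient_id = c("A01", "A02", "A03", "A04", "A05"),
    birth_date = as.Date(c("1970-06-15", "1985-01-01", "1994-05-01",
                           "1950-12-31", "2001-03-10")),
    sex = c("female", "male", "female", "male", "female"),
    rostered = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    obs_start = as.Date(c("2002-01-01", "2009-01-01", "2012-03-01",
                          "2002-01-01", "2002-01-01")),
    obs_end = as.Date(c("2019-12-31", "2019-12-31", "2016-09-30",
                        "2019-12-31", "2019-12-31")),
    portal_date = as.Date(c("2012-05-01", "2011-03-01", NA, NA, NA)),
    income_band = c(">100k", NA, "<40k", NA, NA),
    education_band = c("college", NA, NA, NA, NA),
    dx_cad_onset = as.Date(c(NA, NA, NA, "2005-06-01", NA)),
    dx_chf_onset = as.Date(rep(NA, 5)),
    dx_copd_onset = as.Date(rep(NA, 5)),
    dx_dm_onset = as.Date(c("2012-05-01", NA, NA, NA, NA)),
    dx_htn_onset = as.Date(c(NA, "2010-01-01", NA, "2003-04-01", NA))
  )
}

tiny_bundle <- function() {
  enc <- data.table::data.table(
    patient_id = c("A01", "A01", "A01", "A02", "A04", "A04"),
    date = as.Date(c("2012-04-21", "2011-03-27", "2012-05-01",
                     "2010-09-15", "2014-02-01", "2014-06-30")),
    channel = c("MD", "MD", "TC", "MD", "NPPA", "MD")
  )
  rx <- data.table::data.table(
    patient_id = c("A01", "A01", "A01", "A04"),
    date = as.Date(c("2012-01-10", "2012-02-11", "2011-12-01", "2014-03-01")),
    atc_code = c("C09AA02", "C09AA02", "N02BE01", "C10AA01"),
    schedule_class = c("prescription", "prescription", "OTC", "prescription")
  )
  msg <- data.table::data.table(
    provider_id = c("MD01", "MD01", "MD02"),
    patient_id = c("A01", "A01", "A02"),
    sent_date = as.Date(c("2019-02-01", "2019-08-15", "2019-03-03")),
    minutes = c(3, 4, 5)
  )
  structure(list(patients = tiny_patients(), encounters = enc,
                 prescriptions = rx, messages = msg, truth = NULL),
            class = "emr_bundle")
}

# Balanced noiseless panel whose counts sit exactly on the segmented mean.
zero_noise_panel <- function(coeffs, years = c(-5:-1, 2:6), n = 4) {
  grid <- data.table::CJ(arm = c("control", "portal"), pt = seq_len(n),
                         t = years)
  grid[, `:=`(
    patient_id = paste0(arm, pt),
    A = as.integer(arm == "portal"))]
  grid[, count := outcome_mean(coeffs, t, arm), by = arm]
  grid
}

# A midsize confounded synthetic bundle shared by matching and pipeline
# tests; memoised so the suite only pays generation once.
.shared_env <- new.env(parent = emptyenv())
shared_bundle <- function(n = 3000L, seed = 424L) {
  key <- sprintf("b_%d_%d", n, seed)
  if (is.null(.shared_env[[key]])) {
    .shared_env[[key]] <- generate_population(
      synth_config(n_patients = n, seed = seed))
  }
  .shared_env[[key]]
}
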