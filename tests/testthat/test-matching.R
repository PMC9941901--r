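# Propensity model, candidate sets, unique-first allocation, balance.

fake_cov <- function(n, arm, score_x, year = 2014L) {
  data.table::data.table(
    patient_id = sprintf("%s%03d", ifelse(arm == "portal", "P", "C"),
                         seq_len(n)),
    arm = arm, index_date = as.Date(sprintf("%d-07-01", year)),
    index_year = year, age_years = 40 + score_x, sex = "female",
    rostered = TRUE, dx_cad = FALSE, dx_chf = FALSE, dx_copd = FALSE,
    dx_dm = FALSE, dx_htn = FALSE, md_visits_12m = 0L, nppa_visits_12m = 0L,
    tc_calls_12m = 0L, distinct_meds = 0L)
}

test_that("single binary covariate recovers the table log odds ratio", {
  # 2x2 table: portal (exposed 30 / unexposed 20), control (10 / 40)
  cov <- data.table::data.table(
    patient_id = sprintf("X%03d", 1:100),
    arm = rep(c("portal", "control"), c(50, 50)),
    index_date = as.Date("2014-07-01"), index_year = 2014L,
    flag = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 20, 10, 40)))
  fit <- fit_propensity(cov, ps_covariates = "flag")
  lor <- log((30 / 20) / (10 / 40))
  expect_equal(unname(fit$coefficients["flagTRUE"]), lor, tolerance = 1e-6)
})

test_that("covariates independent of the label give flat scores", {
  set.seed(31)
  cov <- data.table::data.table(
    patient_id = sprintf("X%04d", 1:4000),
    arm = rep(c("portal", "control"), 2000),
    index_date = as.Date("2014-07-01"), index_year = 2014L,
    x = rnorm(4000))
  fit <- fit_propensity(cov, ps_covariates = "x")
  expect_lt(abs(mean(fit$ps) - 0.5), 3 * sqrt(0.25 / 4000))
  expect_lt(diff(range(fit$ps)), 0.2)
})

test_that("degenerate labels and perfect separation are rejected", {
  cov <- fake_cov(10, "portal", rnorm(10))
  expect_error(fit_propensity(cov), "both portal and control")
  cov2 <- rbind(fake_cov(10, "portal", 1:10 + 20), fake_cov(10, "control", 1:10))
  expect_error(fit_propensity(cov2, ps_covariates = "age_years"),
               "separation on covariate: age_years")
})

test_that("candidate sets respect caliper, date gap and one-per-control", {
  cov <- rbind(fake_cov(4, "portal", c(0, 0, 5, 0)),
               fake_cov(4, "control", c(0.01, -0.01, 5.01, 30)))
  # give one control a second, farther person-year record
  extra <- data.table::copy(cov[arm == "control"][1])
  extra[, `:=`(index_year = 2016L, index_date = as.Date("2016-07-01"),
               age_years = 40.3)]
  cov <- rbind(cov, extra)
  fit <- fit_propensity(cov, ps_covariates = "age_years")
  cand <- candidate_sets(fit, caliper_mult = 0.2, max_gap_days = 366)
  pairs <- cand$pairs
  expect_true(all(pairs$ps_distance <= cand$caliper_width))
  expect_true(all(pairs$gap_days <= 366))
  # the 2016 record of C001 is > 366 days from the 2014 portal dates
  expect_false(any(pairs$control_index_year == 2016))
  expect_lte(max(pairs[, .N, by = .(portal_id, control_id)]$N), 1L)
})

test_that("closest person-year record is retained per control patient", {
  portal <- fake_cov(1, "portal", 0, year = 2013L)
  c_a <- fake_cov(1, "control", 0.05, year = 2013L)
  c_b <- data.table::copy(c_a)
  c_b[, `:=`(index_year = 2014L, index_date = as.Date("2014-07-01"),
             age_years = 40.2)]
  # pad with neutral records so the score SD is nonzero
  pad <- rbind(fake_cov(20, "portal", rnorm(20, 0, 2), 2013L),
               fake_cov(20, "control", rnorm(20, 0, 2), 2014L))
  pad[, patient_id := paste0(patient_id, "pad")]
  cov <- rbind(portal, c_a, c_b, pad)
  fit <- fit_propensity(cov, ps_covariates = "age_years")
  pairs <- candidate_sets(fit, max_gap_days = 366)$pairs
  hit <- pairs[portal_id == "P001" & control_id == "C001"]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$control_index_year, 2013L)
})

test_that("unique-first allocation traces the stated examples", {
  mk <- function(df) list(pairs = data.table::as.data.table(df),
                          portal_ids = unique(df$portal_id))
  # P1 -> {C1}, P2 -> {C1, C2}: P1 takes its unique C1, P2 falls to C2
  m <- allocate_matches(mk(data.frame(
    portal_id = c("P1", "P2", "P2"), control_id = c("C1", "C1", "C2"),
    control_index_year = 2014L, ps_distance = c(0.01, 0.001, 0.3),
    gap_days = 0L)))
  expect_equal(m[order(portal_id)]$control_id, c("C1", "C2"))
  # P1 -> {C1, C2}, P2 -> {C2}: rule 1 fires on P2 first
  m2 <- allocate_matches(mk(data.frame(
    portal_id = c("P1", "P1", "P2"), control_id = c("C1", "C2", "C2"),
    control_index_year = 2014L, ps_distance = c(0.3, 0.001, 0.2),
    gap_days = 0L)))
  expect_equal(m2[order(portal_id)]$control_id, c("C1", "C2"))
  # empty candidate set: unmatched, not an error
  m3 <- allocate_matches(list(pairs = data.frame(
    portal_id = character(), control_id = character(),
    control_index_year = integer(), ps_distance = numeric(),
    gap_days = integer()), portal_ids = "P9"))
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "unmatched_portal"), "P9")
})

test_that("allocation is invariant to input row order", {
  set.seed(77)
  n <- 60
  pairs <- data.table::data.table(
    portal_id = sprintf("P%02d", sample(1:25, n, TRUE)),
    control_id = sprintf("C%02d", sample(1:25, n, TRUE)),
    control_index_year = sample(2011:2015, n, TRUE),
    ps_distance = round(runif(n), 3), gap_days = sample(0:300, n, TRUE))
  pairs <- unique(pairs, by = c("portal_id", "control_id"))
  ref <- allocate_matches(list(pairs = pairs))
  for (k in 1:5) {
    perm <- pairs[sample(nrow(pairs))]
    out <- allocate_matches(list(pairs = perm))
    expect_equal(as.data.frame(out), as.data.frame(ref))
  }
})

test_that("no patient is matched twice and constraints hold post hoc", {
  b <- shared_bundle()
  co <- build_cohort(b)
  cv <- build_covariates(rbind(co$portal, co$control), co$patients,
                         b$encounters, b$prescriptions)
  res <- match_cohort(cv)
  m <- res$matches
  expect_gt(nrow(m), 100)
  expect_equal(anyDuplicated(m$portal_id), 0L)
  expect_equal(anyDuplicated(m$control_id), 0L)
  expect_true(all(m$ps_distance <= res$candidates$caliper_width))
  expect_true(all(m$gap_days <= 366))
  # re-check the date gap from raw cohort tables
  chk <- merge(m, co$portal[, .(portal_id = patient_id, p_date = index_date)],
               by = "portal_id")
  chk <- merge(chk, co$control[, .(control_id = patient_id,
                                   control_index_year = index_year,
                                   c_date = index_date)],
               by = c("control_id", "control_index_year"))
  expect_true(all(abs(as.integer(chk$p_date - chk$c_date)) <= 366))
})

test_that("standardized differences reproduce the published arithmetic", {
  expect_equal(round(standardized_difference(0.598, 0.490, "binary"), 2),
               0.22)
  expect_equal(round(standardized_difference(0.988, 0.945, "binary"), 2),
               0.24)
  expect_equal(standardized_difference(c(1.5, 0.3), c(1.5, 0.3),
                                       "continuous"), 0)
  expect_equal(standardized_difference(c(2, 0), c(2, 0), "continuous"), 0)
  expect_error(standardized_difference(1.2, 0.5, "binary"), "\\[0, 1\\]")
})

test_that("matching improves balance below 0.1 on confounded data", {
  b <- shared_bundle()
  co <- build_cohort(b)
  cv <- build_covariates(rbind(co$portal, co$control), co$patients,
                         b$encounters, b$prescriptions)
  res <- match_cohort(cv)
  tab <- res$balance$table
  confounded <- c("sex", "rostered")  # strongest generative effects
  for (v in confounded) {
    pre <- tab[covariate == v & phase == "pre", std_diff]
    post <- tab[covariate == v & phase == "post", std_diff]
    expect_lt(post, pre + 1e-9)
  }
  # at this reduced n (~1400/arm) assert the propensity-driving covariates;
  # the full < 0.1 invariant at n >= 2000/arm runs in the acceptance suite
  driving <- c("age_years", "sex", "rostered", "dx_cad", "dx_chf",
               "dx_copd", "dx_dm", "dx_htn", "ps")
  expect_true(all(tab[phase == "post" & covariate %in% driving,
                      std_diff] < 0.1))
})

test_that("pooled quintile groups split matched records evenly", {
  b <- shared_bundle()
  co <- build_cohort(b)
  cv <- build_covariates(rbind(co$portal, co$control), co$patients,
                         b$encounters, b$prescriptions)
  res <- match_cohort(cv)
  q <- res$balance$quintiles[, .(n = sum(N)), by = ps_group]
  expect_equal(nrow(q), 5L)
  expect_true(all(abs(q$n - sum(q$n) / 5) <= 1 + sum(q$n) * 0.01))
})
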