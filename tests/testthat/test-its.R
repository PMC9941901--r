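# Person-year panel construction and the segmented ITS fit.

test_that("panel rows are the fully observed 12-month spans", {
  idx <- as.Date("2012-05-01")
  pats <- data.table::data.table(
    patient_id = "B1", birth_date = as.Date("1970-01-01"), sex = "male",
    rostered = TRUE,
    obs_start = lubridate::add_with_rollback(idx, lubridate::years(-2)),
    obs_end = lubridate::add_with_rollback(idx, lubridate::years(2)),
    portal_date = idx)
  ctrl <- data.table::copy(pats)
  ctrl[, `:=`(patient_id = "B2", portal_date = as.Date(NA),
              obs_start = as.Date("2002-01-01"),
              obs_end = as.Date("2019-12-31"))]
  cohort <- list(
    portal = data.table::data.table(patient_id = "B1", arm = "portal",
                                    index_date = idx, index_year = 2012L),
    control = data.table::data.table(patient_id = "B2", arm = "control",
                                     index_date = as.Date("2012-07-01"),
                                     index_year = 2012L),
    patients = rbind(pats, ctrl))
  matches <- data.table::data.table(portal_id = "B1", control_id = "B2",
                                    control_index_year = 2012L,
                                    ps_distance = 0, gap_days = 61L)
  enc <- data.table::data.table(
    patient_id = c("B1", "B1", "B1"),
    date = c(idx, idx - 600, as.Date("2013-02-01")),
    channel = "MD")
  pan <- build_panel(matches, cohort, enc, max_abs_year = 8)
  b1 <- pan[patient_id == "B1"]
  # window exactly [index-2y, index+2y]: year -2 would need index-3y data;
  # years -1, 0, 1 and 2 (span ending exactly at obs_end) are fully covered
  expect_equal(sort(b1$t), c(-1L, 0L, 1L, 2L))
  # encounter on the index date itself lands in year 0
  expect_equal(b1[t == 0, MD], 1L)
  # idx - 600 days falls in year -1; 2013-02-01 in year 1
  expect_equal(b1[t == -1, MD], 1L)
  expect_equal(b1[t == 1, MD], 1L)
  expect_equal(b1[t == 2, MD], 0L)
  # control observed 2002-2019 around index 2012-07-01: year 8 would run
  # to 2020-07-01, so years -8..7 are the fully covered spans
  b2 <- pan[patient_id == "B2"]
  expect_equal(sort(b2$t), -8:7)
  expect_true(all(b2$MD == 0L))
})

test_that("zero-noise generative data is recovered exactly", {
  for (nm in c("paper-MD", "paper-NPPA")) {
    cf <- preset_coefficients(nm)
    pan <- zero_noise_panel(cf)
    fit <- fit_its(pan, channel = nm)
    expect_equal(unclass(fit$coefficients), unclass(cf), tolerance = 1e-10)
  }
})

test_that("arm-label swap negates the interaction block", {
  cf <- preset_coefficients("paper-MD")
  pan <- zero_noise_panel(cf)
  fit <- fit_its(pan)
  swapped <- data.table::copy(pan)[, A := 1L - A]
  fit2 <- fit_its(swapped)
  b <- unclass(fit$coefficients); b2 <- unclass(fit2$coefficients)
  expect_equal(unname(b2[5:8]), unname(-b[5:8]), tolerance = 1e-10)
  expect_equal(unname(b2[1:4]), unname(b[1:4] + b[5:8]), tolerance = 1e-10)
})

test_that("null-preset fits keep b6 and b7 at zero (3 MC SE)", {
  cf <- preset_coefficients("null", b0 = 1.2, b1 = 0.02)
  reps <- 30
  est <- sapply(seq_len(reps), function(r) {
    pan <- simulate_panel(cf, 150, c(-4:-1, 2:5), seed = 9000 + r)
    unclass(fit_its(pan, se_mode = "conventional")$coefficients)[c("b6", "b7")]
  })
  for (nm in c("b6", "b7")) {
    mc_se <- stats::sd(est[nm, ]) / sqrt(reps)
    expect_lt(abs(mean(est[nm, ])), 3 * mc_se)
  }
})

test_that("panel guards reject degenerate inputs", {
  cf <- preset_coefficients("null", b0 = 1)
  pan <- zero_noise_panel(cf)
  expect_error(fit_its(pan[A == 1]), "both arms")
  expect_error(fit_its(pan[t %in% c(-1, 2, 3)]), "two distinct pre")
  expect_error(fit_its(pan[t %in% c(-2, -1, 2)]), "post")
})

test_that("predicted_rate reproduces hand arithmetic on the estimates", {
  md <- preset_coefficients("paper-MD")
  expect_equal(predicted_rate(md, -1, 0), 1.563)
  expect_equal(predicted_rate(md, 2, 0), 1.592)
  nl <- preset_coefficients("null", b0 = 3.3)
  for (t in c(-6, -2, 2, 5)) {
    expect_equal(predicted_rate(nl, t, 1), 3.3)
    expect_equal(predicted_rate(nl, t, 0), 3.3)
  }
  expect_error(predicted_rate(md, 1, 0), "excluded")
})

test_that("pre-index predictions are linear with slope b1 (+ b5)", {
  cf <- preset_coefficients("paper-TC")
  tt <- -6:-1
  ctrl <- predicted_rate(cf, tt, 0)
  expect_equal(diff(ctrl), rep(0.045, 5))
  prt <- predicted_rate(cf, tt, 1)
  expect_equal(diff(prt), rep(0.045 - 0.005, 5))
})

test_that("cluster-robust SEs match a per-cluster oracle", {
  cf <- preset_coefficients("paper-MD")
  pan <- simulate_panel(cf, 40, c(-3:-1, 2:4), seed = 77)
  fit <- fit_its(pan)
  # independent CR1 sandwich computed longhand
  X <- design_row(pan$t, pan$A)
  y <- pan$count
  beta <- solve(crossprod(X), crossprod(X, y))
  e <- y - X %*% beta
  bread <- solve(crossprod(X))
  meat <- matrix(0, 8, 8)
  for (cl in unique(pan$patient_id)) {
    i <- pan$patient_id == cl
    s <- crossprod(X[i, , drop = FALSE], e[i])
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(pan$patient_id)); n <- nrow(X); k <- 8
  vc <- (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
  expect_equal(unname(fit$se_cluster), unname(sqrt(diag(vc))),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(as.numeric(beta)),
               tolerance = 1e-10)
})

test_that("its_fit JSON carries the labelled coefficient report", {
  pan <- zero_noise_panel(preset_coefficients("paper-MD"))
  fit <- fit_its(pan)
  path <- tempfile(fileext = ".json")
  write_its_fit(fit, path)
  obj <- jsonlite::read_json(path)
  expect_equal(length(obj$coefficients), 8L)
  expect_equal(obj$coefficients$b6$estimate, 0.417, tolerance = 1e-8)
  expect_match(obj$coefficients$b2$label, "level change")
})
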