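# Synthetic EMR generator.
#
# Emulates a single primary-care practice observed 2002-2019 whose patient
# portal launched in 2010: covariate-dependent registration propensity, and
# per-channel annual encounter counts that follow a linear secular trend
# with a level-and-slope change anchored at the index year.  Ground truth
# (generative coefficients, registration status, latent index dates) is
# carried alongside the tables so downstream matching and ITS stages have
# recovery targets.

.dx_conditions <- c(cad = 0.034, chf = 0.013, copd = 0.024,
                    dm = 0.062, htn = 0.170)

.default_logit_coeffs <- c(
  intercept = -1.75, age_std = 0.10, female = 0.44, rostered = 1.50,
  cad = 0.05, chf = 0.00, copd = -0.30, dm = 0.00, htn = 0.15
)

.atc_pool <- c(
  "A02BC01", "A10BA02", "A10BB01", "B01AC06", "C03CA01", "C07AB02",
  "C08CA01", "C09AA02", "C09CA01", "C10AA01", "C10AA05", "H03AA01",
  "J01CA04", "J01FA09", "M01AE01", "N02BE01", "N05BA06", "N06AB04",
  "N06AB06", "R03AC02", "R03BB04", "R06AE07", "S01ED01", "A12AX",
  "B03BA01", "C01DA14", "D07AC01", "G03CA03", "L04AX03", "M05BA04"
)

#' Configuration for the synthetic EMR generator
#'
#' Defaults encode the practice the generator emulates: calendar period
#' 2002-2019, portal launch 2010-01-01, roughly half of eligible adults
#' registering, and per-channel annual encounter counts following the
#' published segmented trends.
#'
#' @param n_patients number of patients (>= 2).
#' @param seed integer seed; mandatory, drives every random draw.
#' @param calendar_start,calendar_end study period bounds (ISO dates).
#' @param portal_launch first date portal registration is possible.
#' @param registration_logit_coeffs named numeric vector of logistic
#'   coefficients over `intercept`, `age_std` (age at launch standardised as
#'   (age-45)/17), `female`, `rostered`, and the five diagnosis flags
#'   `cad`, `chf`, `copd`, `dm`, `htn`.
#' @param channel_presets named list mapping channel (`MD`, `NPPA`, `TC`) to
#'   an [its_coefficients] vector or a preset name accepted by
#'   [preset_coefficients()].
#' @param pre_year_range,post_year_range integer length-2 vectors of relative
#'   years to emit (years 0 and 1 in between are always emitted for
#'   plotting; the ITS fit excludes them).
#' @param noise count noise model; only `"poisson"` is implemented.
#' @param random_intercept_sd SD of an optional additive patient-level
#'   Gaussian intercept shared across channels (default 0).
#' @param mean_floor positive lower clamp applied to the linear mean before
#'   it is used as a Poisson rate.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 2000L,
                         seed,
                         calendar_start = "2002-01-01",
                         calendar_end = "2019-12-31",
                         portal_launch = "2010-01-01",
                         registration_logit_coeffs = .default_logit_coeffs,
                         channel_presets = list(MD = "paper-MD",
                                                NPPA = "paper-NPPA",
                                                TC = "paper-TC"),
                         pre_year_range = c(-8L, -1L),
                         post_year_range = c(2L, 8L),
                         noise = "poisson",
                         random_intercept_sd = 0,
                         mean_floor = 0.01) {
  if (missing(seed)) stop("seed is a mandatory field of synth_config")
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) stop("n_patients must be >= 2")
  if (mean_floor <= 0) stop("mean_floor must be positive")
  if (random_intercept_sd < 0) stop("random_intercept_sd must be >= 0")
  noise <- match.arg(noise, "poisson")
  presets <- lapply(channel_presets, function(p) {
    if (is.character(p)) preset_coefficients(p) else its_coefficients(p)
  })
  if (is.null(names(presets)) || any(names(presets) == "")) {
    stop("channel_presets must be a named list")
  }
  miss <- setdiff(names(.default_logit_coeffs),
                  names(registration_logit_coeffs))
  if (length(miss)) {
    stop("registration_logit_coeffs is missing: ", paste(miss, collapse = ", "))
  }
  stopifnot(length(pre_year_range) == 2L, length(post_year_range) == 2L,
            pre_year_range[1] <= pre_year_range[2],
            post_year_range[1] <= post_year_range[2],
            post_year_range[1] >= 2L)
  cfg <- list(
    n_patients = n_patients,
    calendar_start = as_date_scalar(calendar_start, "calendar_start"),
    calendar_end = as_date_scalar(calendar_end, "calendar_end"),
    portal_launch = as_date_scalar(portal_launch, "portal_launch"),
    registration_logit_coeffs = registration_logit_coeffs,
    channel_presets = presets,
    pre_year_range = as.integer(pre_year_range),
    post_year_range = as.integer(post_year_range),
    noise = noise,
    random_intercept_sd = random_intercept_sd,
    mean_floor = mean_floor,
    seed = as.integer(seed)
  )
  if (cfg$calendar_start >= cfg$calendar_end) stop("empty calendar period")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic EMR bundle
#'
#' Produces the four practice tables (patients, encounters, prescriptions,
#' provider messages) plus a `truth` component recording the generative
#' coefficients, each patient's registration status and latent index date.
#' Identical configurations (including seed) yield identical bundles.
#'
#' @param config a [synth_config] object.
#' @return an object of class `emr_bundle`: a list with data.table elements
#'   `patients`, `encounters`, `prescriptions`, `messages` and a list
#'   `truth`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  n <- cfg$n_patients
  launch <- cfg$portal_launch

  ids <- sprintf("P%05d", seq_len(n))
  age_at_launch <- pmin(pmax(stats::rnorm(n, 45, 17), 5), 90)
  birth_date <- launch - round(age_at_launch * 365.25)
  female <- stats::runif(n) < 0.543
  rostered <- stats::runif(n) < 0.966

  # Observation windows: most patients span the full study period; a
  # minority enter late and/or leave early (staggered open practice).
  span_days <- as.numeric(cfg$calendar_end - cfg$calendar_start)
  obs_start <- cfg$calendar_start +
    ifelse(stats::runif(n) < 0.70, 0,
           round(stats::runif(n) * 0.6 * span_days))
  obs_end <- cfg$calendar_end -
    ifelse(stats::runif(n) < 0.85, 0,
           round(stats::runif(n) * 0.3 * span_days))
  swap <- obs_end <= obs_start
  obs_end[swap] <- cfg$calendar_end

  dx_onset <- lapply(.dx_conditions, function(prev) {
    has <- stats::runif(n) < prev
    on <- rep(as.Date(NA), n)
    on[has] <- cfg$calendar_start +
      round(stats::runif(sum(has)) * span_days)
    on
  })

  income_levels <- c("<40k", "40k-60k", "60k-100k", ">100k")
  edu_levels <- c("high school or less", "college", "university or more")
  income_band <- ifelse(stats::runif(n) < 1 / 3,
                        sample(income_levels, n, TRUE,
                               prob = c(0.12, 0.16, 0.31, 0.41)),
                        NA_character_)
  education_band <- ifelse(stats::runif(n) < 1 / 3,
                           sample(edu_levels, n, TRUE,
                                  prob = c(0.30, 0.30, 0.40)),
                           NA_character_)

  # Registration propensity: logistic in the covariates the matching stage
  # will use, so the matched design is attainable by construction.
  b <- cfg$registration_logit_coeffs
  lp <- b[["intercept"]] +
    b[["age_std"]] * (age_at_launch - 45) / 17 +
    b[["female"]] * female +
    b[["rostered"]] * rostered +
    b[["cad"]] * !is.na(dx_onset$cad) +
    b[["chf"]] * !is.na(dx_onset$chf) +
    b[["copd"]] * !is.na(dx_onset$copd) +
    b[["dm"]] * !is.na(dx_onset$dm) +
    b[["htn"]] * !is.na(dx_onset$htn)
  can_register <- obs_end >= launch & age_at_launch >= 10
  p_reg <- ifelse(can_register, stats::plogis(lp), 0)
  registered <- stats::runif(n) < p_reg

  # Registration date: uniform over the part of the window that leaves a
  # full pre- and post-year where possible; otherwise anywhere on/after
  # launch (such patients exercise the eligibility exclusions).
  portal_date <- rep(as.Date(NA), n)
  if (any(registered)) {
    lo_strict <- pmax(launch, shift_years(obs_start, 1L))
    hi_strict <- shift_years(obs_end, -1L)
    lo_loose <- pmax(launch, obs_start)
    hi_loose <- obs_end
    use_strict <- lo_strict <= hi_strict
    lo <- as.numeric(ifelse(use_strict, lo_strict, lo_loose))
    hi <- as.numeric(ifelse(use_strict, hi_strict, hi_loose))
    idx <- which(registered & hi >= lo)
    registered[registered & hi < lo] <- FALSE
    portal_date[idx] <- as.Date(
      round(lo[idx] + stats::runif(length(idx)) * (hi[idx] - lo[idx])),
      origin = "1970-01-01")
  }

  # Latent index date: registration date for portal patients; July 1 of the
  # median eligible year for controls (midpoint year fallback).
  index_date <- portal_date
  ctrl <- which(!registered)
  jul1 <- function(y) as.Date(sprintf("%d-07-01", y))
  if (length(ctrl)) {
    eg <- data.table::CJ(i = ctrl, year = 2010:2018)
    eg[, jd := jul1(year)]
    eg <- eg[shift_years(jd, -1L) >= obs_start[i] &
               shift_years(jd, 1L) <= obs_end[i]]
    med <- eg[, .(year = year[ceiling(.N / 2)]), by = i]
    index_date[med$i] <- jul1(med$year)
    rest <- setdiff(ctrl, med$i)
    if (length(rest)) {
      mid <- obs_start[rest] + (obs_end[rest] - obs_start[rest]) / 2
      index_date[rest] <- jul1(as.integer(format(mid, "%Y")))
    }
  }

  patients <- data.table::data.table(
    patient_id = ids, birth_date = birth_date,
    sex = ifelse(female, "female", "male"),
    rostered = rostered, obs_start = obs_start, obs_end = obs_end,
    portal_date = portal_date,
    income_band = income_band, education_band = education_band,
    dx_cad_onset = dx_onset$cad, dx_chf_onset = dx_onset$chf,
    dx_copd_onset = dx_onset$copd, dx_dm_onset = dx_onset$dm,
    dx_htn_onset = dx_onset$htn
  )

  u_i <- if (cfg$random_intercept_sd > 0) {
    stats::rnorm(n, 0, cfg$random_intercept_sd)
  } else {
    numeric(n)
  }

  # Person-year grid: every relative year in [pre_min, post_max] whose full
  # 12-month span lies inside the observation window.
  t_all <- seq(cfg$pre_year_range[1], cfg$post_year_range[2])
  grid <- data.table::CJ(row = seq_len(n), t = t_all)
  grid[, `:=`(
    span_open = shift_years(index_date[row], t - 1L),
    span_end = shift_years(index_date[row], t)
  )]
  grid <- grid[span_open >= obs_start[row] - 1L & span_end <= obs_end[row]]
  grid[, arm := ifelse(registered[row], "portal", "control")]

  floored <- 0L
  enc_list <- vector("list", length(cfg$channel_presets))
  names(enc_list) <- names(cfg$channel_presets)
  for (ch in names(cfg$channel_presets)) {
    mu_lin <- outcome_mean(cfg$channel_presets[[ch]], grid$t, grid$arm,
                           mean_floor = cfg$mean_floor) + u_i[grid$row]
    floored <- floored + sum(mu_lin <= cfg$mean_floor)
    mu <- pmax(cfg$mean_floor, mu_lin)
    k <- stats::rpois(nrow(grid), mu)
    rows <- rep.int(seq_len(nrow(grid)), k)
    if (length(rows)) {
      lo <- as.numeric(grid$span_open[rows]) + 1
      hi <- as.numeric(grid$span_end[rows])
      dates <- as.Date(floor(lo + stats::runif(length(rows)) * (hi - lo + 1)),
                       origin = "1970-01-01")
      dates <- pmin(as.Date(hi, origin = "1970-01-01"), dates)
      enc_list[[ch]] <- data.table::data.table(
        patient_id = ids[grid$row[rows]], date = dates, channel = ch)
    }
  }
  encounters <- data.table::rbindlist(enc_list)
  data.table::setorder(encounters, patient_id, date, channel)
  cells <- nrow(grid) * length(cfg$channel_presets)
  if (cells > 0 && floored / cells > 0.05) {
    warning(sprintf(
      "mean clamped at the floor for %.1f%% of person-year cells; recovery tests may be biased",
      100 * floored / cells))
  }

  # Prescriptions: morbidity-driven volume, ~12.5% in excluded schedules.
  n_dx <- Reduce(`+`, lapply(dx_onset, function(x) !is.na(x)))
  obs_years <- pmax(0.25, as.numeric(obs_end - obs_start) / 365.25)
  n_rx <- stats::rpois(n, obs_years * (0.5 + 1.1 * n_dx))
  rx_rows <- rep.int(seq_len(n), n_rx)
  prescriptions <- data.table::data.table(
    patient_id = ids[rx_rows],
    date = as.Date(
      round(as.numeric(obs_start[rx_rows]) +
              stats::runif(length(rx_rows)) *
              as.numeric(obs_end[rx_rows] - obs_start[rx_rows])),
      origin = "1970-01-01"),
    atc_code = sample(.atc_pool, length(rx_rows), TRUE),
    schedule_class = sample(c("prescription", "OTC", "ethical", "other", "NA"),
                            length(rx_rows), TRUE,
                            prob = c(0.875, 0.049, 0.02, 0.028, 0.028))
  )
  data.table::setorder(prescriptions, patient_id, date)

  # Provider messages to portal patients: ~1.49 messages/patient/year with
  # per-message handling time averaging 3.83 minutes.
  messages <- generate_messages(patients, rate = 1.49, mean_minutes = 3.83)

  bundle <- list(
    patients = patients,
    encounters = encounters,
    prescriptions = prescriptions,
    messages = messages,
    truth = list(
      channel_coeffs = cfg$channel_presets,
      registered = stats::setNames(registered, ids),
      index_date = stats::setNames(index_date, ids),
      registration_lp = stats::setNames(lp, ids),
      config = cfg
    )
  )
  class(bundle) <- "emr_bundle"
  bundle
}

generate_messages <- function(patients, rate = 1.49, mean_minutes = 3.83) {
  reg <- patients[!is.na(patients$portal_date)]
  out <- list()
  if (nrow(reg)) {
    y0 <- as.integer(format(reg$portal_date, "%Y"))
    y1 <- as.integer(format(reg$obs_end, "%Y"))
    nyr <- pmax(0L, y1 - y0 + 1L)
    rows <- rep.int(seq_len(nrow(reg)), nyr)
    yr <- unlist(mapply(function(a, b) if (b >= a) a:b else integer(0),
                        y0, y1, SIMPLIFY = FALSE), use.names = FALSE)
    k <- stats::rpois(length(rows), rate)
    mrow <- rep.int(seq_along(rows), k)
    if (length(mrow)) {
      ystart <- as.numeric(as.Date(sprintf("%d-01-01", yr[mrow])))
      ydays <- 364 + lubridate::leap_year(yr[mrow])
      lo <- pmax(ystart, as.numeric(reg$portal_date[rows[mrow]]))
      hi <- pmin(ystart + ydays, as.numeric(reg$obs_end[rows[mrow]]))
      keep <- hi >= lo
      mrow <- mrow[keep]
      sent <- as.Date(round(lo[keep] + stats::runif(sum(keep)) *
                              (hi[keep] - lo[keep])), origin = "1970-01-01")
      out <- data.table::data.table(
        provider_id = sprintf("MD%02d", sample.int(12L, length(mrow), TRUE)),
        patient_id = reg$patient_id[rows[mrow]],
        sent_date = sent,
        minutes = round(stats::rgamma(length(mrow), shape = 2,
                                      scale = mean_minutes / 2), 2)
      )
    }
  }
  if (!length(out)) {
    out <- data.table::data.table(
      provider_id = character(), patient_id = character(),
      sent_date = as.Date(character()), minutes = numeric())
  }
  data.table::setorder(out, provider_id, patient_id, sent_date)
  out
}

#' @export
print.emr_bundle <- function(x, ...) {
  cat("Synthetic EMR bundle\n")
  cat(sprintf("  patients:      %d (%d portal-registered)\n",
              nrow(x$patients), sum(!is.na(x$patients$portal_date))))
  cat(sprintf("  encounters:    %d\n", nrow(x$encounters)))
  cat(sprintf("  prescriptions: %d\n", nrow(x$prescriptions)))
  cat(sprintf("  messages:      %d\n", nrow(x$messages)))
  invisible(x)
}

#' Simulate a matched person-year panel directly
#'
#' Bypasses the full EMR machinery and draws per-channel annual counts for a
#' balanced two-arm panel at the given relative years, with Poisson noise
#' around the segmented mean.  This is the workhorse for coefficient
#' recovery experiments.
#'
#' @param coeffs an [its_coefficients] vector (generative truth).
#' @param n_per_arm patients per arm.
#' @param years integer vector of relative years to emit (0 and 1 allowed;
#'   the ITS fit excludes them).
#' @param seed integer seed.
#' @param mean_floor positive clamp for the Poisson mean.
#' @return a data.table with columns `patient_id`, `arm`, `A`, `t`, `count`.
#' @export
simulate_panel <- function(coeffs, n_per_arm, years, seed, mean_floor = 0.01) {
  coeffs <- its_coefficients(coeffs)
  stopifnot(n_per_arm >= 1, length(years) >= 1)
  with_seed(seed, {
    grid <- data.table::CJ(arm = c("control", "portal"),
                           pt = seq_len(n_per_arm), t = as.integer(years))
    mu <- outcome_mean(coeffs, grid$t, grid$arm, mean_floor = mean_floor)
    data.table::data.table(
      patient_id = paste0(substr(grid$arm, 1, 1), grid$pt),
      arm = grid$arm,
      A = as.integer(grid$arm == "portal"),
      t = grid$t,
      count = stats::rpois(nrow(grid), mu)
    )
  })
}

#' Write an EMR bundle as four CSV tables
#'
#' @param bundle an `emr_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "emr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.csv", "encounters.csv",
                            "prescriptions.csv", "messages.csv"))
  data.table::fwrite(bundle$patients, paths[1])
  data.table::fwrite(bundle$encounters, paths[2])
  data.table::fwrite(bundle$prescriptions, paths[3])
  data.table::fwrite(bundle$messages, paths[4])
  invisible(paths)
}

#' Read an EMR bundle from CSV tables
#'
#' Accepts the schemas written by [write_bundle()] (or user-supplied tables
#' with identical headers).  The `truth` component is absent for real data.
#'
#' @param dir directory holding `patients.csv`, `encounters.csv`,
#'   `prescriptions.csv`, and optionally `messages.csv`.
#' @return an `emr_bundle`.
#' @export
read_bundle <- function(dir) {
  req <- file.path(dir, c("patients.csv", "encounters.csv",
                          "prescriptions.csv"))
  for (p in req) if (!file.exists(p)) stop("missing input table: ", p)
  # empty fields are missing; the literal string "NA" is a valid schedule
  # class and must survive the round trip
  patients <- data.table::fread(req[1], na.strings = "")
  date_cols <- intersect(
    c("birth_date", "obs_start", "obs_end", "portal_date",
      paste0("dx_", names(.dx_conditions), "_onset")),
    names(patients))
  for (cc in date_cols) data.table::set(patients, j = cc,
                                        value = as.Date(patients[[cc]]))
  stopifnot_cols(patients, c("patient_id", "birth_date", "sex", "obs_start",
                             "obs_end"), "patients")
  encounters <- data.table::fread(req[2], na.strings = "")
  stopifnot_cols(encounters, c("patient_id", "date", "channel"), "encounters")
  encounters[, date := as.Date(date)]
  prescriptions <- data.table::fread(req[3], na.strings = "")
  stopifnot_cols(prescriptions, c("patient_id", "date", "atc_code"),
                 "prescriptions")
  prescriptions[, date := as.Date(date)]
  mp <- file.path(dir, "messages.csv")
  messages <- if (file.exists(mp)) {
    m <- data.table::fread(mp, na.strings = "")
    if ("sent_date" %in% names(m)) m[, sent_date := as.Date(sent_date)]
    m
  } else {
    NULL
  }
  bundle <- list(patients = patients, encounters = encounters,
                 prescriptions = prescriptions, messages = messages,
                 truth = NULL)
  class(bundle) <- "emr_bundle"
  bundle
}
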