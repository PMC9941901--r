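# Index-date covariate construction.
#
# Covariates feed the propensity model and the baseline (Table-1-style)
# report: sex, age at index, rostering, five chronic-condition flags at the
# index date, and 12-month lookback counts of encounters per channel plus
# distinct medications.  The lookback window is half-open, (index - 1y,
# index]: "the 12 months prior" with the index day itself on the closed end.

.excluded_schedules <- c("OTC", "ethical", "other", "NA")

#' 12-month lookback encounter and medication counts
#'
#' @param encounters data.frame with `date` and `channel` (MD/NPPA/TC) for
#'   one patient.
#' @param prescriptions data.frame with `date`, `atc_code` and optionally
#'   `schedule_class` for the same patient.
#' @param index_date Date scalar.
#' @return named numeric vector `(md, nppa, tc, distinct_meds)`.
#' @export
lookback_counts <- function(encounters, prescriptions, index_date) {
  index_date <- as_date_scalar(index_date, "index_date")
  lb <- shift_years(index_date, -1L)
  enc <- data.table::as.data.table(encounters)
  if (nrow(enc)) {
    if (anyNA(enc$date)) stop("undated encounter record")
    enc <- enc[date > lb & date <= index_date]
  }
  cnt <- function(ch) if (nrow(enc)) sum(enc$channel == ch) else 0L
  rx <- data.table::as.data.table(prescriptions)
  meds <- 0L
  if (nrow(rx)) {
    if (anyNA(rx$date)) stop("undated prescription record")
    if (!"schedule_class" %in% names(rx)) rx[, schedule_class := "prescription"]
    rx <- rx[date > lb & date <= index_date &
               !is.na(schedule_class) &
               !schedule_class %in% .excluded_schedules]
    meds <- length(unique(rx$atc_code))
  }
  c(md = cnt("MD"), nppa = cnt("NPPA"), tc = cnt("TC"), distinct_meds = meds)
}

#' Chronic-condition flags at the index date
#'
#' A condition is flagged when its earliest recorded diagnosis date exists
#' and is on or before the index date.
#'
#' @param patient one row of a patients table (with `dx_*_onset` columns).
#' @param index_date Date scalar.
#' @return named logical vector over `cad`, `chf`, `copd`, `dm`, `htn`.
#' @export
diagnosis_flags <- function(patient, index_date) {
  index_date <- as_date_scalar(index_date, "index_date")
  vapply(names(.dx_conditions), function(cond) {
    on <- patient[[paste0("dx_", cond, "_onset")]]
    if (is.null(on)) return(FALSE)
    on <- as.Date(on)
    !is.na(on) && on <= index_date
  }, logical(1))
}

#' Band a utilisation count for baseline reporting
#'
#' Physician-visit and medication counts use bands 0 / 1-2 / 3-5 / 6-10 /
#' >=11; nurse practitioner / physician assistant visits and triage calls
#' use 0 / 1-2 / >=3.  The top band is read as "that many or more" so the
#' bands partition all nonnegative counts.
#'
#' @param count nonnegative integer(s).
#' @param scheme one of `"md"`, `"nppa"`, `"tc"`, `"meds"`.
#' @return factor of band labels.
#' @export
categorize <- function(count, scheme = c("md", "nppa", "tc", "meds")) {
  scheme <- match.arg(scheme)
  if (any(is.na(count)) || any(count < 0) || any(count != round(count))) {
    stop("count must be a nonnegative integer")
  }
  if (scheme %in% c("md", "meds")) {
    breaks <- c(-Inf, 0, 2, 5, 10, Inf)
    labels <- c("0", "1-2", "3-5", "6-10", ">=11")
  } else {
    breaks <- c(-Inf, 0, 2, Inf)
    labels <- c("0", "1-2", ">=3")
  }
  cut(count, breaks = breaks, labels = labels)
}

#' Assemble covariate vectors for a set of index records
#'
#' Vectorised over index records (portal patients once, control patients
#' once per candidate year).  Age is computed in exact years at the index
#' date; counts use the half-open 12-month lookback.
#'
#' @param index_records data.table of IndexRecords (see [build_cohort()]).
#' @param patients trimmed patients table.
#' @param encounters encounters table (`patient_id`, `date`, `channel`).
#' @param prescriptions prescriptions table (`patient_id`, `date`,
#'   `atc_code`, `schedule_class`).
#' @return a data.table keyed by (`patient_id`, `arm`, `index_year`) with
#'   age, sex, rostered, the five diagnosis flags, the four lookback counts
#'   and optional income/education bands.
#' @export
build_covariates <- function(index_records, patients, encounters,
                             prescriptions) {
  recs <- data.table::as.data.table(index_records)
  pats <- data.table::as.data.table(patients)
  stopifnot_cols(recs, c("patient_id", "arm", "index_date", "index_year"),
                 "index_records")
  if (anyNA(pats$sex)) stop("missing sex for at least one patient")

  cov <- merge(recs, pats, by = "patient_id", sort = FALSE)
  if (nrow(cov) != nrow(recs)) stop("index records reference unknown patients")
  cov[, age_years := as.numeric(
    lubridate::interval(birth_date, index_date) / lubridate::years(1))]
  for (cond in names(.dx_conditions)) {
    on <- cov[[paste0("dx_", cond, "_onset")]]
    if (is.null(on)) on <- rep(as.Date(NA), nrow(cov))
    data.table::set(cov, j = paste0("dx_", cond),
                    value = !is.na(on) & on <= cov$index_date)
  }
  cov[, lb_start := shift_years(index_date, -1L)]

  enc <- data.table::as.data.table(encounters)
  key <- cov[, .(patient_id, index_year, lb_start, index_date)]
  if (nrow(enc)) {
    if (anyNA(enc$date)) stop("undated encounter record")
    hits <- enc[key, on = .(patient_id, date > lb_start, date <= index_date),
                nomatch = NULL,
                .(patient_id = x.patient_id, index_date = i.index_date,
                  channel = x.channel)]
    tab <- hits[, .N, by = .(patient_id, index_date, channel)]
    wide <- data.table::dcast(tab, patient_id + index_date ~ channel,
                              value.var = "N", fill = 0L)
  } else {
    wide <- data.table::data.table(patient_id = character(),
                                   index_date = as.Date(character()))
  }
  for (ch in c("MD", "NPPA", "TC")) {
    if (!ch %in% names(wide)) data.table::set(wide, j = ch, value = 0L)
  }
  cov <- merge(cov, wide, by = c("patient_id", "index_date"),
               all.x = TRUE, sort = FALSE)
  for (ch in c("MD", "NPPA", "TC")) {
    v <- cov[[ch]]
    data.table::set(cov, j = ch, value = data.table::fifelse(is.na(v), 0L, v))
  }

  rx <- data.table::as.data.table(prescriptions)
  if (nrow(rx)) {
    if (anyNA(rx$date)) stop("undated prescription record")
    if (!"schedule_class" %in% names(rx)) rx[, schedule_class := "prescription"]
    rx <- rx[!is.na(schedule_class) &
               !schedule_class %in% .excluded_schedules]
    mhits <- rx[key, on = .(patient_id, date > lb_start, date <= index_date),
                nomatch = NULL,
                .(patient_id = x.patient_id, index_date = i.index_date,
                  atc_code = x.atc_code)]
    mtab <- mhits[, .(distinct_meds = data.table::uniqueN(atc_code)),
                  by = .(patient_id, index_date)]
    cov <- merge(cov, mtab, by = c("patient_id", "index_date"),
                 all.x = TRUE, sort = FALSE)
  }
  if (!"distinct_meds" %in% names(cov)) cov[, distinct_meds := 0L]
  cov[, distinct_meds := data.table::fifelse(is.na(distinct_meds), 0L,
                                             as.integer(distinct_meds))]

  keep <- c("patient_id", "arm", "index_date", "index_year", "age_years",
            "sex", "rostered", paste0("dx_", names(.dx_conditions)),
            "MD", "NPPA", "TC", "distinct_meds",
            intersect(c("income_band", "education_band"), names(cov)))
  out <- cov[, ..keep]
  data.table::setnames(out, c("MD", "NPPA", "TC"),
                       c("md_visits_12m", "nppa_visits_12m", "tc_calls_12m"))
  data.table::setorder(out, patient_id, arm, index_year)
  out[]
}
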