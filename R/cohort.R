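# Cohort eligibility and open-cohort index-date assignment.
#
# Portal patients anchor at their registration date and must have a full
# calendar year of observed data on each side of it.  Never-registered
# patients enter the matching pool once per calendar year 2010-2018 for
# which July 1 of that year is covered by a year of data on each side
# (open cohort), provided they have at least two consecutive years of data
# between 2009 and 2019.  Person-time before the 18th birthday is deleted
# before any window is evaluated.

.control_years <- 2010:2018

#' Portal-arm index records
#'
#' @param patients a patients table (see [read_bundle()]); only rows with a
#'   non-missing `portal_date` are considered.
#' @return a data.table with one row per portal-registered patient:
#'   `patient_id`, `arm`, `index_date`, `index_year`, `eligible`, `reason`
#'   (`"ok"`, `"out_of_window"`, `"insufficient_pre"`, `"insufficient_post"`).
#' @export
portal_index <- function(patients) {
  p <- data.table::as.data.table(patients)[!is.na(portal_date)]
  if (!nrow(p)) {
    return(data.table::data.table(
      patient_id = character(), arm = character(),
      index_date = as.Date(character()), index_year = integer(),
      eligible = logical(), reason = character()))
  }
  reason <- rep("ok", nrow(p))
  out_win <- p$portal_date < p$obs_start | p$portal_date > p$obs_end
  no_pre <- shift_years(p$portal_date, -1L) < p$obs_start
  no_post <- shift_years(p$portal_date, 1L) > p$obs_end
  reason[no_pre] <- "insufficient_pre"
  reason[no_post] <- "insufficient_post"
  reason[out_win] <- "out_of_window"
  data.table::data.table(
    patient_id = p$patient_id, arm = "portal",
    index_date = p$portal_date,
    index_year = as.integer(format(p$portal_date, "%Y")),
    eligible = reason == "ok", reason = reason)
}

#' Open-cohort candidate index years for a control patient
#'
#' @param obs_start,obs_end observation window (Date scalars or vectors of
#'   equal length), already trimmed to adult person-time.
#' @param patient_id ids matching `obs_start` (optional for the scalar case).
#' @return a data.table of IndexRecords: one row per (patient, eligible
#'   calendar year in 2010-2018), index date July 1 of that year.  Patients
#'   with fewer than two consecutive years of data between 2009 and 2019
#'   contribute no rows.
#' @export
control_candidate_years <- function(obs_start, obs_end,
                                    patient_id = seq_along(obs_start)) {
  obs_start <- as.Date(obs_start); obs_end <- as.Date(obs_end)
  stopifnot(length(obs_start) == length(obs_end))
  # "two consecutive years of data between 2009 and 2019": continuous
  # registration coverage of at least two full years within that window.
  cov_lo <- pmax(obs_start, as.Date("2009-01-01"))
  cov_hi <- pmin(obs_end, as.Date("2019-12-31"))
  has_2y <- shift_years(cov_lo, 2L) <= cov_hi + 1L
  grid <- data.table::CJ(i = seq_along(obs_start), year = .control_years)
  grid[, index_date := as.Date(sprintf("%d-07-01", year))]
  grid <- grid[has_2y[i] &
                 shift_years(index_date, -1L) >= obs_start[i] &
                 shift_years(index_date, 1L) <= obs_end[i]]
  out <- data.table::data.table(
    patient_id = patient_id[grid$i], arm = "control",
    index_date = grid$index_date, index_year = grid$year,
    eligible = TRUE, reason = "ok")
  data.table::setorder(out, patient_id, index_year)
  out
}

#' Build the study cohort from an EMR bundle
#'
#' Applies the eligibility rules: deletes person-time before the 18th
#' birthday, drops focused-care patients when a `focused_care` flag column
#' is present, assigns portal index records and open-cohort control
#' candidate records, and logs per-reason exclusion counts for a flow
#' diagram.
#'
#' @param bundle an `emr_bundle` (or any list with a conforming `patients`
#'   table).
#' @return a list with elements `portal` (eligible portal IndexRecords),
#'   `control` (control candidate IndexRecords, several rows per patient),
#'   `patients` (the trimmed patients table), and `exclusions` (data.table
#'   of `reason`, `n`).
#' @export
build_cohort <- function(bundle) {
  patients <- data.table::as.data.table(bundle$patients)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient ids in patients table")
  }
  n0 <- nrow(patients)
  excl <- list()

  if ("focused_care" %in% names(patients)) {
    fc <- isTRUE_vec(patients$focused_care)
    excl$focused_care <- sum(fc)
    patients <- patients[!fc]
  }

  # Adult person-time only: trim the window start to the 18th birthday.
  adult_start <- shift_years(patients$birth_date, 18L)
  patients[, obs_start := pmax(obs_start, adult_start)]
  under18 <- patients$obs_start > patients$obs_end
  excl$never_adult_in_window <- sum(under18)
  patients <- patients[!under18]

  pidx <- portal_index(patients)
  for (r in c("out_of_window", "insufficient_pre", "insufficient_post")) {
    k <- sum(pidx$reason == r)
    if (k) excl[[paste0("portal_", r)]] <- k
  }
  portal <- pidx[eligible == TRUE][, .(patient_id, arm, index_date, index_year)]

  ctrl_pat <- patients[is.na(portal_date)]
  control <- control_candidate_years(ctrl_pat$obs_start, ctrl_pat$obs_end,
                                     ctrl_pat$patient_id)
  control <- control[, .(patient_id, arm, index_date, index_year)]
  no_year <- setdiff(ctrl_pat$patient_id, control$patient_id)
  if (length(no_year)) excl$control_no_eligible_year <- length(no_year)

  exclusions <- data.table::data.table(
    reason = names(excl), n = as.integer(unlist(excl)))
  eligible_patients <- length(unique(portal$patient_id)) +
    length(unique(control$patient_id))
  if (eligible_patients + sum(exclusions$n) != n0) {
    stop("cohort bookkeeping failure: eligible + excluded != input")
  }
  list(portal = portal, control = control, patients = patients,
       exclusions = exclusions)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
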