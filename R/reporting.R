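# Descriptive outputs: messaging workload, running-average registration
# cohort curves, ITS overlay material, and file rendering.

#' Mean provider time per portal message
#'
#' @param minutes numeric vector of per-message handling times (minutes).
#' @return arithmetic mean rounded to 2 decimals.
#' @export
mean_message_time <- function(minutes) {
  if (!length(minutes)) stop("no message durations supplied")
  if (any(is.na(minutes)) || any(minutes < 0)) {
    stop("message durations must be nonnegative")
  }
  round(mean(minutes), 2)
}

#' Annual provider messaging workload per portal patient
#'
#' The product of mean minutes per message and messages per patient per
#' year, i.e. the average provider time devoted to portal messaging per
#' registered patient annually.
#'
#' @param mean_min_per_message mean minutes per message (>= 0).
#' @param messages_per_patient_year messages per patient per year (>= 0).
#' @return list of class `workload_estimate` with the two inputs and
#'   `min_per_patient_year` (1 decimal).
#' @examples
#' workload_estimate(3.83, 1.49)
#' @export
workload_estimate <- function(mean_min_per_message,
                              messages_per_patient_year) {
  if (mean_min_per_message < 0 || messages_per_patient_year < 0) {
    stop("workload inputs must be nonnegative")
  }
  structure(list(
    mean_min_per_message = mean_min_per_message,
    messages_per_patient_year = messages_per_patient_year,
    min_per_patient_year = round(
      mean_min_per_message * messages_per_patient_year, 1)
  ), class = "workload_estimate")
}

#' @export
print.workload_estimate <- function(x, ...) {
  cat(sprintf(
    "Messaging workload: %.2f min/message x %.2f messages/patient/year = %.1f min/patient/year\n",
    x$mean_min_per_message, x$messages_per_patient_year,
    x$min_per_patient_year))
  invisible(x)
}

#' Messages per portal patient per year from a messages table
#'
#' Total provider-sent messages in `year` divided by the number of patients
#' registered on the portal on or before the end of that year (and still
#' observed during it).
#'
#' @param messages messages table (`patient_id`, `sent_date`).
#' @param patients patients table with `portal_date`, `obs_end`.
#' @param year calendar year.
#' @param denominator `"registered"` (default: everyone registered by the
#'   end of `year` and observed into it) or `"active"` (patients with at
#'   least one message that year).
#' @return messages per patient per year (numeric scalar).
#' @export
messages_per_patient_year <- function(messages, patients, year,
                                      denominator = c("registered",
                                                      "active")) {
  denominator <- match.arg(denominator)
  msg <- data.table::as.data.table(messages)
  msg <- msg[as.integer(format(sent_date, "%Y")) == year]
  pats <- data.table::as.data.table(patients)
  denom <- if (denominator == "registered") {
    sum(!is.na(pats$portal_date) &
          pats$portal_date <= as.Date(sprintf("%d-12-31", year)) &
          pats$obs_end >= as.Date(sprintf("%d-01-01", year)))
  } else {
    data.table::uniqueN(msg$patient_id)
  }
  if (denom == 0) stop("no portal patients in denominator for year ", year)
  nrow(msg) / denom
}

#' Centered 3-year running average
#'
#' Smooths a per-year series with the mean of the year, the previous year
#' and the following year; boundary years average over the neighbours that
#' exist.
#'
#' @param series named numeric vector (names = calendar years) or a
#'   two-column data.frame (`year`, `value`).
#' @param window odd window width (default 3).
#' @return numeric vector named by year, same length as the input.
#' @export
running_average <- function(series, window = 3L) {
  if (is.data.frame(series)) {
    series <- stats::setNames(series[[2]], series[[1]])
  }
  yrs <- as.integer(names(series))
  if (anyNA(yrs)) stop("series must be named by calendar year")
  o <- order(yrs)
  yrs <- yrs[o]; vals <- as.numeric(series[o])
  half <- (window - 1L) %/% 2L
  out <- vapply(seq_along(yrs), function(i) {
    idx <- which(yrs >= yrs[i] - half & yrs <= yrs[i] + half)
    mean(vals[idx])
  }, numeric(1))
  stats::setNames(out, yrs)
}

#' Calendar-year visit series by registration-year cohort
#'
#' For portal patients grouped by year of portal registration, the mean
#' number of visits per patient per calendar year (per channel), smoothed
#' with the centred 3-year running average.
#'
#' @param panel person-year panel from [build_panel()] (portal rows used).
#' @param registration_year named integer vector: registration year per
#'   portal `patient_id` (e.g. derived from the patients table).
#' @param groups list of integer vectors of registration years defining the
#'   cohorts.
#' @param channel count column to summarise.
#' @return a data.table (`group`, `calendar_year`, `mean_visits`,
#'   `smoothed`, `n_patients`); empty groups are dropped with a warning.
#' @export
registration_cohort_series <- function(panel, registration_year,
                                       groups = list(
                                         `2011-2012` = 2011:2012,
                                         `2013-2014` = 2013:2014,
                                         `2015-2016` = 2015:2016,
                                         `2017-2018` = 2017:2018),
                                       channel = "MD") {
  p <- data.table::as.data.table(panel)[arm == "portal"]
  stopifnot_cols(p, c("patient_id", "calendar_year", channel), "panel")
  p[, reg_year := registration_year[patient_id]]
  out <- list()
  for (g in names(groups)) {
    sub <- p[reg_year %in% groups[[g]]]
    if (!nrow(sub)) {
      warning("registration cohort ", g, " is empty; omitted")
      next
    }
    ann <- sub[, .(mean_visits = mean(get(channel)),
                   n_patients = data.table::uniqueN(patient_id)),
               by = calendar_year]
    data.table::setorder(ann, calendar_year)
    sm <- running_average(stats::setNames(ann$mean_visits,
                                          ann$calendar_year))
    ann[, `:=`(smoothed = as.numeric(sm), group = g)]
    out[[g]] <- ann
  }
  if (!length(out)) stop("all registration cohorts empty")
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("group", "calendar_year", "mean_visits",
                                 "smoothed", "n_patients"))
  res[]
}

#' Render pipeline outputs to files
#'
#' Writes the deterministic file set: `balance.csv`, `matches.csv`,
#' `panel.csv`, `its_fit_<channel>.json` and `its_overlay_<channel>.png`
#' per channel, `cohort_curves.csv` and `workload.json`.  All plotted
#' numbers are materialised in CSV/JSON first, so nothing downstream needs
#' to read pixels.
#'
#' @param results list with components `balance`, `matches`, `panel`,
#'   `fits` (named list of `its_fit`), and optionally `cohort_curves`
#'   (data.table) and `workload` (`workload_estimate`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
render_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  written <- character()
  w <- function(fname) {
    written <<- c(written, file.path(out_dir, fname))
    file.path(out_dir, fname)
  }
  data.table::fwrite(results$balance$table, w("balance.csv"))
  data.table::fwrite(results$matches, w("matches.csv"))
  data.table::fwrite(results$panel, w("panel.csv"))
  for (ch in names(results$fits)) {
    fit <- results$fits[[ch]]
    write_its_fit(fit, w(sprintf("its_fit_%s.json", ch)))
    plot_its_overlay(results$panel, fit, ch,
                     w(sprintf("its_overlay_%s.png", ch)))
  }
  if (!is.null(results$cohort_curves)) {
    data.table::fwrite(results$cohort_curves, w("cohort_curves.csv"))
  }
  if (!is.null(results$workload)) {
    jsonlite::write_json(unclass(results$workload), w("workload.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(written)
}

# Observed mean annual counts by arm and relative year with the fitted
# segmented lines overlaid.
plot_its_overlay <- function(panel, fit, channel, path) {
  p <- data.table::as.data.table(panel)
  obs <- p[, .(mean_count = mean(get(channel))), by = .(arm, t)]
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = range(obs$t), ylim = range(0, obs$mean_count),
                 xlab = "year relative to index", ylab = "mean annual count",
                 main = sprintf("Segmented ITS overlay: %s", channel))
  cols <- c(control = "grey40", portal = "firebrick")
  for (a in c("control", "portal")) {
    oo <- obs[arm == a][order(t)]
    graphics::points(oo$t, oo$mean_count, col = cols[[a]], pch = 16)
    tt_pre <- sort(unique(oo$t[oo$t <= -1]))
    tt_post <- sort(unique(oo$t[oo$t >= 2]))
    A <- as.integer(a == "portal")
    if (length(tt_pre) > 1) {
      graphics::lines(tt_pre, predicted_rate(fit, tt_pre, A),
                      col = cols[[a]], lwd = 2)
    }
    if (length(tt_post) > 1) {
      graphics::lines(tt_post, predicted_rate(fit, tt_post, A),
                      col = cols[[a]], lwd = 2, lty = 2)
    }
  }
  graphics::legend("topleft", legend = names(cols), col = unlist(cols),
                   pch = 16, bty = "n")
  invisible(path)
}
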