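# Segmented interrupted time-series regression on the matched person-year
# panel.
#
# Unit of analysis: patient person-years.  Relative year 0 spans the 12
# months preceding and including the index date; each further unit is a
# 12-month interval.  Years 0 and 1 are excluded from the fit (index-year
# attribution spike; transient adoption year).  Point estimates come from
# OLS; standard errors are reported both conventionally and cluster-robust
# by patient (CR1), the latter as primary because patients contribute
# repeated annual measurements.

.channels <- c("MD", "NPPA", "TC")

#' Build the matched person-year panel
#'
#' One row per matched patient and relative year whose full 12-month span
#' lies inside the patient's observation window; per-channel encounter
#' counts are tallied within each span (an encounter dated exactly on the
#' index date falls in year 0).
#'
#' @param matches matched pairs from [allocate_matches()].
#' @param cohort the [build_cohort()] result (for index dates and trimmed
#'   observation windows).
#' @param encounters encounters table.
#' @param max_abs_year largest |relative year| to tabulate (default 8).
#' @return a data.table with `patient_id`, `arm`, `A`, `t`, `period`,
#'   `calendar_year`, `pair_id` and one count column per channel.
#' @export
build_panel <- function(matches, cohort, encounters, max_abs_year = 8L) {
  stopifnot(nrow(matches) > 0)
  m <- data.table::copy(data.table::as.data.table(matches))
  m[, pair_id := .I]
  recs <- rbind(
    cohort$portal[m, on = .(patient_id = portal_id), nomatch = NULL,
                  .(patient_id = x.patient_id, arm = "portal",
                    index_date = x.index_date, pair_id = i.pair_id)],
    cohort$control[
      data.table::data.table(patient_id = m$control_id,
                             index_year = m$control_index_year,
                             pair_id = m$pair_id),
      on = .(patient_id, index_year), nomatch = NULL,
      .(patient_id = x.patient_id, arm = "control",
        index_date = x.index_date, pair_id = i.pair_id)]
  )
  if (nrow(recs) != 2L * nrow(matches)) {
    stop("matches reference index records absent from the cohort")
  }
  pats <- cohort$patients[, .(patient_id, obs_start, obs_end)]
  recs <- merge(recs, pats, by = "patient_id", sort = FALSE)

  grid <- recs[, {
    t <- seq(-max_abs_year, max_abs_year)
    span_open <- shift_years(index_date, t - 1L)
    span_end <- shift_years(index_date, t)
    ok <- span_open >= obs_start - 1L & span_end <= obs_end
    .(t = t[ok], span_open = span_open[ok], span_end = span_end[ok],
      arm = arm, index_date = index_date)
  }, by = .(patient_id, pair_id)]
  if (anyDuplicated(grid[, .(patient_id, t)])) {
    stop("overlapping person-year spans")  # impossible by construction
  }

  enc <- data.table::as.data.table(encounters)
  counts <- if (nrow(enc)) {
    hits <- enc[grid, on = .(patient_id, date > span_open, date <= span_end),
                nomatch = NULL,
                .(patient_id = x.patient_id, t = i.t, channel = x.channel)]
    data.table::dcast(hits[, .N, by = .(patient_id, t, channel)],
                      patient_id + t ~ channel, value.var = "N", fill = 0L)
  } else {
    data.table::data.table(patient_id = character(), t = integer())
  }
  for (ch in .channels) {
    if (!ch %in% names(counts)) data.table::set(counts, j = ch, value = 0L)
  }
  panel <- merge(grid[, .(patient_id, pair_id, arm, t, index_date)],
                 counts, by = c("patient_id", "t"), all.x = TRUE, sort = FALSE)
  for (ch in .channels) {
    v <- panel[[ch]]
    data.table::set(panel, j = ch,
                    value = data.table::fifelse(is.na(v), 0L, as.integer(v)))
  }
  panel[, `:=`(
    A = as.integer(arm == "portal"),
    period = as.integer(t >= 2),
    calendar_year = as.integer(format(shift_years(index_date, t), "%Y"))
  )]
  data.table::setcolorder(panel, c("patient_id", "pair_id", "arm", "A", "t",
                                   "period", "calendar_year"))
  data.table::setorder(panel, patient_id, t)
  panel[]
}

#' Fit the segmented ITS regression for one channel
#'
#' OLS of the annual count on the eight-term segmented design (see
#' [design_row()]) over person-years with `t` outside `exclude_years`.
#'
#' @param panel a person-year table with columns `A`, `t`, `patient_id` and
#'   either a `count` column or one named column per channel.
#' @param channel which count column to model (ignored when the panel has a
#'   `count` column).
#' @param exclude_years relative years dropped from the fit (default 0, 1).
#' @param se_mode primary SE flavour: `"cluster"` (robust by patient,
#'   default) or `"conventional"`.
#' @return an object of class `its_fit`.
#' @export
fit_its <- function(panel, channel = "MD", exclude_years = c(0L, 1L),
                    se_mode = c("cluster", "conventional")) {
  se_mode <- match.arg(se_mode)
  dat <- data.table::as.data.table(panel)
  ycol <- if ("count" %in% names(dat)) "count" else channel
  stopifnot_cols(dat, c("A", "t", "patient_id", ycol), "panel")
  dat <- dat[!t %in% exclude_years]
  if (length(unique(dat$A)) < 2L) {
    stop("panel must contain both arms")
  }
  if (length(unique(dat$t[dat$t < 2])) < 2L ||
      length(unique(dat$t[dat$t >= 2])) < 2L) {
    stop("need at least two distinct pre-index and two post-index years")
  }
  X <- design_row(dat$t, dat$A)
  y <- as.numeric(dat[[ycol]])

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient ITS design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  resid <- y - as.numeric(X %*% beta)
  n <- length(y); k <- ncol(X)
  XtX_inv <- chol2inv(qr.R(qrX))
  sigma2 <- sum(resid^2) / (n - k)
  se_conv <- sqrt(diag(XtX_inv) * sigma2)

  # CR1 cluster-robust by patient with Stata-style small-sample factor
  cl <- dat$patient_id
  Xe <- X * resid
  meat <- crossprod(rowsum(Xe, cl))
  G <- length(unique(cl))
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  vc <- adj * XtX_inv %*% meat %*% XtX_inv
  se_clust <- sqrt(diag(vc))

  se <- if (se_mode == "cluster") se_clust else se_conv
  df <- if (se_mode == "cluster") G - 1L else n - k
  pval <- 2 * stats::pt(abs(beta / se), df = df, lower.tail = FALSE)

  structure(list(
    channel = if ("count" %in% names(dat)) channel else ycol,
    coefficients = its_coefficients(beta),
    se_conventional = stats::setNames(se_conv, .coef_names),
    se_cluster = stats::setNames(se_clust, .coef_names),
    se_mode = se_mode,
    p_values = stats::setNames(pval, .coef_names),
    labels = .coef_labels,
    n_person_years = n,
    n_patients = G,
    exclude_years = exclude_years
  ), class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Segmented ITS fit: channel %s, %d person-years, %d patients\n",
              x$channel, x$n_person_years, x$n_patients))
  cat(sprintf("  SEs: %s (years %s excluded)\n", x$se_mode,
              paste(x$exclude_years, collapse = ", ")))
  se <- if (x$se_mode == "cluster") x$se_cluster else x$se_conventional
  b <- unclass(x$coefficients)
  for (nm in .coef_names) {
    cat(sprintf("  %-3s %8.3f (SE %.3f, p %s)  %s\n", nm, b[[nm]], se[[nm]],
                format.pval(x$p_values[[nm]], digits = 2, eps = 1e-3),
                x$labels[[nm]]))
  }
  invisible(x)
}

#' Model-predicted annual encounter rate
#'
#' @param fit an `its_fit` (or bare [its_coefficients]).
#' @param t relative year(s), excluding 0 and 1.
#' @param A arm indicator(s): 0 control, 1 portal.
#' @return numeric vector of predicted annual counts.
#' @export
predicted_rate <- function(fit, t, A) {
  coeffs <- if (inherits(fit, "its_fit")) fit$coefficients else
    its_coefficients(fit)
  as.numeric(design_row(t, A) %*% unclass(coeffs))
}

#' Serialise an ITS fit to JSON
#'
#' @param fit an `its_fit`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_its_fit <- function(fit, path) {
  stopifnot(inherits(fit, "its_fit"))
  obj <- list(
    channel = fit$channel,
    se_mode = fit$se_mode,
    n_person_years = fit$n_person_years,
    n_patients = fit$n_patients,
    exclude_years = fit$exclude_years,
    coefficients = lapply(stats::setNames(.coef_names, .coef_names),
                          function(nm) list(
                            label = fit$labels[[nm]],
                            estimate = unclass(fit$coefficients)[[nm]],
                            se_conventional = fit$se_conventional[[nm]],
                            se_cluster = fit$se_cluster[[nm]],
                            p_value = fit$p_values[[nm]]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
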