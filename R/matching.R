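# Propensity-score matching.
#
# One-to-one, without replacement, caliper-constrained on the logit of the
# propensity score (0.2 pooled SDs by default), with the matching pool for
# each portal patient limited to control person-year records whose index
# date is within 1 year (366 days).  Allocation is the iterative
# unique-first greedy scheme: repeatedly match portal patients with a
# unique remaining candidate, then controls that are a candidate of a
# unique portal patient, re-checking after every match; when neither rule
# fires, the globally closest remaining pair (smallest score distance,
# ties by smallest date gap, then lexicographic ids) is matched.

#' Fit the registration propensity model
#'
#' Maximum-likelihood logistic regression of portal registration on the
#' index-date covariates.  Control patients contribute one record per
#' eligible person-year.  Income and education are never used (recorded for
#' too few patients to enter the score).
#'
#' @param covariates a covariate table from [build_covariates()].
#' @param ps_covariates character vector of covariate columns to use.
#' @return an object of class `propensity_model`: list with the `glm` fit,
#'   the score vector `ps`, its logit, and the records they index.
#' @export
fit_propensity <- function(covariates,
                           ps_covariates = c(
                             "age_years", "sex", "rostered",
                             "dx_cad", "dx_chf", "dx_copd", "dx_dm", "dx_htn",
                             "md_visits_12m", "nppa_visits_12m",
                             "tc_calls_12m", "distinct_meds")) {
  cov <- data.table::as.data.table(covariates)
  stopifnot_cols(cov, c("arm", ps_covariates), "covariates")
  y <- as.integer(cov$arm == "portal")
  if (length(unique(y)) < 2L) {
    stop("both portal and control records are required to fit the propensity model")
  }
  check_separation(cov, ps_covariates, y)
  dat <- data.frame(.y = y, cov[, ps_covariates, with = FALSE])
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  ps <- as.numeric(stats::fitted(fit))
  eps <- 1e-12
  ps <- pmin(1 - eps, pmax(eps, ps))
  structure(list(
    fit = fit,
    coefficients = stats::coef(fit),
    records = cov[, .(patient_id, arm, index_date, index_year)],
    ps = ps,
    logit_ps = stats::qlogis(ps),
    n_fitted = nrow(cov)
  ), class = "propensity_model")
}

# Flags covariates that perfectly separate the arms before glm blows up on
# them silently.
check_separation <- function(cov, ps_covariates, y) {
  for (v in ps_covariates) {
    x <- cov[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      tab <- table(x, y)
      if (nrow(tab) > 1L && any(colSums(tab > 0) == 1L) &&
          all(rowSums(tab > 0) == 1L)) {
        stop("perfect separation on covariate: ", v)
      }
    } else {
      if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
        stop("perfect separation on covariate: ", v)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Propensity model: %d records (%d portal), %d covariates\n",
              x$n_fitted, sum(x$records$arm == "portal"),
              length(x$coefficients) - 1L))
  cat(sprintf("  score range: %.4f - %.4f\n", min(x$ps), max(x$ps)))
  invisible(x)
}

#' Candidate control sets under caliper and index-date constraints
#'
#' A control person-year record is a candidate for a portal patient when
#' the logit-score distance is within the caliper and the index dates are
#' within `max_gap_days`.  Each distinct control patient contributes at
#' most one record per portal patient (the closest-scoring, ties broken by
#' smaller date gap then earlier index year).
#'
#' @param model a `propensity_model`.
#' @param caliper_mult caliper width as a multiple of the SD of the pooled
#'   logit scores (default 0.2).
#' @param max_gap_days maximum index-date gap in days (default 366).
#' @param caliper_scale `"logit"` (default) or `"raw"` for a caliper on the
#'   probability scale.
#' @return a list with `pairs` (data.table of candidate pairs:
#'   `portal_id`, `control_id`, `control_index_year`, `ps_distance`,
#'   `gap_days`), the realised `caliper_width`, and the unmatched-portal
#'   bookkeeping inputs.
#' @export
candidate_sets <- function(model, caliper_mult = 0.2, max_gap_days = 366,
                           caliper_scale = c("logit", "raw")) {
  stopifnot(inherits(model, "propensity_model"))
  caliper_scale <- match.arg(caliper_scale)
  score <- if (caliper_scale == "logit") model$logit_ps else model$ps
  width <- caliper_mult * stats::sd(score)
  rec <- data.table::copy(model$records)
  rec[, score := score]
  portal <- rec[arm == "portal"]
  ctrl <- rec[arm == "control"]
  data.table::setnames(portal, c("patient_id", "index_date", "score"),
                       c("portal_id", "p_index_date", "p_score"))
  portal[, `:=`(lo = p_score - width, hi = p_score + width,
                d_lo = p_index_date - max_gap_days,
                d_hi = p_index_date + max_gap_days)]
  pairs <- ctrl[portal,
                on = .(score >= lo, score <= hi,
                       index_date >= d_lo, index_date <= d_hi),
                nomatch = NULL,
                .(portal_id = i.portal_id,
                  control_id = x.patient_id,
                  control_index_year = x.index_year,
                  ps_distance = abs(x.score - i.p_score),
                  gap_days = abs(as.integer(x.index_date - i.p_index_date)))]
  # one record per distinct control patient per portal patient
  data.table::setorder(pairs, portal_id, control_id, ps_distance, gap_days,
                       control_index_year)
  pairs <- unique(pairs, by = c("portal_id", "control_id"))
  list(pairs = pairs[], caliper_width = width,
       portal_ids = portal$portal_id,
       n_control_patients = data.table::uniqueN(ctrl$patient_id))
}

#' Allocate one-to-one matches by iterative unique-first greedy assignment
#'
#' @param candidates the result of [candidate_sets()] (or any list with a
#'   conforming `pairs` table).
#' @return a data.table of matched pairs (`portal_id`, `control_id`,
#'   `control_index_year`, `ps_distance`, `gap_days`, `allocation_round`)
#'   plus attribute `unmatched_portal` (ids with no match).  The result is
#'   invariant to the row order of the input pairs.
#' @export
allocate_matches <- function(candidates) {
  pairs <- data.table::as.data.table(candidates$pairs)
  all_portal <- unique(c(candidates$portal_ids %||% character(),
                         pairs$portal_id))
  if (!nrow(pairs)) {
    out <- data.table::data.table(
      portal_id = character(), control_id = character(),
      control_index_year = integer(), ps_distance = numeric(),
      gap_days = integer(), allocation_round = integer())
    data.table::setattr(out, "unmatched_portal", sort(all_portal))
    return(out)
  }
  # canonical order makes the allocation independent of input row order
  data.table::setorder(pairs, ps_distance, gap_days, portal_id, control_id)
  p_ids <- sort(unique(pairs$portal_id))
  c_ids <- sort(unique(pairs$control_id))
  pi <- match(pairs$portal_id, p_ids)
  ci <- match(pairs$control_id, c_ids)
  np <- length(p_ids); nc <- length(c_ids)

  alive <- rep(TRUE, nrow(pairs))
  p_count <- tabulate(pi, np)
  c_count <- tabulate(ci, nc)
  p_pairs <- split(seq_len(nrow(pairs)), pi)   # names = portal index
  c_pairs <- split(seq_len(nrow(pairs)), ci)
  p_open <- rep(TRUE, np)   # portal not yet matched
  c_open <- rep(TRUE, nc)
  res_pair <- integer(0)
  res_round <- integer(0)
  round_no <- 0L
  scan_ptr <- 1L

  kill_party <- function(pidx, cidx) {
    # remove both parties from every candidate set; within one portal's set
    # the controls are distinct (and vice versa), so vectorised decrements
    # are collision-free
    a <- p_pairs[[as.character(pidx)]]
    a <- a[alive[a]]
    if (length(a)) {
      alive[a] <<- FALSE
      c_count[ci[a]] <<- c_count[ci[a]] - 1L
      p_count[pidx] <<- 0L
    }
    b <- c_pairs[[as.character(cidx)]]
    b <- b[alive[b]]
    if (length(b)) {
      alive[b] <<- FALSE
      p_count[pi[b]] <<- p_count[pi[b]] - 1L
      c_count[cidx] <<- 0L
    }
    p_open[pidx] <<- FALSE
    c_open[cidx] <<- FALSE
  }
  take <- function(j) {
    round_no <<- round_no + 1L
    res_pair <<- c(res_pair, j)
    res_round <<- c(res_round, round_no)
    kill_party(pi[j], ci[j])
  }

  repeat {
    # rule 1: portal patients with exactly one remaining candidate
    u <- which(p_open & p_count == 1L)
    if (length(u)) {
      pidx <- u[1L]   # p_ids sorted, so smallest id first
      j <- p_pairs[[as.character(pidx)]]
      j <- j[alive[j]][1L]
      take(j)
      next
    }
    # rule 2: controls that are a candidate of exactly one portal patient
    u <- which(c_open & c_count == 1L)
    if (length(u)) {
      cidx <- u[1L]
      j <- c_pairs[[as.character(cidx)]]
      j <- j[alive[j]][1L]
      take(j)
      next
    }
    # fallback: globally closest remaining pair (pairs pre-sorted)
    while (scan_ptr <= length(alive) && !alive[scan_ptr]) {
      scan_ptr <- scan_ptr + 1L
    }
    if (scan_ptr > length(alive)) break
    take(scan_ptr)
  }

  out <- pairs[res_pair]
  out[, allocation_round := res_round]
  data.table::setorder(out, portal_id)
  unmatched <- setdiff(all_portal, out$portal_id)
  data.table::setattr(out, "unmatched_portal", sort(unmatched))
  out[]
}

#' Standardized mean difference
#'
#' Continuous: `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`.  Binary:
#' `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`.  Values below 0.1 are
#' conventionally read as negligible imbalance.
#'
#' @param x1,x2 for `kind = "continuous"`: `c(mean, sd)` per group; for
#'   `kind = "binary"`: a proportion per group.
#' @param kind `"continuous"` or `"binary"`.
#' @return nonnegative scalar (0 when both spreads are zero and the
#'   locations agree).
#' @examples
#' standardized_difference(0.598, 0.490, kind = "binary")
#' @export
standardized_difference <- function(x1, x2,
                                    kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    p1 <- x1[[1]]; p2 <- x2[[1]]
    if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
      stop("proportions must lie in [0, 1]")
    }
    num <- abs(p1 - p2)
    den <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  } else {
    stopifnot(length(x1) == 2L, length(x2) == 2L)
    num <- abs(x1[[1]] - x2[[1]])
    den <- sqrt((x1[[2]]^2 + x2[[2]]^2) / 2)
  }
  if (den == 0) {
    return(if (num == 0) 0 else Inf)
  }
  num / den
}

#' Covariate balance before and after matching
#'
#' Emits a baseline-table layout: per covariate, group summaries and
#' standardized differences for the full (pre-matching) pool and for the
#' matched pairs, plus propensity-score quintile groups cut at pooled
#' quintiles (labelled 0-4).
#'
#' @param covariates covariate table (all index records).
#' @param model the fitted `propensity_model` over the same records.
#' @param matches matched pairs from [allocate_matches()].
#' @param ps_covariates covariates to tabulate.
#' @return a list with `table` (data.table: covariate, phase, summaries,
#'   `std_diff`) and `quintiles` (counts per PS quintile group and arm,
#'   matched records).
#' @export
balance_table <- function(covariates, model, matches,
                          ps_covariates = c(
                            "age_years", "sex", "rostered",
                            "dx_cad", "dx_chf", "dx_copd", "dx_dm", "dx_htn",
                            "md_visits_12m", "nppa_visits_12m",
                            "tc_calls_12m", "distinct_meds")) {
  if (!nrow(matches)) stop("no matched pairs to tabulate")
  cov <- data.table::as.data.table(covariates)
  cov[, ps := model$ps[match(
    paste(cov$patient_id, cov$arm, cov$index_year),
    paste(model$records$patient_id, model$records$arm,
          model$records$index_year))]]

  matched_keys <- unique(rbind(
    data.table::data.table(patient_id = matches$portal_id, arm = "portal"),
    data.table::data.table(patient_id = matches$control_id, arm = "control",
                           index_year = matches$control_index_year),
    fill = TRUE))
  m_portal <- cov[arm == "portal" &
                    patient_id %in% matches$portal_id]
  m_control <- cov[matched_keys[arm == "control"],
                   on = .(patient_id, arm, index_year), nomatch = NULL]
  # controls may have several candidate years; the matched record is the
  # person-year that was actually allocated
  phases <- list(
    pre = list(portal = cov[arm == "portal"], control = cov[arm == "control"]),
    post = list(portal = m_portal, control = m_control)
  )

  one_cov <- function(v, g1, g2) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    if (is.numeric(x1) && !is.logical(x1)) {
      sd_ <- standardized_difference(c(mean(x1), stats::sd(x1)),
                                     c(mean(x2), stats::sd(x2)),
                                     "continuous")
      list(mean_portal = mean(x1), mean_control = mean(x2), std_diff = sd_)
    } else {
      lv <- if (is.logical(x1)) TRUE else sort(unique(c(x1, x2)))[1]
      p1 <- mean(x1 == lv); p2 <- mean(x2 == lv)
      list(mean_portal = p1, mean_control = p2,
           std_diff = standardized_difference(p1, p2, "binary"))
    }
  }
  rows <- list()
  for (ph in names(phases)) {
    for (v in c(ps_covariates, "ps")) {
      s <- one_cov(v, phases[[ph]]$portal, phases[[ph]]$control)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        covariate = v, phase = ph,
        mean_portal = s$mean_portal, mean_control = s$mean_control,
        std_diff = s$std_diff)
    }
  }
  tab <- data.table::rbindlist(rows)

  pooled <- rbind(m_portal, m_control)
  qs <- stats::quantile(pooled$ps, probs = seq(0, 1, 0.2), names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  pooled[, ps_group := cut(ps, breaks = qs,
                           labels = seq_len(length(qs) - 1L) - 1L,
                           include.lowest = TRUE)]
  quint <- pooled[, .N, by = .(ps_group, arm)]
  data.table::setorder(quint, ps_group, arm)
  list(table = tab[], quintiles = quint[])
}

#' One-call matching of a cohort
#'
#' Convenience wrapper: fit the propensity model, build candidate sets and
#' allocate matches.
#'
#' @param covariates covariate table over all index records.
#' @param caliper_mult,max_gap_days,caliper_scale,ps_covariates passed to
#'   [candidate_sets()] / [fit_propensity()].
#' @return list with `model`, `candidates`, `matches`, `balance`.
#' @export
match_cohort <- function(covariates, caliper_mult = 0.2, max_gap_days = 366,
                         caliper_scale = "logit",
                         ps_covariates = NULL) {
  args <- list(covariates)
  if (!is.null(ps_covariates)) args$ps_covariates <- ps_covariates
  model <- do.call(fit_propensity, args)
  cand <- candidate_sets(model, caliper_mult = caliper_mult,
                         max_gap_days = max_gap_days,
                         caliper_scale = caliper_scale)
  matches <- allocate_matches(cand)
  bal <- if (nrow(matches)) {
    bargs <- list(covariates, model, matches)
    if (!is.null(ps_covariates)) bargs$ps_covariates <- ps_covariates
    do.call(balance_table, bargs)
  } else {
    NULL
  }
  list(model = model, candidates = cand, matches = matches, balance = bal)
}
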