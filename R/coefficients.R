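# Segmented-ITS coefficient vectors and published presets.
#
# The eight coefficients parameterise the segmented regression
#   E[count | t, A] = b0 + b1*t + b2*P + b3*(t-2)*P
#                     + A*(b4 + b5*t + b6*P + b7*(t-2)*P)
# with relative year t, post-period indicator P = 1{t >= 2}, and arm
# indicator A (1 = portal, 0 = control).  The post-period slope term is
# anchored at t = 2 so that b2 (and b6) measure the level change in year 2
# relative to what the pre-index slope would have predicted.

.coef_names <- c("b0", "b1", "b2", "b3", "b4", "b5", "b6", "b7")

.coef_labels <- c(
  b0 = "intercept (control)",
  b1 = "annual visits (pre-index slope, control)",
  b2 = "period (level change at year 2, control)",
  b3 = "annual visits x period (slope change, control)",
  b4 = "portal (intercept difference)",
  b5 = "portal x annual visits (pre-slope difference)",
  b6 = "portal x period (level-change difference)",
  b7 = "portal x annual visits x period (slope-change difference)"
)

# Published ITS estimates per encounter channel, used as generative truth
# in recovery experiments. MD = physician visits, NPPA = nurse practitioner
# or physician assistant visits, TC = triage calls.
.preset_table <- list(
  `paper-MD`   = c(1.572, 0.009,  0.002,  0.036,  0.008,  0.014, 0.417, -0.054),
  `paper-NPPA` = c(0.618, 0.049, -0.011, -0.042, -0.018, -0.010, 0.069,  0.028),
  `paper-TC`   = c(0.335, 0.045,  0.062,  0.010, -0.033, -0.005, 0.102, -0.005)
)

#' Construct an ITS coefficient vector
#'
#' @param x numeric vector of length 8: control intercept, control pre-index
#'   slope, control period jump, control slope change, and the four
#'   portal-minus-control differences of the same quantities.
#' @return an object of class `its_coefficients` (a named numeric vector).
#' @export
its_coefficients <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 8L) stop("an ITS coefficient vector has exactly 8 entries")
  if (any(!is.finite(x))) stop("ITS coefficients must be finite")
  names(x) <- .coef_names
  class(x) <- c("its_coefficients", "numeric")
  x
}

#' @export
print.its_coefficients <- function(x, ...) {
  cat("ITS coefficient vector:\n")
  for (nm in .coef_names) {
    cat(sprintf("  %-3s %8.3f  %s\n", nm, unclass(x)[[nm]], .coef_labels[[nm]]))
  }
  invisible(x)
}

#' Published or null coefficient presets
#'
#' `"paper-MD"`, `"paper-NPPA"` and `"paper-TC"` return the published
#' segmented-regression estimates for physician visits, nurse practitioner /
#' physician assistant visits and triage calls respectively; `"null"` returns
#' a no-effect vector (b2..b7 = 0) with configurable intercept and slope.
#'
#' @param name one of `"paper-MD"`, `"paper-NPPA"`, `"paper-TC"`, `"null"`.
#' @param b0,b1 intercept and pre-index slope for the `"null"` preset
#'   (ignored otherwise).
#' @return an [its_coefficients] vector.
#' @examples
#' preset_coefficients("paper-MD")
#' preset_coefficients("null", b0 = 2)
#' @export
preset_coefficients <- function(name, b0 = 1, b1 = 0) {
  valid <- c(names(.preset_table), "null")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop(sprintf("unknown preset %s; valid names: %s",
                 deparse(substitute(name)), paste(valid, collapse = ", ")))
  }
  if (name == "null") {
    return(its_coefficients(c(b0, b1, 0, 0, 0, 0, 0, 0)))
  }
  its_coefficients(.preset_table[[name]])
}

#' Expected annual encounter count under the segmented model
#'
#' Evaluates the segmented mean at relative year `t` for the given arm and
#' clamps it below at `mean_floor` so that it can serve as a Poisson mean.
#' Years 0 and 1 are permitted here (the generator may emit them for
#' plotting); they are rejected only by ITS-facing design construction.
#'
#' @param coeffs an [its_coefficients] vector.
#' @param t integer relative year (vectorised).
#' @param arm `"portal"` or `"control"` (recycled against `t`).
#' @param mean_floor lower clamp for the mean (default 0.01).
#' @return numeric vector of expected counts, each `>= mean_floor`.
#' @examples
#' outcome_mean(preset_coefficients("paper-MD"), t = -1, arm = "control")
#' @export
outcome_mean <- function(coeffs, t, arm = c("control", "portal"),
                         mean_floor = 0.01) {
  coeffs <- its_coefficients(coeffs)
  if (any(t != round(t))) stop("relative year t must be integer-valued")
  if (mean_floor <= 0) stop("mean_floor must be positive")
  arm <- match.arg(arm, c("control", "portal"), several.ok = TRUE)
  A <- as.numeric(rep_len(arm == "portal", length(t)))
  P <- as.numeric(t >= 2)
  b <- unclass(coeffs)
  mu <- b[1] + b[2] * t + b[3] * P + b[4] * (t - 2) * P +
    A * (b[5] + b[6] * t + b[7] * P + b[8] * (t - 2) * P)
  pmax(mean_floor, mu)
}

#' Segmented-regression design row(s)
#'
#' Returns the covariate row `(1, t, P, (t-2)P, A, At, AP, A(t-2)P)` used by
#' both the generator and the ITS fit.  Years 0 and 1 are excluded from the
#' ITS (index-year attribution spike and transient adoption year) and are
#' rejected here.
#'
#' @param t integer relative year(s), none equal to 0 or 1.
#' @param A arm indicator(s), 0 = control, 1 = portal (recycled).
#' @return a numeric matrix with one row per `t` and 8 named columns.
#' @examples
#' design_row(t = 4, A = 1)
#' @export
design_row <- function(t, A) {
  if (any(t != round(t))) stop("relative year t must be integer-valued")
  if (any(t %in% c(0, 1))) {
    stop("years 0 and 1 are excluded from the ITS design")
  }
  if (!all(A %in% c(0, 1))) stop("A must be 0 (control) or 1 (portal)")
  n <- max(length(t), length(A))
  t <- rep_len(as.numeric(t), n)
  A <- rep_len(as.numeric(A), n)
  P <- as.numeric(t >= 2)
  m <- cbind(1, t, P, (t - 2) * P, A, A * t, A * P, A * (t - 2) * P)
  colnames(m) <- .coef_names
  m
}
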