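# Internal helpers: seeded RNG scoping, calendar arithmetic, misc checks.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that generator calls
#' are referentially transparent: the same seed always produces the same
#' draws regardless of surrounding RNG use.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic child seed for a pipeline stage
#'
#' Keeps derived seeds below 2^31 so they remain valid R integers.
#'
#' @param seed master integer seed.
#' @param stage stage name (character) or offset (integer).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  off <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) %% 1203793L) * 1783L + off + 1L)
}

# Calendar-exact year shift; Feb 29 rolls back to Feb 28 in non-leap years.
shift_years <- function(date, n) {
  lubridate::add_with_rollback(date, lubridate::years(n))
}

as_date_scalar <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) stop(sprintf("invalid %s: %s", what, x))
  d
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
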