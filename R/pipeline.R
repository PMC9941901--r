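# End-to-end orchestration: generate/load -> cohort -> covariates -> match
# -> ITS -> report, with a manifest and deterministic per-stage seeds.

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (generate an EMR bundle) or `"files"` (read
#'   CSV tables from `input_dir`).
#' @param seed master integer seed; mandatory in synthetic mode.  Stage
#'   seeds are derived deterministically so stages can be rerun alone.
#' @param out_dir output directory.
#' @param n_patients synthetic population size.
#' @param input_dir directory of CSV tables (files mode).
#' @param caliper_mult,max_gap_days,caliper_scale matching parameters.
#' @param channels encounter channels to fit.
#' @param exclude_years relative years excluded from the ITS.
#' @param max_abs_year person-year panel half-width.
#' @param synth further arguments passed to [synth_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), seed = NULL,
                       out_dir = tempfile("portalits-run-"),
                       n_patients = 2000L, input_dir = NULL,
                       caliper_mult = 0.2, max_gap_days = 366,
                       caliper_scale = "logit",
                       channels = c("MD", "NPPA", "TC"),
                       exclude_years = c(0L, 1L), max_abs_year = 8L,
                       synth = list()) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed)) {
    stop("seed is mandatory in synthetic mode")
  }
  if (mode == "files") {
    if (is.null(input_dir)) stop("files mode requires input_dir")
    for (f in c("patients.csv", "encounters.csv", "prescriptions.csv")) {
      p <- file.path(input_dir, f)
      if (!file.exists(p)) stop("missing input table: ", p)
    }
  }
  structure(list(mode = mode, seed = seed, out_dir = out_dir,
                 n_patients = as.integer(n_patients), input_dir = input_dir,
                 caliper_mult = caliper_mult, max_gap_days = max_gap_days,
                 caliper_scale = caliper_scale, channels = channels,
                 exclude_years = as.integer(exclude_years),
                 max_abs_year = as.integer(max_abs_year), synth = synth),
            class = "run_config")
}

#' Read a run configuration from a key-value (DCF) file
#'
#' Recognised keys: `mode`, `seed`, `out_dir`, `n_patients`, `input_dir`,
#' `caliper_mult`, `max_gap_days`, `caliper_scale`, `channels`
#' (comma-separated), `exclude_years` (comma-separated), `max_abs_year`.
#'
#' @param path path to a DCF file (`key: value` lines).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- as.list(read.dcf(path)[1L, ])
  args <- list()
  num <- function(x) as.numeric(x)
  if (!is.null(kv$mode)) args$mode <- kv$mode
  if (!is.null(kv$seed)) args$seed <- as.integer(kv$seed)
  if (!is.null(kv$out_dir)) args$out_dir <- kv$out_dir
  if (!is.null(kv$n_patients)) args$n_patients <- as.integer(kv$n_patients)
  if (!is.null(kv$input_dir)) args$input_dir <- kv$input_dir
  if (!is.null(kv$caliper_mult)) args$caliper_mult <- num(kv$caliper_mult)
  if (!is.null(kv$max_gap_days)) args$max_gap_days <- num(kv$max_gap_days)
  if (!is.null(kv$caliper_scale)) args$caliper_scale <- kv$caliper_scale
  if (!is.null(kv$channels)) {
    args$channels <- trimws(strsplit(kv$channels, ",")[[1]])
  }
  if (!is.null(kv$exclude_years)) {
    args$exclude_years <- as.integer(trimws(
      strsplit(kv$exclude_years, ",")[[1]]))
  }
  if (!is.null(kv$max_abs_year)) {
    args$max_abs_year <- as.integer(kv$max_abs_year)
  }
  do.call(run_config, args)
}

#' Run the full evaluation pipeline
#'
#' Executes generate/load, cohort, covariates, matching, ITS and reporting;
#' writes all rendered outputs plus `manifest.json` (config, per-stage row
#' counts, wall times) under `config$out_dir`.  The same config and seed
#' yield numerically identical outputs.  On stage failure a `FAILED` marker
#' naming the stage is left in the output directory and the error is
#' re-raised.
#'
#' @param config a `run_config` (or a path to a DCF config file).
#' @return a list (invisibly a `run_report`): `cohort`, `covariates`,
#'   `matched` (model/candidates/matches/balance), `panel`, `fits`,
#'   `workload`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t_all <- proc.time()[["elapsed"]]
  current_stage <- "init"
  record <- function(name, rows) {
    stages[[name]] <<- list(rows = rows,
                            seconds = round(proc.time()[["elapsed"]] - t_st, 3))
  }
  fail_marker <- function(e) {
    writeLines(c(paste("stage:", current_stage), paste("error:",
                                                       conditionMessage(e))),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }

  tryCatch({
    current_stage <- "data"; t_st <- proc.time()[["elapsed"]]
    bundle <- if (config$mode == "synthetic") {
      sargs <- utils::modifyList(
        list(n_patients = config$n_patients,
             seed = derive_seed(config$seed, "simulate")),
        config$synth)
      generate_population(do.call(synth_config, sargs))
    } else {
      read_bundle(config$input_dir)
    }
    record("data", nrow(bundle$patients))

    current_stage <- "cohort"; t_st <- proc.time()[["elapsed"]]
    cohort <- build_cohort(bundle)
    record("cohort", nrow(cohort$portal) + nrow(cohort$control))

    current_stage <- "covariates"; t_st <- proc.time()[["elapsed"]]
    covs <- build_covariates(rbind(cohort$portal, cohort$control),
                             cohort$patients, bundle$encounters,
                             bundle$prescriptions)
    record("covariates", nrow(covs))

    current_stage <- "match"; t_st <- proc.time()[["elapsed"]]
    matched <- match_cohort(covs, caliper_mult = config$caliper_mult,
                            max_gap_days = config$max_gap_days,
                            caliper_scale = config$caliper_scale)
    record("match", nrow(matched$matches))

    current_stage <- "its"; t_st <- proc.time()[["elapsed"]]
    panel <- build_panel(matched$matches, cohort, bundle$encounters,
                         max_abs_year = config$max_abs_year)
    fits <- lapply(stats::setNames(config$channels, config$channels),
                   function(ch) fit_its(panel, channel = ch,
                                        exclude_years = config$exclude_years))
    record("its", nrow(panel))

    current_stage <- "report"; t_st <- proc.time()[["elapsed"]]
    workload <- NULL
    if (!is.null(bundle$messages) && nrow(bundle$messages)) {
      yr <- max(as.integer(format(bundle$messages$sent_date, "%Y")))
      workload <- workload_estimate(
        mean_message_time(bundle$messages$minutes),
        messages_per_patient_year(bundle$messages, bundle$patients, yr))
    }
    reg_year <- NULL
    curves <- NULL
    reg_pat <- bundle$patients[!is.na(bundle$patients$portal_date)]
    if (nrow(reg_pat)) {
      reg_year <- stats::setNames(
        as.integer(format(reg_pat$portal_date, "%Y")), reg_pat$patient_id)
      curves <- tryCatch(
        registration_cohort_series(panel, reg_year),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(registration_cohort_series(panel, reg_year))
        })
    }
    files <- render_outputs(
      list(balance = matched$balance, matches = matched$matches,
           panel = panel, fits = fits, cohort_curves = curves,
           workload = workload),
      config$out_dir)
    data.table::fwrite(rbind(cohort$portal, cohort$control),
                       file.path(config$out_dir, "cohort.csv"))
    jsonlite::write_json(
      stats::setNames(as.list(cohort$exclusions$n), cohort$exclusions$reason),
      file.path(config$out_dir, "exclusions.json"),
      auto_unbox = TRUE, digits = NA)
    data.table::fwrite(covs, file.path(config$out_dir, "covariates.csv"))
    record("report", length(files) + 3L)

    manifest <- list(
      package_version = as.character(utils::packageVersion("portalits")),
      config = config[setdiff(names(config), "synth")],
      stages = stages,
      total_seconds = round(proc.time()[["elapsed"]] - t_all, 3)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(structure(
      list(cohort = cohort, covariates = covs, matched = matched,
           panel = panel, fits = fits, workload = workload,
           manifest = manifest),
      class = "run_report"))
  }, error = fail_marker)
}

#' @export
print.run_report <- function(x, ...) {
  cat("portalits pipeline run\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-10s rows %-8d %.2fs\n", s, x$manifest$stages[[s]]$rows,
                x$manifest$stages[[s]]$seconds))
  }
  if (!is.null(x$workload)) print(x$workload)
  invisible(x)
}
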