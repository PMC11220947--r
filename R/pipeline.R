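# End-to-end pipeline: generate/ingest -> screen -> doses -> fits ->
# threshold tables -> report artifacts.

#' Binned dose-distribution summaries per formulation
#'
#' Frequency histograms of the chosen dose re-expressed under every
#' formulation (the machine-readable counterpart of kernel-density dose
#' plots). Total counts per formulation equal the cohort size.
#'
#' @param cohort Screened cohort tibble (needs the chosen dose column).
#' @param dose `"peak"` or `"diagnosis"`.
#' @param binwidth Bin width in ug/kg/min (default 0.05).
#' @param registry Formulation registry.
#' @return Tibble: `formulation`, `bin_left`, `bin_right`, `count`.
#' @export
summarize_distributions <- function(cohort, dose = c("peak", "diagnosis"),
                                    binwidth = 0.05,
                                    registry = ne_formulations()) {
  dose <- match.arg(dose)
  col <- if (dose == "peak") "peak_dose_24h" else "diagnosis_dose"
  stopifnot(nrow(cohort) > 0, binwidth > 0, col %in% names(cohort))
  d_base <- cohort[[col]][!is.na(cohort[[col]])]
  out <- lapply(seq_len(nrow(registry)), function(i) {
    d <- d_base * registry$factor[i]
    idx <- floor(d / binwidth)
    cnt <- table(idx)
    tibble::tibble(formulation = registry$formulation[i],
                   bin_left = as.numeric(names(cnt)) * binwidth,
                   bin_right = (as.numeric(names(cnt)) + 1) * binwidth,
                   count = as.integer(cnt))
  })
  dplyr::bind_rows(out)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = paste0("stage '", stage, "' failed: ",
                                         conditionMessage(e)),
                        call = NULL, stage = stage)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes generate/ingest -> Sepsis-3 screen -> dose extraction and
#' formulation conversion -> logistic fits -> threshold tables, and writes
#' the report bundle: `cohort.csv`, `ledger.json`, `fits.json`,
#' `threshold_peak.csv`, `threshold_diagnosis.csv`, `histograms.csv` and a
#' run `manifest.json` (config hash, seed, package version). Any stage
#' failure aborts with a condition of class `pipeline_error` carrying the
#' stage name.
#'
#' @param config List with exactly one of `generator` (a [cohort_config()])
#'   or `tables_dir` (directory of the five CSV tables); optional `criteria`
#'   (a [screen_criteria()]), `variant` (model variant for
#'   [fit_dose_response()]), `binwidth`, and `out_dir` (default
#'   `"nedose-report"`).
#' @return Invisibly, a list with `screen`, `fits` (per dose variable),
#'   `thresholds`, `histograms` and the output paths.
#' @export
run_pipeline <- function(config) {
  has_gen <- !is.null(config$generator)
  has_dir <- !is.null(config$tables_dir)
  if (has_gen == has_dir) {
    stop("config must supply exactly one of 'generator' or 'tables_dir'",
         call. = FALSE)
  }
  criteria <- config$criteria %||% screen_criteria()
  variant <- config$variant %||% "per_formulation"
  out_dir <- config$out_dir %||% "nedose-report"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- pipeline_stage("ingest", {
    if (has_gen) generate_cohort(config$generator)$tables
    else read_tables(config$tables_dir)
  })
  screen <- pipeline_stage("screen", apply_screen(tables, criteria))
  if (nrow(screen$cohort) == 0) {
    stop("stage 'screen' failed: empty cohort after screening", call. = FALSE)
  }
  fits <- list(); thresholds <- list()
  for (dv in c("peak", "diagnosis")) {
    design <- pipeline_stage("stack",
                             stack_formulations(screen$cohort, dose = dv))
    fits[[dv]] <- pipeline_stage("fit", fit_dose_response(design, variant))
    thresholds[[dv]] <- pipeline_stage("thresholds",
                                       threshold_table(fits[[dv]]))
  }
  hist_tab <- pipeline_stage("histograms",
                             summarize_distributions(
                               screen$cohort, "peak",
                               binwidth = config$binwidth %||% 0.05))

  paths <- pipeline_stage("write", {
    co <- screen$cohort
    for (col in c("t_sepsis", "t_shock")) {
      co[[col]] <- format(co[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
    utils::write.csv(co, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_input = screen$n_input, retained = nrow(screen$cohort),
           exclusions = as.list(screen$ledger)),
      file.path(out_dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(fits, function(f) list(variant = f$variant,
                                    estimates = f$estimates)),
      file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(thresholds$peak,
                     file.path(out_dir, "threshold_peak.csv"),
                     row.names = FALSE)
    utils::write.csv(thresholds$diagnosis,
                     file.path(out_dir, "threshold_diagnosis.csv"),
                     row.names = FALSE)
    utils::write.csv(hist_tab, file.path(out_dir, "histograms.csv"),
                     row.names = FALSE)
    cfg_json <- jsonlite::toJSON(
      list(generator = if (has_gen) unclass(config$generator),
           tables_dir = config$tables_dir,
           criteria = unclass(criteria), variant = variant),
      digits = NA, null = "null", auto_unbox = TRUE)
    jsonlite::write_json(
      list(config_hash = fnv1a_hash(cfg_json),
           seed = if (has_gen) config$generator$seed,
           package_version = as.character(utils::packageVersion("nedose")),
           r_version = as.character(getRversion())),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    file.path(out_dir, c("cohort.csv", "ledger.json", "fits.json",
                         "threshold_peak.csv", "threshold_diagnosis.csv",
                         "histograms.csv", "manifest.json"))
  })
  invisible(list(screen = screen, fits = fits, thresholds = thresholds,
                 histograms = hist_tab, paths = paths))
}
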