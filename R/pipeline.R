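#' Configuration for the end-to-end synthetic washout analysis
#'
#' Bundles the analog presets, recording protocol, noise level, replicate
#' counts and seeds for [run_pipeline()]. The default replicate counts
#' (7, 3, 4 for C3, C6, C10) mirror the patch counts of the emulated study.
#' Replicate seeds are `seed + 1, ..., seed + n` per analog so the whole
#' pipeline is reproducible from a single integer.
#'
#' @param presets named list of [analog_preset()] objects (>= 1).
#' @param protocol a [protocol()].
#' @param noise_sd relative noise level passed to [generate_trace()].
#' @param replicates integer vector of replicate counts, one per preset.
#' @param seed base integer seed.
#' @param out_dir directory for output tables, or `NULL` to skip writing.
#' @param write_traces if `TRUE`, also write each trace CSV (large files).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(presets = analog_presets(c("CFTRi-C3", "CFTRi-C6",
                                                       "CFTRi-C10")),
                            protocol = memwash::protocol(),
                            noise_sd = 0.05,
                            replicates = c(7L, 3L, 4L)[seq_along(presets)],
                            seed = 1L,
                            out_dir = NULL,
                            write_traces = FALSE) {
  stopifnot(is.list(presets), length(presets) >= 1,
            all(vapply(presets, inherits, TRUE, "analog_preset")),
            inherits(protocol, "protocol"),
            length(replicates) == length(presets), all(replicates >= 1),
            noise_sd >= 0)
  structure(list(presets = presets, protocol = protocol, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 out_dir = out_dir, write_traces = isTRUE(write_traces)),
            class = "pipeline_config")
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic washout analysis
#'
#' For each analog preset: generate seeded replicate traces, estimate
#' fold-potentiation and fit the washout decay constant per trace, then
#' summarize replicates; finally fit the one-parameter logP rate model
#' across analogs and report its scale and r2. With an `out_dir` set in the
#' config, writes `replicates.csv` (analog, seed, potentiation, tau_s),
#' `summary.csv` (per-analog mean/sd/n), `analogs.csv` (the replicate table
#' in [read_analog_csv()] format) and `report.json`. Identical config and
#' seeds produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list (class `"pipeline_report"`) with `replicates` and
#'   `summary` data frames, the `rate_fit` ([fit_rate_model()] result) and
#'   `schema_version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$presets) < 2L)
    .stage("fit_rate_model",
           stop("the logP rate model needs at least 2 analogs; ",
                "configure more presets"))

  rows <- list()
  for (i in seq_along(config$presets)) {
    preset <- config$presets[[i]]
    for (r in seq_len(config$replicates[i])) {
      seed_r <- config$seed + r
      tr <- .stage("generate_trace",
                   generate_trace(preset, config$protocol,
                                  noise_sd = config$noise_sd, seed = seed_r))
      pot <- .stage("estimate_potentiation", estimate_potentiation(tr))
      fw <- .stage("fit_washout", fit_washout(tr))
      if (config$write_traces && !is.null(config$out_dir))
        write_trace_csv(tr, file.path(config$out_dir,
                                      sprintf("trace_%s_seed%d.csv",
                                              gsub("[^A-Za-z0-9]", "_",
                                                   preset$name), seed_r)))
      rows[[length(rows) + 1L]] <- data.frame(
        analog = preset$name, rgroup_logP = preset$rgroup_logP,
        seed = seed_r, potentiation = pot, tau_s = fw$tau,
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(split(reps, reps$analog)[unique(reps$analog)],
                                function(d) {
    sp <- summarize_replicates(d$potentiation)
    st <- summarize_replicates(d$tau_s)
    data.frame(analog = d$analog[1], rgroup_logP = d$rgroup_logP[1],
               n = sp$n,
               potentiation_mean = sp$mean, potentiation_sd = sp$sd,
               tau_mean_s = st$mean, tau_sd_s = st$sd,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  records <- .stage("fit_rate_model", lapply(
    split(reps, reps$analog)[unique(reps$analog)],
    function(d) analog_record(d$analog[1], d$rgroup_logP[1], d$tau_s)))
  fit <- .stage("fit_rate_model", fit_rate_model(records))

  report <- structure(list(replicates = reps, summary = summ,
                           rate_fit = fit, schema_version = "1.0"),
                      class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(reps, file.path(config$out_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    write_analog_csv(records, file.path(config$out_dir, "analogs.csv"))
    jsonlite::write_json(
      list(schema_version = report$schema_version,
           summary = summ,
           rate_model = list(scale = fit$scale, r2 = fit$r2,
                             loss = fit$loss, per_analog = fit$per_analog)),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Synthetic washout analysis\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$rate_fit)
  invisible(x)
}
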