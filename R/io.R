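#' Read and write kinetic parameters as JSON
#'
#' JSON objects with keys `k_a`, `k_minus_a`, `k_lw`, `k_wl`, `P_t`.
#'
#' @param params a [kinetic_params()] object.
#' @param path file path.
#' @return `read_params_json()` returns a [kinetic_params()] object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k_a", "k_minus_a", "k_lw", "k_wl", "P_t")
  if (!all(need %in% names(x)))
    stop("parameter JSON must have keys: ", paste(need, collapse = ", "))
  kinetic_params(x$k_a, x$k_minus_a, x$k_lw, x$k_wl, x$P_t)
}

#' Read and write occupancy trajectories as CSV
#'
#' Columns `time_s`, `bound_fraction`, `membrane_conc`.
#'
#' @param traj an [occupancy_trajectory()].
#' @param path file path.
#' @param mode trajectory mode to tag the re-read object with.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "occupancy_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, mode = "linear") {
  df <- utils::read.csv(path)
  occupancy_trajectory(df$time_s, df$bound_fraction, df$membrane_conc,
                       mode = mode)
}

#' Read and write patch traces as CSV with a JSON metadata sidecar
#'
#' The trace CSV has columns `time_s`, `current`, `segment`; the sidecar
#' (`<path>.json`) records the preset name, seed, noise level and protocol.
#'
#' @param trace a [generate_trace()] result.
#' @param path CSV file path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "patch_trace"))
  utils::write.csv(as.data.frame(trace)[c("time_s", "current", "segment")],
                   path, row.names = FALSE)
  meta <- attr(trace, "meta")
  meta$protocol <- unclass(meta$protocol)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "current", "segment")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$protocol)) meta$protocol <- do.call(protocol, meta$protocol)
    attr(df, "meta") <- meta
  }
  class(df) <- c("patch_trace", "data.frame")
  df
}
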