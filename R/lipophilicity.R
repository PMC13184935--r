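#' Per-analog record of R-group logP and replicate washout constants
#'
#' @param name analog label.
#' @param rgroup_logP logP of the conjugated R group (dimensionless, finite).
#' @param taus replicate washout time constants (seconds, all > 0).
#' @return An object of class `"analog_record"`; `rates` holds the
#'   reciprocal time constants (per second).
#' @export
analog_record <- function(name, rgroup_logP, taus) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(rgroup_logP), length(rgroup_logP) == 1L,
            is.finite(rgroup_logP))
  if (length(taus) == 0L || any(!is.finite(taus)) || any(taus <= 0))
    stop("'taus' must be positive and finite")
  structure(list(name = name, rgroup_logP = rgroup_logP,
                 taus = as.numeric(taus), rates = 1 / as.numeric(taus)),
            class = "analog_record")
}

#' Ratio of membrane dissociation rates from R-group logP
#'
#' The free-energy cost of moving an R group from lipid to water scales with
#' its logP, which gives the ratio of membrane-to-water exit rates for two
#' analogs as
#' \deqn{k_{lw,1} / k_{lw,2} = 10^{-logP_1/2} / 10^{-logP_2/2}
#'       = 10^{(logP_2 - logP_1)/2}.}
#' The square root (the /2) reflects the transition state sitting roughly
#' halfway along the transfer coordinate.
#'
#' @param logP1,logP2 R-group logP values of the two analogs.
#' @return `k_lw` of analog 1 over `k_lw` of analog 2.
#' @examples
#' klw_ratio(5, 3)  # more lipophilic analog exits 10x slower
#' @export
klw_ratio <- function(logP1, logP2) {
  stopifnot(is.finite(logP1), is.finite(logP2))
  10^((logP2 - logP1) / 2)
}

#' Predicted washout rate from R-group logP
#'
#' In the fast-rebinding regime the washout rate is proportional to `k_lw`
#' (`1/T = 1.53 K_d k_lw / P_t`), so combining with the logP scaling gives
#' `rate = scale * 10^(-logP/2)` with a single free proportionality constant
#' shared by the series. The predicted time constant is the reciprocal rate.
#'
#' @param logP R-group logP (vectorized).
#' @param scale proportionality constant (per second, > 0).
#' @return Predicted washout rate(s), per second.
#' @export
predict_rate <- function(logP, scale) {
  if (scale <= 0) stop("'scale' must be positive")
  scale * 10^(-logP / 2)
}

#' Fit the one-parameter logP rate model to a washout series
#'
#' Finds the proportionality constant `A` in `rate = A * 10^(-logP/2)` by
#' minimizing the squared errors in the ratios of actual to predicted time
#' constants, \eqn{\sum_i (\bar T_i / \hat T_i(A) - 1)^2}, over the per-analog
#' mean time constants \eqn{\bar T_i}. The ratio loss weights every analog
#' equally instead of biasing the fit toward analogs with large absolute time
#' constants. Because \eqn{\bar T_i/\hat T_i = A \bar T_i 10^{-logP_i/2}} is
#' linear in `A`, the minimizer is closed form:
#' \eqn{A = \sum u_i / \sum u_i^2} with \eqn{u_i = \bar T_i 10^{-logP_i/2}}.
#' A log-ratio loss \eqn{\sum (\log(\bar T_i/\hat T_i))^2} is available as an
#' option (its minimizer is the geometric mean correction).
#'
#' The goodness of fit `r2 = 1 - SS_res / SS_tot` is computed on the
#' per-analog mean experimental rates (`1/T_i`) about their grand mean, not
#' on time constants.
#'
#' @param records list of [analog_record()] objects (>= 2 analogs).
#' @param loss `"ratio"` (default) or `"log_ratio"`.
#' @return An object of class `"rate_model_fit"`: list with `scale`, `r2`,
#'   `loss`, and `per_analog`, a data frame with one row per analog (name,
#'   logP, mean tau, predicted tau, mean rate, predicted rate, ratio of
#'   actual to predicted tau).
#' @examples
#' recs <- list(analog_record("a", 2, 1 / 0.3 / 10^(-1)),
#'              analog_record("b", 4, 1 / 0.3 / 10^(-2)))
#' fit_rate_model(recs)$scale  # 0.3
#' @export
fit_rate_model <- function(records, loss = c("ratio", "log_ratio")) {
  loss <- match.arg(loss)
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE,
                                         "analog_record")))
  if (length(records) < 2L)
    stop("need at least 2 analogs to fit the rate model")
  mean_tau <- vapply(records, function(r) mean(r$taus), 0)
  logP <- vapply(records, `[[`, 0, "rgroup_logP")
  u <- mean_tau * 10^(-logP / 2)      # = (T_bar / T_hat) / scale
  scale <- if (loss == "ratio") sum(u) / sum(u * u)
           else exp(-mean(log(u)))
  pred_rate <- predict_rate(logP, scale)
  mean_rate <- 1 / mean_tau
  ss_res <- sum((mean_rate - pred_rate)^2)
  ss_tot <- sum((mean_rate - mean(mean_rate))^2)
  r2 <- 1 - ss_res / ss_tot
  per <- data.frame(
    name = vapply(records, `[[`, "", "name"),
    rgroup_logP = logP,
    mean_tau_s = mean_tau,
    predicted_tau_s = 1 / pred_rate,
    mean_rate = mean_rate,
    predicted_rate = pred_rate,
    tau_ratio = mean_tau * pred_rate,
    stringsAsFactors = FALSE
  )
  structure(list(scale = scale, r2 = r2, loss = loss, per_analog = per),
            class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat(sprintf("logP rate model: rate = %.4g * 10^(-logP/2) /s   (r2 = %.3f)\n",
              x$scale, x$r2))
  print(x$per_analog, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-analog standard deviation of replicate washout rates
#'
#' Sample SD of the reciprocal time constants for each analog, the error
#' bars of the rate-vs-logP plot. A single replicate yields SD 0 with a
#' warning.
#'
#' @inheritParams fit_rate_model
#' @return Named numeric vector of rate SDs (per second).
#' @export
rate_error_bars <- function(records) {
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE,
                                         "analog_record")))
  out <- vapply(records, function(r) {
    if (length(r$rates) < 2L) {
      warning(sprintf("analog '%s' has a single replicate; SD set to 0",
                      r$name))
      0
    } else stats::sd(r$rates)
  }, 0)
  stats::setNames(out, vapply(records, `[[`, "", "name"))
}

#' Read / write an analog replicate table
#'
#' CSV with one row per replicate and columns `analog`, `rgroup_logP`,
#' `tau_s`.
#'
#' @param path file path.
#' @return `read_analog_csv()` returns a list of [analog_record()] objects.
#' @export
read_analog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analog", "rgroup_logP", "tau_s")
  if (!all(need %in% names(df)))
    stop("analog table must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$analog), function(d)
    analog_record(d$analog[1], d$rgroup_logP[1], d$tau_s))
}

#' @rdname read_analog_csv
#' @param records list of [analog_record()] objects to write.
#' @export
write_analog_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(analog = r$name, rgroup_logP = r$rgroup_logP, tau_s = r$taus,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
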