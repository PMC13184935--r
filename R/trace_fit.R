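#' Estimate fold-potentiation from a trace
#'
#' Ratio of the mean current over the plateau of the drug segment to the mean
#' current over the plateau of the baseline segment. The plateau is the final
#' `plateau_frac` (default 25%) of each segment, which excludes the
#' equilibration transient without assuming anything about the kinetics; at
#' least 1 s of plateau is required in each segment.
#'
#' @param trace a [generate_trace()] result or any data frame with `time_s`,
#'   `current` and `segment` columns.
#' @param plateau_frac fraction of each segment treated as plateau.
#' @return Fold-potentiation (dimensionless).
#' @export
estimate_potentiation <- function(trace, plateau_frac = 0.25) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "current", "segment") %in% names(trace)))
  plateau_mean <- function(seg) {
    idx <- which(trace$segment == seg)
    if (length(idx) == 0L) stop(sprintf("trace has no '%s' segment", seg))
    tt <- trace$time_s[idx]
    t_cut <- tt[1] + (1 - plateau_frac) * (tt[length(idx)] - tt[1])
    keep <- idx[tt >= t_cut]
    if (diff(range(trace$time_s[keep])) < 1)
      stop(sprintf("'%s' plateau shorter than 1 s", seg))
    mean(trace$current[keep])
  }
  base <- plateau_mean("baseline")
  drug <- plateau_mean("drug")
  if (base <= 0) stop("non-positive baseline plateau current")
  drug / base
}

#' Fit a single-exponential decay to the washout segment
#'
#' Nonlinear least squares of `offset + amplitude * exp(-(t - t0) / tau)`
#' over the washout window, from washout onset to the first crossing of 5%
#' of the decay amplitude (or the segment end if the trace is truncated
#' earlier). A free offset absorbs residual baseline current, since washed
#' patches return toward but not exactly to baseline. Initial guesses come
#' from the segment endpoints and a log-linear regression on the upper half
#' of the decay; optimization uses Levenberg-Marquardt with a relative
#' parameter tolerance of 1e-8 and at most 200 iterations.
#'
#' The decay amplitude must exceed three times the noise standard deviation
#' (estimated from first differences of the washout current), otherwise there
#' is no resolvable decay and an error is raised.
#'
#' @inheritParams estimate_potentiation
#' @param frac window cutoff as a fraction of the decay amplitude.
#' @return An object of class `"washout_fit"`: a list with `tau` (seconds),
#'   `amplitude`, `offset`, `rss` and `window` (`c(start_s, end_s)`).
#' @export
fit_washout <- function(trace, frac = 0.05) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "current", "segment") %in% names(trace)))
  idx <- which(trace$segment == "washout")
  if (length(idx) < 20L) stop("trace has no usable 'washout' segment")
  tt <- trace$time_s[idx]
  y <- trace$current[idx]
  t0 <- tt[1]

  n <- length(y)
  head_mean <- mean(y[seq_len(max(5L, n %/% 1000L))])
  tail_mean <- mean(y[seq(n - max(5L, round(0.01 * n)) + 1L, n)])
  amp0 <- head_mean - tail_mean
  noise_sd <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(amp0) || amp0 <= 3 * noise_sd)
    stop("washout decay amplitude does not exceed 3x the noise floor; ",
         "no resolvable decay")

  # model-free window end: first smoothed crossing of frac * amplitude.
  # Smoothing over ~1% of the segment keeps the crossing (and hence the
  # window) stable against noise.
  k <- min(2001L, max(5L, n %/% 100L))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  cross <- which(!is.na(ys) & ys - tail_mean <= frac * amp0)
  iend <- if (length(cross)) max(cross[1], 20L) else n
  tw <- tt[seq_len(iend)]
  yw <- y[seq_len(iend)]

  # log-linear initial guess for tau on the upper half of the decay
  upper <- which(yw - tail_mean > 0.5 * amp0)
  tau0 <- if (length(upper) >= 5L) {
    z <- log(yw[upper] - tail_mean)
    fit0 <- stats::lm.fit(cbind(1, tw[upper] - t0), z)
    sl <- unname(fit0$coefficients[2])
    if (is.finite(sl) && sl < 0) -1 / sl else (tw[iend] - t0) / 3
  } else (tw[iend] - t0) / 3

  df <- data.frame(t = tw - t0, y = yw)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-t / tau),
      data = df,
      start = list(offset = unname(tail_mean), amplitude = unname(amp0),
                   tau = unname(tau0)),
      lower = c(-Inf, 0, .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-8)
    ),
    error = function(e) stop("washout fit did not converge: ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  structure(
    list(tau = unname(cf["tau"]), amplitude = unname(cf["amplitude"]),
         offset = unname(cf["offset"]),
         rss = sum(stats::residuals(fit)^2),
         window = c(t0, tw[iend])),
    class = "washout_fit"
  )
}

#' @export
print.washout_fit <- function(x, ...) {
  cat(sprintf(
    "Washout fit: tau = %.4g s, amplitude = %.4g, offset = %.4g\n",
    x$tau, x$amplitude, x$offset))
  cat(sprintf("  window %.2f - %.2f s, RSS = %.4g\n",
              x$window[1], x$window[2], x$rss))
  invisible(x)
}

#' Summarize replicate measurements
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and count,
#' the mean +/- SD (n) convention used to report replicate potentiation and
#' washout constants.
#'
#' @param values numeric vector of replicate measurements (length >= 1).
#' @return An object of class `"replicate_summary"`: list with `mean`, `sd`,
#'   `n`. For a single value `sd` is 0.
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0L) stop("no values to summarize")
  stopifnot(is.numeric(values), all(is.finite(values)))
  structure(
    list(mean = mean(values),
         sd = if (length(values) > 1L) stats::sd(values) else 0,
         n = length(values)),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%.3g +/- %.3g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}
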