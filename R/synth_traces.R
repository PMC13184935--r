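#' Recording protocol for a synthetic patch-clamp trace
#'
#' Describes the three-phase inside-out patch protocol: a PKA/ATP-activated
#' baseline, drug application at a fixed bath concentration, and washout with
#' drug-free solution. Current is sampled at `sample_rate` (500 Hz by
#' default, the acquisition rate of the emulated recordings).
#'
#' @param sample_rate samples per second (Hz).
#' @param baseline_s baseline duration (seconds).
#' @param drug_s drug-application duration (seconds).
#' @param washout_s washout duration (seconds).
#' @param bath_conc aqueous drug concentration during the drug phase
#'   (arbitrary concentration units, same scale as the kinetic parameters).
#' @return An object of class `"protocol"`.
#' @export
protocol <- function(sample_rate = 500, baseline_s = 10, drug_s = 30,
                     washout_s = 600, bath_conc = 0.05) {
  if (sample_rate <= 0) stop("'sample_rate' must be positive")
  if (baseline_s <= 0 || drug_s <= 0 || washout_s <= 0)
    stop("all protocol durations must be positive")
  if (bath_conc < 0) stop("'bath_conc' must be non-negative")
  structure(list(sample_rate = sample_rate, baseline_s = baseline_s,
                 drug_s = drug_s, washout_s = washout_s,
                 bath_conc = bath_conc),
            class = "protocol")
}

#' Per-analog simulation preset
#'
#' Couples an analog label with its fold-potentiation, kinetic parameters and
#' the logP of its conjugated R group. See [analog_presets()] for the packaged
#' series.
#'
#' @param name analog label.
#' @param fold_potentiation steady-state current with drug over baseline
#'   current (>= 1).
#' @param kinetics a [kinetic_params()] object.
#' @param rgroup_logP logP of the conjugated R group (dimensionless).
#' @return An object of class `"analog_preset"`.
#' @export
analog_preset <- function(name, fold_potentiation, kinetics, rgroup_logP) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(kinetics, "kinetic_params"),
            is.numeric(rgroup_logP), is.finite(rgroup_logP))
  if (fold_potentiation < 1) stop("'fold_potentiation' must be >= 1")
  structure(list(name = name, fold_potentiation = fold_potentiation,
                 kinetics = kinetics, rgroup_logP = rgroup_logP),
            class = "analog_preset")
}

# Shared protein-side kinetics across the series: the alkyl tail points into
# the lipid, so protein-ligand affinity is treated as R-group independent.
# K_d = 0.01 (arb. conc.), deep fast-rebinding regime.
.preset_shared <- list(k_a = 1e4, k_minus_a = 100, P_t = 1)

# membrane/water partition ratio k_wl / k_lw, shared across analogs
.preset_partition <- 1000

# k_lw for the parent scaffold (isobutyl R group), per second; analogs scale
# from it by 10^(-dlogP/2)
.preset_klw_ref <- 13
.preset_logP_ref <- 2.0

.preset_kinetics <- function(rgroup_logP) {
  k_lw <- .preset_klw_ref *
    10^(-(rgroup_logP - .preset_logP_ref) / 2)
  kinetic_params(k_a = .preset_shared$k_a,
                 k_minus_a = .preset_shared$k_minus_a,
                 k_lw = k_lw, k_wl = .preset_partition * k_lw,
                 P_t = .preset_shared$P_t)
}

#' Packaged analog presets
#'
#' The potentiator series: the parent scaffold (ABBV-974), its isobutyl
#' analog (CFTRi-C3, kinetically equivalent to the parent), the hexyl
#' (CFTRi-C6) and decyl (CFTRi-C10) chain-extended analogs, and the
#' NBD-labeled fluorescent probe (CFTRi-NBD). Fold-potentiation values are
#' the measured means of the emulated series (2.94, 1.74 and 2.52 for
#' C3/parent, C6 and C10). The probe's fold is nominal (set to the parent's;
#' no measured value exists) and its washout mirrors the parent's.
#'
#' R-group logP values are fragment estimates (isobutyl 2.0, hexyl 3.0,
#' decyl 5.0; about 0.5 per CH2) and are inputs to the simulation, not
#' measured ground truth; override them via [analog_preset()]. Membrane exit
#' rates `k_lw` scale from the parent's by `10^(-dlogP/2)`, so washout slows
#' with chain length (C3 < C6 < C10 time constants). Protein-side kinetics
#' are shared across the series.
#'
#' @param names which presets to return (default: all five).
#' @return A named list of [analog_preset()] objects.
#' @examples
#' pr <- analog_presets(c("CFTRi-C3", "CFTRi-C10"))
#' sapply(pr, function(p) p$kinetics$k_lw)
#' @export
analog_presets <- function(names = NULL) {
  tab <- list(
    `ABBV-974`  = list(fold = 2.94, logP = 2.0),
    `CFTRi-C3`  = list(fold = 2.94, logP = 2.0),
    `CFTRi-C6`  = list(fold = 1.74, logP = 3.0),
    `CFTRi-C10` = list(fold = 2.52, logP = 5.0),
    `CFTRi-NBD` = list(fold = 2.94, logP = 2.0)
  )
  if (is.null(names)) names <- base::names(tab)
  missing <- setdiff(names, base::names(tab))
  if (length(missing))
    stop("unknown preset(s): ", paste(missing, collapse = ", "))
  out <- lapply(names, function(nm) {
    analog_preset(nm, tab[[nm]]$fold, .preset_kinetics(tab[[nm]]$logP),
                  tab[[nm]]$logP)
  })
  stats::setNames(out, names)
}

#' Map occupancy to macroscopic current
#'
#' Linear potentiation: current is `baseline * (1 + (fold - 1) * bound)`, so
#' zero occupancy gives the baseline current and full occupancy the
#' fold-potentiated current. Potentiated (inward) currents are reported
#' positive.
#'
#' @param bound fractional occupancy in \[0, 1\] (vectorized).
#' @param baseline_current baseline current (arbitrary units, > 0).
#' @param fold fold-potentiation at full occupancy (>= 1).
#' @return Current, same length as `bound`.
#' @export
occupancy_to_current <- function(bound, baseline_current, fold) {
  if (any(bound < -1e-9 | bound > 1 + 1e-9)) stop("'bound' must be in [0, 1]")
  if (fold < 1) stop("'fold' must be >= 1")
  if (baseline_current <= 0) stop("'baseline_current' must be positive")
  baseline_current * (1 + (fold - 1) * pmin(pmax(bound, 0), 1))
}

#' Drug loading with the bath clamped at a fixed concentration
#'
#' Integrates the full three-state scheme during drug application: the
#' aqueous compartment is held at `bath_conc` by perfusion, the membrane
#' loads at `k_wl * bath_conc` and drains at `k_lw`, and binding follows
#' mass action with a saturable site pool. Occupancy rises monotonically to
#' the steady state, at which the membrane concentration equals
#' `bath_conc * k_wl / k_lw` (perfusion balances escape regardless of
#' binding).
#'
#' @inheritParams Kd
#' @param bath_conc clamped aqueous concentration (> 0 to load).
#' @param times strictly increasing time grid starting at 0 (seconds).
#' @param b0,m0 initial occupancy and membrane concentration (default: naive
#'   patch, both zero).
#' @return An [occupancy_trajectory()] with `mode = "saturable"`.
#' @export
simulate_loading <- function(params, bath_conc, times, b0 = 0, m0 = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (bath_conc < 0) stop("'bath_conc' must be non-negative")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (params$k_wl == 0 && bath_conc > 0)
    warning("k_wl = 0: membrane never loads from the bath")
  rhs <- function(t, y, p) {
    B <- y[1]; M <- y[2]
    bind <- params$k_a * (params$P_t - B) * M
    unbind <- params$k_minus_a * B
    list(c(bind - unbind,
           params$k_wl * bath_conc - params$k_lw * M + unbind - bind))
  }
  sol <- deSolve::lsoda(y = c(B = params$P_t * b0, M = m0), times = times,
                        func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  occupancy_trajectory(times, sol[, "B"] / params$P_t, sol[, "M"],
                       mode = "saturable", params = params)
}

# run body() with the global RNG seeded, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic per-segment sub-seed from the trace seed
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435761) %% 2147483647)
}

# integrate a phase on a coarse grid and spline occupancy/membrane onto the
# sampling grid; occupancy is smooth so the interpolation error is negligible
.phase_on_grid <- function(solver, duration, t_grid, n_coarse = 2001) {
  coarse <- solver(seq(0, duration, length.out = n_coarse))
  list(bound = stats::spline(coarse$time_s, coarse$bound_fraction,
                             xout = t_grid)$y,
       membrane = stats::spline(coarse$time_s, coarse$membrane_conc,
                                xout = t_grid)$y,
       end = coarse[nrow(coarse), ])
}

#' Generate a synthetic inside-out patch-clamp trace
#'
#' Concatenates a baseline phase (no drug), a drug-application phase (bath
#' clamped at the protocol concentration) and a washout phase (drug-free
#' bath), mapping occupancy to current with [occupancy_to_current()] and
#' adding white Gaussian noise of standard deviation
#' `noise_sd * baseline_current`. The deterministic model curve underneath a
#' given preset and protocol is seed-independent; the same seed reproduces
#' the identical trace bit for bit. An optional two-pass moving-average
#' low-pass (off by default) stands in for the recording chain's output
#' filter; its shape is irrelevant for decay constants much slower than
#' 10 ms.
#'
#' @param preset an [analog_preset()].
#' @param protocol a [protocol()].
#' @param noise_sd noise standard deviation relative to the baseline current.
#' @param seed integer seed for the noise stream.
#' @param baseline_current baseline current amplitude (arbitrary units).
#' @param lowpass if `TRUE`, apply a two-pass moving-average low-pass with a
#'   nominal 100 Hz cutoff.
#' @return A data frame of class `"patch_trace"` with columns `time_s`,
#'   `current`, `segment` (`baseline`/`drug`/`washout`) and a `meta`
#'   attribute recording the preset name, seed, noise level and protocol.
#' @examples
#' tr <- generate_trace(analog_presets("CFTRi-C3")[[1]],
#'                      protocol(washout_s = 30), noise_sd = 0.05, seed = 1)
#' estimate_potentiation(tr)
#' @export
generate_trace <- function(preset, protocol, noise_sd = 0.05, seed = 1,
                           baseline_current = 10, lowpass = FALSE) {
  stopifnot(inherits(preset, "analog_preset"), inherits(protocol, "protocol"))
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  dt <- 1 / protocol$sample_rate
  p <- preset$kinetics

  t_base <- seq(0, protocol$baseline_s - dt, by = dt)
  t_drug <- seq(0, protocol$drug_s - dt, by = dt)
  t_wash <- seq(0, protocol$washout_s - dt, by = dt)

  b_base <- numeric(length(t_base))
  drug <- .phase_on_grid(function(tt)
    simulate_loading(p, protocol$bath_conc, tt), protocol$drug_s, t_drug)
  L_end <- drug$end$membrane_conc + p$P_t * drug$end$bound_fraction
  wash <- .phase_on_grid(function(tt)
    washout_saturable(p, L_end, tt, method = "full",
                      b0 = drug$end$bound_fraction,
                      m0 = drug$end$membrane_conc),
    protocol$washout_s, t_wash)

  bound <- c(b_base, drug$bound, wash$bound)
  times <- c(t_base,
             protocol$baseline_s + t_drug,
             protocol$baseline_s + protocol$drug_s + t_wash)
  segment <- rep(c("baseline", "drug", "washout"),
                 c(length(t_base), length(t_drug), length(t_wash)))
  current <- occupancy_to_current(pmin(pmax(bound, 0), 1),
                                  baseline_current,
                                  preset$fold_potentiation)
  if (noise_sd > 0) {
    lens <- c(length(t_base), length(t_drug), length(t_wash))
    noise <- unlist(lapply(seq_along(lens), function(k) {
      .with_seed(.sub_seed(seed, k), stats::rnorm(lens[k]))
    }), use.names = FALSE)
    current <- current + noise_sd * baseline_current * noise
  }
  if (lowpass) {
    k <- max(1L, round(protocol$sample_rate / 100 / 2))
    w <- rep(1 / (2 * k + 1), 2 * k + 1)
    for (i in 1:2)
      current <- as.numeric(stats::filter(current, w, sides = 2))
    keep <- !is.na(current)
    times <- times[keep]; current <- current[keep]; segment <- segment[keep]
    bound <- bound[keep]
  }
  out <- data.frame(time_s = times, current = current, segment = segment,
                    stringsAsFactors = FALSE)
  attr(out, "meta") <- list(preset = preset$name, seed = seed,
                            noise_sd = noise_sd,
                            baseline_current = baseline_current,
                            fold_potentiation = preset$fold_potentiation,
                            protocol = protocol)
  attr(out, "bound") <- bound
  class(out) <- c("patch_trace", "data.frame")
  out
}

#' @export
print.patch_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Synthetic patch-clamp trace: %s (seed %s, noise %g)\n",
              meta$preset, meta$seed, meta$noise_sd))
  for (seg in unique(x$segment)) {
    r <- range(x$time_s[x$segment == seg])
    cat(sprintf("  %-8s %8.1f - %8.1f s\n", seg, r[1], r[2]))
  }
  invisible(x)
}
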