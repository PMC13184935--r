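#' Rate constants of the three-state washout scheme
#'
#' Bundles the rate constants of the water/membrane/protein-bound kinetic
#' scheme that governs potentiator washout. A ligand in the membrane either
#' binds the protein (rate `k_a * [P_t]`, with `P_t` the total concentration of
#' protein sites) or escapes to water (rate `k_lw`); a bound ligand dissociates
#' back into the membrane at `k_minus_a`; aqueous ligand re-enters the membrane
#' at `k_wl` (inactive during washout, when the bath is drug-free).
#'
#' Time is in seconds throughout; concentrations are in arbitrary units with
#' the dissociation constant `K_d = k_minus_a / k_a` as the natural scale.
#'
#' @param k_a protein association rate constant (per concentration per second).
#' @param k_minus_a protein dissociation rate constant (per second).
#' @param k_lw membrane-to-water rate constant (per second).
#' @param k_wl water-to-membrane rate constant (per second); only used while
#'   drug is present in the bath.
#' @param P_t total concentration of protein binding sites (> 0).
#' @return An object of class `"kinetic_params"`.
#' @seealso [Kd()], [classify_regime()], [scenario1_tau()], [scenario2_tau()]
#' @examples
#' p <- kinetic_params(k_a = 100, k_minus_a = 1, k_lw = 5, k_wl = 50, P_t = 1)
#' Kd(p)
#' classify_regime(p)
#' @export
kinetic_params <- function(k_a, k_minus_a, k_lw, k_wl = 0, P_t = 1) {
  for (nm in c("k_a", "k_minus_a", "k_lw", "k_wl", "P_t")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
    if (v < 0) stop(sprintf("'%s' must be non-negative", nm))
  }
  if (P_t <= 0) stop("'P_t' must be strictly positive")
  structure(
    list(k_a = k_a, k_minus_a = k_minus_a, k_lw = k_lw, k_wl = k_wl, P_t = P_t),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Three-state washout kinetics\n")
  cat(sprintf("  k_a  = %g /conc/s   k_-a = %g /s   (K_d = %s)\n",
              x$k_a, x$k_minus_a,
              if (x$k_a > 0) format(x$k_minus_a / x$k_a) else "undefined"))
  cat(sprintf("  k_lw = %g /s        k_wl = %g /s\n", x$k_lw, x$k_wl))
  cat(sprintf("  [P_t] = %g   regime: %s\n", x$P_t, classify_regime(x)))
  invisible(x)
}

#' Equilibrium dissociation constant
#'
#' `K_d = k_minus_a / k_a`. Requesting `K_d` for a scheme with `k_a = 0`
#' (no binding) is an error.
#'
#' @param params a [kinetic_params()] object.
#' @return The dissociation constant, in concentration units.
#' @export
Kd <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k_a <= 0)
    stop("K_d is undefined when k_a = 0 (no protein binding)")
  params$k_minus_a / params$k_a
}

#' Is binding favorable at this site density?
#'
#' Binding is favorable when dissociation is slower than rebinding from the
#' membrane, i.e. `k_minus_a < k_a * P_t` (equivalently `P_t > K_d`).
#'
#' @inheritParams Kd
#' @return `TRUE` or `FALSE`.
#' @export
binding_favorable <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k_minus_a < params$k_a * params$P_t
}

#' Classify the washout kinetic regime
#'
#' A membrane-resident ligand either escapes to water or rebinds the protein.
#' When escape dominates (`k_lw >> k_a * P_t`) protein dissociation is rate
#' limiting and washout decays with time constant `1/k_minus_a` (scenario 1).
#' When rebinding dominates (`k_a * P_t >> k_lw`) the ligand shuttles between
#' protein and membrane many times before escaping and the decay slows to
#' `P_t / (1.53 * K_d * k_lw)` (scenario 2). The `>>` is operationalized as a
#' configurable factor (default 10, the conventional order-of-magnitude
#' criterion).
#'
#' @inheritParams Kd
#' @param threshold separation factor interpreted as "much greater than".
#' @return `"scenario-1"`, `"scenario-2"` or `"intermediate"`.
#' @export
classify_regime <- function(params, threshold = 10) {
  stopifnot(inherits(params, "kinetic_params"), threshold >= 1)
  rebind <- params$k_a * params$P_t
  if (params$k_lw >= threshold * rebind) "scenario-1"
  else if (rebind >= threshold * params$k_lw) "scenario-2"
  else "intermediate"
}

#' Washout time constant in the fast-escape regime (scenario 1)
#'
#' With `k_lw >> k_a * P_t` every dissociation event is terminal, so the
#' current decays exponentially with the protein residence time `1/k_minus_a`.
#'
#' @inheritParams Kd
#' @return Time constant in seconds.
#' @export
scenario1_tau <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k_minus_a <= 0)
    stop("k_minus_a = 0: ligand never dissociates (infinite residence time)")
  1 / params$k_minus_a
}

#' Washout time constant in the fast-rebinding regime (scenario 2)
#'
#' With `k_a * P_t >> k_lw` and a nearly saturated protein pool the decay is
#' not a true exponential, but it is well approximated by one with time
#' constant `P_t / (prefactor * K_d * k_lw)`. The dimensionless prefactor is
#' 1.53 under the reference conditions reconstructed by
#' [scenario2_prefactor()] (protein pool 100-fold above `K_d`, washout from
#' 90% occupancy, fit to 5% of the initial amplitude); see that function for
#' its sensitivity to the starting occupancy.
#'
#' @inheritParams Kd
#' @param prefactor dimensionless constant relating the fitted exponential
#'   time constant to `P_t / (K_d * k_lw)`.
#' @return Time constant in seconds.
#' @export
scenario2_tau <- function(params, prefactor = 1.53) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k_a <= 0 || params$k_lw <= 0)
    stop("scenario-2 time constant requires k_a > 0 and k_lw > 0")
  params$P_t / (prefactor * Kd(params) * params$k_lw)
}

#' Occupancy trajectory of the washout scheme
#'
#' Container for a solved time course: fractional protein-site occupancy and
#' free membrane ligand concentration on a strictly increasing time grid.
#' Normally produced by [washout_linear()], [washout_saturable()] or
#' [simulate_loading()] rather than called directly.
#'
#' @param times seconds, strictly increasing.
#' @param bound fractional occupancy in \[0, 1\].
#' @param membrane free ligand in the membrane compartment (concentration).
#' @param mode `"linear"` or `"saturable"`.
#' @param params the generating [kinetic_params()], kept as an attribute.
#' @return A data frame of class `"occupancy_trajectory"` with columns
#'   `time_s`, `bound_fraction`, `membrane_conc`.
#' @export
occupancy_trajectory <- function(times, bound, membrane,
                                 mode = c("linear", "saturable"),
                                 params = NULL) {
  mode <- match.arg(mode)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least two points")
  if (length(bound) != length(times) || length(membrane) != length(times))
    stop("'bound' and 'membrane' must match 'times' in length")
  # forgive integrator-level rounding just past the physical limits
  eps <- 1e-9
  if (any(bound < -eps) || any(bound > 1 + eps))
    stop("occupancy left [0, 1]; the linearized model is invalid here, ",
         "use the saturable solver")
  bound <- pmin(pmax(bound, 0), 1)
  membrane <- pmax(membrane, 0)
  out <- data.frame(time_s = times, bound_fraction = bound,
                    membrane_conc = membrane)
  attr(out, "mode") <- mode
  attr(out, "params") <- params
  class(out) <- c("occupancy_trajectory", "data.frame")
  out
}

# Right-hand side of the full (saturable) scheme during washout: water clamped
# at zero so k_wl is inactive. State y = c(B, M), B = concentration of bound
# ligand (= P_t * occupancy).
.washout_full_rhs <- function(params) {
  force(params)
  function(t, y, parms) {
    B <- y[1]; M <- y[2]
    bind <- params$k_a * (params$P_t - B) * M
    unbind <- params$k_minus_a * B
    list(c(bind - unbind, unbind - bind - params$k_lw * M))
  }
}

#' Washout of the linearized two-compartment scheme
#'
#' Solves the washout phase (drug-free bath, water compartment clamped at
#' zero) of the linearized scheme, valid when the protein pool is far from
#' saturation so free sites are approximately constant at `P_t`:
#' \deqn{dB/dt = k_a P_t M - k_{-a} B, \quad
#'       dM/dt = k_{-a} B - (k_a P_t + k_{lw}) M,}
#' with `B` the bound-ligand concentration and `M` the free membrane
#' concentration. The 2x2 linear system is solved exactly by
#' eigen-decomposition (falling back to a stiff numerical integrator for
#' near-degenerate eigenvalues).
#'
#' @inheritParams Kd
#' @param b0 initial fractional occupancy in \[0, 1\].
#' @param m0 initial free membrane concentration (>= 0).
#' @param times strictly increasing time grid starting at 0 (seconds).
#' @return An [occupancy_trajectory()] with `mode = "linear"`.
#' @examples
#' p <- kinetic_params(k_a = 10, k_minus_a = 0.1, k_lw = 1, P_t = 1)
#' tr <- washout_linear(p, b0 = 0.5, m0 = 0.01, times = seq(0, 50, 0.1))
#' effective_tau(tr)$tau
#' @export
washout_linear <- function(params, b0, m0, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(b0) || b0 < 0 || b0 > 1) stop("'b0' must be in [0, 1]")
  if (!is.numeric(m0) || m0 < 0) stop("'m0' must be non-negative")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (abs(times[1]) > .Machine$double.eps) stop("'times' must start at 0")

  kaPt <- params$k_a * params$P_t
  A <- matrix(c(-params$k_minus_a, kaPt,
                params$k_minus_a, -(kaPt + params$k_lw)),
              nrow = 2, byrow = TRUE)
  y0 <- c(params$P_t * b0, m0)
  eg <- eigen(A)
  sep <- abs(diff(eg$values))
  if (is.complex(eg$values) || sep < 1e-10 * max(abs(eg$values), 1e-300)) {
    # (near-)degenerate spectrum: eigenbasis is ill-conditioned, integrate
    sol <- deSolve::lsoda(
      y = y0, times = times,
      func = function(t, y, p) list(as.numeric(A %*% y)),
      parms = NULL, rtol = 1e-10, atol = 1e-12
    )
    B <- sol[, 2]; M <- sol[, 3]
  } else {
    coef <- solve(eg$vectors, y0)
    expl <- exp(outer(times, eg$values))       # n x 2
    Y <- expl %*% (t(eg$vectors) * coef)       # rows: t(V %*% diag(coef))
    B <- Y[, 1]; M <- Y[, 2]
  }
  occupancy_trajectory(times, B / params$P_t, M, mode = "linear",
                       params = params)
}

# membrane concentration consistent with total ligand L under the binding
# isotherm: M + P_t*M/(K_d + M) = L  (positive root of the quadratic)
.membrane_from_total <- function(L, K_d, P_t) {
  a <- K_d + P_t - L
  (-a + sqrt(a * a + 4 * K_d * L)) / 2
}

#' Washout with a saturable protein pool
#'
#' Integrates the washout of total ligand `L = M + P_t * bound` when the
#' protein pool saturates, the regime behind the non-exponential decay of the
#' fast-rebinding scenario. Two variants are provided:
#'
#' * `method = "quasi"` (default, fast): binding is assumed instantaneously
#'   equilibrated, `bound = M / (K_d + M)`, and the single ODE
#'   `dL/dt = -k_lw * M(L)` is integrated.
#' * `method = "full"`: the explicit two-ODE mass-action system with the
#'   nonlinear `k_a * (P_t - B) * M` binding term, no equilibrium assumption.
#'
#' The quasi-equilibrium variant is accurate when `k_a * P_t >> k_lw`.
#'
#' @inheritParams Kd
#' @param L_tot0 initial total ligand concentration (membrane + bound).
#' @param times strictly increasing time grid starting at 0 (seconds).
#' @param method `"quasi"` or `"full"`.
#' @param b0,m0 initial partition of `L_tot0` for `method = "full"`; by
#'   default the equilibrium partition implied by `L_tot0`.
#' @return An [occupancy_trajectory()] with `mode = "saturable"`.
#' @export
washout_saturable <- function(params, L_tot0, times,
                              method = c("quasi", "full"),
                              b0 = NULL, m0 = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  method <- match.arg(method)
  if (params$k_a <= 0)
    stop("saturable washout requires k_a > 0 (binding equilibrium undefined)")
  if (!is.numeric(L_tot0) || L_tot0 < 0) stop("'L_tot0' must be non-negative")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  K <- Kd(params); P_t <- params$P_t

  if (method == "quasi") {
    sol <- deSolve::lsoda(
      y = c(L = L_tot0), times = times,
      func = function(t, y, p) {
        list(-params$k_lw * .membrane_from_total(y[1], K, P_t))
      },
      parms = NULL, rtol = 1e-10, atol = 1e-13 * max(L_tot0, 1)
    )
    M <- .membrane_from_total(pmax(sol[, "L"], 0), K, P_t)
    bound <- M / (K + M)
  } else {
    if (is.null(m0)) m0 <- .membrane_from_total(L_tot0, K, P_t)
    if (is.null(b0)) b0 <- m0 / (K + m0)
    sol <- deSolve::lsoda(
      y = c(B = P_t * b0, M = m0), times = times,
      func = .washout_full_rhs(params),
      parms = NULL, rtol = 1e-10, atol = 1e-13 * max(L_tot0, 1)
    )
    bound <- sol[, "B"] / P_t
    M <- sol[, "M"]
  }
  occupancy_trajectory(times, bound, M, mode = "saturable", params = params)
}

#' Effective single-exponential time constant of a decay
#'
#' The saturable washout is not a true exponential, but experimentally a
#' single time constant is reported. This fits `A * exp(-t / T)` by least
#' squares to the normalized occupancy over the window from washout start to
#' the first crossing of `frac` (default 5%) of the initial value, mirroring
#' how a decay constant is read off a current record. The amplitude `A` is
#' free because the absolute current scale is arbitrary.
#'
#' @param traj an [occupancy_trajectory()] (or any data frame with `time_s`
#'   and `bound_fraction` columns) covering the decay down to at least
#'   `frac` of its initial value.
#' @param frac fit-window cutoff as a fraction of the initial occupancy.
#' @return A list with `tau` (seconds), `amplitude`, `resid_norm` (root sum
#'   of squared residuals of the normalized fit) and `window` (`c(start, end)`
#'   in seconds).
#' @export
effective_tau <- function(traj, frac = 0.05) {
  stopifnot(is.data.frame(traj),
            all(c("time_s", "bound_fraction") %in% names(traj)))
  tt <- traj$time_s - traj$time_s[1]
  b <- traj$bound_fraction
  if (b[1] <= 0) stop("initial occupancy is zero: nothing to fit")
  bn <- b / b[1]
  cross <- which(bn <= frac)
  if (length(cross) == 0L)
    stop(sprintf("trajectory does not decay to %g%% of its initial value; ",
                 100 * frac),
         "extend the time grid")
  iend <- cross[1]
  if (iend < 10L) stop("decay window too short to fit (fewer than 10 samples)")
  tw <- tt[1:iend]; bw <- bn[1:iend]
  if (bw[iend] >= bw[1]) stop("input does not decay over the fit window")

  T0 <- tw[iend] / log(1 / frac)
  obj <- function(p) {
    r <- p[2] * exp(-tw / exp(p[1])) - bw
    sum(r * r)
  }
  fit <- stats::optim(c(log(T0), 1), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(tau = exp(fit$par[1]),
       amplitude = fit$par[2],
       resid_norm = sqrt(fit$value),
       window = c(traj$time_s[1], traj$time_s[iend]))
}

#' Empirical prefactor of the scenario-2 exponential approximation
#'
#' Recomputes, from the model itself, the dimensionless constant `c` in
#' `T = P_t / (c * K_d * k_lw)` by integrating the saturable washout in the
#' fast-rebinding, protein-saturated regime and fitting a single exponential
#' with [effective_tau()]. The reference conditions (defaults) are a protein
#' pool at `P_t = 100 * K_d`, washout started from the steady state reached
#' with a membrane concentration of `9 * K_d` (occupancy 0.9), and a fit
#' window down to 5% of the initial occupancy. Under these conditions
#' `c = 1.53` to three significant figures. The constant is mildly sensitive
#' to the starting occupancy (it saturates near 1.57 as occupancy approaches
#' 1 and falls towards 1.27 for shallow protein pools), so the conditions are
#' exposed as arguments.
#'
#' @param Pt_over_Kd ratio of total site concentration to `K_d`.
#' @param b0 pre-washout fractional occupancy (sets the initial membrane
#'   concentration through the binding isotherm).
#' @param rebinding_ratio `k_a * P_t / k_lw`; must be >= 100 for the
#'   fast-rebinding regime.
#' @param method integrator passed to [washout_saturable()].
#' @param frac fit-window cutoff passed to [effective_tau()].
#' @param n number of time samples in the fitted window.
#' @return A list with the dimensionless `prefactor`, the fitted `tau`, the
#'   parameter set used and the fit diagnostics.
#' @export
scenario2_prefactor <- function(Pt_over_Kd = 100, b0 = 0.9,
                                rebinding_ratio = 1000,
                                method = c("full", "quasi"),
                                frac = 0.05, n = 4000) {
  method <- match.arg(method)
  stopifnot(Pt_over_Kd > 1, b0 > 0, b0 < 1, rebinding_ratio >= 100)
  K <- 0.01; P_t <- Pt_over_Kd * K; k_lw <- 1
  k_a <- rebinding_ratio * k_lw / P_t
  params <- kinetic_params(k_a = k_a, k_minus_a = k_a * K, k_lw = k_lw,
                           P_t = P_t)
  m0 <- K * b0 / (1 - b0)
  L0 <- m0 + P_t * b0
  tau_scale <- P_t / (K * k_lw)
  # generous horizon: saturated-pool drainage plus free-membrane transient
  horizon <- 4 * tau_scale + 6 * m0 / k_lw
  coarse <- washout_saturable(params, L0, seq(0, horizon, length.out = n),
                              method = method)
  cross <- which(coarse$bound_fraction <= frac * b0)[1]
  if (is.na(cross)) stop("horizon too short for the requested fit window")
  fine <- washout_saturable(params, L0,
                            seq(0, coarse$time_s[cross], length.out = n),
                            method = method)
  fit <- effective_tau(fine, frac = frac)
  list(prefactor = tau_scale / fit$tau, tau = fit$tau, params = params,
       b0 = b0, fit = fit)
}
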