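# Shared fixtures: an independent reference integrator for the linearized
# washout system, a preset whose washout is essentially a clean exponential
# (fast-escape regime), and hand-built exponential traces.

# independent oracle: integrate the linear washout ODEs directly
ref_linear_traj <- function(params, b0, m0, times) {
  kaPt <- params$k_a * params$P_t
  rhs <- function(t, y, p) {
    list(c(kaPt * y[2] - params$k_minus_a * y[1],
           params$k_minus_a * y[1] - (kaPt + params$k_lw) * y[2]))
  }
  sol <- deSolve::lsoda(c(B = params$P_t * b0, M = m0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-13)
  list(times = sol[, "time"], bound = sol[, "B"] / params$P_t,
       membrane = sol[, "M"])
}

# independent oracle: full two-ODE saturable washout without the
# quasi-equilibrium assumption
ref_saturable_traj <- function(params, L0, times) {
  K <- params$k_minus_a / params$k_a
  a <- K + params$P_t - L0
  m0 <- (-a + sqrt(a^2 + 4 * K * L0)) / 2
  b0 <- m0 / (K + m0)
  rhs <- function(t, y, p) {
    bind <- params$k_a * (params$P_t - y[1]) * y[2]
    unbind <- params$k_minus_a * y[1]
    list(c(bind - unbind, unbind - bind - params$k_lw * y[2]))
  }
  sol <- deSolve::lsoda(c(B = params$P_t * b0, M = m0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-13)
  list(times = sol[, "time"], bound = sol[, "B"] / params$P_t,
       membrane = sol[, "M"])
}

# fast-escape (scenario-1) preset: washout decays as a clean exponential
# with time constant 1/k_minus_a = 2 s; drug phase equilibrates to ~99%
# occupancy so the decay amplitude is close to the full potentiation span
exp_preset <- function(fold = 2.5) {
  analog_preset("exp-regime", fold,
                kinetic_params(k_a = 1, k_minus_a = 0.5, k_lw = 5000,
                               k_wl = 5e6, P_t = 1),
                rgroup_logP = 2)
}

fast_protocol <- function(washout_s = 15) {
  protocol(baseline_s = 5, drug_s = 15, washout_s = washout_s,
           bath_conc = 0.05)
}

# hand-built three-segment trace whose washout is offset + amp * exp(-t/tau)
make_exp_trace <- function(tau, amp = 20, offset = 10, noise_sd = 0,
                           washout_s = 8 * tau, rate = 250, seed = NULL) {
  dt <- 1 / rate
  tb <- seq(0, 5 - dt, by = dt)
  td <- seq(0, 5 - dt, by = dt)
  tw <- seq(0, washout_s - dt, by = dt)
  cur <- c(rep(offset, length(tb)),
           rep(offset + amp, length(td)),
           offset + amp * exp(-tw / tau))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cur <- cur + stats::rnorm(length(cur), sd = noise_sd * offset)
  }
  df <- data.frame(
    time_s = c(tb, 5 + td, 10 + tw),
    current = cur,
    segment = rep(c("baseline", "drug", "washout"),
                  c(length(tb), length(td), length(tw))),
    stringsAsFactors = FALSE)
  class(df) <- c("patch_trace", "data.frame")
  df
}
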