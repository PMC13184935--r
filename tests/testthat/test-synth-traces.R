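test_that("occupancy maps linearly to potentiated current", {
  expect_equal(occupancy_to_current(0, 10, 3), 10)
  expect_equal(occupancy_to_current(1, 10, 2.94), 29.4)
  expect_equal(occupancy_to_current(0.5, 10, 3), 20)
  expect_error(occupancy_to_current(0.5, 10, 0.9), "fold")
  expect_error(occupancy_to_current(1.2, 10, 2))
})

test_that("drug loading reaches the algebraic steady state", {
  p <- kinetic_params(k_a = 50, k_minus_a = 2, k_lw = 4, k_wl = 40, P_t = 1)
  tt <- seq(0, 30, 0.01)

  # no ligand in the bath: nothing loads
  tr0 <- simulate_loading(p, bath_conc = 0, times = tt)
  expect_equal(max(tr0$bound_fraction), 0)

  # steady state: membrane from perfusion balance, occupancy from the isotherm
  bath <- 0.2
  tr <- simulate_loading(p, bath, times = tt)
  M_ss <- bath * p$k_wl / p$k_lw
  B_ss <- M_ss / (Kd(p) + M_ss)
  n <- length(tt)
  expect_equal(tr$membrane_conc[n], M_ss, tolerance = 1e-6)
  expect_equal(tr$bound_fraction[n], B_ss, tolerance = 1e-6)
  # occupancy rises monotonically
  expect_true(all(diff(tr$bound_fraction) > -1e-12))

  # doubling k_wl doubles the steady-state membrane concentration
  p2 <- kinetic_params(p$k_a, p$k_minus_a, p$k_lw, 2 * p$k_wl, p$P_t)
  tr2 <- simulate_loading(p2, bath, times = tt)
  expect_equal(tr2$membrane_conc[n] / tr$membrane_conc[n], 2,
               tolerance = 1e-6)

  expect_warning(
    simulate_loading(kinetic_params(1, 1, 1, 0, 1), 0.5, seq(0, 1, 0.01)),
    "never loads")
})

test_that("noiseless traces equal the model curve and seeds are reproducible", {
  preset <- exp_preset()
  prot <- fast_protocol()

  tr0 <- generate_trace(preset, prot, noise_sd = 0, seed = 7)
  model <- occupancy_to_current(attr(tr0, "bound"), 10,
                                preset$fold_potentiation)
  expect_equal(max(abs(tr0$current - model)), 0)

  tr_a <- generate_trace(preset, prot, noise_sd = 0.05, seed = 11)
  tr_b <- generate_trace(preset, prot, noise_sd = 0.05, seed = 11)
  expect_identical(tr_a$current, tr_b$current)
  tr_c <- generate_trace(preset, prot, noise_sd = 0.05, seed = 12)
  expect_false(identical(tr_a$current, tr_c$current))

  # segments are contiguous and in protocol order
  expect_identical(unique(tr_a$segment), c("baseline", "drug", "washout"))
  expect_identical(rle(tr_a$segment)$values, c("baseline", "drug", "washout"))

  # the generator restores the caller's RNG stream
  set.seed(99); x1 <- stats::rnorm(1)
  set.seed(99); invisible(generate_trace(preset, prot, 0.05, seed = 5))
  expect_identical(stats::rnorm(1), x1)
})

test_that("injected noise has the requested standard deviation", {
  preset <- exp_preset()
  prot <- protocol(baseline_s = 20, drug_s = 4, washout_s = 4,
                   bath_conc = 0.05)  # 1e4 baseline samples at 500 Hz
  tr <- generate_trace(preset, prot, noise_sd = 0.05, seed = 21)
  base <- tr$current[tr$segment == "baseline"]
  expect_length(base, 1e4)
  expect_equal(stats::sd(base - 10), 0.05 * 10, tolerance = 0.05)
})

test_that("trace-level decay constant agrees with the occupancy-level one", {
  # exponential-regime preset: the two estimators share the answer to < 1e-3
  preset <- exp_preset()
  prot <- fast_protocol()
  tr <- generate_trace(preset, prot, noise_sd = 0, seed = 1)
  tau_trace <- fit_washout(tr)$tau

  widx <- which(tr$segment == "washout")
  occ <- occupancy_trajectory(tr$time_s[widx] - tr$time_s[widx[1]],
                              attr(tr, "bound")[widx],
                              numeric(length(widx)), mode = "saturable")
  tau_occ <- effective_tau(occ)$tau
  expect_equal(tau_trace, tau_occ, tolerance = 1e-3)

  # strongly non-exponential (fast-rebinding) decay: the free-offset trace
  # fit and the offset-free occupancy fit are different conventions; they
  # agree only approximately
  pr6 <- analog_presets("CFTRi-C6")[[1]]
  tr6 <- generate_trace(pr6, protocol(washout_s = 120), noise_sd = 0, seed = 1)
  widx <- which(tr6$segment == "washout")
  occ6 <- occupancy_trajectory(tr6$time_s[widx] - tr6$time_s[widx[1]],
                               attr(tr6, "bound")[widx],
                               numeric(length(widx)), mode = "saturable")
  expect_equal(fit_washout(tr6)$tau, effective_tau(occ6)$tau,
               tolerance = 0.35)
})

test_that("packaged presets slow washout with chain length", {
  pr <- analog_presets()
  expect_named(pr, c("ABBV-974", "CFTRi-C3", "CFTRi-C6", "CFTRi-C10",
                     "CFTRi-NBD"))
  klw <- vapply(pr[c("CFTRi-C3", "CFTRi-C6", "CFTRi-C10")],
                function(p) p$kinetics$k_lw, 0)
  expect_true(all(diff(klw) < 0))

  taus <- vapply(pr[c("CFTRi-C3", "CFTRi-C6", "CFTRi-C10")], function(p) {
    fit_washout(generate_trace(p, protocol(), noise_sd = 0, seed = 1))$tau
  }, 0)
  expect_true(all(diff(taus) > 0))

  expect_error(analog_presets("no-such-analog"), "unknown")
})

test_that("traces round-trip through CSV with their metadata sidecar", {
  preset <- exp_preset()
  tr <- generate_trace(preset, fast_protocol(), noise_sd = 0.02, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$current, tr$current, tolerance = 1e-12)
  expect_identical(back$segment, tr$segment)
  meta <- attr(back, "meta")
  expect_identical(meta$preset, "exp-regime")
  expect_equal(meta$noise_sd, 0.02)
  expect_equal(estimate_potentiation(back), estimate_potentiation(tr),
               tolerance = 1e-9)
  unlink(c(f, paste0(f, ".json")))
})
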