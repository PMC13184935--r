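test_that("parameter container validates inputs and derives K_d and regime", {
  p <- kinetic_params(k_a = 100, k_minus_a = 1, k_lw = 5, k_wl = 50, P_t = 2)
  expect_equal(Kd(p), 0.01)
  expect_true(binding_favorable(p))

  expect_error(kinetic_params(-1, 1, 1, 1, 1), "non-negative")
  expect_error(kinetic_params(1, 1, 1, 1, 0), "positive")
  expect_error(Kd(kinetic_params(0, 1, 1, 1, 1)), "undefined")

  expect_identical(
    classify_regime(kinetic_params(1, 0, 100, 0, 1)), "scenario-1")
  expect_identical(
    classify_regime(kinetic_params(10, 0, 0.01, 0, 1)), "scenario-2")
  # boundary: equal rates are neither limit
  expect_identical(
    classify_regime(kinetic_params(1, 0, 1, 0, 1)), "intermediate")
})

test_that("regime time constants follow the closed forms", {
  expect_equal(scenario1_tau(kinetic_params(1, 0.1, 1, 0, 1)), 10)
  expect_equal(scenario1_tau(kinetic_params(1, 1, 1, 0, 1)), 1)
  expect_equal(scenario1_tau(kinetic_params(1, 2.5, 1, 0, 1)), 0.4)
  expect_error(scenario1_tau(kinetic_params(1, 0, 1, 0, 1)), "residence")

  # P_t = 1, K_d = 0.01, k_lw = 1 -> 1 / (1.53 * 0.01) s
  p <- kinetic_params(k_a = 100, k_minus_a = 1, k_lw = 1, P_t = 1)
  expect_equal(scenario2_tau(p), 65.3594771, tolerance = 1e-8)
  # prefactor cancellation
  p2 <- kinetic_params(k_a = 1, k_minus_a = 1, k_lw = 1, P_t = 1.53)
  expect_equal(scenario2_tau(p2), 1)
  # doubling k_lw halves the constant
  for (klw in c(0.2, 3)) {
    pa <- kinetic_params(17, 0.3, klw, 0, 0.7)
    pb <- kinetic_params(17, 0.3, 2 * klw, 0, 0.7)
    expect_equal(scenario2_tau(pa) / scenario2_tau(pb), 2)
  }
  expect_error(scenario2_tau(kinetic_params(0, 1, 1, 0, 1)))
})

test_that("linear washout reduces to first-order decay and conserves ligand", {
  tt <- seq(0, 30, 0.05)
  # no rebinding: pure exponential protein decay
  p <- kinetic_params(k_a = 0, k_minus_a = 0.3, k_lw = 2, P_t = 1)
  tr <- washout_linear(p, b0 = 1, m0 = 0, times = tt)
  expect_equal(tr$bound_fraction, exp(-0.3 * tt), tolerance = 1e-9)

  # sealed membrane: total ligand conserved
  p2 <- kinetic_params(k_a = 5, k_minus_a = 0.5, k_lw = 0, P_t = 2)
  tr2 <- washout_linear(p2, b0 = 0.4, m0 = 0.3, times = tt)
  total <- tr2$membrane_conc + p2$P_t * tr2$bound_fraction
  expect_equal(total, rep(total[1], length(tt)), tolerance = 1e-8)

  expect_error(washout_linear(p, 0.5, 0, times = c(0, 2, 1)), "increasing")
  expect_error(washout_linear(p, -0.1, 0, times = tt))
  expect_error(washout_linear(p, 0.5, -1, times = tt))
})

test_that("eigen-solution matches an independent stiff integrator", {
  # spec'd spot check
  p <- kinetic_params(k_a = 10, k_minus_a = 0.1, k_lw = 1, P_t = 1)
  tt <- seq(0, 100, 0.25)
  tr <- washout_linear(p, b0 = 0.9, m0 = 0.01, times = tt)
  ref <- ref_linear_traj(p, 0.9, 0.01, tt)
  keep <- ref$bound > 1e-6
  expect_lt(max(abs(tr$bound_fraction[keep] - ref$bound[keep]) /
                  ref$bound[keep]), 1e-6)

  # property: 100 random draws, rates log-uniform over 4 decades
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    r <- 10^stats::runif(3, -2, 2)
    p <- kinetic_params(k_a = r[1], k_minus_a = r[2], k_lw = r[3],
                        P_t = 10^stats::runif(1, -1, 1))
    b0 <- stats::runif(1, 0.1, 0.9)
    m0 <- stats::runif(1, 0, 0.9 * (1 - b0)) * p$P_t
    tt <- seq(0, 5 / max(p$k_minus_a, 0.01), length.out = 201)
    tr <- washout_linear(p, b0, m0, tt)
    ref <- ref_linear_traj(p, b0, m0, tt)
    keep <- ref$bound > 1e-6
    if (any(keep))
      worst <- max(worst, max(abs(tr$bound_fraction[keep] -
                                    ref$bound[keep]) / ref$bound[keep]))
    expect_true(all(tr$bound_fraction >= 0 & tr$bound_fraction <= 1))
  }
  expect_lt(worst, 1e-5)
})

test_that("saturable washout honours its limits and the full-kinetics oracle", {
  tt <- seq(0, 6, 0.01)
  # vanishing protein pool: pure membrane escape
  p <- kinetic_params(k_a = 1, k_minus_a = 1, k_lw = 1, P_t = 1e-8)
  tr <- washout_saturable(p, L_tot0 = 0.5, times = tt)
  expect_equal(tr$membrane_conc, 0.5 * exp(-tt), tolerance = 1e-5)

  # weak-binding limit: effective decay rate approaches k_lw
  pw <- kinetic_params(k_a = 1, k_minus_a = 100, k_lw = 1, P_t = 1)  # K_d=100
  trw <- washout_saturable(pw, L_tot0 = 0.5, times = seq(0, 8, 0.005))
  fit <- effective_tau(trw)
  expect_equal(1 / fit$tau, pw$k_lw, tolerance = 0.05)

  # mass balance along the quasi-equilibrium path: dL/dt = -k_lw * M
  p3 <- kinetic_params(k_a = 100, k_minus_a = 1, k_lw = 1, P_t = 1)
  tr3 <- washout_saturable(p3, L_tot0 = 0.5, times = tt)
  L <- tr3$membrane_conc + p3$P_t * tr3$bound_fraction
  flux <- -p3$k_lw * tr3$membrane_conc
  dL <- diff(L) / diff(tt)
  mid <- (flux[-1] + flux[-length(flux)]) / 2
  expect_equal(dL, mid, tolerance = 1e-3)

  # quasi-equilibrium vs explicit two-ODE integration at k_a*P_t = 1000*k_lw
  pf <- kinetic_params(k_a = 1000, k_minus_a = 10, k_lw = 1, P_t = 1)
  ttf <- seq(0, 12, 0.01)
  trq <- washout_saturable(pf, L_tot0 = 0.5, times = ttf)
  ref <- ref_saturable_traj(pf, 0.5, ttf)
  expect_lt(max(abs(trq$bound_fraction - ref$bound)), 5e-3)

  expect_error(washout_saturable(kinetic_params(0, 1, 1, 0, 1), 0.5, tt),
               "k_a")
  expect_error(washout_saturable(p3, -1, tt))
})

test_that("effective_tau fits exponentials exactly and matches a grid search", {
  tt <- seq(0, 40, 0.01)
  traj <- occupancy_trajectory(tt, exp(-tt / 5), numeric(length(tt)),
                               mode = "linear")
  expect_equal(effective_tau(traj)$tau, 5, tolerance = 1e-6)

  # biexponential: compare against a dense grid search with closed-form
  # optimal amplitude at each trial T
  b <- 0.5 * exp(-tt) + 0.5 * exp(-tt / 10)
  traj2 <- occupancy_trajectory(tt, b, numeric(length(tt)), mode = "linear")
  fit <- effective_tau(traj2)
  iend <- which(b / b[1] <= 0.05)[1]
  tw <- tt[1:iend]; bw <- b[1:iend] / b[1]
  grid <- seq(0.5, 20, length.out = 20000)
  loss <- vapply(grid, function(Tc) {
    e <- exp(-tw / Tc)
    A <- sum(e * bw) / sum(e * e)
    sum((A * e - bw)^2)
  }, 0)
  expect_equal(fit$tau, grid[which.min(loss)], tolerance = 1e-3)

  # non-decaying and too-short inputs are rejected
  up <- occupancy_trajectory(tt, pmin(1, 0.5 + tt / 100),
                             numeric(length(tt)), mode = "linear")
  expect_error(effective_tau(up), "decay")
  short <- occupancy_trajectory(seq(0, 1, 0.1), exp(-seq(0, 1, 0.1) / 5),
                                numeric(11), mode = "linear")
  expect_error(effective_tau(short), "decay")
})

test_that("limiting regimes reproduce their closed-form time constants", {
  # fast escape: effective tau equals the protein residence time
  p1 <- kinetic_params(k_a = 0.1, k_minus_a = 0.5, k_lw = 100, P_t = 1)
  tt <- seq(0, 14, 0.002)
  tr <- washout_linear(p1, b0 = 0.9, m0 = 0, times = tt)
  expect_equal(effective_tau(tr)$tau, 1 / p1$k_minus_a, tolerance = 0.05)

  # fast rebinding, deep saturation: fitted tau ~ P_t / (K_d k_lw) with
  # log-log slopes of +1 / -1 / -1 over one decade
  tau_of <- function(P_t, K_d, k_lw, b0 = 0.9) {
    p <- kinetic_params(k_a = 1 / K_d, k_minus_a = 1, k_lw = k_lw, P_t = P_t)
    m0 <- K_d * b0 / (1 - b0)
    L0 <- m0 + P_t * b0
    horizon <- 4 * P_t / (K_d * k_lw) + 6 * m0 / k_lw
    coarse <- washout_saturable(p, L0, seq(0, horizon, length.out = 1500))
    tcross <- coarse$time_s[which(coarse$bound_fraction <= 0.05 * b0)[1]]
    fine <- washout_saturable(p, L0, seq(0, tcross, length.out = 1500))
    effective_tau(fine)$tau
  }
  slope <- function(t_hi, t_lo) log10(t_hi / t_lo)
  expect_equal(slope(tau_of(10, 1e-3, 1), tau_of(1, 1e-3, 1)), 1,
               tolerance = 0.02)
  expect_equal(slope(tau_of(1, 1e-3, 1), tau_of(1, 1e-2, 1)), 1,
               tolerance = 0.02)
  expect_equal(slope(tau_of(1, 1e-3, 1), tau_of(1, 1e-3, 10)), 1,
               tolerance = 0.02)
})

test_that("saturable decay in the fast-rebinding regime carries the 1.53 prefactor", {
  pf <- scenario2_prefactor(method = "quasi", n = 2000)
  expect_equal(pf$prefactor, 1.53, tolerance = 0.02)
  # and the fitted tau then matches the scenario-2 closed form
  expect_equal(pf$tau, scenario2_tau(pf$params, prefactor = pf$prefactor),
               tolerance = 1e-6)
})

test_that("kinetic parameters round-trip through JSON", {
  p <- kinetic_params(k_a = 12.5, k_minus_a = 0.7, k_lw = 3, k_wl = 30,
                      P_t = 0.8)
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  q <- read_params_json(f)
  expect_equal(unclass(q), unclass(p))
  unlink(f)
})
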