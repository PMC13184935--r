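#' Built-in 1-D toy potentials
#'
#' Energy profiles (in kT, with the thermal energy set to 1) for the toy
#' landscape used to exercise the weighted-ensemble machinery:
#'
#' * `"double_well"`: `U(x) = h * (x^2 - 1)^2`, minima at x = -1 and +1
#'   separated by a barrier of height `h` kT at x = 0.
#' * `"tilted"`: `U(x) = -f * x`, a barrierless downhill slope.
#' * `"flat"`: `U(x) = 0`, free diffusion.
#'
#' @param name potential name.
#' @param barrier_kT barrier height `h` for the double well (kT).
#' @param force tilt `f` for the tilted potential (kT per unit length).
#' @return A list with functions `U(x)` and `dU(x)` and a `label`.
#' @export
make_potential <- function(name = c("double_well", "tilted", "flat"),
                           barrier_kT = 4, force = 2) {
  name <- match.arg(name)
  switch(name,
    double_well = list(
      U = function(x) barrier_kT * (x^2 - 1)^2,
      dU = function(x) 4 * barrier_kT * x * (x^2 - 1),
      label = sprintf("double_well(h=%g kT)", barrier_kT)),
    tilted = list(
      U = function(x) -force * x,
      dU = function(x) rep(-force, length(x)),
      label = sprintf("tilted(f=%g)", force)),
    flat = list(
      U = function(x) rep(0, length(x)),
      dU = function(x) rep(0, length(x)),
      label = "flat")
  )
}

#' One-dimensional overdamped-Langevin toy system
#'
#' Desk-scale stand-in for the solvated protein/membrane system: a single
#' progress coordinate diffusing on an energy profile with overdamped
#' (Brownian) dynamics
#' \deqn{x \leftarrow x - D U'(x) \Delta t + \sqrt{2 D \Delta t}\,\xi,}
#' at unit thermal energy (kT = 1).
#'
#' @param potential a [make_potential()] result, or any list with `U` and
#'   `dU` functions.
#' @param diffusion_coeff diffusion coefficient (coordinate^2 per time).
#' @param timestep integration timestep (time units).
#' @param temperature thermal energy kT; 1 by convention (the potential is
#'   in kT units). Set to 0 for the noise-free, drift-only limit.
#' @param reflect_at optional reflecting wall position (coordinate); walkers
#'   below it are folded back. `-Inf` (default) disables it.
#' @return An object of class `"toy_system"`.
#' @export
toy_system <- function(potential, diffusion_coeff = 1, timestep = 2e-4,
                       temperature = 1, reflect_at = -Inf) {
  stopifnot(is.list(potential), is.function(potential$U),
            is.function(potential$dU),
            diffusion_coeff >= 0, timestep > 0, temperature >= 0)
  structure(list(potential = potential, D = diffusion_coeff,
                 dt = timestep, kT = temperature, reflect_at = reflect_at),
            class = "toy_system")
}

# one batch of Brownian-dynamics steps for a position vector
.bd_steps <- function(x, system, n_steps) {
  sdstep <- sqrt(2 * system$D * system$kT * system$dt)
  drift <- system$D * system$dt
  for (i in seq_len(n_steps)) {
    x <- x - drift * system$potential$dU(x)
    if (sdstep > 0) x <- x + sdstep * stats::rnorm(length(x))
    if (is.finite(system$reflect_at))
      x <- ifelse(x < system$reflect_at, 2 * system$reflect_at - x, x)
  }
  x
}

#' Initialize a weighted ensemble
#'
#' Creates the walker population for weighted-ensemble sampling: `n` walkers
#' at the bound-state position with equal weights summing to 1, fixed bin
#' boundaries along the progress coordinate, a per-bin walker target
#' (default 4) and an absorbing (recycling) boundary beyond which walkers
#' are re-initialized at the bound state and their weight recorded as flux.
#'
#' The timestep must resolve the bins: the per-step displacement SD
#' `sqrt(2 D dt)` must be below 10% of the smallest bin width (validated
#' here, where the bins are first known).
#'
#' @param system a [toy_system()].
#' @param bins ordered interior bin boundaries over the progress coordinate.
#' @param target_per_bin walkers kept per occupied bin after resampling.
#' @param round_length propagation steps per resampling round.
#' @param recycle_boundary coordinate beyond which walkers are absorbed.
#' @param init_pos bound-state (re-)initialization position.
#' @return An object of class `"we_ensemble"`.
#' @export
we_ensemble <- function(system, bins, target_per_bin = 4, round_length = 50,
                        recycle_boundary, init_pos) {
  stopifnot(inherits(system, "toy_system"), length(bins) >= 1,
            !is.unsorted(bins, strictly = TRUE),
            target_per_bin >= 1, round_length >= 1)
  if (init_pos >= recycle_boundary)
    stop("'init_pos' must lie before 'recycle_boundary'")
  sdstep <- sqrt(2 * system$D * system$kT * system$dt)
  minw <- if (length(bins) > 1) min(diff(bins)) else Inf
  if (sdstep >= 0.1 * minw * (1 + 1e-9))
    stop(sprintf(paste0("timestep too coarse for these bins: per-step SD ",
                        "%.3g >= 10%% of the smallest bin width %.3g"),
                 sdstep, minw))
  n <- as.integer(target_per_bin)
  structure(list(
    system = system, bins = bins,
    target_per_bin = as.integer(target_per_bin),
    round_length = as.integer(round_length),
    recycle_boundary = recycle_boundary, init_pos = init_pos,
    x = rep(init_pos, n), w = rep(1 / n, n)
  ), class = "we_ensemble")
}

#' Propagate all walkers for one round
#'
#' Advances every walker `round_length` steps of overdamped Langevin
#' dynamics; weights are untouched. With a seed, the result is reproducible.
#'
#' @param ensemble a [we_ensemble()].
#' @param seed optional integer seed.
#' @return The ensemble with updated positions.
#' @export
we_propagate <- function(ensemble, seed = NULL) {
  stopifnot(inherits(ensemble, "we_ensemble"))
  ensemble$x <- if (is.null(seed)) {
    .bd_steps(ensemble$x, ensemble$system, ensemble$round_length)
  } else {
    .with_seed(seed,
               .bd_steps(ensemble$x, ensemble$system, ensemble$round_length))
  }
  ensemble
}

# absorb walkers past the recycling boundary: their weight becomes flux and
# they restart at the bound state
.we_recycle <- function(ensemble) {
  hit <- ensemble$x >= ensemble$recycle_boundary
  flux <- sum(ensemble$w[hit])
  ensemble$x[hit] <- ensemble$init_pos
  list(ensemble = ensemble, flux = flux)
}

#' Split and merge walkers to the per-bin target
#'
#' Within each occupied bin: while the bin holds fewer than
#' `target_per_bin` walkers, the highest-weight walker is split into two
#' halves; while it holds more, the two lowest-weight walkers are merged,
#' the survivor drawn with probability proportional to weight (set
#' `deterministic = TRUE` to always keep the heavier one, useful in tests).
#' Total weight is conserved exactly.
#'
#' @param ensemble a [we_ensemble()].
#' @param deterministic if `TRUE`, merges keep the heavier walker instead of
#'   sampling the survivor.
#' @return The resampled ensemble.
#' @export
we_split_merge <- function(ensemble, deterministic = FALSE) {
  stopifnot(inherits(ensemble, "we_ensemble"))
  bin_id <- findInterval(ensemble$x, ensemble$bins)
  xs <- list(); ws <- list(); j <- 0L
  for (b in sort(unique(bin_id))) {
    idx <- which(bin_id == b)
    x <- ensemble$x[idx]; w <- ensemble$w[idx]
    tgt <- ensemble$target_per_bin
    while (length(x) < tgt) {
      i <- which.max(w)
      x <- c(x, x[i]); w[i] <- w[i] / 2; w <- c(w, w[i])
    }
    while (length(x) > tgt) {
      ord <- order(w)[1:2]
      keep <- if (deterministic) ord[which.max(w[ord])]
              else sample(ord, 1L, prob = w[ord])
      wsum <- sum(w[ord])
      drop <- setdiff(ord, keep)
      w[keep] <- wsum
      x <- x[-drop]; w <- w[-drop]
    }
    j <- j + 1L; xs[[j]] <- x; ws[[j]] <- w
  }
  ensemble$x <- unlist(xs, use.names = FALSE)
  ensemble$w <- unlist(ws, use.names = FALSE)
  ensemble
}

#' Run a steady-state weighted-ensemble simulation
#'
#' Iterates propagate -> recycle -> split/merge for `n_rounds`, recording
#' the recycled probability weight per round. Recycling walkers at the
#' unbound boundary back into the bound state drives the ensemble to a
#' nonequilibrium steady state whose boundary flux estimates the
#' dissociation rate.
#'
#' @inheritParams we_ensemble
#' @param n_rounds number of resampling rounds.
#' @param seed integer seed for dynamics and merge draws.
#' @return An object of class `"we_history"`: list with `history` (data
#'   frame: round, recycled_weight, n_walkers), `ensemble` (final state),
#'   and the run settings.
#' @examples
#' sys <- toy_system(make_potential("tilted", force = 4), timestep = 2e-4)
#' h <- we_run(sys, bins = seq(-1, 1, 0.2), n_rounds = 60,
#'             recycle_boundary = 1, init_pos = -1, seed = 1)
#' estimate_rate(h)
#' @export
we_run <- function(system, bins, n_rounds, target_per_bin = 4,
                   round_length = 50, recycle_boundary, init_pos, seed = 1) {
  ens <- we_ensemble(system, bins, target_per_bin, round_length,
                     recycle_boundary, init_pos)
  flux <- numeric(n_rounds)
  nw <- integer(n_rounds)
  .with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      ens$x <- .bd_steps(ens$x, ens$system, ens$round_length)
      rec <- .we_recycle(ens)
      ens <- rec$ensemble
      flux[r] <- rec$flux
      ens <- we_split_merge(ens)
      nw[r] <- length(ens$x)
      # guard against weight drift over many rounds
      ens$w <- ens$w / sum(ens$w)
    }
  })
  structure(list(
    history = data.frame(round = seq_len(n_rounds), recycled_weight = flux,
                         n_walkers = nw),
    ensemble = ens,
    round_time = ens$round_length * system$dt
  ), class = "we_history")
}

#' Flux-based rate estimate from a weighted-ensemble run
#'
#' The dissociation rate is the mean recycled probability weight per unit
#' time over the second half of the run (the first half is discarded as the
#' relaxation toward steady state). Uncertainty is a block-bootstrap
#' standard deviation of that mean (blocks of consecutive rounds, preserving
#' the autocorrelation induced by resampling).
#'
#' @param we_history a [we_run()] result (>= 20 rounds).
#' @param block_rounds bootstrap block length, in rounds; by default 1/20 of
#'   the analysis window (at least 5), coarse enough to span the weight
#'   correlations that resampling induces.
#' @param n_boot bootstrap resamples.
#' @return A list with `rate` (per time), `sd`, `n_events` (rounds with
#'   nonzero flux in the analysis window) and `relative_uncertainty`
#'   (`Inf`, with a warning, when no flux was recycled).
#' @export
estimate_rate <- function(we_history, block_rounds = NULL, n_boot = 200) {
  stopifnot(inherits(we_history, "we_history"))
  h <- we_history$history
  if (nrow(h) < 20L) stop("need at least 20 rounds of history")
  half <- h$recycled_weight[(nrow(h) %/% 2 + 1):nrow(h)]
  if (is.null(block_rounds)) block_rounds <- max(5L, length(half) %/% 20L)
  rate <- mean(half) / we_history$round_time
  if (all(half == 0)) {
    warning("no recycling events in the analysis window; rate is 0 with ",
            "infinite relative uncertainty")
    return(list(rate = 0, sd = 0, n_events = 0L,
                relative_uncertainty = Inf))
  }
  nb <- max(1L, length(half) %/% block_rounds)
  blocks <- split(half, rep(seq_len(nb), each = block_rounds,
                            length.out = length(half)))
  bmeans <- vapply(blocks, mean, 0)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(sample(bmeans, length(bmeans), replace = TRUE)), 0)
  list(rate = rate, sd = stats::sd(boot) / we_history$round_time,
       n_events = sum(half > 0),
       relative_uncertainty = stats::sd(boot) / mean(half))
}

#' Brute-force first-passage rate
#'
#' Validation oracle for the weighted-ensemble estimate: simulates `n_events`
#' independent trajectories from the bound state until each first reaches
#' the absorbing boundary, and returns `1 / mean(first-passage time)`.
#'
#' @param system a [toy_system()].
#' @param n_events number of independent first-passage events (>= 10).
#' @param seed integer seed.
#' @param init_pos starting (bound-state) position.
#' @param boundary absorbing boundary position.
#' @param max_steps per-trajectory step budget; exceeding it with unabsorbed
#'   walkers is an error that reports the partial statistics.
#' @return A list with `rate` (per time), `mean_fpt`, `sd_fpt` and `fpt`
#'   (the per-event first-passage times).
#' @export
brute_force_rate <- function(system, n_events, seed, init_pos, boundary,
                             max_steps = 5e6) {
  stopifnot(inherits(system, "toy_system"), n_events >= 10)
  fpt <- rep(NA_real_, n_events)
  .with_seed(seed, {
    x <- rep(init_pos, n_events)
    alive <- rep(TRUE, n_events)
    steps <- 0L
    # propagate survivors in vectorized chunks
    chunk <- 100L
    while (any(alive) && steps < max_steps) {
      idx <- which(alive)
      xi <- x[idx]
      for (s in seq_len(chunk)) {
        xi <- .bd_steps(xi, system, 1L)
        done <- xi >= boundary
        if (any(done)) {
          fpt[idx[done]] <- (steps + s) * system$dt
          keep <- !done
          idx <- idx[keep]
          xi <- xi[keep]
          if (length(idx) == 0L) break
        }
      }
      x[idx] <- xi
      alive[] <- FALSE
      alive[idx] <- TRUE
      steps <- steps + chunk
    }
  })
  if (anyNA(fpt))
    stop(sprintf(
      "step budget exceeded with %d/%d events unabsorbed (partial mean FPT %.4g)",
      sum(is.na(fpt)), n_events, mean(fpt, na.rm = TRUE)))
  list(rate = 1 / mean(fpt), mean_fpt = mean(fpt), sd_fpt = stats::sd(fpt),
       fpt = fpt)
}
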