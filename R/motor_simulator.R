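# evaluate expr with a private, restorable RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Configuration of a stochastic motor ensemble simulation
#'
#' @param n_molecules Number of independent motor molecules (>= 1).
#' @param t_end Simulated operation time, s (> 0). Default 48 h.
#' @param seed Integer RNG seed; required for reproducibility.
#' @param fuel_model `"constant"` (fuel fixed at its initial value, the
#'   headline regime) or `"depleting"` (1 equivalent consumed per reduction
#'   plus background decomposition).
#' @param racemization How the transient aldehyde phase is resolved:
#'   `"complete"` - the aldehyde racemizes fully before reduction, so each
#'   cycle commits a 180 degree step with probability 1/2 (the limit
#'   r_enant >> r_red); `"partial"` - the step probability is the two-state
#'   absorption closed form [flip_probability()], k_enant/(k_red_eff +
#'   2 k_enant). Both are consistent with the measured hierarchy
#'   r_enant > r_red; see the package vignette for the choice of default.
#' @param record_trajectories Keep the per-molecule half-turn and cycle-count
#'   vectors in the result (default `TRUE`).
#' @return An object of class `motor_sim_config`.
#' @export
motor_sim_config <- function(n_molecules = 1e5,
                             t_end = 48 * 3600,
                             seed = 1L,
                             fuel_model = c("constant", "depleting"),
                             racemization = c("complete", "partial"),
                             record_trajectories = TRUE) {
  stopifnot(n_molecules >= 1, t_end > 0, is.numeric(seed))
  structure(
    list(n_molecules = as.integer(n_molecules), t_end = t_end,
         seed = as.integer(seed), fuel_model = match.arg(fuel_model),
         racemization = match.arg(racemization),
         record_trajectories = isTRUE(record_trajectories)),
    class = "motor_sim_config"
  )
}

# deterministic ensemble fuel trajectory: every oxidation event is followed
# (almost immediately) by a reduction, so fuel is consumed at stoich * v_ox
# mM/s plus first-order background decomposition.
.fuel_at <- function(t, params, stoich = 1) {
  a <- stoich * params$v_ox
  b <- params$k_fuel_bg
  f0 <- params$conc_fuel0
  f <- if (b > 0) (f0 + a / b) * exp(-b * t) - a / b else f0 - a * t
  pmax(f, 0)
}

.step_prob <- function(params, fuel, racemization) {
  if (racemization == "complete") {
    rep(0.5, length(fuel))
  } else {
    ifelse(fuel > 0,
           flip_probability(params$k_enant, params$k_red2 * pmax(fuel, 1e-300)),
           0)
  }
}

#' Stochastic per-molecule simulation of directional motor rotation
#'
#' Simulates an ensemble of independent motor molecules through the cyclic
#' redox network. Each molecule waits an exponential time to oxidation with
#' per-molecule hazard `v_ox / conc_motor_total` (the reduced triol is the
#' resting state, so its concentration is effectively constant), is oxidized
#' to the Sa aldehyde with probability (1 + ee_ox)/2, and the aldehyde phase
#' is resolved by competition between enantiomerization and reduction (see
#' [motor_sim_config()] for the two racemization treatments). Reduction from
#' the enantiomer opposite to the one formed commits a 180 degree step:
#' oxidation to Sa followed by reduction from Ra is +180 (anticlockwise,
#' upper ring viewed from above); the mirror event is -180.
#'
#' Under `fuel_model = "constant"` the per-cycle step statistics are
#' time-invariant, so per-molecule cycle counts are Poisson and the signed
#' half-turn total is sampled exactly from the per-cycle outcome
#' probabilities. Under `"depleting"` each oxidation event is placed
#' uniformly in time (valid for a constant oxidation hazard) and sees the
#' deterministic ensemble fuel level at that moment; events after fuel
#' exhaustion cannot complete a cycle and are dropped.
#'
#' @param params A [rate_parameters()] object.
#' @param config A [motor_sim_config()].
#' @return An object of class `motor_ensemble`: list with `half_turns`
#'   (per-molecule signed count of 180 degree steps), `mean_rotations`
#'   (= mean(half_turns)/2, full 360 turns), `sd_rotations`, `se_rotations`,
#'   `n_cycles_mean`, `histogram` (from [angle_histogram()]), plus the
#'   generating `params`/`config`.
#' @examples
#' res <- simulate_motor(rate_parameters(), motor_sim_config(2e4, seed = 7))
#' res$mean_rotations
#' @export
simulate_motor <- function(params, config) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(config, "motor_sim_config"))
  lambda <- params$v_ox / params$conc_motor_total * config$t_end
  if (lambda > 1e6) {
    stop(sprintf(
      "expected %.3g oxidation cycles per molecule exceeds the 1e6 guard",
      lambda), call. = FALSE)
  }
  n <- config$n_molecules
  # simulate with |ee| and restore the sign afterwards: the model is mirror
  # symmetric, and this makes ee -> -ee negate half_turns exactly at fixed seed
  sgn_ee <- if (params$ee_ox < 0) -1L else 1L
  p_S <- (1 + abs(params$ee_ox)) / 2
  out <- with_seed(config$seed, {
    N <- stats::rpois(n, lambda)
    if (config$fuel_model == "constant") {
      q <- .step_prob(params, params$conc_fuel0, config$racemization)[1]
      steps <- stats::rbinom(n, N, q)          # cycles that commit a 180 step
      plus <- stats::rbinom(n, steps, p_S)     # anticlockwise steps
      half <- 2L * plus - steps
      list(half = half, N = N)
    } else if (sum(N) == 0L) {
      list(half = integer(n), N = integer(n))
    } else {
      K <- sum(N)
      mol <- rep.int(seq_len(n), N)
      tev <- stats::runif(K, 0, config$t_end)
      fuel <- .fuel_at(tev, params, params_stoich(params))
      alive <- fuel > 0
      q <- .step_prob(params, fuel, config$racemization)
      stepped <- alive & (stats::runif(K) < q)
      plus_ev <- stepped & (stats::runif(K) < p_S)
      sgn <- integer(K)
      sgn[stepped] <- -1L
      sgn[plus_ev] <- 1L
      half <- as.integer(rowsum(sgn, mol, reorder = TRUE))
      halfN <- integer(n)
      halfN[sort(unique(mol))] <- half
      Ncompleted <- integer(n)
      cyc <- as.integer(rowsum(as.integer(alive), mol, reorder = TRUE))
      Ncompleted[sort(unique(mol))] <- cyc
      list(half = halfN, N = Ncompleted)
    }
  })
  half <- sgn_ee * out$half
  res <- structure(
    list(half_turns = if (config$record_trajectories) half else NULL,
         n_molecules = n,
         mean_rotations = mean(half) / 2,
         sd_rotations = stats::sd(half) / 2,
         se_rotations = stats::sd(half) / 2 / sqrt(n),
         n_cycles_mean = mean(out$N),
         params = params, config = config),
    class = "motor_ensemble"
  )
  res$histogram <- .angle_histogram_from_half(half)
  res
}

# fuel stoichiometry is a network_spec concept; for rate_parameters assume 1
params_stoich <- function(params) 1

#' @export
print.motor_ensemble <- function(x, ...) {
  cat(sprintf(
    "Motor ensemble: %d molecules, %.3g cycles/molecule (%s fuel, %s racemization)\n",
    x$n_molecules, x$n_cycles_mean, x$config$fuel_model, x$config$racemization))
  cat(sprintf("  mean rotations %.4f +/- %.4f (sd %.3f)\n",
              x$mean_rotations, x$se_rotations, x$sd_rotations))
  invisible(x)
}

#' Closed-form mean number of full rotations (drift oracle)
#'
#' Under constant fuel the expected signed half-turn count is the product of
#' the expected number of oxidation cycles `(v_ox / conc_motor_total) t_end`,
#' the per-cycle step probability (1/2 for complete racemization, the
#' [flip_probability()] closed form otherwise) and the directional bias
#' `ee_ox`; the mean number of 360 degree rotations is half that. This is the
#' analytic oracle against which [simulate_motor()] is validated.
#'
#' @param params A [rate_parameters()] object.
#' @param t_end Operation time, s.
#' @param racemization `"complete"` or `"partial"` (see [motor_sim_config()]).
#' @return Expected number of full 360 rotations per molecule.
#' @examples
#' analytic_mean_rotations(rate_parameters(), 48 * 3600)
#' @export
analytic_mean_rotations <- function(params, t_end,
                                    racemization = c("complete", "partial")) {
  stopifnot(inherits(params, "rate_parameters"), t_end >= 0)
  racemization <- match.arg(racemization)
  cycles <- params$v_ox / params$conc_motor_total * t_end
  q <- if (racemization == "complete") 0.5 else
    flip_probability(params$k_enant, params$k_red2 * params$conc_fuel0)
  cycles * q * params$ee_ox / 2
}

.angle_histogram_from_half <- function(half) {
  rng <- range(half)
  bins <- seq(rng[1], rng[2])
  counts <- tabulate(half - rng[1] + 1L, nbins = length(bins))
  data.frame(angle_deg = bins * 180, count = counts)
}

#' Histogram of net rotation angles
#'
#' Bins the per-molecule net angles at 180 degree resolution. Counts sum to
#' the number of molecules and the distribution mean equals
#' `360 * mean_rotations`.
#'
#' @param result A `motor_ensemble` from [simulate_motor()] (with
#'   `record_trajectories = TRUE`).
#' @return Data frame with columns `angle_deg`, `count`.
#' @export
angle_histogram <- function(result) {
  stopifnot(inherits(result, "motor_ensemble"))
  if (is.null(result$half_turns)) {
    stop("trajectories were not recorded; rerun with record_trajectories = TRUE",
         call. = FALSE)
  }
  .angle_histogram_from_half(result$half_turns)
}

#' Benzylic deuterium incorporation under a deuterated fuel
#'
#' Tracks the hydrogen isotopes at the four benzylic positions (two CH2OH
#' arms, two geminal sites each) of every motor molecule through repeated
#' redox cycles. Each oxidation removes one geminal H/D from one arm (arm and
#' site chosen uniformly when `kie_removal = 1`; with a primary KIE the D
#' sites are chosen with weight `1/kie_removal`) and the subsequent reduction
#' installs the fuel's isotope at the carbonyl carbon. With H3N-BD3 the
#' benzylic D fraction therefore rises monotonically toward 1; with ordinary
#' fuel it stays 0. For `kie_removal = 1` and constant fuel the mean D
#' fraction has the closed form `1 - exp(-lambda(t)/4)` with `lambda(t)` the
#' expected cycle count, which serves as the simulator's oracle.
#'
#' @param params A [rate_parameters()] object.
#' @param config A [motor_sim_config()].
#' @param fuel_isotope `"D"` (trideuteroborane) or `"H"`.
#' @param t_grid Output times, s (defaults to 25 points over the run).
#' @param kie_removal Primary kinetic isotope effect applied to removal of a
#'   deuterium during oxidation (>= 1 slows C-D cleavage). Default 1 (off).
#' @return A data frame of class `deuterium_series` with columns `time_s`,
#'   `frac_D` (mean fraction of benzylic sites carrying D).
#' @export
simulate_deuterium_incorporation <- function(params, config,
                                             fuel_isotope = c("D", "H"),
                                             t_grid = NULL,
                                             kie_removal = 1) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(config, "motor_sim_config"), kie_removal >= 1)
  fuel_isotope <- match.arg(fuel_isotope)
  if (is.null(t_grid)) t_grid <- seq(0, config$t_end, length.out = 25)
  lambda <- params$v_ox / params$conc_motor_total * config$t_end
  if (lambda > 1e6) stop("expected cycle count exceeds the 1e6 guard", call. = FALSE)
  n <- config$n_molecules
  if (fuel_isotope == "H") {
    out <- data.frame(time_s = t_grid, frac_D = 0)
  } else if (kie_removal == 1) {
    # uniform site replacement: only the first hit of each site matters
    out <- with_seed(config$seed, {
      N <- stats::rpois(n, lambda)
      K <- sum(N)
      mol <- rep.int(seq_len(n), N)
      tev <- stats::runif(K, 0, config$t_end)
      site <- sample.int(4L, K, replace = TRUE)
      id <- (mol - 1L) * 4L + site
      first_hit <- rep(Inf, 4L * n)
      ord <- order(tev, decreasing = TRUE)
      first_hit[id[ord]] <- tev[ord]   # earliest event assigned last
      data.frame(time_s = t_grid,
                 frac_D = vapply(t_grid, function(tt) mean(first_hit <= tt),
                                 numeric(1)))
    })
  } else {
    # state-dependent removal weights: sequential per-molecule bookkeeping
    out <- with_seed(config$seed, {
      fracs <- matrix(0, nrow = n, ncol = length(t_grid))
      for (i in seq_len(n)) {
        Ni <- stats::rpois(1L, lambda)
        if (Ni > 0) {
          tev <- sort(stats::runif(Ni, 0, config$t_end))
          sites <- matrix(FALSE, 2L, 2L)  # TRUE = D; [site, arm]
          traj <- numeric(Ni)
          for (cyc in seq_len(Ni)) {
            arm <- sample.int(2L, 1L)
            w <- ifelse(sites[, arm], 1 / kie_removal, 1)
            s <- sample.int(2L, 1L, prob = w)
            sites[s, arm] <- TRUE
            traj[cyc] <- mean(sites)
          }
          idx <- findInterval(t_grid, tev)
          fracs[i, ] <- c(0, traj)[idx + 1L]
        }
      }
      data.frame(time_s = t_grid, frac_D = colMeans(fracs))
    })
  }
  structure(out, class = c("deuterium_series", "data.frame"),
            fuel_isotope = fuel_isotope, kie_removal = kie_removal,
            params = params, config = config)
}
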