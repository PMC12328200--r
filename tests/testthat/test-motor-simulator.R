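test_that("simulation is bit-reproducible and validated", {
  p <- std_params()
  cfg <- motor_sim_config(5000, seed = 99)
  r1 <- simulate_motor(p, cfg)
  r2 <- simulate_motor(p, cfg)
  expect_identical(r1$half_turns, r2$half_turns)
  expect_identical(r1$mean_rotations, r2$mean_rotations)
  # mean_rotations is exactly mean(half_turns)/2
  expect_identical(r1$mean_rotations, mean(r1$half_turns) / 2)
  # resource guard on absurd horizons
  expect_error(
    simulate_motor(p, motor_sim_config(10, t_end = 1e14, seed = 1)),
    "guard")
})

test_that("ensemble mean matches the analytic drift oracle in both modes", {
  p <- std_params()
  for (mode in c("complete", "partial")) {
    r <- simulate_motor(p, motor_sim_config(1e5, seed = 21, racemization = mode))
    expect_lt(abs(r$mean_rotations - analytic_mean_rotations(p, r$config$t_end, mode)),
              3 * r$se_rotations)
  }
})

test_that("drift oracle agreement holds across random parameter sets", {
  set.seed(13)
  for (i in 1:10) {
    p <- rate_parameters(
      k_enant = stats::runif(1, 0.05, 1),
      k_red2 = stats::runif(1, 5e-4, 5e-3),
      v_ox = stats::runif(1, 2e-4, 1e-3),
      ee_ox = stats::runif(1, -1, 1),
      conc_fuel0 = stats::runif(1, 20, 200))
    mode <- if (i %% 2 == 0) "complete" else "partial"
    r <- simulate_motor(p, motor_sim_config(1e5, seed = 1000 + i,
                                            racemization = mode))
    drift <- analytic_mean_rotations(p, r$config$t_end, mode)
    se <- max(r$se_rotations, 1e-12)
    expect_lt(abs(r$mean_rotations - drift), 3 * se)
  }
})

test_that("no enantioselectivity means no net rotation; sign reversal negates it", {
  p0 <- std_params(ee_ox = 0)
  r0 <- simulate_motor(p0, motor_sim_config(1e5, seed = 5))
  expect_lt(abs(r0$mean_rotations), 3 * r0$se_rotations)
  # exact antisymmetry at fixed seed
  rp <- simulate_motor(std_params(ee_ox = 0.876), motor_sim_config(2e4, seed = 8))
  rm <- simulate_motor(std_params(ee_ox = -0.876), motor_sim_config(2e4, seed = 8))
  expect_identical(rp$half_turns, -rm$half_turns)
  expect_identical(rp$mean_rotations, -rm$mean_rotations)
})

test_that("full-selectivity, fast-racemization limit gives N/2 half-turns", {
  # expected cycles N with step probability 1/2 and ee 1: drift N/4 rotations
  p <- std_params(ee_ox = 1, k_enant = 1e4)
  r <- simulate_motor(p, motor_sim_config(1e5, seed = 17, racemization = "partial"))
  N <- p$v_ox / p$conc_motor_total * r$config$t_end
  expect_lt(abs(mean(r$half_turns) - N / 2), 6 * sd(r$half_turns) / sqrt(1e5))
})

test_that("per-molecule cycle counts are Poisson under constant fuel", {
  p <- std_params()
  cfg <- motor_sim_config(1e5, seed = 31)
  lam <- p$v_ox / p$conc_motor_total * cfg$t_end
  r <- simulate_motor(p, cfg)
  expect_within(r$n_cycles_mean, lam, 0.02)
  # chi-square GOF on the count distribution; the per-molecule counts are
  # the first draws of the seeded stream
  N <- local({
    set.seed(cfg$seed)
    stats::rpois(cfg$n_molecules, lam)
  })
  expect_equal(mean(N), r$n_cycles_mean, tolerance = 1e-12)
  brk <- c(0:18, Inf)
  obs <- table(cut(N, breaks = brk, right = FALSE))
  pr <- diff(c(ppois(-1:17, lam), 1))
  keep <- pr * cfg$n_molecules >= 5
  chi <- sum((as.numeric(obs[keep]) - cfg$n_molecules * pr[keep])^2 /
             (cfg$n_molecules * pr[keep]))
  expect_lt(chi, qchisq(0.99, sum(keep) - 1))
})

test_that("angle histogram is consistent with the half-turn counts", {
  r <- simulate_motor(std_params(), motor_sim_config(2e4, seed = 4))
  h <- angle_histogram(r)
  expect_equal(sum(h$count), r$n_molecules)
  expect_equal(sum(h$angle_deg * h$count) / r$n_molecules,
               360 * r$mean_rotations, tolerance = 1e-12)
  expect_true(all(diff(h$angle_deg) == 180))
  # headline-parameter run drifts anticlockwise (right-shifted, positive mean)
  expect_gt(r$mean_rotations, 0)
  # degenerate ensembles
  r0 <- simulate_motor(std_params(v_ox = 0), motor_sim_config(100, seed = 1))
  h0 <- angle_histogram(r0)
  expect_equal(h0, data.frame(angle_deg = 0, count = 100L))
})

test_that("depleting fuel slows rotation relative to constant fuel", {
  p <- std_params(conc_fuel0 = 40)  # exhausted partway through 48 h
  rc <- simulate_motor(p, motor_sim_config(5e4, seed = 12, fuel_model = "constant",
                                           racemization = "partial"))
  rd <- simulate_motor(p, motor_sim_config(5e4, seed = 12, fuel_model = "depleting",
                                           racemization = "partial"))
  # cycles completed after fuel exhaustion are lost in the depleting model
  expect_lt(rd$n_cycles_mean, rc$n_cycles_mean)
  expect_lt(rd$mean_rotations, rc$mean_rotations)
  expect_gt(rd$mean_rotations, 0)
})

test_that("deuterium incorporation follows the per-site replacement chain", {
  p <- std_params()
  cfg <- motor_sim_config(4000, seed = 23)
  # ordinary fuel installs no deuterium
  dH <- simulate_deuterium_incorporation(p, cfg, "H")
  expect_true(all(dH$frac_D == 0))
  # deuterated fuel: monotone rise toward the closed-form chain prediction
  dD <- simulate_deuterium_incorporation(p, cfg, "D")
  expect_true(all(diff(dD$frac_D) >= 0))
  lam_t <- p$v_ox / p$conc_motor_total * dD$time_s
  pred <- 1 - exp(-lam_t / 4)
  expect_lt(max(abs(dD$frac_D - pred)), 0.03)
  # doubling v_ox accelerates the approach at every time point
  cfg2 <- motor_sim_config(4000, seed = 23)
  dFast <- simulate_deuterium_incorporation(std_params(v_ox = 2 * 5.59e-4),
                                            cfg2, "D", t_grid = dD$time_s)
  expect_true(all(dFast$frac_D[-1] >= dD$frac_D[-1]))
  # a primary removal KIE slows nothing at t=0 and still saturates below 1
  dk <- simulate_deuterium_incorporation(p, motor_sim_config(500, seed = 2),
                                         "D", kie_removal = 4)
  expect_true(all(diff(dk$frac_D) >= -1e-12))
  expect_lte(max(dk$frac_D), 1)
})
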