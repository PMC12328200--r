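test_that("Eyring conversion reproduces the measured barrier/rate pairs", {
  # 79 kJ/mol at 40 C was reported alongside a 4.2e-1 /s enantiomerization
  # coefficient; within rounding of the printed barrier the rate is 0.40-0.45
  k79 <- eyring_rate(barrier_spec(79, 313.15))
  expect_gt(k79, 0.40)
  expect_lt(k79, 0.45)
  # zero-barrier limit is the kB*T/h prefactor
  expect_equal(eyring_rate(list(dG_double_dagger = 1e-12, temperature = 313.15)),
               1.380649e-23 * 313.15 / 6.62607015e-34,
               tolerance = 1e-9)
  # frozen closed-form value, cross-checked by independent arithmetic:
  # (kB*373.15/h) * exp(-136000 / (8.314462618*373.15)) = 7.135e-7
  expect_equal(eyring_rate(barrier_spec(136, 373.15)), 7.135106e-07,
               tolerance = 1e-6)
  expect_error(barrier_spec(79, -1), "temperature")
  expect_error(barrier_spec(-5, 300), "dG")
})

test_that("barrier_from_rate inverts eyring_rate across the physical range", {
  expect_equal(barrier_from_rate(0.42, 313.15)$dG_double_dagger, 79,
               tolerance = 0.002)
  expect_equal(barrier_from_rate(7.135106e-07, 373.15)$dG_double_dagger, 136,
               tolerance = 1e-4)
  for (dG in seq(10, 200, by = 19)) {
    for (TK in c(250, 313.15, 373.15, 400)) {
      k <- eyring_rate(barrier_spec(dG, TK))
      expect_equal(eyring_rate(barrier_from_rate(k, TK)), k,
                   tolerance = 1e-9)
    }
  }
  expect_error(barrier_from_rate(0, 313.15), "positive")
})

test_that("no-racemization bound matches the two-day 100 C observation", {
  # frozen from the closed form: k_max = -ln(1-loss)/(2t), then inverse Eyring
  b05 <- min_barrier_from_no_racemization(2 * 86400, 373.15, 0.05)
  expect_equal(b05$dG_double_dagger, 140.8715, tolerance = 1e-6)
  # a ~21.5% detection threshold reproduces the printed 136 kJ/mol bound
  b <- min_barrier_from_no_racemization(2 * 86400, 373.15, 0.215)
  expect_equal(b$dG_double_dagger, 136, tolerance = 1e-3)
  # monotone decreasing in the detection threshold
  losses <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  bars <- vapply(losses, function(l)
    min_barrier_from_no_racemization(2 * 86400, 373.15, l)$dG_double_dagger,
    numeric(1))
  expect_true(all(diff(bars) < 0))
  expect_error(min_barrier_from_no_racemization(100, 373.15, 1.2), "loss")
})

test_that("racemization half-life follows ln2/(2k) and its scaling", {
  expect_equal(racemization_halflife(0.42), log(2) / 0.84, tolerance = 1e-12)
  expect_equal(racemization_halflife(log(2) / 2), 1, tolerance = 1e-12)
  k <- 0.17
  expect_equal(racemization_halflife(2 * k), racemization_halflife(k) / 2,
               tolerance = 1e-12)
  expect_error(racemization_halflife(0), "positive")
})

test_that("flip probability closed form matches the CTMC oracle", {
  set.seed(42)
  n <- 1e6
  p_hat <- ctmc_flip_oracle(0.42, 0.21, n)
  p <- flip_probability(0.42, 0.21)
  expect_equal(p, 0.4, tolerance = 1e-12)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), 3 * se)
  # limits
  expect_identical(flip_probability(0, 1), 0)
  expect_equal(flip_probability(1e12, 1), 0.5, tolerance = 1e-9)
  expect_error(flip_probability(1, 0), "k_red_eff")
})

test_that("flip probability agrees with the oracle over random rate pairs", {
  set.seed(7)
  for (i in 1:10) {
    k_e <- stats::runif(1, 0.05, 1)
    k_r <- stats::runif(1, 0.2, 2)   # bounded flip/absorb ratio keeps the
    n <- 1e6                         # oracle's jump count small
    p <- flip_probability(k_e, k_r)
    p_hat <- ctmc_flip_oracle(k_e, k_r, n)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("hierarchy report reproduces the 0.50 ratio and is linear in fuel", {
  hr <- hierarchy_report(std_params())
  expect_equal(hr$ratio_red_over_enant, 0.50, tolerance = 1e-12)
  expect_true(hr$hierarchy_satisfied)
  hr2 <- hierarchy_report(std_params(conc_fuel0 = 200))
  expect_equal(hr2$ratio_red_over_enant, 1.0, tolerance = 1e-12)
  expect_false(hr2$hierarchy_satisfied)
  # linear in fuel
  fuels <- c(10, 50, 100, 150)
  ratios <- vapply(fuels, function(f)
    hierarchy_report(std_params(conc_fuel0 = f))$ratio_red_over_enant,
    numeric(1))
  expect_equal(ratios, 0.50 * fuels / 100, tolerance = 1e-12)
  hr0 <- hierarchy_report(std_params(conc_fuel0 = 0))
  expect_equal(hr0$ratio_red_over_enant, 0)
  expect_true(hr0$hierarchy_satisfied)
  expect_match(hr0$notes, "no fuel")
  expect_error(hierarchy_report(std_params(k_enant = 0)), "undefined")
})

test_that("pseudo-zero-order fit recovers slopes, windows saturating tails", {
  t <- seq(0, 3600, length.out = 20)
  fit <- fit_pseudo_zero_order(t, 5.59e-4 * t)
  expect_equal(fit$estimate, 5.59e-4, tolerance = 1e-10)
  expect_lt(fit$stderr, 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant series: zero slope
  fit0 <- fit_pseudo_zero_order(t, rep(0.3, 20))
  expect_equal(fit0$estimate, 0, tolerance = 1e-12)
  # noisy recovery at the stated noise level
  g <- gen_oxidation_progress(v_ox = 5.59e-4, noise_sd = 0.02, n_points = 20,
                              seed = 11)
  fitn <- fit_pseudo_zero_order(g$time_s, g$conc_mM)
  expect_within(fitn$estimate, 5.59e-4, 0.05)
  # saturating tail triggers windowing
  gs <- gen_oxidation_progress(v_ox = 5.59e-4, t_max = 4000, noise_sd = 0.002,
                               n_points = 40, saturating = TRUE, c_max = 1,
                               seed = 5)
  fits <- fit_pseudo_zero_order(gs$time_s, gs$conc_mM)
  expect_lt(fits$n, 40)
  expect_within(fits$estimate, 5.59e-4, 0.1)
  expect_error(fit_pseudo_zero_order(t[1:2], t[1:2]), "3 points")
  expect_error(fit_pseudo_zero_order(c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("pseudo-first-order reduction fit recovers k_red2", {
  t <- seq(0, 30, length.out = 30)
  y <- 0.1 * exp(-2.1e-3 * 100 * t)
  fit <- fit_pseudo_first_order_reduction(t, y, fuel_conc = 100)
  expect_equal(fit$estimate, 2.1e-3, tolerance = 1e-7)
  expect_false(fit$flagged)
  # noisy recovery
  g <- gen_reduction_progress(k_red2 = 2.1e-3, fuel = 100, noise_sd = 0.01,
                              n_points = 30, seed = 3)
  fitn <- fit_pseudo_first_order_reduction(g$time_s, g$conc_mM, 100)
  expect_within(fitn$estimate, 2.1e-3, 0.05)
  # flat data: near-zero estimate, flagged
  flat <- fit_pseudo_first_order_reduction(t, rep(0.1, 30), fuel_conc = 100)
  expect_true(flat$flagged)
  expect_lt(flat$estimate, 1e-6)
  expect_error(fit_pseudo_first_order_reduction(t, -y, 100), "positive")
  expect_warning(fit_pseudo_first_order_reduction(t, y, fuel_conc = 0.5),
                 "excess")
})
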