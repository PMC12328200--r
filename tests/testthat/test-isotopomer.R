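obs_Sa <- isotopomer_observation("Sa", 0.93, 0.07)
obs_Ra <- isotopomer_observation("Ra", 0.05, 0.95)

test_that("forward model reproduces the measured label distributions", {
  # no selectivity, no KIE: label splits evenly
  expect_equal(forward_cdo_fraction(1, 1, "Sa"), 0.5, tolerance = 1e-12)
  expect_equal(forward_cdo_fraction(1, 1, "Ra"), 0.5, tolerance = 1e-12)
  # the jointly estimated (s, kie) reproduce both observed ratios
  est <- joint_ee_kie(obs_Sa, obs_Ra)
  expect_equal(forward_cdo_fraction(est$selectivity_s, est$kie, "Sa"), 0.93,
               tolerance = 1e-9)
  expect_equal(forward_cdo_fraction(est$selectivity_s, est$kie, "Ra"), 0.05,
               tolerance = 1e-9)
  # reduced label purity pulls both configurations toward 0.5
  f_pure <- forward_cdo_fraction(15.9, 1.2, "Sa", purity = 1)
  f_95 <- forward_cdo_fraction(15.9, 1.2, "Sa", purity = 0.95)
  expect_lt(f_95, f_pure)
  expect_gt(f_95, 0.5)
  expect_error(forward_cdo_fraction(-1, 1, "Sa"), "positive")
})

test_that("per-experiment estimates match the direct ratio arithmetic", {
  eS <- ee_per_experiment_no_kie(obs_Sa)
  expect_equal(eS$selectivity_s, 0.93 / 0.07, tolerance = 1e-9)
  expect_equal(eS$ee, (0.93 / 0.07 - 1) / (0.93 / 0.07 + 1), tolerance = 1e-9)
  expect_equal(round(eS$ee, 3), 0.860)
  eR <- ee_per_experiment_no_kie(obs_Ra)
  expect_equal(eR$selectivity_s, 19, tolerance = 1e-9)
  expect_equal(eR$ee, 0.9, tolerance = 1e-9)
  expect_equal(ee_per_experiment_no_kie(
    isotopomer_observation("Sa", 0.5, 0.5))$ee, 0, tolerance = 1e-12)
  expect_error(ee_per_experiment_no_kie(
    isotopomer_observation("Sa", 1, 0)), "degenerate")
})

test_that("joint estimator solves the two-experiment system exactly", {
  est <- joint_ee_kie(obs_Sa, obs_Ra)
  expect_equal(est$selectivity_s, sqrt((0.93 / 0.07) * 19), tolerance = 1e-9)
  expect_equal(est$kie, sqrt(19 / (0.93 / 0.07)), tolerance = 1e-9)
  expect_equal(round(est$ee, 3), 0.882)
  expect_equal(round(est$kie, 2), 1.20)
  # symmetric observations imply kie = 1 and s = a/b
  est_sym <- joint_ee_kie(isotopomer_observation("Sa", 0.8, 0.2),
                          isotopomer_observation("Ra", 0.2, 0.8))
  expect_equal(est_sym$kie, 1, tolerance = 1e-12)
  expect_equal(est_sym$selectivity_s, 4, tolerance = 1e-12)
  # no information: s = 1, ee = 0, kie = 1
  est0 <- joint_ee_kie(isotopomer_observation("Sa", 0.5, 0.5),
                       isotopomer_observation("Ra", 0.5, 0.5))
  expect_equal(c(est0$selectivity_s, est0$ee, est0$kie), c(1, 0, 1),
               tolerance = 1e-12)
  expect_error(joint_ee_kie(obs_Ra, obs_Sa), "configuration")
})

test_that("forward/inverse roundtrip recovers (s, kie) to 1e-9 relative", {
  for (s in c(1, 2.5, 15.9, 50)) {
    for (kie in c(0.8, 1, 1.2, 4, 8)) {
      fS <- forward_cdo_fraction(s, kie, "Sa")
      fR <- forward_cdo_fraction(s, kie, "Ra")
      est <- joint_ee_kie(isotopomer_observation("Sa", fS, 1 - fS),
                          isotopomer_observation("Ra", fR, 1 - fR))
      expect_equal(est$selectivity_s, s, tolerance = 1e-9)
      expect_equal(est$kie, kie, tolerance = 1e-9)
    }
  }
})

test_that("the two no-KIE estimates bracket the joint estimate when KIE > 1", {
  eS <- ee_per_experiment_no_kie(obs_Sa)$ee
  eR <- ee_per_experiment_no_kie(obs_Ra)$ee
  joint <- joint_ee_kie(obs_Sa, obs_Ra)
  expect_gt(joint$kie, 1)
  expect_lte(eS, joint$ee)
  expect_lte(joint$ee, eR)
})

test_that("ee estimates are antisymmetric under swapping the channels", {
  # exchanging the roles of the two channels inverts s and negates ee
  e1 <- ee_per_experiment_no_kie(isotopomer_observation("Sa", 0.93, 0.07))
  e2 <- ee_per_experiment_no_kie(isotopomer_observation("Sa", 0.07, 0.93))
  expect_equal(e1$ee, -e2$ee, tolerance = 1e-12)
  expect_equal(e1$selectivity_s, 1 / e2$selectivity_s, tolerance = 1e-12)
})

test_that("bootstrap CI behaves with integral uncertainty", {
  oS <- isotopomer_observation("Sa", 0.93, 0.07, integral_sd = 0.02)
  oR <- isotopomer_observation("Ra", 0.05, 0.95, integral_sd = 0.02)
  est <- bootstrap_ci(oS, oR, n_boot = 5000, seed = 77)
  # point estimate unchanged by bootstrapping
  expect_equal(est$ee, joint_ee_kie(obs_Sa, obs_Ra)$ee, tolerance = 1e-9)
  expect_true(est$ci_ee[1] <= est$ee && est$ee <= est$ci_ee[2])
  width <- diff(as.numeric(est$ci_ee))
  expect_gt(width, 0.005)
  expect_lt(width, 0.15)  # a few % ee
  # reproducible under the seed
  est2 <- bootstrap_ci(oS, oR, n_boot = 5000, seed = 77)
  expect_identical(est$ci_ee, est2$ci_ee)
  # zero uncertainty: zero-width CI
  est0 <- bootstrap_ci(obs_Sa, obs_Ra, n_boot = 1000, seed = 1)
  expect_equal(diff(as.numeric(est0$ci_ee)), 0, tolerance = 1e-12)
  # CI width monotone non-decreasing in the integral uncertainty
  widths <- vapply(c(0.005, 0.01, 0.02, 0.04), function(sd) {
    o1 <- isotopomer_observation("Sa", 0.93, 0.07, integral_sd = sd)
    o2 <- isotopomer_observation("Ra", 0.05, 0.95, integral_sd = sd)
    diff(as.numeric(bootstrap_ci(o1, o2, n_boot = 4000, seed = 5)$ci_ee))
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})
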