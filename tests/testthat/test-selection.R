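test_that("AICc follows the small-sample correction formula", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17)
  expect_equal(aicc(-10, 2, 20), 24.70588, tolerance = 1e-5)
  # undefined when n <= k + 1
  expect_identical(aicc(-10, 5, 6), Inf)
})

test_that("proportional-consumption trends classify the canonical shapes", {
  N0 <- rep(c(2, 4, 8, 16, 32, 64), each = 5)
  # exactly constant proportions
  flat <- trial_set(N0 = N0, eaten = N0 / 2, T = 1)
  expect_equal(proportional_trend(flat), "flat")
  # strictly decreasing proportions
  prop <- 0.9 * (N0 / 2)^(-0.45)
  dec <- trial_set(N0 = N0, eaten = round(N0 * prop), T = 1)
  expect_equal(proportional_trend(dec), "decreasing")
  # sigmoidal generator: proportions rise then fall
  tr3 <- generate_trials(fr_params(0.02, 0.05, 1),
                         c(2, 4, 8, 16, 32, 64, 128), 25, T = 1, seed = 2)
  expect_equal(proportional_trend(tr3), "hump")
  expect_error(proportional_trend(trial_set(N0 = rep(8, 4), eaten = 1, T = 1)),
               "one density level")
})

test_that("AICc selection picks the generating variant on clear data", {
  tr <- strong_type2_trials(b = 0.5, h = 0.1, seed = 21)
  sel <- fr_select(tr)
  expect_equal(sel$selected$variant, "II")
  expect_equal(sel$table$dAICc[1], 0)
  # ranked table is internally consistent
  expect_equal(sel$table$AICc, sel$table$AICc[1] + sel$table$dAICc)
  expect_equal(sel$table$AICc,
               mapply(aicc, sel$table$logLik, sel$table$k, nrow(tr)))
  tr3 <- generate_trials(fr_params(0.02, 0.05, 1),
                         c(2, 4, 8, 16, 32, 64, 128), 25, T = 1, seed = 22)
  sel3 <- fr_select(tr3)
  expect_true(sel3$selected$variant %in% c("III", "general"))
  if (sel3$selected$variant == "general")
    expect_gt(sel3$selected$params$q, 0.5)
})

test_that("competitive models are separated by the diagnostic", {
  # weak saturation: I and II typically competitive; decreasing proportions
  # should resolve towards II when they are
  tr <- generate_trials(fr_params(0.15, 0.08, 0), c(2, 4, 8, 16, 32, 64),
                        30, T = 1, seed = 8)
  sel <- fr_select(tr)
  if (sum(sel$table$dAICc < 2) > 1 && sel$diagnostic == "decreasing") {
    expect_true(sel$selected$variant %in% c("II", "general"))
  }
  expect_true(sel$selected$variant != "I" ||
                sel$diagnostic %in% c("flat", "ambiguous", NA_character_))
})

test_that("bootstrap of group mean shape exponents behaves", {
  # all values equal: zero-width interval
  r <- bootstrap_mean_q(rep(1, 8), rep("a", 8), n_boot = 200, seed = 1)
  expect_equal(r$lo, r$hi)
  expect_equal(r$mean, 1)
  # {0, 1} group: mean near 0.5 with binomial-scale spread
  set.seed(1)
  q <- rep(c(0, 1), 50)
  r2 <- bootstrap_mean_q(q, rep("g", 100), n_boot = 2000, seed = 4)
  expect_equal(r2$mean, 0.5, tolerance = 1e-9)
  expect_lt(r2$lo, 0.5)
  expect_gt(r2$hi, 0.5)
  expect_lt(r2$hi - r2$lo, 4 * sqrt(0.25 / 100) * 2)
  # determinism under seed
  r3 <- bootstrap_mean_q(q, rep("g", 100), n_boot = 2000, seed = 4)
  expect_identical(r2, r3)
  # single-member groups flagged degenerate
  r4 <- bootstrap_mean_q(c(0, 1), c("a", "b"), n_boot = 50, seed = 2)
  expect_true(all(r4$degenerate))
})

test_that("half-saturation capture rate has the right closed forms", {
  expect_equal(half_saturation_rate(fr_params(0.3, 0.5, 0)), 0.3)
  # q = 1, b = 4, h = 1: N_half = 0.5, rate = 2
  expect_equal(half_saturation_rate(fr_params(4, 1, 1)), 2.0)
  # effective-coefficient and derivative readings agree up to (q+1)/4
  p <- fr_params(0.7, 0.2, 1.3)
  eff <- half_saturation_rate(p)
  der <- half_saturation_rate(p, method = "derivative")
  expect_equal(der, eff * (p$q + 1) / 4, tolerance = 1e-12)
  # derivative reading equals a numeric slope of the response curve
  N_half <- (p$b * p$h)^(-1 / (p$q + 1))
  eps <- N_half * 1e-6
  num <- (holling_rate(N_half + eps, p) - holling_rate(N_half - eps, p)) /
    (2 * eps)
  expect_equal(der, num, tolerance = 1e-5)
  expect_warning(half_saturation_rate(fr_params(0.3, 0, 0)), "saturate")
})

test_that("biomass conversion scales by resource mass and day length", {
  p <- fr_params(0.3, 0.5, 0)
  r <- biomass_rates(p, resource_mass_g = 2, time_unit = "s")
  expect_equal(r$capture_gd, 0.3 * 2 * 86400)
  expect_equal(r$max_feed_gd, (1 / 0.5) * 2 * 86400)
  r2 <- biomass_rates(p, resource_mass_g = 2, time_unit = "d")
  expect_equal(r2$capture_gd, 0.6)
})
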