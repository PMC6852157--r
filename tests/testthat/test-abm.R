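test_that("a still world with distant resources never encounters", {
  set.seed(1)
  res <- cbind(rep(0.05, 5), seq(0.05, 0.25, length.out = 5))
  w <- static_world(res, extent = 1, r = 0.1)
  w$consumer_pos <- c(0.7, 0.7)
  lg <- abm_run(w, 50)
  expect_equal(sum(lg$counts), 0)
  expect_equal(lg$unitary_rate, 0)
})

test_that("a resource placed inside the region registers once, immediately", {
  set.seed(2)
  w <- static_world(matrix(c(0.52, 0.5), nrow = 1), extent = 1, r = 0.1)
  lg1 <- abm_step(w)
  expect_equal(lg1$step_encounters, 1L)
  # relocation happened: resource is now outside the region
  d <- sqrt(sum((lg1$res_pos[1, ] - lg1$consumer_pos)^2))
  expect_gt(d, 0.1)
})

test_that("resource count is conserved and biomass identity holds exactly", {
  set.seed(3)
  w <- abm_world(2, extent = 2, r = 0.1, consumer_speed = 0.05,
                 n_resources = 40, resource_mass = 0.37)
  for (i in 1:30) {
    w <- abm_step(w)
    expect_equal(nrow(w$res_pos), 40)
  }
  lg <- run_replicate(0.5, "active-static", seed = 9, n_steps = 100)
  expect_equal(lg$biomass_rate, lg$unitary_rate * lg$resource_mass)
})

test_that("replicates are bitwise reproducible under a fixed seed", {
  lg1 <- run_replicate(1, "filter", seed = 77, n_steps = 60)
  lg2 <- run_replicate(1, "filter", seed = 77, n_steps = 60)
  expect_identical(lg1, lg2)
  lg3 <- run_replicate(1, "filter", seed = 78, n_steps = 60)
  expect_false(identical(lg1$counts, lg3$counts))
})

test_that("zero duration yields zero rates and config is guarded", {
  w <- abm_world(2, extent = 1, r = 0.05, consumer_speed = 0.01,
                 n_resources = 5)
  lg <- abm_run(w, 0)
  expect_equal(lg$unitary_rate, 0)
  expect_equal(lg$biomass_rate, 0)
  # aliasing guard: step length above half the arena
  expect_error(abm_world(2, extent = 1, r = 0.05, consumer_speed = 10,
                         n_resources = 5, dt = 1), "aliasing")
  expect_error(abm_world(2, extent = 0.05, r = 0.05, n_resources = 1),
               "twice the reaction distance")
})

test_that("quantile bands collapse at one replicate and flag small n", {
  expect_warning(
    sw <- sweep_consumer_mass("active-static", 1, replicates = 1,
                              n_steps = 50, seed = 1),
    "unstable")
  expect_equal(sw$unitary_lo, sw$unitary_med)
  expect_equal(sw$unitary_med, sw$unitary_hi)
  tidy <- attr(sw, "replicates")
  expect_equal(nrow(tidy), 1)
})

test_that("analytic encounter rates follow the kinetic formulas", {
  expect_equal(analytic_encounter_rate("2D-active-static", r = 0.1, n = 10,
                                       V = 0.05), 0.1)
  expect_equal(analytic_encounter_rate("3D-advective-filter", r = 0.05,
                                       n = 1000, U = 0.1),
               1000 * 0.1 * pi * 0.05^2 / 2)
  expect_equal(analytic_encounter_rate("2D-active-static", r = 0.1, n = 0,
                                       V = 0.05), 0)
  # relative speed: resting partner reduces to the mover's speed
  expect_equal(mean_relative_speed(0.05, 0), 0.05)
  expect_equal(mean_relative_speed(0, 0), 0)
  # symmetric and at least as large as the speed difference
  expect_equal(mean_relative_speed(0.02, 0.05), mean_relative_speed(0.05, 0.02))
  expect_gt(mean_relative_speed(0.05, 0.05), 0.05)
  expect_error(analytic_encounter_rate("2D-active-static", r = 0.1, n = 1),
               "V required")
})

test_that("simulated 2D search rate approaches 2rVn in the ballistic regime", {
  set.seed(11)
  tot <- 0; dur <- 0
  for (i in 1:150) {
    w <- abm_world(2, extent = 3, r = 0.1, consumer_speed = 0.05,
                   n_resources = 90, resource_mass = 1,
                   sigma_turn = 5 * pi / 180)
    lg <- abm_run(w, 150)
    tot <- tot + sum(lg$counts); dur <- dur + lg$duration
  }
  expect_lt(abs(tot / dur - 0.1) / 0.1, 0.1)
})

test_that("realised advective current matches its configuration", {
  lg <- run_replicate(1, "filter", seed = 13, n_steps = 500,
                      n_resources = 100)
  se <- 0.01 / sqrt(lg$n_current_samples)
  expect_lt(abs(lg$mean_current - 0.1), 2 * se + 1e-6)
})

test_that("density rescaling preserves rate linearity within noise", {
  # same physical density simulated at two resource counts
  rates <- vapply(c(300, 900), function(nres) {
    set.seed(21)
    tot <- 0; dur <- 0
    for (i in 1:40) {
      w <- abm_world(3, extent = 0.4, r = 0.05, consumer_speed = 0,
                     n_resources = nres, resource_mass = 1,
                     planktonic = TRUE, height = 0.5)
      lg <- abm_run(w, 100)
      tot <- tot + sum(lg$counts); dur <- dur + lg$duration
    }
    tot / dur
  }, numeric(1))
  expect_lt(abs(rates[2] / rates[1] - 3), 0.35)
})
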