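test_that("trial generator honours the degenerate limits", {
  # zero capture: nothing eaten
  tr <- generate_trials(fr_params(0, 0.5, 1), c(2, 4, 8, 16), 10, T = 1,
                        seed = 1)
  expect_true(all(tr$eaten == 0))
  # exhaustive depletion: h = 0, q = 0, large bT
  tr2 <- generate_trials(fr_params(20, 0, 0), c(2, 4, 8, 16), 10, T = 5,
                         seed = 2)
  expect_true(all(tr2$eaten == tr2$N0))
  expect_error(generate_trials(fr_params(1, 0, 0), c(0, 4), 5, 1, 1),
               "positive integers")
})

test_that("binomial trial noise is centred on the depletion expectation", {
  p <- fr_params(0.01, 0.1, 0)
  levels <- c(2, 4, 8, 16, 32)
  reps <- 20
  tr <- generate_trials(p, levels, reps, T = 1, seed = 31)
  ne <- rogers_eaten(levels, 1, p)
  for (i in seq_along(levels)) {
    pe <- ne[i] / levels[i]
    obs <- mean(tr$eaten[tr$N0 == levels[i]] / levels[i])
    se <- sqrt(pe * (1 - pe) / (levels[i] * reps))
    expect_lt(abs(obs - pe), 3 * se + 1e-12)
  }
  # deterministic under seed
  tr_b <- generate_trials(p, levels, reps, T = 1, seed = 31)
  expect_identical(tr, tr_b)
})

test_that("event-level depletion mode tracks the binomial mode in the mean", {
  p <- fr_params(0.05, 0.2, 0)
  tr <- generate_trials(p, c(8, 32), 150, T = 1, seed = 5,
                        depletion_mode = "event")
  ne <- rogers_eaten(c(8, 32), 1, p)
  for (i in c(1, 2)) {
    lvl <- c(8, 32)[i]
    expect_lt(abs(mean(tr$eaten[tr$N0 == lvl]) - ne[i]) / ne[i], 0.25)
  }
})

test_that("meta-dataset generator is deterministic and structured", {
  cfg0 <- generator_config(seed = 4, n_pairs = 0)
  empty <- generate_meta_dataset(cfg0)
  expect_equal(nrow(empty$trials), 0)
  expect_equal(nrow(empty$truth), 0)

  cfg <- generator_config(seed = 4, n_pairs = 15, replicates = 6)
  d1 <- generate_meta_dataset(cfg)
  d2 <- generate_meta_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$truth), 15)
  expect_equal(nrow(d1$trials), 15 * cfg$n_levels * 6)
  # truth and trials agree on covariates
  m <- match(d1$trials$pair_id, d1$truth$pair_id)
  expect_equal(d1$trials$consumer_mass_g, d1$truth$consumer_mass_g[m])
  # filter feeders face the smallest resources at 3D geometry
  if (any(d1$truth$strategy == "filter") &&
      any(d1$truth$strategy == "active-static")) {
    expect_lt(max(d1$truth$resource_mass_g[d1$truth$strategy == "filter"]),
              min(d1$truth$resource_mass_g[d1$truth$strategy == "active-static"]))
    expect_true(all(d1$truth$arena_dim[d1$truth$strategy == "filter"] == 3))
  }
})

test_that("strategy assignment is multinomial around the requested mix", {
  cfg <- generator_config(seed = 10, n_pairs = 99, replicates = 2,
                          n_levels = 4,
                          strategy_mix = c("active-mobile" = 1 / 3,
                                           "active-static" = 1 / 3,
                                           "filter" = 1 / 3))
  d <- generate_meta_dataset(cfg)
  counts <- table(d$truth$strategy)
  # 3 binomial SDs around 33
  expect_true(all(abs(counts - 33) <= 3 * sqrt(99 * (1 / 3) * (2 / 3))))
})

test_that("generated trial tables pass the pipeline schema unchanged", {
  cfg <- generator_config(seed = 6, n_pairs = 5, replicates = 4)
  d <- generate_meta_dataset(cfg)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(d$trials, path)
  expect_true(validate_table(path, "trials")$ok)
  back <- read_trials_csv(path)
  expect_equal(nrow(back), nrow(d$trials))
  expect_equal(attr(back, "time_unit"), "d")
  expect_equal(back$eaten, d$trials$eaten)
})

test_that("allometry point generator matches its law exactly when noiseless", {
  law <- power_law(2.67, 1.05)
  pts <- generate_allometry_points(law, 10, sigma = 0, x_range = c(1, 1),
                                   seed = 1)
  expect_equal(pts$y, rep(2.67, 10))
  flat <- generate_allometry_points(power_law(1, 0), 10, 0, c(0.1, 10), 2)
  expect_equal(flat$y, rep(1, 10))
  expect_error(generate_allometry_points(law, 10, 0, c(-1, 1), 1), "positive")
})

test_that("power-law exponent is recovered from noisy points", {
  law <- power_law(2.67, 1.05)
  pts <- generate_allometry_points(law, 500, sigma = 0.2,
                                   x_range = c(1e-3, 1), seed = 12)
  fit <- fit_power_law(pts$x, pts$y)
  expect_lt(abs(fit$exponent - 1.05), 0.05)
})

test_that("fitting trials generated with the true variant recovers b and h", {
  # scaled version of the round-trip contract: 5 density levels, 20
  # replicates, medium signal; estimates should fall within twice the Wald
  # interval half-width in the large majority of repetitions
  n_rep <- 25
  hits <- 0
  for (s in seq_len(n_rep)) {
    tr <- generate_trials(fr_params(0.4, 0.12, 0), c(2, 4, 8, 16, 32), 20,
                          T = 1, seed = 1000 + s)
    f <- fr_fit(tr, "II")
    if (is.null(f$se_log)) next
    ok_b <- abs(log(coef(f)[["b"]]) - log(0.4)) <=
      2 * 1.96 * f$se_log[["logb"]]
    ok_h <- abs(log(coef(f)[["h"]]) - log(0.12)) <=
      2 * 1.96 * f$se_log[["logh"]]
    hits <- hits + (ok_b && ok_h)
  }
  expect_gte(hits / n_rep, 0.85)
})
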