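test_that("the fixed-effect structure set is exactly the hierarchical 36", {
  st <- enumerate_structures()
  expect_length(st, 36)
  labels <- vapply(st, bencounter:::format_structure, character(1))
  expect_equal(anyDuplicated(labels), 0)
  expect_true("~ 1" %in% labels)
  # marginality: every interaction's parents are present
  for (s in st) {
    for (int in s$interactions) {
      parents <- strsplit(int, ":")[[1]]
      expect_true(all(parents %in% s$mains))
    }
  }
  # 18 without strategy, 18 with
  expect_equal(sum(vapply(st, function(s) s$strategy, logical(1))), 18)
})

test_that("mixed-model fits recover known slopes and group structure", {
  rec <- generate_meta_records(200, beta_C = 0.8, beta_R = 0.2,
                               group_sd = 0.5, sigma = 0.5, seed = 17)
  s <- structure(list(mains = c("C", "R"), interactions = character(),
                      strategy = FALSE), class = "meta_structure")
  f <- fit_structure(rec, s, response = "response")
  fe <- lme4::fixef(f$model)
  ci_half <- 2 * sqrt(diag(as.matrix(stats::vcov(f$model))))
  expect_lt(abs(fe[["log_consumer_mass"]] - 0.8),
            ci_half[2] + 0.1)
  expect_lt(abs(fe[["log_resource_mass"]] - 0.2), ci_half[3] + 0.1)
  # k counts fixed effects + two variance components
  expect_equal(f$k, 3L + 2L)
  expect_equal(f$AICc, aicc(f$loglik, f$k, nrow(rec)))

  # degenerate group variance is detected
  rec0 <- generate_meta_records(150, group_sd = 0, sigma = 0.4, seed = 18)
  f0 <- fit_structure(rec0, s, response = "response")
  sd_est <- attr(lme4::VarCorr(f0$model)$taxon_group, "stddev")
  expect_lt(unname(sd_est), 0.1)

  # null structure on a standardised response: intercept near zero
  rec$response <- as.numeric(scale(rec$response))
  null_s <- structure(list(mains = character(), interactions = character(),
                           strategy = FALSE), class = "meta_structure")
  fn <- fit_structure(rec, null_s, response = "response")
  expect_lt(abs(lme4::fixef(fn$model)[["(Intercept)"]]), 0.3)
  expect_error(fit_structure(rec[rec$taxon_group == rec$taxon_group[1], ],
                             null_s, "response"), "taxon groups")
})

test_that("structure selection finds strong generating effects", {
  found <- 0
  for (s in 1:4) {
    rec <- generate_meta_records(200, beta_C = 1, beta_R = 0.6,
                                 strategy_effects = c("active-mobile" = 0,
                                                      "active-static" = 0.3,
                                                      "filter" = -1.5),
                                 group_sd = 0.3, sigma = 0.4, seed = 100 + s)
    sel <- select_structure(rec, "response", refit_reml = FALSE)
    top <- sel$table$structure[1]
    if (grepl("C", top, fixed = TRUE) && grepl("R", top, fixed = TRUE) &&
        grepl("strategy", top, fixed = TRUE)) found <- found + 1
  }
  expect_gte(found, 3)
})

test_that("pure-noise responses keep the null model competitive", {
  good <- 0
  for (s in 1:4) {
    rec <- generate_meta_records(120, beta_C = 0, beta_R = 0, beta_T = 0,
                                 group_sd = 0, sigma = 1, seed = 200 + s)
    sel <- select_structure(rec, "response", refit_reml = FALSE)
    d_null <- sel$table$dAICc[sel$table$structure == "~ 1"]
    if (length(d_null) == 1 && d_null < 2) good <- good + 1
  }
  expect_gte(good, 3)
  # and the reported AICc values match direct recomputation
  rec <- generate_meta_records(100, seed = 300)
  sel <- select_structure(rec, "response", refit_reml = FALSE)
  n <- nrow(rec)
  expect_equal(sel$table$AICc,
               mapply(aicc, sel$table$logLik, sel$table$k, n))
})

test_that("meta-table assembly transforms, standardises and excludes", {
  cfg <- generator_config(seed = 31, n_pairs = 18, replicates = 10,
                          n_levels = 5)
  d <- generate_meta_dataset(cfg)
  fitted <- fit_all_pairs(d$trials)
  tab <- build_meta_table(fitted, time_unit = "d")
  expect_s3_class(tab, "meta_table")
  # both responses are z-scored over the retained rows
  expect_equal(mean(tab$log_capture), 0, tolerance = 1e-8)
  expect_equal(stats::sd(tab$log_capture), 1, tolerance = 1e-8)
  # only focal strategies retained; exclusions accounted for
  expect_true(all(tab$strategy %in% c("active-mobile", "active-static",
                                      "filter")))
  excl <- attr(tab, "excluded")
  expect_equal(nrow(tab) + sum(excl), attr(tab, "n_input"))
  # temperature handling: log of Celsius requires positive temperatures
  bad <- fitted
  bad$temp_C[1] <- -2
  tab2 <- build_meta_table(bad, time_unit = "d")
  expect_gte(attr(tab2, "excluded")[["temperature"]], 1)
})

test_that("bootstrap prediction bands behave and separate shifted groups", {
  rec <- generate_meta_records(150, beta_C = 0.8, beta_R = 0.1,
                               strategy_effects = c("active-mobile" = 0,
                                                    "active-static" = 0.2,
                                                    "filter" = -2),
                               group_sd = 0.2, sigma = 0.3, seed = 55)
  s <- structure(list(mains = c("C", "R"), interactions = character(),
                      strategy = TRUE), class = "meta_structure")
  f <- fit_structure(rec, s, response = "response")
  # n_boot = 0: point predictions only
  p0 <- bootstrap_predictions(f, rec, n_boot = 0)
  expect_true(all(is.na(p0$lo)))
  bp <- bootstrap_predictions(f, rec, n_boot = 40, seed = 2)
  expect_true(all(bp$lo <= bp$fit & bp$fit <= bp$hi))
  # the depressed filter band sits fully below the active bands at the
  # top of the mass grid
  top <- max(bp$log_consumer_mass)
  at_top <- bp[bp$log_consumer_mass == top, ]
  expect_lt(at_top$hi[at_top$strategy == "filter"],
            min(at_top$lo[at_top$strategy != "filter"]))
})
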