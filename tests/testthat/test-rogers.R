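test_that("holling_rate matches its closed form and limits", {
  expect_equal(holling_rate(0, fr_params(1, 1, 0)), 0)
  # half-saturation identity: at N = 1/(b h), rate = 1/(2h)
  b <- 0.3; h <- 0.4
  expect_equal(holling_rate(1 / (b * h), fr_params(b, h, 0)), 1 / (2 * h))
  expect_equal(holling_rate(1, fr_params(2, 0.5, 1)), 1)
  # monotone non-decreasing, saturating at 1/h
  N <- seq(0, 1e4, length.out = 200)
  r <- holling_rate(N, fr_params(0.05, 0.2, 1))
  expect_true(all(diff(r) >= 0))
  expect_lt(abs(r[length(r)] - 1 / 0.2), 1e-3)
  expect_error(holling_rate(-1, fr_params(1, 0, 0)), "non-negative")
})

test_that("lambert_w0 inverts w * exp(w) and agrees with pracma", {
  x <- c(0, 1e-12, 1e-4, 0.1, 1, 2.99, 3, 10, 500, 1e4, 1e10, 1e100, 1e300)
  w <- lambert_w0(x)
  small <- x < 700
  expect_lt(max(abs(w[small] * exp(w[small]) - x[small]) /
                  pmax(x[small], 1e-300)), 1e-12)
  # overflow-safe identity w + log(w) = log(x)
  big <- x >= 3
  expect_lt(max(abs(w[big] + log(w[big]) - log(x[big]))), 1e-12)
  # independent implementation (over the range where it terminates)
  xs <- c(0.01, 0.5, 1, 5, 50, 1000)
  expect_equal(lambert_w0(xs),
               vapply(xs, pracma::lambertWp, numeric(1)), tolerance = 1e-10)
})

test_that("rogers_eaten handles the degenerate closed forms", {
  expect_equal(rogers_eaten(10, 1, fr_params(0, 0.5, 1)), 0)
  # h = 0, q = 0: exponential depletion N0 (1 - exp(-b T))
  expect_equal(rogers_eaten(10, log(2), fr_params(1, 0, 0)), 5.0)
  N0 <- c(1, 7, 100)
  expect_equal(rogers_eaten(N0, 2, fr_params(0.3, 0, 0)),
               N0 * (1 - exp(-0.3 * 2)))
  expect_error(rogers_eaten(-1, 1, fr_params(1, 0, 0)))
  expect_error(rogers_eaten(10, 0, fr_params(1, 0, 0)))
})

test_that("Lambert-W path matches the damped fixed-point oracle", {
  # reference example values
  ne <- rogers_eaten(20, 1, fr_params(0.05, 0.2, 0))
  expect_equal(ne, rogers_fixed_point(20, 1, 0.05, 0.2, 0), tolerance = 1e-10)
  # both exponent conventions, against a guaranteed-convergent bisection
  # (the plain fixed-point map is expansive at stronger depletion)
  for (conv in c("q", "q_plus_1")) {
    for (q in c(0, 0.5, 1)) {
      ne <- rogers_eaten(15, 2, fr_params(0.03, 0.4, q), convention = conv)
      expect_equal(ne, rogers_bisect(15, 2, 0.03, 0.4, q, conv),
                   tolerance = 1e-8)
    }
  }
  # and the bracketed root-finder path agrees
  p <- fr_params(0.05, 0.2, 0)
  expect_equal(rogers_eaten(20, 1, p, method = "lambert"),
               rogers_eaten(20, 1, p, method = "uniroot"), tolerance = 1e-8)
})

test_that("rogers_eaten is monotone and bounded", {
  p <- fr_params(0.08, 0.3, 0.5)
  N0 <- 2^(0:9)
  ne <- rogers_eaten(N0, 1, p)
  expect_true(all(diff(ne) >= -1e-10))
  expect_true(all(ne <= N0 + 1e-10))
  # bounded by the no-depletion consumption holling_rate(N0) * T
  expect_true(all(ne <= holling_rate(N0, p) * 1 + 1e-10))
  # monotone in T and in b
  Ts <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(rogers_eaten(rep(20, 5), Ts, p)) >= -1e-10))
  bs <- c(0.01, 0.05, 0.1, 0.5)
  nes <- vapply(bs, function(b)
    rogers_eaten(20, 1, fr_params(b, 0.3, 0.5)), numeric(1))
  expect_true(all(diff(nes) >= -1e-10))
})

test_that("convention 'q' at q = 0 reproduces the classic random-predator equation", {
  # classic form: Ne = N0 - W(a h N0 exp(-a (T - h N0))) / (a h)
  a <- 0.07; h <- 0.25; N0 <- 30; T <- 1.5
  w <- lambert_w0(a * h * N0 * exp(-a * (T - h * N0)))
  classic <- N0 - w / (a * h)
  for (q in c(0)) {
    expect_equal(rogers_eaten(N0, T, fr_params(a, h, q)), classic,
                 tolerance = 1e-12)
  }
  # the as-printed q+1 convention differs once q > 0
  p1 <- rogers_eaten(N0, T, fr_params(a, h, 1), convention = "q")
  p2 <- rogers_eaten(N0, T, fr_params(a, h, 1), convention = "q_plus_1")
  expect_gt(abs(p1 - p2), 1e-6)
})

test_that("fr_nll equals the term-by-term binomial sum", {
  # single trial, N0 = 1, eaten = 0, b = 0: probability ~1
  tr <- trial_set(N0 = 1, eaten = 0, T = 1)
  expect_lt(fr_nll(fr_params(0, 0, 0), tr), 1e-6)
  # p = 0.5 by construction: h = 0, bT = log 2
  tr2 <- trial_set(N0 = 2, eaten = 1, T = 1)
  expect_equal(fr_nll(fr_params(log(2), 0, 0), tr2), -log(0.5),
               tolerance = 1e-9)
  # arbitrary trials: brute-force sum over rows
  set.seed(9)
  p <- fr_params(0.12, 0.3, 0.5)
  tr3 <- generate_trials(p, c(2, 4, 8, 16), 5, T = 1, seed = 10)
  manual <- 0
  for (i in seq_len(nrow(tr3))) {
    pe <- rogers_eaten(tr3$N0[i], tr3$T[i], p) / tr3$N0[i]
    pe <- min(max(pe, 1e-9), 1 - 1e-9)
    manual <- manual - dbinom(tr3$eaten[i], tr3$N0[i], pe, log = TRUE)
  }
  expect_equal(fr_nll(p, tr3), manual, tolerance = 1e-10)
  expect_error(fr_nll(p, trial_set(N0 = 0, eaten = 0, T = 1)), "N0 = 0")
})
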