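# Independent oracles used across tests.

# Damped fixed-point solution of the depletion equation
# x = N0 (1 - exp(cc (h x - T))), independent of the Lambert-W path.
rogers_fixed_point <- function(N0, T, b, h, q, convention = "q",
                               tol = 1e-12, max_iter = 100000) {
  expo <- if (convention == "q") q else q + 1
  cc <- b * N0^expo
  x <- N0 / 2
  for (i in seq_len(max_iter)) {
    xn <- 0.5 * x + 0.5 * N0 * (1 - exp(cc * (h * x - T)))
    if (abs(xn - x) < tol) return(xn)
    x <- xn
  }
  x
}

# Bisection solution of the same equation: guaranteed convergence on
# [0, N0] for any parameters (the bracket always signs correctly).
rogers_bisect <- function(N0, T, b, h, q, convention = "q", iters = 200) {
  expo <- if (convention == "q") q else q + 1
  cc <- b * N0^expo
  g <- function(x) x - N0 * (1 - exp(pmin(cc * (h * x - T), 700)))
  lo <- 0; hi <- N0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# A well-signed type II trial set used by several tests.
strong_type2_trials <- function(b = 0.5, h = 0.1, seed = 42,
                                levels = c(2, 4, 8, 16, 32, 64),
                                replicates = 20) {
  generate_trials(fr_params(b, h, 0), levels, replicates, T = 1, seed = seed)
}

# Manually built world with everything pinned, for deterministic ABM checks.
static_world <- function(res_xy, extent = 1, r = 0.1, dim = 2, ...) {
  w <- abm_world(dim, extent = extent, r = r, consumer_speed = 0,
                 n_resources = nrow(res_xy), resource_speed = 0,
                 resource_mass = 1, ...)
  w$res_pos <- res_xy
  w
}
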