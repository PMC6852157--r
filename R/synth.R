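#' Generate replicated feeding trials from known parameters
#'
#' Draws consumption counts `eaten ~ Binomial(N0, Ne/N0)` around the
#' deterministic depletion expectation `Ne` from [rogers_eaten()], matching
#' the likelihood fitted downstream. `depletion_mode = "event"` instead
#' simulates the trial as a stochastic pure-death process (Gillespie) whose
#' per-capita hazard follows the instantaneous response with handling
#' carried explicitly, for robustness checks against the binomial shortcut.
#'
#' @param true_params an [fr_params()] object (the generating truth).
#' @param N0_levels initial resource counts (positive integers); a doubling
#'   (geometric) series is the conventional design.
#' @param replicates replicates per density level.
#' @param T trial duration.
#' @param seed integer seed; output is deterministic given the seed.
#' @param depletion_mode `"binomial"` (default) or `"event"`.
#' @param convention exponent convention for [rogers_eaten()].
#' @param ... covariates passed through to [trial_set()] (arena, masses,
#'   temperature, strategy, ...).
#' @return A [trial_set()] with `replicates * length(N0_levels)` rows.
#' @examples
#' tr <- generate_trials(fr_params(0.05, 0.2), N0_levels = c(2, 4, 8, 16, 32),
#'                       replicates = 10, T = 1, seed = 42)
#' @export
generate_trials <- function(true_params, N0_levels, replicates, T, seed,
                            depletion_mode = c("binomial", "event"),
                            convention = "q", ...) {
  depletion_mode <- match.arg(depletion_mode)
  true_params <- as_fr_params(true_params)
  if (any(N0_levels <= 0) || any(N0_levels != round(N0_levels)))
    stop("N0_levels must be positive integers")
  set.seed(seed)
  N0 <- rep(as.integer(N0_levels), each = replicates)
  if (depletion_mode == "binomial") {
    ne <- rogers_eaten(N0_levels, T, true_params, convention)
    if (any(ne > N0_levels + 1e-8))
      stop("expected consumption exceeds N0: depletion solver fault")
    p <- ne / N0_levels
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
      stop("consumption probability outside [0, 1]")
    p <- pmin(pmax(p, 0), 1)
    eaten <- stats::rbinom(length(N0), N0, rep(p, each = replicates))
  } else {
    eaten <- vapply(N0, function(n0)
      sim_depletion_event(n0, T, true_params, convention), integer(1))
  }
  trial_set(N0 = N0, eaten = eaten, T = T, ...)
}

# Stochastic depletion: resources are removed one at a time at the current
# total hazard holling_rate(N/arena); arena = 1 so density = count.
sim_depletion_event <- function(n0, T, params, convention = "q") {
  t <- 0; n <- n0; eaten <- 0L
  while (n > 0) {
    rate <- holling_rate(n, params)
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t > T) break
    n <- n - 1L
    eaten <- eaten + 1L
  }
  eaten
}

#' Generate noisy points from a power law
#'
#' `y = coefficient * x^exponent * exp(e)` with `e ~ Normal(0, sigma^2)`,
#' at `x` drawn log-uniformly over `x_range`. Used to exercise
#' [fit_power_law()] and the allometric refitting stage.
#'
#' @param law a [power_law()].
#' @param n number of points, `n >= 3`.
#' @param sigma log-normal noise SD, `sigma >= 0`.
#' @param x_range positive length-2 bounds for x.
#' @param seed integer seed.
#' @return Data frame with columns `x`, `y`.
#' @export
generate_allometry_points <- function(law, n, sigma, x_range, seed) {
  stopifnot(n >= 3, sigma >= 0)
  if (any(x_range <= 0)) stop("x_range must be positive")
  set.seed(seed)
  x <- exp(stats::runif(n, log(min(x_range)), log(max(x_range))))
  y <- pl_eval(law, x) * exp(stats::rnorm(n, 0, sigma))
  data.frame(x = x, y = y)
}

#' Configuration for the synthetic meta-dataset generator
#'
#' Defines the study conditions emulated by [generate_meta_dataset()]:
#' consumer masses spanning eight orders of magnitude (1e-6 to 1e2 g), a
#' strategy mix dominated by active-static, active-mobile and filter
#' feeding, allometric structure in the true capture coefficients and
#' handling times, and a shape-exponent distribution mixing point masses
#' at 0 and 1 with positive reals.
#'
#' @param seed master seed; per-pair substreams are derived from it.
#' @param n_pairs number of consumer-resource pairs.
#' @param strategy_mix named proportions over [encounter_strategies()];
#'   must sum to 1. The default mirrors a benthic compilation dominated by
#'   active-static, active-mobile and filter strategies.
#' @param consumer_mass_range grams, log-uniform bounds.
#' @param b_law,h_law [power_law()] giving the median capture coefficient
#'   and handling time vs consumer mass (time unit: days).
#' @param q_mix probabilities of `q = 0`, `q = 1`, and a positive draw
#'   `q ~ Uniform(0, 2)`.
#' @param sigma_b,sigma_h log-normal scatter around the allometries.
#' @param temperature_range degrees C.
#' @param n_levels,replicates,T_days trial design per pair: number of
#'   doubling density levels starting at `N0_min`, replicates per level,
#'   and trial duration in days.
#' @param N0_min lowest density level.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, n_pairs = 30,
                             strategy_mix = c("active-mobile" = 0.33,
                                              "active-static" = 0.38,
                                              "filter" = 0.21,
                                              "sit-and-wait" = 0.04,
                                              "deposit" = 0.02,
                                              "grazer" = 0.02),
                             consumer_mass_range = c(1e-6, 1e2),
                             b_law = power_law(0.5, 0.7, "g", "arena d^-1"),
                             h_law = power_law(0.01, -0.6, "g", "d"),
                             q_mix = c(q0 = 0.55, q1 = 0.25, pos = 0.20),
                             sigma_b = 0.4, sigma_h = 0.4,
                             temperature_range = c(5, 25),
                             n_levels = 5, replicates = 12, T_days = 1,
                             N0_min = 2) {
  stopifnot(abs(sum(strategy_mix) - 1) < 1e-8,
            all(consumer_mass_range > 0),
            sigma_b >= 0, sigma_h >= 0,
            abs(sum(q_mix) - 1) < 1e-8)
  if (!all(names(strategy_mix) %in% encounter_strategies()))
    stop("unknown strategy in strategy_mix")
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic meta-dataset of feeding trials with known truth
#'
#' Draws `n_pairs` consumer-resource pairs with strategy-specific resource
#' regimes (filter feeders get the smallest resources and the highest
#' unitary densities), true `(b, h, q)` from mass allometries with
#' log-normal scatter, and replicated feeding trials from
#' [generate_trials()]. Each pair uses an RNG substream derived from the
#' master seed, so regenerating any single pair reproduces the full-run
#' values.
#'
#' @param config a [generator_config()].
#' @return List with `trials` (stacked [trial_set()] rows across pairs) and
#'   `truth` (one row per pair: true parameters, covariates, allometric
#'   inputs).
#' @export
generate_meta_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_pairs == 0)
    return(list(trials = empty_trials(), truth = empty_truth()))
  if (diff(range(config$consumer_mass_range)) <= 0 &&
      config$consumer_mass_range[1] == config$consumer_mass_range[2])
    stop("degenerate consumer mass range")

  set.seed(substream_seed(config$seed, "meta", "assign"))
  strategies <- sample(names(config$strategy_mix), config$n_pairs,
                       replace = TRUE, prob = config$strategy_mix)
  scal <- default_strategy_scalings()

  truth_rows <- vector("list", config$n_pairs)
  trial_rows <- vector("list", config$n_pairs)
  for (i in seq_len(config$n_pairs)) {
    pid <- sprintf("pair%03d", i)
    set.seed(substream_seed(config$seed, "pair", pid))
    strat <- strategies[i]
    cmass <- exp(stats::runif(1, log(config$consumer_mass_range[1]),
                              log(config$consumer_mass_range[2])))
    ss <- scal[[strat]] %||% scal[["active-mobile"]]
    rmass <- pl_eval(ss$resource_mass_law, cmass) *
      exp(stats::rnorm(1, 0, 0.3))
    dim_arena <- ss$dimensionality
    temp <- stats::runif(1, config$temperature_range[1],
                         config$temperature_range[2])
    b <- pl_eval(config$b_law, cmass) * exp(stats::rnorm(1, 0, config$sigma_b))
    h <- pl_eval(config$h_law, cmass) * exp(stats::rnorm(1, 0, config$sigma_h))
    u <- stats::runif(1)
    q <- if (u < config$q_mix[["q0"]]) 0
         else if (u < config$q_mix[["q0"]] + config$q_mix[["q1"]]) 1
         else stats::runif(1, 0, 2)
    # taxon group nested loosely within strategy (2 groups per strategy)
    taxon <- paste0(strat, "_taxon", sample(1:2, 1))
    N0_levels <- config$N0_min * 2^(seq_len(config$n_levels) - 1)
    tr <- generate_trials(fr_params(b, h, q, dim_arena), N0_levels,
                          config$replicates, T = config$T_days,
                          seed = substream_seed(config$seed, "trials", pid),
                          arena = 1, arena_dim = dim_arena,
                          consumer_mass_g = cmass, resource_mass_g = rmass,
                          temp_C = temp, strategy = strat,
                          taxon_group = taxon, pair_id = pid,
                          time_unit = "d")
    trial_rows[[i]] <- tr
    truth_rows[[i]] <- data.frame(
      pair_id = pid, strategy = strat, taxon_group = taxon,
      consumer_mass_g = cmass, resource_mass_g = rmass, temp_C = temp,
      b = b, h = h, q = q, arena_dim = dim_arena,
      b_coeff = config$b_law$coefficient, b_exp = config$b_law$exponent,
      h_coeff = config$h_law$coefficient, h_exp = config$h_law$exponent,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trial_rows)
  attr(trials, "time_unit") <- "d"
  class(trials) <- c("trial_set", "data.frame")
  list(trials = trials, truth = do.call(rbind, truth_rows))
}

empty_trials <- function() {
  df <- data.frame(pair_id = character(), N0 = integer(), eaten = integer(),
                   T = numeric(), arena = numeric(), arena_dim = integer(),
                   consumer_mass_g = numeric(), resource_mass_g = numeric(),
                   temp_C = numeric(), strategy = character(),
                   taxon_group = character(), stringsAsFactors = FALSE)
  attr(df, "time_unit") <- "d"
  class(df) <- c("trial_set", "data.frame")
  df
}

empty_truth <- function() {
  data.frame(pair_id = character(), strategy = character(),
             taxon_group = character(), consumer_mass_g = numeric(),
             resource_mass_g = numeric(), temp_C = numeric(), b = numeric(),
             h = numeric(), q = numeric(), arena_dim = integer(),
             b_coeff = numeric(), b_exp = numeric(), h_coeff = numeric(),
             h_exp = numeric(), stringsAsFactors = FALSE)
}

#' Generate synthetic meta-analysis records with known fixed effects
#'
#' Directly simulates standardised log response values from a linear model
#' in log consumer mass (slope `beta_C`), log resource mass (`beta_R`) and
#' log temperature (`beta_T`), optional strategy offsets, a random
#' intercept per taxon group, and residual noise. Used for recovery tests
#' of the mixed-model stage without running the trial-level pipeline.
#'
#' @param n number of records.
#' @param beta_C,beta_R,beta_T fixed-effect slopes on the (unstandardised)
#'   log covariates.
#' @param strategy_effects named numeric offsets per strategy (`NULL` for
#'   none).
#' @param n_groups number of taxon groups.
#' @param group_sd random-intercept SD.
#' @param sigma residual SD.
#' @param seed integer seed.
#' @return A `data.frame` shaped like the meta-table of
#'   [build_meta_table()]: `pair_id`, `response`, `log_consumer_mass`,
#'   `log_resource_mass`, `log_temperature`, `strategy`, `taxon_group`, `q`.
#' @export
generate_meta_records <- function(n, beta_C = 0.8, beta_R = 0.2, beta_T = 0,
                                  strategy_effects = NULL, n_groups = 6,
                                  group_sd = 0.5, sigma = 0.5, seed = 1) {
  set.seed(seed)
  strategies <- names(strategy_effects) %||%
    c("active-mobile", "active-static", "filter")
  strat <- sample(strategies, n, replace = TRUE)
  lC <- stats::runif(n, log(1e-6), log(1e2))
  lR <- stats::runif(n, log(1e-9), log(1e1))
  lT <- log(stats::runif(n, 5, 25))
  grp <- sample(paste0("taxon", seq_len(n_groups)), n, replace = TRUE)
  u <- stats::rnorm(n_groups, 0, group_sd)
  names(u) <- paste0("taxon", seq_len(n_groups))
  off <- if (is.null(strategy_effects)) 0 else strategy_effects[strat]
  y <- beta_C * scale(lC)[, 1] + beta_R * scale(lR)[, 1] +
    beta_T * scale(lT)[, 1] + off + u[grp] + stats::rnorm(n, 0, sigma)
  data.frame(pair_id = sprintf("rec%04d", seq_len(n)), response = y,
             log_consumer_mass = scale(lC)[, 1],
             log_resource_mass = scale(lR)[, 1],
             log_temperature = scale(lT)[, 1],
             strategy = strat, taxon_group = grp,
             q = sample(c(0, 1), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Read / write trial sets as CSV
#'
#' Header: `pair_id, N0, eaten, T, arena, arena_dim, consumer_mass_g,
#' resource_mass_g, temp_C, strategy, taxon_group`. UTF-8, comma-separated,
#' `.` decimal; units are encoded in the column names.
#'
#' @param trials a [trial_set()].
#' @param path file path.
#' @param time_unit declared time unit written/read alongside (attribute).
#' @return `read_trials_csv` returns a [trial_set()].
#' @export
write_trials_csv <- function(trials, path, time_unit = NULL) {
  tu <- time_unit %||% attr(trials, "time_unit") %||% "s"
  df <- as.data.frame(trials)
  df$time_unit <- tu
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tu <- if ("time_unit" %in% names(df)) df$time_unit[1] else "s"
  df$time_unit <- NULL
  validate_trial_set(df)
  attr(df, "time_unit") <- tu
  class(df) <- c("trial_set", "data.frame")
  df
}
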