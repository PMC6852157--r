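#' Functional response parameters
#'
#' Container for the parameters of the generalised functional response
#' \deqn{f(N) = \frac{b N^{q+1}}{1 + b h N^{q+1}}}{f(N) = b N^(q+1) / (1 + b h N^(q+1))}
#' where `b` is the capture (search) coefficient, `h` the handling time and
#' `q` the dimensionless shape exponent interpolating between a hyperbolic
#' type II (`q = 0`) and a sigmoidal type III (`q = 1`) response.
#'
#' @param b capture rate / search coefficient, in units of
#'   resource-density^-1 time^-1 (arena area or volume per time).
#' @param h handling time per resource unit (same time unit as trials).
#' @param q shape exponent, dimensionless, `q >= 0`.
#' @param dimensionality 2 for areal (m^2) arenas, 3 for volumetric (m^3).
#' @return An object of class `fr_params`.
#' @examples
#' p <- fr_params(b = 0.5, h = 0.1)
#' holling_rate(c(0, 1, 10), p)
#' @export
fr_params <- function(b, h = 0, q = 0, dimensionality = 2) {
  stopifnot(is.numeric(b), length(b) == 1, b >= 0,
            is.numeric(h), length(h) == 1, h >= 0,
            is.numeric(q), length(q) == 1, q >= 0,
            dimensionality %in% c(2, 3))
  structure(list(b = b, h = h, q = q, dimensionality = dimensionality),
            class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat(sprintf("Functional response parameters (%dD arena)\n", x$dimensionality))
  cat(sprintf("  b (capture coefficient): %g\n", x$b))
  cat(sprintf("  h (handling time):       %g\n", x$h))
  cat(sprintf("  q (shape exponent):      %g\n", x$q))
  invisible(x)
}

as_fr_params <- function(x) {
  if (inherits(x, "fr_params")) return(x)
  fr_params(b = x$b %||% x[["b"]], h = x$h %||% 0, q = x$q %||% 0,
            dimensionality = x$dimensionality %||% 2)
}

#' Construct a set of replicated feeding trials
#'
#' One row per trial replicate for a single consumer-resource pair in a
#' non-replacement (depletion) design: initial resource density, number
#' eaten, and trial duration, with arena geometry and covariates carried as
#' columns so trial sets can be stacked across pairs.
#'
#' @param N0 initial resource counts per arena (positive integers).
#' @param eaten number of resource units consumed, `0 <= eaten <= N0`.
#' @param T trial duration (all in the same unit, declared by `time_unit`).
#' @param arena arena footprint (m^2) or volume (m^3).
#' @param arena_dim 2 or 3, dimensionality of the arena.
#' @param consumer_mass_g,resource_mass_g wet masses in grams.
#' @param temp_C trial temperature in degrees Celsius.
#' @param strategy encounter strategy, one of [encounter_strategies()].
#' @param taxon_group coarse taxonomic grouping (random-effect level).
#' @param pair_id identifier of the consumer-resource pair.
#' @param time_unit `"s"` or `"d"`; used when converting rates to per-day.
#' @return A `data.frame` of class `trial_set`.
#' @export
trial_set <- function(N0, eaten, T, arena = 1, arena_dim = 2,
                      consumer_mass_g = NA_real_, resource_mass_g = NA_real_,
                      temp_C = NA_real_, strategy = NA_character_,
                      taxon_group = NA_character_, pair_id = "pair1",
                      time_unit = c("s", "d")) {
  time_unit <- match.arg(time_unit)
  df <- data.frame(pair_id = pair_id, N0 = as.integer(N0),
                   eaten = as.integer(eaten), T = T, arena = arena,
                   arena_dim = as.integer(arena_dim),
                   consumer_mass_g = consumer_mass_g,
                   resource_mass_g = resource_mass_g, temp_C = temp_C,
                   strategy = strategy, taxon_group = taxon_group,
                   stringsAsFactors = FALSE)
  validate_trial_set(df)
  attr(df, "time_unit") <- time_unit
  class(df) <- c("trial_set", "data.frame")
  df
}

validate_trial_set <- function(df) {
  stopifnot(all(df$N0 >= 0), all(df$eaten >= 0))
  if (any(df$eaten > df$N0)) stop("eaten exceeds N0 in at least one trial")
  if (any(df$T <= 0)) stop("trial duration T must be positive")
  if (any(df$arena <= 0)) stop("arena size must be positive")
  invisible(df)
}

#' The encounter-strategy taxonomy
#'
#' Active strategies search for mobile or static resources; passive
#' strategies (filter feeding, deposit feeding, sit-and-wait predation)
#' rely on resource movement. Grazers are kept distinct from active-static
#' consumers because encounter, capture and handling overlap.
#'
#' @return Character vector of the six strategy labels.
#' @export
encounter_strategies <- function() {
  c("active-mobile", "active-static", "filter", "sit-and-wait",
    "deposit", "grazer")
}
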