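#' Capture rate at the half-saturation density
#'
#' For responses with `q > 0` the raw coefficient `b` is not comparable
#' across fits (its units depend on `q`), so capture rates are compared at
#' the half-saturation density, where the feeding rate equals half its
#' maximum: `N_half = (b h)^(-1/(q+1))`. The default reading reports the
#' effective attack coefficient at that density, `b * N_half^q` (which
#' reduces to `b` when `q = 0`); `method = "derivative"` instead reports the
#' local slope of the functional response there,
#' `b (q+1) N_half^q / 4`.
#'
#' @param params an [fr_params()] object with `b > 0`; if `h = 0` the
#'   response never saturates and `b` is returned with a warning.
#' @param method `"effective"` (default) or `"derivative"`.
#' @return Per-capita capture rate at half-saturation (same units as `b`
#'   when `q = 0`).
#' @export
half_saturation_rate <- function(params, method = c("effective", "derivative")) {
  method <- match.arg(method)
  params <- as_fr_params(params)
  if (params$b <= 0) stop("half-saturation rate requires b > 0")
  if (params$h == 0) {
    warning("h = 0: response does not saturate; returning b")
    return(params$b)
  }
  N_half <- (params$b * params$h)^(-1 / (params$q + 1))
  if (method == "effective") {
    params$b * N_half^params$q
  } else {
    params$b * (params$q + 1) * N_half^params$q / 4
  }
}

#' Maximum feeding rate
#'
#' The handling time bounds intake at `1/h` resource units per time unit.
#'
#' @param params an [fr_params()] object.
#' @return `1/h`, or `Inf` when `h = 0`.
#' @export
max_feeding_rate <- function(params) {
  params <- as_fr_params(params)
  if (params$h == 0) return(Inf)
  1 / params$h
}

#' Convert fitted rates to biomass units
#'
#' Expresses the capture rate at half-saturation in g per arena-dimension
#' unit per day (g m^2 d^-1 or g m^3 d^-1) and the maximum feeding rate in
#' g per day, by multiplying per-individual rates by the resource wet mass
#' and rescaling time to days.
#'
#' @param fit an `fr_fit`, or an [fr_params()] object.
#' @param resource_mass_g resource wet mass in grams (taken from the trials
#'   when `fit` is an `fr_fit` and the column is present).
#' @param time_unit time unit of `b` and `h`: `"s"` or `"d"` (taken from the
#'   trial set attribute when available).
#' @return Named list: `capture_gd` (g m^(2 or 3) d^-1), `max_feed_gd`
#'   (g d^-1), `dimensionality`.
#' @export
biomass_rates <- function(fit, resource_mass_g = NULL, time_unit = NULL) {
  if (inherits(fit, "fr_fit")) {
    params <- fit$params
    resource_mass_g <- resource_mass_g %||% fit$trials$resource_mass_g[1]
    time_unit <- time_unit %||% (attr(fit$trials, "time_unit") %||% "s")
  } else {
    params <- as_fr_params(fit)
    time_unit <- time_unit %||% "s"
  }
  if (is.null(resource_mass_g) || !is.finite(resource_mass_g) ||
      resource_mass_g <= 0)
    stop("resource_mass_g must be a positive number")
  per_day <- if (time_unit == "s") 86400 else 1
  cap <- if (params$b > 0 && params$h > 0)
    half_saturation_rate(params) else params$b
  list(capture_gd = cap * resource_mass_g * per_day,
       max_feed_gd = max_feeding_rate(params) * resource_mass_g * per_day,
       dimensionality = params$dimensionality)
}
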