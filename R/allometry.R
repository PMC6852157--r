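#' Power-law relation
#'
#' Every allometric relation in the package (velocity-length, encounter
#' region radius-mass, resource mass and density vs consumer mass) is a
#' power law `y = coefficient * x^exponent`.
#'
#' @param coefficient positive multiplier, in `y_units` at `x = 1`.
#' @param exponent scaling exponent.
#' @param x_units,y_units unit labels (documentation only).
#' @param source one of `"literature"`, `"fitted"`, `"config"`.
#' @param se optional named numeric: standard errors `log_coefficient`,
#'   `exponent` from a log-log fit.
#' @return An object of class `power_law`; evaluate with
#'   [predict.power_law()] or `pl_eval()`.
#' @export
power_law <- function(coefficient, exponent, x_units = "", y_units = "",
                      source = c("config", "fitted", "literature"), se = NULL) {
  source <- match.arg(source)
  stopifnot(is.numeric(coefficient), coefficient > 0, is.numeric(exponent))
  structure(list(coefficient = coefficient, exponent = exponent,
                 x_units = x_units, y_units = y_units, source = source,
                 se = se), class = "power_law")
}

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("Power law: y = %.4g * x^%.4g  [%s -> %s, %s]\n",
              x$coefficient, x$exponent, x$x_units, x$y_units, x$source))
  if (!is.null(x$se))
    cat(sprintf("  SE(log coeff) = %.3g, SE(exponent) = %.3g\n",
                x$se[["log_coefficient"]], x$se[["exponent"]]))
  invisible(x)
}

#' Evaluate a power law
#' @param object a [power_law()].
#' @param x positive values at which to evaluate.
#' @param ... unused.
#' @export
predict.power_law <- function(object, x, ...) {
  if (any(x < 0)) stop("power laws are evaluated on x >= 0")
  object$coefficient * x^object$exponent
}

#' @rdname predict.power_law
#' @export
pl_eval <- function(object, x) predict.power_law(object, x)

#' Body velocity from body length
#'
#' Velocity-length allometry for moving consumers and resources, refitted
#' from compiled swimming/crawling speed data: `V = 2.67 * l^1.05` with `V`
#' in m/s and `l` in m.
#'
#' @param l body length in metres, `l >= 0`.
#' @param law optionally a different [power_law()] (e.g. refitted).
#' @return Velocity in m/s.
#' @examples
#' velocity_from_length(1.0) # 2.67 m/s
#' @export
velocity_from_length <- function(l, law = velocity_length_law()) {
  if (any(l < 0)) stop("body length must be non-negative")
  ifelse(l == 0, 0, pl_eval(law, l))
}

#' @rdname velocity_from_length
#' @export
velocity_length_law <- function() {
  power_law(2.67, 1.05, x_units = "m", y_units = "m s^-1", source = "literature")
}

#' Body length from wet mass
#'
#' Geometric conversion assuming tissue density `rho` (g cm^-3) and a cubic
#' shape factor: `l = shape * (m / rho)^(1/3)` centimetres, returned in
#' metres. With the defaults, 1 g maps to 1 cm = 0.01 m.
#'
#' @param m wet mass in grams, `m > 0`.
#' @param rho tissue density in g cm^-3 (default 1).
#' @param shape dimensionless shape factor (default 1).
#' @return Body length in metres.
#' @export
length_from_mass <- function(m, rho = 1, shape = 1) {
  if (any(m <= 0)) stop("mass must be positive")
  shape * (m / rho)^(1 / 3) / 100
}

#' Reaction distance (encounter-region radius) from consumer mass
#'
#' The radius of the discoid (2D) or hemispheric (3D) encounter region
#' scales with consumer mass as `m^0.36`; the coefficient `r0` (radius in
#' metres at 1 g) is a calibration constant.
#'
#' @param m consumer wet mass in grams, `m > 0`.
#' @param r0 radius coefficient in m g^-0.36 (default 0.01).
#' @param exponent mass-scaling exponent (default 0.36).
#' @return Radius in metres.
#' @export
reaction_distance <- function(m, r0 = 0.01, exponent = 0.36) {
  if (any(m <= 0)) stop("mass must be positive")
  if (r0 <= 0) stop("r0 must be positive")
  r0 * m^exponent
}

#' Hemispheric encounter-region radius from a clearance rate
#'
#' For filter feeders the clearance rate (volume of water stripped of
#' resources per unit time) bounds the encounter region: a seabed
#' hemisphere facing a horizontal current of speed `U` intercepts flux
#' through its half-disc cross-section `pi r^2 / 2`, so the radius whose
#' intercepted flux equals `Q` is `r = sqrt(2 Q / (pi U))`. This is a
#' flux-balance reconstruction of the clearance-based region.
#'
#' @param Q clearance rate in m^3 s^-1, `Q >= 0`.
#' @param U current speed in m s^-1, `U > 0`.
#' @return Radius in metres.
#' @export
clearance_region_radius <- function(Q, U) {
  if (any(Q < 0)) stop("clearance rate must be non-negative")
  if (any(U <= 0)) stop("current speed must be positive (region undefined in still water)")
  sqrt(2 * Q / (pi * U))
}

#' Fit a power law by ordinary least squares on log-log axes
#'
#' @param x,y positive numeric vectors, `length >= 3`.
#' @param x_units,y_units unit labels stored on the result.
#' @return A [power_law()] with `source = "fitted"` and standard errors.
#' @export
fit_power_law <- function(x, y, x_units = "", y_units = "") {
  if (length(x) < 3 || length(y) != length(x))
    stop("need at least 3 paired observations")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fitting needs positive x and y")
  if (length(unique(x)) < 2) stop("degenerate x: all values equal")
  fit <- stats::lm(log(y) ~ log(x))
  cf <- stats::coef(fit)
  # noiseless inputs fit exactly; the perfect-fit warning is expected
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  power_law(exp(cf[[1]]), cf[[2]], x_units = x_units, y_units = y_units,
            source = "fitted",
            se = c(log_coefficient = se[[1]], exponent = se[[2]]))
}

#' Default per-strategy resource scalings for the encounter simulator
#'
#' Calibration power laws giving unitary resource mass (g) and unitary
#' resource density (individuals m^-2 or m^-3) as functions of consumer
#' mass, per focal strategy. Filter feeders face very small planktonic
#' resources at high volumetric densities in 3D; active strategies face
#' larger benthic resources at low areal densities in 2D, with static
#' resources denser and larger than mobile ones. The values are
#' calibration inputs spanning realistic benthic ranges (resource masses
#' roughly 1e-11 to 1e1 g) and can be replaced by laws fitted to data with
#' [fit_power_law()].
#'
#' @return Named list per strategy with elements `resource_mass_law`,
#'   `resource_density_law` (both [power_law()]) and `dimensionality`.
#' @export
default_strategy_scalings <- function() {
  list(
    "filter" = list(
      resource_mass_law = power_law(1e-8, 0.10, "g", "g"),
      resource_density_law = power_law(3e7, -0.25, "g", "individuals m^-3"),
      dimensionality = 3),
    "active-static" = list(
      resource_mass_law = power_law(0.05, 0.5, "g", "g"),
      resource_density_law = power_law(30, -0.25, "g", "individuals m^-2"),
      dimensionality = 2),
    "active-mobile" = list(
      resource_mass_law = power_law(0.02, 0.5, "g", "g"),
      resource_density_law = power_law(12, -0.25, "g", "individuals m^-2"),
      dimensionality = 2))
}

#' Fit strategy scalings from a meta-table
#'
#' Recovers the resource-mass and resource-density power laws per strategy
#' from observed pairs. Following the encounter-limited logic (when
#' resources are scarce consumption is encounter- not handling-limited),
#' the density law is fitted to per-consumer-mass-bin minima by default;
#' `quantile_alt = 0.1` fits a lower decile instead.
#'
#' @param consumer_mass_g,resource_mass_g,density positive vectors.
#' @param strategy strategy label per record.
#' @param use_minimum fit density to binned minima (default `TRUE`).
#' @param quantile_alt lower quantile used when `use_minimum = FALSE`.
#' @param bins number of log-mass bins for the minima.
#' @return List as [default_strategy_scalings()], laws `source = "fitted"`.
#' @export
fit_strategy_scalings <- function(consumer_mass_g, resource_mass_g, density,
                                  strategy, use_minimum = TRUE,
                                  quantile_alt = 0.1, bins = 6) {
  out <- list()
  for (s in unique(strategy)) {
    i <- strategy == s
    mass_law <- fit_power_law(consumer_mass_g[i], resource_mass_g[i], "g", "g")
    cm <- consumer_mass_g[i]; dn <- density[i]
    br <- seq(min(log10(cm)), max(log10(cm)), length.out = bins + 1)
    bin <- cut(log10(cm), breaks = unique(br), include.lowest = TRUE)
    agg <- if (use_minimum) tapply(dn, bin, min)
           else tapply(dn, bin, stats::quantile, probs = quantile_alt)
    mid <- tapply(cm, bin, function(v) exp(mean(log(v))))
    keep <- is.finite(agg) & is.finite(mid)
    dens_law <- if (sum(keep) >= 3)
      fit_power_law(mid[keep], agg[keep], "g", "individuals per arena unit")
    else fit_power_law(cm, dn, "g", "individuals per arena unit")
    out[[s]] <- list(resource_mass_law = mass_law,
                     resource_density_law = dens_law,
                     dimensionality = if (s == "filter") 3 else 2)
  }
  out
}

#' Read / write power laws as a structured text config
#'
#' Laws are serialised to YAML as a named list of
#' `(coefficient, exponent, x_units, y_units, source)` blocks.
#'
#' @param laws named list of [power_law()] objects.
#' @param path file path.
#' @return `read_power_laws` returns a named list of [power_law()].
#' @export
write_power_laws <- function(laws, path) {
  stopifnot(is.list(laws), length(names(laws)) == length(laws))
  payload <- lapply(laws, function(l)
    list(coefficient = l$coefficient, exponent = l$exponent,
         x_units = l$x_units, y_units = l$y_units, source = l$source))
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_power_laws
#' @export
read_power_laws <- function(path) {
  payload <- yaml::read_yaml(path)
  lapply(payload, function(l)
    power_law(l$coefficient, l$exponent, l$x_units %||% "",
              l$y_units %||% "", l$source %||% "config"))
}
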