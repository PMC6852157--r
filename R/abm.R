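#' Build a simulation world for the encounter-rate model
#'
#' The arena is a square torus (side `extent`) in the x-y plane; in 3D a
#' slab of height `height` sits on the seabed with reflecting boundaries at
#' `z = 0` and `z = height`. One consumer sits at the arena centre with a
#' discoid (2D, in-plane) or hemispheric (3D, anchored to the seabed)
#' encounter region of radius `r`. Resources move by random walks
#' (persistent heading with Gaussian turning noise in 2D, isotropic redraw
#' in 3D); planktonic resources are additionally advected along +x by a
#' laminar current drawn per step and per resource from
#' `Normal(current_mean, current_sd)`.
#'
#' @param dimensionality 2 or 3.
#' @param extent arena side length (m); must exceed twice the region radius.
#' @param r encounter-region radius (m).
#' @param consumer_speed consumer speed (m/s), 0 for passive strategies.
#' @param n_resources number of resource agents (constant: encountered
#'   resources are relocated uniformly outside the region, keeping density
#'   fixed in the encounter-limited regime).
#' @param resource_speed random-walk speed of resources (m/s).
#' @param resource_mass resource wet mass (g), for biomass rates.
#' @param mobile do resources random-walk?
#' @param planktonic are resources advected by the current? (3D only)
#' @param height slab height for 3D (default `10 * r`).
#' @param dt time step (s); default `min(r / (5 * vmax), 1)` so no agent can
#'   tunnel through the region between steps.
#' @param current_mean,current_sd laminar current (m/s), defaults 0.1 and
#'   0.01.
#' @param sigma_turn turning-angle SD per step (radians, default 30 deg).
#' @return A list of class `abm_world`.
#' @export
abm_world <- function(dimensionality = 2, extent, r, consumer_speed = 0,
                      n_resources, resource_speed = 0, resource_mass = 1,
                      mobile = resource_speed > 0, planktonic = FALSE,
                      height = 10 * r, dt = NULL,
                      current_mean = 0.1, current_sd = 0.01,
                      sigma_turn = pi / 6) {
  stopifnot(dimensionality %in% c(2, 3), extent > 0, r > 0, n_resources >= 0)
  if (extent <= 2 * r)
    stop("arena extent must exceed twice the reaction distance")
  if (planktonic && dimensionality != 3)
    stop("planktonic (advected) resources require a 3D world")
  vmax <- max(consumer_speed, resource_speed +
                if (planktonic) current_mean + 3 * current_sd else 0)
  if (is.null(dt)) dt <- if (vmax > 0) min(r / (5 * vmax), 1) else 1
  if (dt <= 0) stop("dt must be positive")
  if (vmax * dt > extent / 2)
    stop("step length exceeds extent/2: aliasing; refine dt or enlarge arena")

  world <- list(
    dim = dimensionality, extent = extent, height = height, dt = dt,
    r = r, consumer_pos = c(extent / 2, extent / 2),
    consumer_speed = consumer_speed,
    consumer_heading = stats::runif(1, 0, 2 * pi),
    res_pos = matrix(numeric(0), ncol = dimensionality),
    res_heading = stats::runif(n_resources, 0, 2 * pi),
    resource_speed = resource_speed, resource_mass = resource_mass,
    mobile = mobile, planktonic = planktonic,
    current_mean = current_mean, current_sd = current_sd,
    sigma_turn = sigma_turn,
    encounters = 0L, advect_sum = 0, advect_n = 0L)
  class(world) <- "abm_world"
  # resources start uniform conditioned outside the region, the same
  # stationary distribution the relocation rule maintains
  if (n_resources > 0) world$res_pos <- relocate_outside(world, n_resources)
  world
}

wrap_torus <- function(x, extent) x %% extent

#' Advance the simulation world by one time step
#'
#' Moves every mobile agent, applies the advective current to planktonic
#' resources, wraps the torus / reflects the slab, registers encounters
#' (resource within the consumer's region after movement), and relocates
#' encountered resources uniformly at random outside the region so resource
#' density stays constant.
#'
#' @param world an [abm_world()].
#' @return The updated world; `$encounters` accumulates the encounter
#'   count, `$step_encounters` holds this step's count.
#' @export
abm_step <- function(world) {
  w <- world
  ext <- w$extent
  n <- nrow(w$res_pos)

  if (w$consumer_speed > 0) {
    w$consumer_heading <- w$consumer_heading + stats::rnorm(1, 0, w$sigma_turn)
    w$consumer_pos <- wrap_torus(
      w$consumer_pos + w$consumer_speed * w$dt *
        c(cos(w$consumer_heading), sin(w$consumer_heading)), ext)
  }

  if (n > 0) {
    if (w$mobile && w$resource_speed > 0) {
      if (w$dim == 2) {
        w$res_heading <- w$res_heading + stats::rnorm(n, 0, w$sigma_turn)
        w$res_pos[, 1] <- w$res_pos[, 1] +
          w$resource_speed * w$dt * cos(w$res_heading)
        w$res_pos[, 2] <- w$res_pos[, 2] +
          w$resource_speed * w$dt * sin(w$res_heading)
      } else {
        # isotropic direction redraw each step
        z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
        nrm <- sqrt(x^2 + y^2 + z^2)
        nrm[nrm == 0] <- 1
        w$res_pos <- w$res_pos +
          w$resource_speed * w$dt * cbind(x / nrm, y / nrm, z / nrm)
      }
    }
    if (w$planktonic) {
      u <- stats::rnorm(n, w$current_mean, w$current_sd)
      w$res_pos[, 1] <- w$res_pos[, 1] + u * w$dt
      w$advect_sum <- w$advect_sum + sum(u)
      w$advect_n <- w$advect_n + n
      # flow-through boundary along the current: a resource leaving the
      # downstream edge is replaced by one entering upstream with a fresh
      # uniform cross-section (the current carries new water), keeping the
      # cross-stream distribution stationary
      cross <- w$res_pos[, 1] < 0 | w$res_pos[, 1] >= ext
      if (any(cross)) {
        w$res_pos[cross, 2] <- stats::runif(sum(cross), 0, ext)
        w$res_pos[cross, 3] <- stats::runif(sum(cross), 0, w$height)
      }
    }
    w$res_pos[, 1] <- wrap_torus(w$res_pos[, 1], ext)
    w$res_pos[, 2] <- wrap_torus(w$res_pos[, 2], ext)
    if (w$dim == 3) {
      # reflect at the seabed and the slab top
      z <- w$res_pos[, 3]
      z <- abs(z)
      over <- z > w$height
      z[over] <- 2 * w$height - z[over]
      w$res_pos[, 3] <- pmin(pmax(z, 0), w$height)
    }

    dx <- abs(w$res_pos[, 1] - w$consumer_pos[1])
    dx <- pmin(dx, ext - dx)
    dy <- abs(w$res_pos[, 2] - w$consumer_pos[2])
    dy <- pmin(dy, ext - dy)
    d2 <- dx^2 + dy^2
    if (w$dim == 3) d2 <- d2 + w$res_pos[, 3]^2 # hemisphere anchored at z = 0
    hit <- which(d2 <= w$r^2)
    w$step_encounters <- length(hit)
    w$encounters <- w$encounters + length(hit)
    if (length(hit) > 0) w$res_pos[hit, ] <- relocate_outside(w, length(hit))
  } else {
    w$step_encounters <- 0L
  }
  w
}

# Uniform positions conditioned on lying outside the encounter region.
relocate_outside <- function(w, k) {
  out <- matrix(NA_real_, nrow = k, ncol = w$dim)
  need <- seq_len(k)
  for (tries in 1:100) {
    m <- length(need)
    if (m == 0) break
    p <- matrix(stats::runif(m * 2, 0, w$extent), ncol = 2)
    if (w$dim == 3) p <- cbind(p, stats::runif(m, 0, w$height))
    dx <- abs(p[, 1] - w$consumer_pos[1]); dx <- pmin(dx, w$extent - dx)
    dy <- abs(p[, 2] - w$consumer_pos[2]); dy <- pmin(dy, w$extent - dy)
    d2 <- dx^2 + dy^2
    if (w$dim == 3) d2 <- d2 + p[, 3]^2
    ok <- d2 > w$r^2
    out[need[ok], ] <- p[ok, , drop = FALSE]
    need <- need[!ok]
  }
  if (length(need) > 0) stop("could not relocate resources outside the region")
  out
}

#' Run a built world for a fixed number of steps
#'
#' @param world an [abm_world()].
#' @param n_steps number of steps (0 allowed: zero rates).
#' @return An `encounter_log`: unitary and biomass encounter rates, the
#'   per-step encounter counts, the realised mean advective current, and a
#'   configuration echo.
#' @export
abm_run <- function(world, n_steps) {
  stopifnot(n_steps >= 0)
  counts <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    world <- abm_step(world)
    counts[s] <- world$step_encounters
  }
  duration <- n_steps * world$dt
  unitary <- if (duration > 0) world$encounters / duration else 0
  structure(list(
    unitary_rate = unitary,
    biomass_rate = unitary * world$resource_mass,
    counts = counts, n_steps = n_steps, dt = world$dt, duration = duration,
    resource_mass = world$resource_mass,
    mean_current = if (world$advect_n > 0) world$advect_sum / world$advect_n
                   else NA_real_,
    n_current_samples = world$advect_n,
    config = world[c("dim", "extent", "height", "r", "consumer_speed",
                     "resource_speed", "mobile", "planktonic",
                     "current_mean", "current_sd", "sigma_turn")]),
    class = "encounter_log")
}

#' @export
print.encounter_log <- function(x, ...) {
  cat(sprintf("Encounter log: %d steps x dt = %.3g s (%.3g s simulated)\n",
              x$n_steps, x$dt, x$duration))
  cat(sprintf("  unitary rate: %.4g individuals/s\n", x$unitary_rate))
  cat(sprintf("  biomass rate: %.4g g/s (resource mass %.3g g)\n",
              x$biomass_rate, x$resource_mass))
  if (is.finite(x$mean_current))
    cat(sprintf("  realised mean current: %.4g m/s (%d samples)\n",
                x$mean_current, x$n_current_samples))
  invisible(x)
}

#' Run one encounter-rate replicate for a consumer mass and strategy
#'
#' Builds the consumer from allometry (region radius via
#' [reaction_distance()] or, for filter feeders with `clearance_Q` set,
#' [clearance_region_radius()]; speed via
#' `velocity_from_length(length_from_mass(m))` for active strategies, 0 for
#' filter feeders) and the resource field from the strategy scalings
#' (unitary density and mass as power laws of consumer mass), then runs the
#' world. When the nominal resource count implied by the density law falls
#' outside `[min_resources, max_resources]`, the simulation runs at a
#' rescaled density and the reported rates are scaled back linearly
#' (encounter rates are linear in density in the encounter-limited,
#' constant-density regime).
#'
#' @param consumer_mass consumer wet mass (g).
#' @param strategy `"filter"`, `"active-static"` or `"active-mobile"`.
#' @param scalings per-strategy scalings, see [default_strategy_scalings()].
#' @param seed integer seed; the log is bitwise reproducible given the seed.
#' @param n_steps steps to run (default 1000).
#' @param n_resources override the resource count implied by the density
#'   law (density is preserved by adjusting the arena only when this is
#'   `NULL`; an explicit override keeps the default arena).
#' @param min_resources,max_resources clamp on simulated resource count.
#' @param r0 reaction-distance coefficient (m at 1 g).
#' @param clearance_Q optional clearance rate (m^3/s) to size a filter
#'   feeder's region from flux instead of reaction distance.
#' @param extent_factor arena side as a multiple of the region radius
#'   (default 8).
#' @param dt override the adaptive time step.
#' @param current_mean,current_sd,sigma_turn as in [abm_world()].
#' @return An `encounter_log` with `strategy`, `consumer_mass`, and the
#'   density `scale_factor` recorded.
#' @export
run_replicate <- function(consumer_mass, strategy, scalings = default_strategy_scalings(),
                          seed = 1, n_steps = 1000, n_resources = NULL,
                          min_resources = 20, max_resources = 3000,
                          r0 = 0.01, clearance_Q = NULL, extent_factor = 8,
                          dt = NULL, current_mean = 0.1, current_sd = 0.01,
                          sigma_turn = pi / 6) {
  if (!strategy %in% names(scalings))
    stop("no scalings available for strategy: ", strategy)
  ss <- scalings[[strategy]]
  set.seed(seed)

  r <- if (!is.null(clearance_Q) && strategy == "filter")
    clearance_region_radius(clearance_Q, current_mean)
  else reaction_distance(consumer_mass, r0)
  speed <- if (strategy == "filter") 0
           else velocity_from_length(length_from_mass(consumer_mass))
  dim_w <- ss$dimensionality
  res_mass <- pl_eval(ss$resource_mass_law, consumer_mass)
  density <- pl_eval(ss$resource_density_law, consumer_mass)

  extent <- extent_factor * r
  height <- 10 * r
  vol <- if (dim_w == 3) extent^2 * height else extent^2
  n_nominal <- density * vol
  if (n_nominal <= 0) {
    warning("density law yields zero resources; returning zero rates")
    log0 <- abm_run(abm_world(dim_w, extent, r, speed, 0,
                              resource_mass = res_mass, height = height), 0)
    log0$strategy <- strategy; log0$consumer_mass <- consumer_mass
    log0$scale_factor <- 1
    return(log0)
  }
  if (is.null(n_resources)) {
    n_sim <- round(min(max(n_nominal, min_resources), max_resources))
    scale_factor <- n_nominal / n_sim
  } else {
    n_sim <- n_resources
    scale_factor <- 1
  }
  res_speed <- velocity_from_length(length_from_mass(res_mass))
  mobile <- strategy %in% c("active-mobile", "filter")
  planktonic <- strategy == "filter"

  w <- abm_world(dim_w, extent, r, consumer_speed = speed,
                 n_resources = n_sim, resource_speed = if (mobile) res_speed else 0,
                 resource_mass = res_mass, mobile = mobile,
                 planktonic = planktonic, height = height, dt = dt,
                 current_mean = current_mean, current_sd = current_sd,
                 sigma_turn = sigma_turn)
  log <- abm_run(w, n_steps)
  log$unitary_rate <- log$unitary_rate * scale_factor
  log$biomass_rate <- log$biomass_rate * scale_factor
  log$strategy <- strategy
  log$consumer_mass <- consumer_mass
  log$scale_factor <- scale_factor
  log$density <- density
  log$n_resources <- n_sim
  log
}

#' Sweep encounter rates across a consumer-mass grid
#'
#' Runs `replicates` independent replicates of [run_replicate()] per mass
#' and summarises unitary and biomass encounter rates by the 0.025, 0.5 and
#' 0.975 quantiles, the plotting schema of the encounter-rate figures.
#'
#' @param strategy strategy label.
#' @param mass_grid consumer masses (g).
#' @param replicates replicates per mass (default 1000; fewer than 40 flags
#'   the quantiles as unstable).
#' @param seed master seed; replicate seeds are derived substreams.
#' @param ... passed to [run_replicate()].
#' @return Data frame of class `abm_sweep` with per-mass quantiles; the
#'   per-replicate tidy table is attached as `attr(x, "replicates")`.
#' @export
sweep_consumer_mass <- function(strategy, mass_grid, replicates = 1000,
                                seed = 1, ...) {
  stopifnot(replicates >= 1)
  rows <- list(); tidy <- list()
  for (m in mass_grid) {
    u <- numeric(replicates); bm <- numeric(replicates)
    for (i in seq_len(replicates)) {
      lg <- run_replicate(m, strategy, seed = substream_seed(seed, strategy, m, i),
                          ...)
      u[i] <- lg$unitary_rate; bm[i] <- lg$biomass_rate
    }
    qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    qu <- qs(u); qb <- qs(bm)
    rows[[length(rows) + 1]] <- data.frame(
      strategy = strategy, mass = m,
      unitary_lo = qu[1], unitary_med = qu[2], unitary_hi = qu[3],
      biomass_lo = qb[1], biomass_med = qb[2], biomass_hi = qb[3],
      replicates = replicates, stringsAsFactors = FALSE)
    tidy[[length(tidy) + 1]] <- data.frame(
      strategy = strategy, mass = m, replicate = seq_len(replicates),
      unitary_rate = u, biomass_rate = bm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, tidy)
  attr(out, "unstable") <- replicates < 40
  if (replicates < 40)
    warning("fewer than 40 replicates: quantile bands are unstable")
  class(out) <- c("abm_sweep", "data.frame")
  out
}

#' Kinetic-theory encounter rates for the validation scenarios
#'
#' Closed-form expected encounter rates used as the simulator's oracle:
#' \describe{
#'   \item{`"2D-active-static"`}{`2 r V n`: a searcher of speed `V` sweeps a
#'     band of width `2r` through static resources at areal density `n`.}
#'   \item{`"2D-active-mobile"`}{`2 r <V_rel> n` with `<V_rel>` the mean
#'     relative speed of two independent random walkers
#'     ([mean_relative_speed()]).}
#'   \item{`"3D-advective-filter"`}{`n U pi r^2 / 2`: flux of advected
#'     resources at volumetric density `n` through the half-disc
#'     cross-section of a seabed hemisphere facing the current.}
#' }
#'
#' @param scenario one of the three labels above.
#' @param r region radius (m).
#' @param n resource density (m^-2 or m^-3 by scenario).
#' @param V consumer speed (m/s), active scenarios.
#' @param V_resource resource speed (m/s), `"2D-active-mobile"`.
#' @param U current speed (m/s), filter scenario.
#' @return Expected encounter rate in individuals per second.
#' @export
analytic_encounter_rate <- function(scenario = c("2D-active-static",
                                                 "2D-active-mobile",
                                                 "3D-advective-filter"),
                                    r, n, V = NULL, V_resource = NULL,
                                    U = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(r > 0, n >= 0)
  switch(scenario,
    "2D-active-static" = {
      if (is.null(V)) stop("V required for 2D-active-static")
      2 * r * V * n
    },
    "2D-active-mobile" = {
      if (is.null(V) || is.null(V_resource))
        stop("V and V_resource required for 2D-active-mobile")
      2 * r * mean_relative_speed(V, V_resource) * n
    },
    "3D-advective-filter" = {
      if (is.null(U)) stop("U required for 3D-advective-filter")
      n * U * pi * r^2 / 2
    })
}

#' Mean relative speed of two independent 2D random walkers
#'
#' `E sqrt(V1^2 + V2^2 - 2 V1 V2 cos(theta))` for a uniformly random angle
#' `theta` between the two headings, by numerical quadrature.
#'
#' @param V1,V2 speeds (m/s).
#' @return Mean relative speed (m/s).
#' @export
mean_relative_speed <- function(V1, V2) {
  if (V1 == 0 && V2 == 0) return(0)
  stats::integrate(function(th) sqrt(V1^2 + V2^2 - 2 * V1 * V2 * cos(th)),
                   0, 2 * pi, rel.tol = 1e-10)$value / (2 * pi)
}
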