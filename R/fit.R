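#' Fit a functional response to depletion feeding trials
#'
#' Maximum-likelihood fit of one of four variants of the depletion-corrected
#' functional response ([rogers_eaten()]) to a [trial_set()]:
#' \describe{
#'   \item{`"I"`}{linear (Lotka-Volterra) response, `h = q = 0`; 1 parameter.}
#'   \item{`"II"`}{hyperbolic response, `q = 0`; 2 parameters.}
#'   \item{`"III"`}{sigmoidal response, `q = 1`; 2 parameters.}
#'   \item{`"general"`}{all of `b`, `h`, `q >= 0` free; 3 parameters.}
#' }
#' Optimisation is on `log(b)` and `log(h)` (scale invariance; keeps the
#' `h -> 0` boundary at `-Inf` rather than a hard wall) with `q` box
#' constrained at 0, from multiple starts: the binomial negative
#' log-likelihood is evaluated on a coarse grid of starting values
#' (5 x 5 in `b`, `h`; 3 values of `q` for the general model) and local
#' optimisation is run from the `n_starts` best grid points.
#'
#' @param trials a [trial_set()]; at least `k + 2` rows and (for the
#'   saturating variants) at least 4 distinct `N0` levels are recommended.
#' @param variant `"I"`, `"II"`, `"III"` or `"general"`.
#' @param convention exponent convention for [rogers_eaten()].
#' @param n_starts number of local optimisations (>= 5 grid candidates are
#'   always scored).
#' @param control optional list passed to [stats::optim()].
#' @return An object of class `fr_fit` with components `params`
#'   ([fr_params()]), `variant`, `logLik`, `k`, `n`, `AICc`, `converged`,
#'   `se_log` (standard errors on the optimised scale), `trials`,
#'   `convention`, and `null_fit` (flag: every trial ate zero).
#' @seealso [fr_select()] for fitting all four variants and choosing by
#'   AICc, [predict.fr_fit()], [simulate.fr_fit()].
#' @export
fr_fit <- function(trials, variant = c("II", "I", "III", "general"),
                   convention = c("q", "q_plus_1"), n_starts = 5,
                   control = list()) {
  variant <- match.arg(variant)
  convention <- match.arg(convention)
  validate_trial_set(trials)
  n <- nrow(trials)
  k <- switch(variant, I = 1L, II = 2L, III = 2L, general = 3L)
  if (n < k + 2) stop(sprintf("need at least %d trials to fit variant %s", k + 2, variant))
  n_levels <- length(unique(trials$N0))
  if (n_levels < 4 && variant != "I")
    warning("fewer than 4 distinct N0 levels; saturating fits may be weakly identified")

  if (all(trials$eaten == 0)) {
    # zero consumption everywhere: b = 0 is the (flagged) ML solution
    params <- fr_params(0, 0, if (variant == "III") 1 else 0,
                        dimensionality = trials$arena_dim[1])
    ll <- -fr_nll(params, trials, convention)
    out <- structure(list(params = params, variant = variant, logLik = ll,
                          k = k, n = n, AICc = aicc(ll, k, n),
                          converged = TRUE, null_fit = TRUE,
                          se_log = NULL, trials = trials,
                          convention = convention), class = "fr_fit")
    return(out)
  }

  dim_arena <- trials$arena_dim[1]
  Tbar <- stats::median(trials$T)
  pbar <- sum(trials$eaten) / sum(trials$N0)
  pbar <- min(max(pbar, 1e-3), 1 - 1e-3)
  # crude scales from the exponential-depletion limit and max observed intake
  b0 <- -log(1 - pbar) / Tbar / stats::median(trials$N0)^0 # per-capita scale
  h0 <- Tbar / max(trials$eaten, 1)

  grid_b <- log(b0) + log(10) * seq(-2, 2, length.out = 5)
  grid_h <- log(h0) + log(10) * seq(-2, 2, length.out = 5)
  grid_q <- c(0, 0.5, 1)

  free <- switch(variant,
                 I = "logb",
                 II = c("logb", "logh"),
                 III = c("logb", "logh"),
                 general = c("logb", "logh", "q"))
  q_fixed <- switch(variant, I = 0, II = 0, III = 1, general = NA)

  build_params <- function(theta) {
    b <- exp(theta[["logb"]])
    h <- if ("logh" %in% free) exp(theta[["logh"]]) else 0
    q <- if ("q" %in% free) theta[["q"]] else q_fixed
    fr_params(b, h, q, dimensionality = dim_arena)
  }
  obj <- function(par) {
    theta <- stats::setNames(par, free)
    val <- try(fr_nll(build_params(theta), trials, convention), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e10)
    val
  }

  starts <- switch(variant,
    I = lapply(grid_b, function(b) c(logb = b)),
    II = ,
    III = {
      g <- expand.grid(logb = grid_b, logh = grid_h)
      lapply(seq_len(nrow(g)), function(i) c(logb = g$logb[i], logh = g$logh[i]))
    },
    general = {
      g <- expand.grid(logb = grid_b, logh = grid_h, q = grid_q)
      lapply(seq_len(nrow(g)), function(i)
        c(logb = g$logb[i], logh = g$logh[i], q = g$q[i]))
    })
  scores <- vapply(starts, obj, numeric(1))
  best_starts <- starts[order(scores)][seq_len(min(n_starts, length(starts)))]

  lower <- ifelse(free == "q", 0, -Inf)
  fits <- lapply(best_starts, function(s) {
    if (length(free) == 1) {
      o <- try(stats::optim(s, obj, method = "Brent", lower = log(b0) - 25,
                            upper = log(b0) + 25, control = control,
                            hessian = TRUE), silent = TRUE)
    } else {
      o <- try(stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                            control = control, hessian = TRUE), silent = TRUE)
    }
    o
  })
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  fits <- fits[ok]
  if (length(fits) == 0) stop("all optimisation starts failed")
  vals <- vapply(fits, function(o) o$value, numeric(1))
  best <- fits[[which.min(vals)]]
  converged <- best$convergence == 0
  if (!converged)
    warning(sprintf("fr_fit(variant = %s): optimiser did not report convergence", variant))

  theta <- stats::setNames(best$par, free)
  params <- build_params(theta)
  se_log <- tryCatch({
    v <- solve(best$hessian)
    stats::setNames(sqrt(pmax(diag(as.matrix(v)), 0)), free)
  }, error = function(e) NULL)
  ll <- -best$value
  structure(list(params = params, variant = variant, logLik = ll, k = k,
                 n = n, AICc = aicc(ll, k, n), converged = converged,
                 null_fit = FALSE, se_log = se_log, trials = trials,
                 convention = convention), class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("Functional response fit (variant %s%s)\n", x$variant,
              if (x$null_fit) ", null: zero consumption" else ""))
  cat(sprintf("  b = %.4g  h = %.4g  q = %.3g\n",
              x$params$b, x$params$h, x$params$q))
  cat(sprintf("  logLik = %.3f  k = %d  n = %d  AICc = %.3f\n",
              x$logLik, x$k, x$n, x$AICc))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) {
  c(b = object$params$b, h = object$params$h, q = object$params$q)
}

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.fr_fit <- function(object, ...) {
  est <- coef(object)
  ci <- confint(object)
  out <- list(fit = object, coefficients = est, ci = ci,
              max_feeding_rate = max_feeding_rate(object$params),
              half_sat = if (object$params$b > 0 && object$params$h > 0)
                half_saturation_rate(object$params) else NA_real_)
  class(out) <- "summary.fr_fit"
  out
}

#' @export
print.summary.fr_fit <- function(x, ...) {
  print(x$fit)
  cat("Wald 95% CIs (log-scale for b, h):\n")
  print(x$ci)
  cat(sprintf("Maximum feeding rate (1/h): %.4g per time unit\n",
              x$max_feeding_rate))
  if (is.finite(x$half_sat))
    cat(sprintf("Capture rate at half-saturation: %.4g\n", x$half_sat))
  invisible(x)
}

#' Wald confidence intervals for a functional response fit
#'
#' Intervals are computed on the optimised scale (`log b`, `log h`, free
#' `q`) from the observed-information standard errors and back-transformed.
#'
#' @param object an `fr_fit`.
#' @param parm ignored; all free parameters are returned.
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.fr_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$se_log)) return(NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  free <- names(object$se_log)
  centre <- c(logb = log(object$params$b), logh = log(object$params$h),
              q = object$params$q)[free]
  lo <- centre - z * object$se_log
  hi <- centre + z * object$se_log
  back <- function(v) {
    out <- v
    out[grep("^log", free)] <- exp(v[grep("^log", free)])
    out
  }
  m <- cbind(back(lo), back(hi))
  rownames(m) <- sub("^log", "", free)
  colnames(m) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  m
}

#' Predict expected consumption for new initial densities
#'
#' @param object an `fr_fit`.
#' @param newdata optional data frame with columns `N0` and `T`; defaults to
#'   the fitted trials.
#' @param type `"eaten"` (depletion expectation, default) or `"rate"`
#'   (instantaneous per-capita rate at constant density `N0`).
#' @param ... unused.
#' @export
predict.fr_fit <- function(object, newdata = NULL, type = c("eaten", "rate"),
                           ...) {
  type <- match.arg(type)
  nd <- newdata %||% object$trials
  if (type == "rate") return(holling_rate(nd$N0, object$params))
  rogers_eaten(nd$N0, nd$T, object$params, object$convention)
}

#' Simulate feeding trials from a fitted response
#'
#' Draws `eaten ~ Binomial(N0, Ne/N0)` around the fitted depletion
#' expectation, matching the fitted likelihood.
#'
#' @param object an `fr_fit`.
#' @param nsim number of simulated replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with one column per simulation, as for [stats::lm()]
#'   simulate methods.
#' @export
simulate.fr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ne <- predict(object)
  p <- ifelse(object$trials$N0 > 0, ne / object$trials$N0, 0)
  out <- as.data.frame(lapply(seq_len(nsim), function(i)
    stats::rbinom(length(p), object$trials$N0, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.fr_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  ne <- predict(object)
  r <- object$trials$eaten - ne
  if (type == "response") return(r)
  p <- ifelse(object$trials$N0 > 0, ne / object$trials$N0, 0)
  v <- object$trials$N0 * p * (1 - p)
  r / sqrt(pmax(v, .Machine$double.eps))
}

#' Plot a fitted functional response over the trial data
#'
#' @param x an `fr_fit`.
#' @param ... passed to [plot()].
#' @export
plot.fr_fit <- function(x, ...) {
  tr <- x$trials
  graphics::plot(jitter(tr$N0), tr$eaten, xlab = "initial resource density N0",
                 ylab = "number eaten", ...)
  grid_N0 <- seq(0, max(tr$N0), length.out = 100)
  ne <- rogers_eaten(grid_N0[-1], stats::median(tr$T), x$params, x$convention)
  graphics::lines(grid_N0, c(0, ne), col = "steelblue", lwd = 2)
  invisible(x)
}
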