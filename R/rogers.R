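#' Generalised Holling functional response
#'
#' Per-capita consumption rate at constant resource density:
#' `b * N^(q+1) / (1 + b * h * N^(q+1))`. With `h > 0` the rate saturates at
#' `1/h` as density grows; `q = 0` gives the hyperbolic type II form and
#' `q = 1` the sigmoidal type III form.
#'
#' @param N resource density (individuals per arena unit), `N >= 0`;
#'   vectorised.
#' @param params an [fr_params()] object.
#' @return Per-capita consumption rate, same length as `N`.
#' @export
holling_rate <- function(N, params) {
  params <- as_fr_params(params)
  if (any(N < 0)) stop("resource density N must be non-negative")
  u <- params$b * N^(params$q + 1)
  u / (1 + params$b * params$h * N^(params$q + 1))
}

#' Expected number eaten under depletion (Rogers random-predator equation)
#'
#' Solves the implicit depletion-corrected functional response
#' \deqn{N_e = N_0 (1 - e^{c (h N_e - T)})}{Ne = N0 (1 - exp(c (h Ne - T)))}
#' for the expected number eaten over a trial of duration `T` starting from
#' `N0` resources, where `c = b N0^q` (default convention, consistent with a
#' per-capita attack coefficient `b N^q` and reducing to the classic Rogers
#' equation at `q = 0`) or `c = b N0^(q+1)` (`convention = "q_plus_1"`).
#'
#' The unique root in `[0, N0]` is obtained in closed form through the
#' principal branch of the Lambert-W function,
#' `Ne = N0 - W(c h N0 exp(-c (T - h N0))) / (c h)` when `h > 0`, with a
#' bracketed root-finder fallback wherever the W argument would overflow.
#'
#' @param N0 initial resource count(s), vectorised.
#' @param T trial duration, `T > 0` (scalar or same length as `N0`).
#' @param params an [fr_params()] object.
#' @param convention `"q"` (default) or `"q_plus_1"`, the exponent applied
#'   to `N0` in the depletion exponent.
#' @param method `"lambert"` (closed form, default) or `"uniroot"`
#'   (bracketed root finder); both agree to high precision and `"lambert"`
#'   silently falls back on the root finder when `exp` would overflow.
#' @return Expected number eaten, in `[0, N0]` elementwise.
#' @examples
#' p <- fr_params(b = 0.05, h = 0.2)
#' rogers_eaten(c(5, 10, 20), T = 1, p)
#' @export
rogers_eaten <- function(N0, T, params, convention = c("q", "q_plus_1"),
                         method = c("lambert", "uniroot")) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  params <- as_fr_params(params)
  if (any(N0 < 0)) stop("N0 must be non-negative")
  if (any(T <= 0)) stop("T must be positive")
  n <- max(length(N0), length(T))
  N0 <- rep_len(as.numeric(N0), n)
  T <- rep_len(as.numeric(T), n)
  b <- params$b; h <- params$h; q <- params$q
  if (b == 0) return(numeric(n))

  expo <- if (convention == "q") q else q + 1
  cc <- b * N0^expo
  cc[N0 == 0] <- 0

  if (h == 0) return(N0 * (1 - exp(-cc * T)))

  ne <- numeric(n)
  pos <- N0 > 0
  if (method == "lambert") {
    log_arg <- log(cc * h * N0) - cc * (T - h * N0)
    safe <- pos & is.finite(log_arg) & log_arg < 700
    if (any(safe)) {
      w <- lambert_w0(exp(log_arg[safe]))
      ne[safe] <- N0[safe] - w / (cc[safe] * h)
    }
    hard <- pos & !safe
  } else {
    hard <- pos
  }
  for (i in which(hard)) {
    ne[i] <- rogers_root(N0[i], T[i], cc[i], h)
  }
  pmin(pmax(ne, 0), N0)
}

# Bracketed root of x - N0 (1 - exp(cc (h x - T))) on [0, N0]. The
# exponent is clamped at 700 so the bracket stays finite even for extreme
# depletion parameters; the clamp cannot move the root, which always lies
# where the exponent is moderate.
rogers_root <- function(N0, T, cc, h) {
  f <- function(x) x - N0 * (1 - exp(pmin(cc * (h * x - T), 700)))
  lo <- f(0); hi <- f(N0)
  if (!is.finite(lo) || !is.finite(hi)) stop("Rogers solver: non-finite bracket")
  if (lo > 0 || hi < 0) stop("Rogers solver: no root in [0, N0]")
  stats::uniroot(f, c(0, N0), tol = 1e-12 * max(1, N0))$root
}

#' Negative log-likelihood of a trial set under the depletion model
#'
#' Binomial likelihood of the observed counts given the Rogers expectation:
#' `eaten ~ Binomial(N0, rogers_eaten(N0, T)/N0)`, with the success
#' probability clipped to `[eps, 1 - eps]` for numerical stability.
#'
#' @param params an [fr_params()] object.
#' @param trials a [trial_set()] (columns `N0`, `eaten`, `T`).
#' @param convention exponent convention passed to [rogers_eaten()].
#' @param eps probability clip, default `1e-9`.
#' @return The negative log-likelihood (scalar).
#' @export
fr_nll <- function(params, trials, convention = "q", eps = 1e-9) {
  if (all(trials$N0 == 0)) stop("all trials have N0 = 0; likelihood undefined")
  key <- paste(trials$N0, trials$T)
  uk <- !duplicated(key)
  ne <- rogers_eaten(trials$N0[uk], trials$T[uk], params, convention)
  p_unique <- ifelse(trials$N0[uk] > 0, ne / trials$N0[uk], 0)
  p <- p_unique[match(key, key[uk])]
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(stats::dbinom(trials$eaten, trials$N0, p, log = TRUE))
}
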