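#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through a
#' named substream, so regenerating a single pair or stage reproduces the
#' same values as a full run.
#'
#' @param master integer master seed.
#' @param ... character or numeric keys naming the substream
#'   (e.g. `"generate"`, `pair_id`).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  keys <- paste(c(master, ...), collapse = "/")
  p <- 2147483629 # largest prime < 2^31
  h <- 17
  for (ch in utf8ToInt(keys)) h <- (h * 31 + ch) %% p
  as.integer(h %% (p - 1L) + 1L)
}

#' Small-sample corrected Akaike information criterion
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc value; `Inf` when `n <= k + 1` (correction undefined).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Principal branch of the Lambert W function on non-negative arguments
#'
#' Solves `w * exp(w) = x` for `x >= 0`, vectorised. Small arguments
#' (`x < 3`) use Halley iteration on `w e^w = x` started at `x / (1 + x)`;
#' larger arguments solve the overflow-safe logarithmic form
#' `w + log(w) = log(x)` by Newton iteration, so arguments up to the
#' double-precision limit are handled without evaluating `exp(w)`.
#'
#' @param x non-negative numeric vector.
#' @param tol convergence tolerance on the update (default 1e-14).
#' @param max_iter iteration cap.
#' @return `W0(x)`, same length as `x`.
#' @export
lambert_w0 <- function(x, tol = 1e-14, max_iter = 60) {
  if (any(x < 0)) stop("lambert_w0 is defined here for x >= 0 only")
  w <- numeric(length(x))
  small <- x > 0 & x < 3
  if (any(small)) {
    xs <- x[small]
    ws <- xs / (1 + xs)
    for (i in seq_len(max_iter)) {
      ew <- exp(ws)
      f <- ws * ew - xs
      d <- f / (ew * (ws + 1) - (ws + 2) * f / (2 * ws + 2))
      ws <- ws - d
      if (max(abs(d)) < tol) break
    }
    w[small] <- ws
  }
  large <- x >= 3
  if (any(large)) {
    lx <- log(x[large])
    wl <- lx - log(lx)
    for (i in seq_len(max_iter)) {
      d <- (wl + log(wl) - lx) / (1 + 1 / wl)
      wl <- wl - d
      if (max(abs(d)) < tol) break
    }
    w[large] <- wl
  }
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
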