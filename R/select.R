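#' Classify the trend in proportional consumption across densities
#'
#' The proportion eaten (`eaten / N0`) carries a model-selection diagnostic:
#' constant proportions indicate a linear (type I) response, monotonically
#' decreasing proportions a hyperbolic (type II) response, and proportions
#' that rise then fall a sigmoidal (type III) response. A locally weighted
#' regression of proportion on log10 density is smoothed and compared at the
#' lowest density, the interior maximum, and the highest density.
#'
#' @param trials a [trial_set()] with at least 4 distinct `N0` levels.
#' @param span loess span (default 0.75).
#' @param tol flat-slope tolerance: trends are declared flat when the total
#'   smoothed change per decade of density is below `tol` times the mean
#'   proportion (default 0.05, i.e. 5% per decade).
#' @return One of `"flat"`, `"decreasing"`, `"hump"`, `"ambiguous"`.
#' @export
proportional_trend <- function(trials, span = 0.75, tol = 0.05) {
  lv <- sort(unique(trials$N0[trials$N0 > 0]))
  if (length(lv) < 2) stop("need more than one density level to classify a trend")
  p <- trials$eaten / pmax(trials$N0, 1)
  x <- log10(pmax(trials$N0, 1))
  fit <- try(suppressWarnings(stats::loess(p ~ x, span = span, degree = 1)),
             silent = TRUE)
  xs <- seq(min(x), max(x), length.out = 41)
  if (inherits(fit, "try-error")) {
    sm <- stats::approx(x, stats::ave(p, x), xout = xs, rule = 2)$y
  } else {
    sm <- stats::predict(fit, data.frame(x = xs))
  }
  sm[!is.finite(sm)] <- mean(p)
  decades <- max(x) - min(x)
  if (decades <= 0) return("ambiguous")
  thr <- tol * mean(p) * decades # tolerated total change across the range
  i_max <- which.max(sm)
  rise <- sm[i_max] - sm[1]
  fall <- sm[i_max] - sm[length(sm)]
  total <- max(sm) - min(sm)
  if (total <= thr) return("flat")
  interior <- i_max > 3 && i_max < length(sm) - 3
  if (interior && rise > thr && fall > thr) return("hump")
  if (sm[1] - sm[length(sm)] > thr && rise <= thr) return("decreasing")
  if (sm[length(sm)] - sm[1] > thr) return("ambiguous") # monotone increase: no class
  "ambiguous"
}

#' Fit all four response variants and select by AICc
#'
#' Fits the type I, II, III and general variants with [fr_fit()], ranks them
#' by small-sample AICc, and selects the lowest-scoring model outright when
#' no competitor is within `delta_competitive` AICc units. When two or more
#' models are competitive the proportional-consumption diagnostic
#' ([proportional_trend()]) arbitrates: flat favours type I, decreasing
#' type II, hump type III; the general model is treated as II-like when its
#' fitted `q < 0.5` and III-like otherwise. Remaining ties go to the model
#' with fewest parameters.
#'
#' @param trials a [trial_set()].
#' @param convention exponent convention for [rogers_eaten()].
#' @param delta_competitive AICc window defining competitive models
#'   (default 2).
#' @param span,tol diagnostic settings, see [proportional_trend()].
#' @param ... passed to [fr_fit()].
#' @return An object of class `fr_selection`: list with `fits` (named list
#'   of `fr_fit`), `table` (AICc ranking), `diagnostic`, `selected`
#'   (the winning `fr_fit`), `by_diagnostic` (logical).
#' @export
fr_select <- function(trials, convention = c("q", "q_plus_1"),
                      delta_competitive = 2, span = 0.75, tol = 0.05, ...) {
  convention <- match.arg(convention)
  variants <- c("I", "II", "III", "general")
  fits <- lapply(variants, function(v)
    try(fr_fit(trials, variant = v, convention = convention, ...),
        silent = TRUE))
  names(fits) <- variants
  failed <- vapply(fits, inherits, logical(1), "try-error")
  if (all(failed)) stop("no functional response variant could be fitted")
  fits_ok <- fits[!failed]

  tab <- data.frame(
    variant = names(fits_ok),
    k = vapply(fits_ok, function(f) f$k, integer(1)),
    logLik = vapply(fits_ok, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits_ok, function(f) f$AICc, numeric(1)),
    converged = vapply(fits_ok, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), ]
  tab$dAICc <- tab$AICc - min(tab$AICc)
  rownames(tab) <- NULL

  competitive <- tab$variant[tab$dAICc < delta_competitive]
  diagnostic <- NA_character_
  by_diag <- FALSE
  if (length(competitive) == 1) {
    winner <- competitive
  } else {
    diagnostic <- tryCatch(proportional_trend(trials, span, tol),
                           error = function(e) "ambiguous")
    shape_of <- function(v) {
      if (v == "I") return("flat")
      if (v == "II") return("decreasing")
      if (v == "III") return("hump")
      if (fits_ok[[v]]$params$q < 0.5) "decreasing" else "hump"
    }
    shapes <- vapply(competitive, shape_of, character(1))
    match_diag <- competitive[shapes == diagnostic]
    pool <- if (diagnostic != "ambiguous" && length(match_diag) > 0) {
      by_diag <- TRUE
      match_diag
    } else competitive
    ks <- tab$k[match(pool, tab$variant)]
    pool <- pool[ks == min(ks)]
    winner <- pool[which.min(tab$AICc[match(pool, tab$variant)])]
  }

  structure(list(fits = fits_ok, table = tab, diagnostic = diagnostic,
                 selected = fits_ok[[winner]], by_diagnostic = by_diag),
            class = "fr_selection")
}

#' @export
print.fr_selection <- function(x, ...) {
  cat("Functional response model selection (AICc)\n")
  print(x$table, digits = 4)
  if (!is.na(x$diagnostic))
    cat(sprintf("Proportional-consumption diagnostic: %s%s\n", x$diagnostic,
                if (x$by_diagnostic) " (used to break AICc tie)" else ""))
  cat(sprintf("Selected: variant %s\n", x$selected$variant))
  invisible(x)
}

#' Bootstrap group means of the shape exponent q
#'
#' The distribution of fitted shape exponents is atypical (point masses at
#' 0 and 1 mixed with positive reals), so group means are compared by
#' non-parametric bootstrap rather than a parametric model.
#'
#' @param q numeric vector of fitted shape exponents.
#' @param group grouping factor (e.g. encounter strategy), same length.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed; resampling is deterministic given the seed.
#' @return Data frame with one row per group: `group`, `n`, `mean`, `lo`,
#'   `hi` (2.5/97.5 percentiles) and `degenerate` (single-member group).
#' @export
bootstrap_mean_q <- function(q, group, n_boot = 2000, seed = 1) {
  stopifnot(length(q) == length(group), n_boot >= 0)
  set.seed(seed)
  groups <- unique(as.character(group))
  rows <- lapply(groups, function(g) {
    v <- q[group == g]
    if (length(v) == 0) stop("empty group: ", g)
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(v, length(v), replace = TRUE)), numeric(1))
    qs <- if (n_boot > 0) stats::quantile(bm, c(0.025, 0.975), names = FALSE)
          else c(NA_real_, NA_real_)
    data.frame(group = g, n = length(v), mean = mean(v),
               lo = qs[1], hi = qs[2], degenerate = length(v) == 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
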