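#' Enumerate the hierarchical set of fixed-effect structures
#'
#' The maximal model for either response (capture rate or maximum feeding
#' rate) contains the three metabolic predictors — log consumer mass (C),
#' log resource mass (R), log temperature (T) — their two-way interactions,
#' and encounter strategy as a non-interacting categorical predictor.
#' Respecting marginality (an interaction is only included alongside both
#' of its main effects), the hierarchical set contains the null (1), the
#' three singletons, each of the three pairs with and without its
#' interaction (6), and the full triple with every subset of the three
#' two-way interactions (8) — 18 structures, each with and without
#' strategy: 36 in total.
#'
#' @return List of `meta_structure` objects, each with elements `mains`
#'   (subset of `c("C","R","T")`), `interactions` (subset of pairs, e.g.
#'   `"C:R"`), and `strategy` (logical).
#' @export
enumerate_structures <- function() {
  mains_sets <- unlist(lapply(0:3, function(k)
    utils::combn(c("C", "R", "T"), k, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (mains in mains_sets) {
    pairs <- if (length(mains) >= 2)
      utils::combn(mains, 2, paste, collapse = ":") else character()
    int_sets <- unlist(lapply(0:length(pairs), function(k)
      utils::combn(pairs, k, simplify = FALSE)), recursive = FALSE)
    for (ints in int_sets) {
      for (strat in c(FALSE, TRUE)) {
        out[[length(out) + 1]] <- structure(
          list(mains = mains, interactions = ints, strategy = strat),
          class = "meta_structure")
      }
    }
  }
  out
}

#' @export
print.meta_structure <- function(x, ...) {
  cat(format_structure(x), "\n")
  invisible(x)
}

format_structure <- function(s) {
  terms <- c(s$mains, s$interactions, if (s$strategy) "strategy")
  if (length(terms) == 0) "~ 1" else paste("~", paste(terms, collapse = " + "))
}

structure_formula <- function(s, response) {
  map <- c(C = "log_consumer_mass", R = "log_resource_mass",
           T = "log_temperature")
  terms <- map[s$mains]
  if (length(s$interactions) > 0) {
    ints <- vapply(strsplit(s$interactions, ":"), function(p)
      paste(map[p], collapse = ":"), character(1))
    terms <- c(terms, ints)
  }
  if (s$strategy) terms <- c(terms, "strategy")
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs, "+ (1 | taxon_group)"))
}

#' Assemble the meta-analysis table from fitted responses
#'
#' Joins per-pair fitted responses with their covariates, converts to
#' biomass rates ([biomass_rates()]), natural-log transforms masses,
#' temperature and both feeding parameters, and z-standardises the two
#' responses across the full table. Pairs whose fit failed, whose response
#' is non-positive (null fits), or whose temperature is at or below 0 C
#' (the natural log of Celsius temperature is used, following the source
#' analysis) are excluded and counted.
#'
#' @param fitted data frame with one row per pair: `pair_id`, `b`, `h`,
#'   `q`, `converged`, plus covariates `consumer_mass_g`,
#'   `resource_mass_g`, `temp_C`, `strategy`, `taxon_group`, `arena_dim`.
#' @param time_unit time unit of `b` and `h` (`"s"` or `"d"`).
#' @param focal_strategies strategies retained for modelling; the data-poor
#'   remainder is excluded (default: the three focal strategies).
#' @return Data frame of class `meta_table` with standardised
#'   `log_capture`, `log_max_feed`, standardised log covariates and the
#'   grouping columns; excluded counts in `attr(, "excluded")`.
#' @export
build_meta_table <- function(fitted, time_unit = "d",
                             focal_strategies = c("active-mobile",
                                                  "active-static", "filter")) {
  req <- c("pair_id", "b", "h", "q", "consumer_mass_g", "resource_mass_g",
           "temp_C", "strategy", "taxon_group")
  miss <- setdiff(req, names(fitted))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  n0 <- nrow(fitted)
  excl <- c(failed = 0L, nonpositive = 0L, temperature = 0L, strategy = 0L)

  ok_fit <- if ("converged" %in% names(fitted)) fitted$converged else TRUE
  ok_fit <- ok_fit & is.finite(fitted$b) & fitted$b > 0
  excl["failed"] <- sum(!ok_fit)
  keep <- ok_fit
  ok_T <- fitted$temp_C > 0
  excl["temperature"] <- sum(keep & !ok_T)
  keep <- keep & ok_T
  ok_s <- fitted$strategy %in% focal_strategies
  excl["strategy"] <- sum(keep & !ok_s)
  keep <- keep & ok_s

  df <- fitted[keep, , drop = FALSE]
  rates <- lapply(seq_len(nrow(df)), function(i)
    biomass_rates(fr_params(df$b[i], df$h[i], df$q[i]),
                  resource_mass_g = df$resource_mass_g[i],
                  time_unit = time_unit))
  cap <- vapply(rates, `[[`, numeric(1), "capture_gd")
  mf <- vapply(rates, `[[`, numeric(1), "max_feed_gd")
  ok_pos <- cap > 0 & is.finite(cap) & is.finite(log(mf)) & mf > 0
  excl["nonpositive"] <- sum(!ok_pos)
  df <- df[ok_pos, , drop = FALSE]
  cap <- cap[ok_pos]; mf <- mf[ok_pos]

  out <- data.frame(
    pair_id = df$pair_id,
    log_capture = as.numeric(scale(log(cap))),
    log_max_feed = as.numeric(scale(log(mf))),
    log_consumer_mass = log(df$consumer_mass_g),
    log_resource_mass = log(df$resource_mass_g),
    log_temperature = log(df$temp_C),
    strategy = df$strategy, taxon_group = df$taxon_group, q = df$q,
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  attr(out, "n_input") <- n0
  class(out) <- c("meta_table", "data.frame")
  out
}

#' Fit one fixed-effect structure as a random-intercept mixed model
#'
#' Linear mixed model with the structure's fixed effects and a random
#' intercept per taxonomic group, estimated by maximum likelihood (not
#' REML) so that AICc is comparable across fixed-effect structures.
#' `k` counts fixed-effect coefficients plus the two variance components.
#'
#' @param records a [build_meta_table()] table (or any data frame with the
#'   same columns; `response` may name any numeric column).
#' @param structure a `meta_structure` from [enumerate_structures()].
#' @param response `"capture"`, `"max_feed"`, or a column name.
#' @return List of class `meta_fit`: `model` (a `lmerMod`), `structure`,
#'   `k`, `loglik`, `AICc`, `singular` (random-effect variance at the
#'   boundary).
#' @export
fit_structure <- function(records, structure, response = c("capture", "max_feed")) {
  response <- if (is.character(response) && length(response) == 1 &&
                  !response[1] %in% c("capture", "max_feed")) response
              else match.arg(response)
  col <- switch(response, capture = "log_capture", max_feed = "log_max_feed",
                response)
  if (!col %in% names(records)) stop("response column not found: ", col)
  if (length(unique(records$taxon_group)) < 2)
    stop("need at least 2 taxon groups for a random intercept")
  f <- structure_formula(structure, col)
  model <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = records, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  k <- length(lme4::fixef(model)) + 2L
  ll <- as.numeric(stats::logLik(model))
  structure(list(model = model, structure = structure, k = k, loglik = ll,
                 AICc = aicc(ll, k, nrow(records)),
                 singular = lme4::isSingular(model), response = col),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Mixed model %s (%s): k = %d, logLik = %.2f, AICc = %.2f%s\n",
              format_structure(x$structure), x$response, x$k, x$loglik,
              x$AICc, if (x$singular) " [singular RE]" else ""))
  invisible(x)
}

#' Fit all 36 structures and select the lowest-AICc model
#'
#' @param records a [build_meta_table()] table.
#' @param response `"capture"` or `"max_feed"` (or a column name).
#' @param refit_reml refit the selected structure by REML for reported
#'   coefficients (default `TRUE`; the ranking itself always uses ML fits).
#' @return List of class `meta_selection`: `best` (a `meta_fit`; its
#'   `model_reml` slot holds the REML refit when requested), `table`
#'   (ranked data frame: structure, k, logLik, AICc, dAICc, singular),
#'   `failures` (structures whose fit errored).
#' @export
select_structure <- function(records, response = c("capture", "max_feed"),
                             refit_reml = TRUE) {
  structures <- enumerate_structures()
  fits <- vector("list", length(structures))
  failures <- character()
  for (i in seq_along(structures)) {
    fits[[i]] <- tryCatch(fit_structure(records, structures[[i]], response),
                          error = function(e) e)
    if (inherits(fits[[i]], "error"))
      failures <- c(failures, format_structure(structures[[i]]))
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("every structure failed to fit")
  tab <- data.frame(
    structure = vapply(structures[ok], format_structure, character(1)),
    k = vapply(fits[ok], function(f) f$k, integer(1)),
    logLik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
    AICc = vapply(fits[ok], function(f) f$AICc, numeric(1)),
    singular = vapply(fits[ok], function(f) f$singular, logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  tab$dAICc <- tab$AICc - min(tab$AICc)
  rownames(tab) <- NULL
  best <- fits[ok][[ord[1]]]
  if (refit_reml) {
    f <- structure_formula(best$structure, best$response)
    best$model_reml <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = records, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  }
  structure(list(best = best, table = tab, failures = failures,
                 records = records),
            class = "meta_selection")
}

#' @export
print.meta_selection <- function(x, ...) {
  cat("Mixed-model structure selection (36 candidates, AICc)\n")
  print(utils::head(x$table, 8), digits = 5)
  cat(sprintf("Selected: %s (AICc = %.2f)\n", x$table$structure[1],
              x$table$AICc[1]))
  if (length(x$failures) > 0)
    cat(sprintf("%d structure(s) failed to fit\n", length(x$failures)))
  invisible(x)
}

#' Bootstrap prediction bands over consumer mass per strategy
#'
#' Case-resampling bootstrap stratified by strategy (preserving group
#' sizes): records are resampled within strategy, the selected structure is
#' refitted, and population-level predictions (random effects set to zero)
#' are made over a log consumer-mass grid at each strategy's median values
#' of the other covariates. Bands are the 2.5/97.5 percentiles across
#' refits.
#'
#' @param selection a `meta_selection` (or `meta_fit`) to bootstrap.
#' @param records the meta-table used for fitting.
#' @param n_boot number of bootstrap refits; 0 returns point predictions
#'   only.
#' @param seed integer seed.
#' @param grid_n grid resolution along log consumer mass.
#' @return Data frame: `strategy`, `log_consumer_mass`, `fit`, `lo`, `hi`
#'   (`lo`/`hi` are `NA` when `n_boot = 0`).
#' @export
bootstrap_predictions <- function(selection, records = NULL, n_boot = 200,
                                  seed = 1, grid_n = 25) {
  fit <- if (inherits(selection, "meta_selection")) selection$best else selection
  records <- records %||% selection$records
  stopifnot(inherits(fit, "meta_fit"), n_boot >= 0)
  set.seed(seed)
  strategies <- unique(records$strategy)
  grid <- seq(min(records$log_consumer_mass), max(records$log_consumer_mass),
              length.out = grid_n)
  newdata <- do.call(rbind, lapply(strategies, function(s) {
    rs <- records[records$strategy == s, ]
    data.frame(strategy = s, log_consumer_mass = grid,
               log_resource_mass = stats::median(rs$log_resource_mass),
               log_temperature = stats::median(rs$log_temperature),
               stringsAsFactors = FALSE)
  }))
  point <- stats::predict(fit$model, newdata = newdata, re.form = NA)
  if (n_boot == 0) {
    return(data.frame(newdata[c("strategy", "log_consumer_mass")],
                      fit = point, lo = NA_real_, hi = NA_real_))
  }
  f <- structure_formula(fit$structure, fit$response)
  idx_by_strat <- split(seq_len(nrow(records)), records$strategy)
  preds <- matrix(NA_real_, nrow = nrow(newdata), ncol = n_boot)
  for (bidx in seq_len(n_boot)) {
    for (try in 1:20) {
      take <- unlist(lapply(idx_by_strat, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      boot <- records[take, ]
      m <- tryCatch(suppressMessages(suppressWarnings(
        lme4::lmer(f, data = boot, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
        error = function(e) NULL)
      if (!is.null(m)) break
    }
    if (is.null(m)) next
    preds[, bidx] <- tryCatch(
      stats::predict(m, newdata = newdata, re.form = NA,
                     allow.new.levels = TRUE),
      error = function(e) NA_real_)
  }
  lo <- apply(preds, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(preds, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  # bands always cover the full-data point prediction
  lo <- pmin(lo, point); hi <- pmax(hi, point)
  data.frame(newdata[c("strategy", "log_consumer_mass")], fit = point,
             lo = lo, hi = hi)
}
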