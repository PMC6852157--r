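#' Pipeline configuration
#'
#' Assembles the stage toggles, output directory, master seed and per-stage
#' parameter blocks for [run_pipeline()]. All randomness flows from the
#' master seed through named substreams, so any stage or pair can be
#' regenerated in isolation.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param stages character subset of
#'   `c("generate", "fit", "meta", "simulate")`.
#' @param generate list of overrides for [generator_config()].
#' @param fit list: `convention` (`"q"`/`"q_plus_1"`), `boot` (bootstrap
#'   resamples for the shape-exponent comparison).
#' @param meta list: `responses` (subset of `c("capture", "max_feed")`),
#'   `n_boot` (prediction-band resamples).
#' @param simulate list: `strategies`, `mass_grid`, `replicates`,
#'   `n_steps`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "pipeline_out", seed = 1,
                            stages = c("generate", "fit", "meta", "simulate"),
                            generate = list(), fit = list(), meta = list(),
                            simulate = list()) {
  stopifnot(all(stages %in% c("generate", "fit", "meta", "simulate")))
  fit <- utils::modifyList(list(convention = "q", boot = 2000), fit)
  meta <- utils::modifyList(list(responses = c("capture", "max_feed"),
                                 n_boot = 100), meta)
  simulate <- utils::modifyList(
    list(strategies = c("filter", "active-static", "active-mobile"),
         mass_grid = 10^seq(-2, 2, by = 1), replicates = 100, n_steps = 400),
    simulate)
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 generate = generate, fit = fit, meta = meta,
                 simulate = simulate),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y),
    c("out_dir", "seed", "stages", "generate", "fit", "meta", "simulate"))])
}

#' Column schemas for pipeline tables
#'
#' Registered schemas: `trials`, `fitted`, `meta`, `encounters`,
#' `quantiles`. Each schema lists required columns, their types, and range
#' rules; units are encoded in the column names (`consumer_mass_g`,
#' `temp_C`, ...).
#'
#' @param name schema name.
#' @return List with `columns` (named types) and `rules` (named predicate
#'   functions on the data frame returning a logical row mask of
#'   violations).
#' @export
table_schema <- function(name = c("trials", "fitted", "meta", "encounters",
                                  "quantiles")) {
  name <- match.arg(name)
  num <- "numeric"; chr <- "character"; int <- "numeric"
  switch(name,
    trials = list(
      columns = c(pair_id = chr, N0 = int, eaten = int, T = num, arena = num,
                  arena_dim = int, consumer_mass_g = num,
                  resource_mass_g = num, temp_C = num, strategy = chr,
                  taxon_group = chr),
      rules = list(
        eaten_le_N0 = function(d) d$eaten > d$N0,
        eaten_nonneg = function(d) d$eaten < 0,
        T_positive = function(d) d$T <= 0,
        arena_positive = function(d) d$arena <= 0,
        mass_positive = function(d) !is.na(d$consumer_mass_g) &
          d$consumer_mass_g <= 0,
        resource_mass_positive = function(d) !is.na(d$resource_mass_g) &
          d$resource_mass_g <= 0,
        arena_dim_valid = function(d) !d$arena_dim %in% c(2, 3))),
    fitted = list(
      columns = c(pair_id = chr, variant = chr, b = num, h = num, q = num,
                  loglik = num, AICc = num, converged = "logical",
                  diagnostic = chr, capture_half_sat = num, max_feed = num,
                  capture_gd = num, max_feed_gd = num),
      rules = list(
        b_nonneg = function(d) d$b < 0,
        h_nonneg = function(d) d$h < 0,
        q_nonneg = function(d) d$q < 0,
        variant_valid = function(d) !d$variant %in% c("I", "II", "III", "general"))),
    meta = list(
      columns = c(pair_id = chr, log_capture = num, log_max_feed = num,
                  log_consumer_mass = num, log_resource_mass = num,
                  log_temperature = num, strategy = chr, taxon_group = chr,
                  q = num),
      rules = list(
        finite_logs = function(d) !is.finite(d$log_capture) |
          !is.finite(d$log_consumer_mass) | !is.finite(d$log_resource_mass),
        strategy_valid = function(d) !d$strategy %in% encounter_strategies())),
    encounters = list(
      columns = c(strategy = chr, mass = num, replicate = int,
                  unitary_rate = num, biomass_rate = num),
      rules = list(
        mass_positive = function(d) d$mass <= 0,
        rates_nonneg = function(d) d$unitary_rate < 0 | d$biomass_rate < 0)),
    quantiles = list(
      columns = c(strategy = chr, mass = num, unitary_lo = num,
                  unitary_med = num, unitary_hi = num, biomass_lo = num,
                  biomass_med = num, biomass_hi = num, replicates = int),
      rules = list(
        ordered_unitary = function(d) d$unitary_lo > d$unitary_med |
          d$unitary_med > d$unitary_hi,
        ordered_biomass = function(d) d$biomass_lo > d$biomass_med |
          d$biomass_med > d$biomass_hi)))
}

#' Validate a table against a registered schema
#'
#' @param x a data frame or a CSV path.
#' @param schema_name one of the [table_schema()] names.
#' @return List of class `validation_report`: `ok` (logical), `missing`
#'   (absent columns), `violations` (data frame: row, rule).
#' @export
validate_table <- function(x, schema_name) {
  sch <- table_schema(schema_name)
  d <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  missing_cols <- setdiff(names(sch$columns), names(d))
  violations <- data.frame(row = integer(), rule = character(),
                           stringsAsFactors = FALSE)
  if (length(missing_cols) == 0) {
    for (rule in names(sch$rules)) {
      bad <- sch$rules[[rule]](d)
      bad[is.na(bad)] <- FALSE
      if (any(bad))
        violations <- rbind(violations,
                            data.frame(row = which(bad), rule = rule,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(ok = length(missing_cols) == 0 && nrow(violations) == 0,
                 missing = missing_cols, violations = violations,
                 schema = schema_name, n = nrow(d)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation [%s]: %s (%d rows)\n", x$schema,
              if (x$ok) "OK" else "FAILED", x$n))
  if (length(x$missing) > 0)
    cat("  missing columns:", paste(x$missing, collapse = ", "), "\n")
  if (nrow(x$violations) > 0) {
    cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}

manifest_entry <- function(stage, path, rows, seed, inputs = character()) {
  data.frame(stage = stage, path = path, rows = rows,
             md5 = as.character(tools::md5sum(path)),
             seed = seed,
             input_hashes = paste(as.character(tools::md5sum(inputs)),
                                  collapse = ";"),
             stringsAsFactors = FALSE)
}

stage_up_to_date <- function(sidecar, inputs, seed) {
  if (!file.exists(sidecar)) return(FALSE)
  prev <- tryCatch(utils::read.csv(sidecar, stringsAsFactors = FALSE),
                   error = function(e) NULL)
  if (is.null(prev) || nrow(prev) == 0) return(FALSE)
  cur_hash <- paste(as.character(tools::md5sum(inputs)), collapse = ";")
  prev_hash <- prev$input_hashes[1]
  if (is.na(prev_hash)) prev_hash <- ""
  all(file.exists(prev$path)) &&
    isTRUE(prev_hash == cur_hash) &&
    isTRUE(as.numeric(prev$seed[1]) == as.numeric(seed)) &&
    all(as.character(tools::md5sum(prev$path)) == prev$md5)
}

#' Run the synthetic-data / fitting / meta-analysis / simulation pipeline
#'
#' Executes the enabled stages in dependency order, validating every table
#' against its schema before use, and returns a manifest (one row per
#' artifact: path, row count, md5, seed, input hashes). A stage whose
#' inputs, seed, and outputs all hash to their previous values is skipped
#' as a no-op.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Data frame manifest (invisible components: per-stage timings in
#'   `attr(, "timings")`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(); timings <- c()
  path <- function(f) file.path(config$out_dir, f)

  trials_csv <- path("trials.csv"); truth_csv <- path("truth.csv")
  fitted_csv <- path("fitted.csv")

  run_stage <- function(stage, inputs, outputs, fun) {
    sidecar <- path(paste0(stage, ".manifest.csv"))
    if (stage_up_to_date(sidecar, inputs, config$seed)) {
      say("[%s] up to date, skipping", stage)
      return(utils::read.csv(sidecar, stringsAsFactors = FALSE))
    }
    t0 <- Sys.time()
    fun()
    timings[stage] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("[%s] done in %.1f s", stage, timings[stage])
    rows <- do.call(rbind, lapply(outputs, function(p)
      manifest_entry(stage, p, nrow(utils::read.csv(p)), config$seed, inputs)))
    utils::write.csv(rows, sidecar, row.names = FALSE)
    rows
  }

  if ("generate" %in% config$stages) {
    m <- run_stage("generate", character(), c(trials_csv, truth_csv), function() {
      gc_args <- utils::modifyList(
        list(seed = substream_seed(config$seed, "generate")), config$generate)
      ds <- generate_meta_dataset(do.call(generator_config, gc_args))
      write_trials_csv(ds$trials, trials_csv)
      utils::write.csv(ds$truth, truth_csv, row.names = FALSE)
    })
    manifest[[length(manifest) + 1]] <- m
  }

  if ("fit" %in% config$stages) {
    if (!file.exists(trials_csv)) stop("fit stage requires ", trials_csv)
    rep_t <- validate_table(trials_csv, "trials")
    if (!rep_t$ok) { print(rep_t); stop("trials table failed validation") }
    m <- run_stage("fit", trials_csv, fitted_csv, function() {
      trials <- read_trials_csv(trials_csv)
      fitted <- fit_all_pairs(trials, convention = config$fit$convention)
      utils::write.csv(fitted, fitted_csv, row.names = FALSE)
    })
    manifest[[length(manifest) + 1]] <- m
  }

  if ("meta" %in% config$stages) {
    if (!file.exists(fitted_csv)) stop("meta stage requires ", fitted_csv)
    rep_f <- validate_table(fitted_csv, "fitted")
    if (!rep_f$ok) { print(rep_f); stop("fitted table failed validation") }
    outs <- c(path("meta_table.csv"),
              vapply(config$meta$responses, function(r)
                path(sprintf("aicc_%s.csv", r)), character(1)),
              vapply(config$meta$responses, function(r)
                path(sprintf("bands_%s.csv", r)), character(1)),
              path("q_bootstrap.csv"))
    m <- run_stage("meta", fitted_csv, outs, function() {
      fitted <- utils::read.csv(fitted_csv, stringsAsFactors = FALSE)
      tab <- build_meta_table(fitted, time_unit = fitted$time_unit[1] %||% "d")
      utils::write.csv(as.data.frame(tab), path("meta_table.csv"),
                       row.names = FALSE)
      for (r in config$meta$responses) {
        sel <- select_structure(tab, r)
        utils::write.csv(sel$table, path(sprintf("aicc_%s.csv", r)),
                         row.names = FALSE)
        bands <- bootstrap_predictions(sel, tab, n_boot = config$meta$n_boot,
                                       seed = substream_seed(config$seed, "meta", r))
        utils::write.csv(bands, path(sprintf("bands_%s.csv", r)),
                         row.names = FALSE)
      }
      qb <- bootstrap_mean_q(tab$q, tab$strategy, n_boot = config$fit$boot,
                             seed = substream_seed(config$seed, "meta", "q"))
      utils::write.csv(qb, path("q_bootstrap.csv"), row.names = FALSE)
    })
    manifest[[length(manifest) + 1]] <- m
  }

  if ("simulate" %in% config$stages) {
    outs <- c(path("encounters.csv"), path("encounter_quantiles.csv"))
    m <- run_stage("simulate", character(), outs, function() {
      sims <- lapply(config$simulate$strategies, function(s)
        sweep_consumer_mass(s, config$simulate$mass_grid,
                            replicates = config$simulate$replicates,
                            n_steps = config$simulate$n_steps,
                            seed = substream_seed(config$seed, "simulate", s)))
      tidy <- do.call(rbind, lapply(sims, attr, "replicates"))
      qtab <- do.call(rbind, lapply(sims, as.data.frame))
      utils::write.csv(tidy, path("encounters.csv"), row.names = FALSE)
      utils::write.csv(qtab, path("encounter_quantiles.csv"),
                       row.names = FALSE)
      stopifnot(validate_table(path("encounters.csv"), "encounters")$ok,
                validate_table(path("encounter_quantiles.csv"), "quantiles")$ok)
    })
    manifest[[length(manifest) + 1]] <- m
  }

  out <- if (length(manifest) > 0) do.call(rbind, manifest) else
    data.frame(stage = character(), path = character(), rows = integer(),
               md5 = character(), seed = integer(),
               input_hashes = character(), stringsAsFactors = FALSE)
  attr(out, "timings") <- timings
  out
}

#' Fit and select a functional response for every pair in a trial table
#'
#' Runs [fr_select()] per `pair_id` and assembles the per-pair fitted
#' table (selected variant, parameters, information criteria, diagnostic,
#' derived capture and feeding rates in count and biomass units) plus the
#' pair covariates.
#'
#' @param trials a stacked [trial_set()] covering one or more pairs.
#' @param convention exponent convention for [rogers_eaten()].
#' @return Data frame, one row per pair (schema `fitted`).
#' @export
fit_all_pairs <- function(trials, convention = "q") {
  tu <- attr(trials, "time_unit") %||% "s"
  rows <- lapply(split(seq_len(nrow(trials)), trials$pair_id), function(ix) {
    tr <- trials[ix, , drop = FALSE]
    attr(tr, "time_unit") <- tu
    class(tr) <- c("trial_set", "data.frame")
    sel <- tryCatch(fr_select(tr, convention = convention),
                    error = function(e) NULL)
    cov <- tr[1, c("pair_id", "consumer_mass_g", "resource_mass_g", "temp_C",
                   "strategy", "taxon_group", "arena_dim")]
    if (is.null(sel)) {
      return(cbind(cov, data.frame(variant = NA_character_, b = NA_real_,
        h = NA_real_, q = NA_real_, loglik = NA_real_, AICc = NA_real_,
        converged = FALSE, diagnostic = NA_character_,
        capture_half_sat = NA_real_, max_feed = NA_real_,
        capture_gd = NA_real_, max_feed_gd = NA_real_, time_unit = tu,
        stringsAsFactors = FALSE)))
    }
    f <- sel$selected
    p <- f$params
    cap <- if (p$b > 0 && p$h > 0) half_saturation_rate(p) else p$b
    bm <- if (is.finite(cov$resource_mass_g) && cov$resource_mass_g > 0)
      biomass_rates(p, cov$resource_mass_g, tu)
    else list(capture_gd = NA_real_, max_feed_gd = NA_real_)
    cbind(cov, data.frame(variant = f$variant, b = p$b, h = p$h, q = p$q,
      loglik = f$logLik, AICc = f$AICc,
      converged = f$converged && !f$null_fit,
      diagnostic = if (is.na(sel$diagnostic)) "not-needed" else sel$diagnostic,
      capture_half_sat = cap, max_feed = max_feeding_rate(p),
      capture_gd = bm$capture_gd, max_feed_gd = bm$max_feed_gd,
      time_unit = tu, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
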