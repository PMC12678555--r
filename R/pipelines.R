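#' Pipeline configuration
#'
#' Builds and validates a run configuration from a YAML file or an in-memory
#' list. Recognised top-level fields: `seed`, `output_dir`, `mcmc` (chains,
#' iterations, burn_in, thin), `data` (input CSV paths, or `simulate: true`
#' with an optional `truth` block of generator overrides), and `model`
#' (spec overrides such as `standardize`, `two_component`, `lambda`).
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated list with class `run_config` and a `config_hash`
#'   attribute.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "."
  config$mcmc <- config$mcmc %||% list()
  config$model <- config$model %||% list()
  config$data <- config$data %||% list(simulate = TRUE)
  attr(config, "config_hash") <- rlang::hash(config)
  class(config) <- "run_config"
  config
}

config_mcmc <- function(config) {
  m <- config$mcmc
  mcmc_config(
    chains = m$chains %||% 5, iterations = m$iterations %||% 201000,
    burn_in = m$burn_in %||% 1000, thin = m$thin %||% 100,
    seed = config$seed
  )
}

write_run_metadata <- function(config, dir, stages) {
  meta <- list(
    config_hash = attr(config, "config_hash"),
    seed = config$seed,
    stages = stages,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("beartroph")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

write_draws_csv <- function(draws, path) {
  readr::write_csv(draws, path)
}

#' Run the macroecological pipeline end to end
#'
#' Reads (or simulates) diet data, validates it, fits the macroecological
#' model and writes: the posterior draw table, the fixed-effect summary, the
#' per-dataset imputed animal-prey shares, partial-residual tables for NPP
#' and GSL, a diagnostics JSON and a run-metadata JSON.
#'
#' @param config A [run_config()], YAML path or list.
#' @return The `macro_fit`, invisibly; artifacts are written to
#'   `config$output_dir`.
#' @export
run_macro_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()

  categories <- if (!is.null(config$data$categories)) {
    read_categories(config$data$categories)
  } else default_diet_categories()

  if (isTRUE(config$data$simulate)) {
    truth_args <- config$data$truth %||% list()
    truth_args$seed <- config$seed
    truth <- do.call(macro_truth, truth_args)
    sim <- simulate_macro(truth, categories = categories)
    data <- sim$data
    stages$data <- list(source = "simulated", n_datasets = truth$n_obs)
  } else {
    path <- config$data$diet
    if (is.null(path) || !file.exists(path)) {
      stop("macro pipeline: diet table not found: ",
           path %||% "<missing 'data$diet'>", call. = FALSE)
    }
    data <- read_diet_table(path, categories = categories)
    stages$data <- list(source = path,
                        n_datasets = length(unique(data$dataset_id)))
  }

  spec <- macro_model_spec(
    standardize = config$model$standardize %||% TRUE,
    two_component = config$model$two_component %||% FALSE
  )
  fit <- fit_macro(data, spec = spec, mcmc = config_mcmc(config),
                   categories = categories)
  stages$fit <- list(n_draws = fit$mcmc$chains * kept_per_chain(fit$mcmc))

  write_draws_csv(fit$draws, file.path(config$output_dir, "macro_draws.csv"))
  readr::write_csv(tidy(fit), file.path(config$output_dir, "macro_summary.csv"))
  if (!is.null(fit$imputed)) {
    readr::write_csv(fit$imputed,
                     file.path(config$output_dir, "macro_imputed.csv"))
  }
  for (pred in intersect(c("npp_s", "gsl_s"), colnames(fit$design))) {
    pr <- partial_residuals(fit, pred)
    readr::write_csv(pr$points, file.path(
      config$output_dir, paste0("macro_partial_", pred, ".csv")))
  }
  diag <- fit$diagnostics
  diag$vif <- as.list(stats::setNames(diag$vif$vif, diag$vif$predictor))
  jsonlite::write_json(diag, file.path(config$output_dir,
                                       "macro_diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_metadata(config, config$output_dir, stages)
  invisible(fit)
}

#' Read a category correction-factor table
#' @param path CSV with columns category, trophic_class, c_D, c_E.
#' @return Validated tibble.
#' @export
read_categories <- function(path) {
  validate_categories(readr::read_csv(path, show_col_types = FALSE))
}

#' Run the paleoecological pipeline end to end
#'
#' Reads (or simulates) isotope samples and reference tables, applies
#' collagen QC and time-bin assignment, runs the marine screen, fits the
#' joint paleoecological model and writes: QC report, screened-sample table,
#' posterior draws, per-period trophic-position table, regression summary,
#' diagnostics JSON and run metadata.
#'
#' @param config A [run_config()], YAML path or list.
#' @return The `paleo_fit`, invisibly.
#' @export
run_paleo_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()

  bins <- if (!is.null(config$data$bins)) {
    b <- readr::read_csv(config$data$bins, show_col_types = FALSE)
    ord <- b[order(b$lower), ]
    if (any(utils::head(ord$upper, -1) > utils::tail(ord$lower, -1) + 1e-12)) {
      stop("configuration error: overlapping time bins", call. = FALSE)
    }
    b
  } else default_time_bins()

  if (isTRUE(config$data$simulate)) {
    truth_args <- config$data$truth %||% list()
    truth_args$seed <- config$seed
    truth <- do.call(paleo_truth, truth_args)
    sim <- simulate_paleo(truth, bins = bins)
    samples <- sim$samples; refs <- sim$refs; period_env <- sim$period_env
    stages$data <- list(source = "simulated", n_samples = nrow(samples))
  } else {
    paths <- config$data
    for (p in c("samples", "tooth_bone", "elevation", "tdf", "period_env")) {
      if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
        stop("paleo pipeline: input not found: ", p, " = ",
             paths[[p]] %||% "<missing>", call. = FALSE)
      }
    }
    samples <- readr::read_csv(paths$samples, show_col_types = FALSE)
    refs <- list(
      tooth_bone = readr::read_csv(paths$tooth_bone, show_col_types = FALSE),
      elevation = readr::read_csv(paths$elevation, show_col_types = FALSE),
      tdf = readr::read_csv(paths$tdf, show_col_types = FALSE)
    )
    if (!is.null(paths$marine)) {
      refs$marine <- readr::read_csv(paths$marine, show_col_types = FALSE)
    }
    period_env <- readr::read_csv(paths$period_env, show_col_types = FALSE)
    stages$data <- list(source = paths$samples, n_samples = nrow(samples))
  }

  samples <- validate_isotope_table(samples, bins = bins)
  readr::write_csv(
    samples[, c("sample_id", "qc_pass", "qc_reasons", "period")],
    file.path(config$output_dir, "qc_report.csv"))
  stages$qc <- list(n = nrow(samples), n_pass = sum(samples$qc_pass),
                    n_binned = sum(!is.na(samples$period)))

  if (!is.null(refs$marine)) {
    scr <- marine_screen(dplyr::filter(samples, .data$taxon == "brown_bear"),
                         refs$marine)
    readr::write_csv(scr$samples[, c("sample_id", "marine_flag")],
                     file.path(config$output_dir, "marine_screen.csv"))
    stages$marine_screen <- as.list(scr$summary)
  }

  spec <- paleo_model_spec(lambda = config$model$lambda %||% 2,
                           standardize = config$model$standardize %||% TRUE)
  fit <- fit_paleo(samples, refs, period_env, spec = spec,
                   mcmc = config_mcmc(config))
  stages$fit <- list(
    n_draws = fit$mcmc$chains * kept_per_chain(fit$mcmc),
    identified_periods = sum(fit$periods$identified))

  write_draws_csv(fit$draws, file.path(config$output_dir, "paleo_draws.csv"))
  readr::write_csv(fit$periods,
                   file.path(config$output_dir, "paleo_periods.csv"))
  readr::write_csv(tidy(fit, "regression"),
                   file.path(config$output_dir, "paleo_regression.csv"))
  diag <- fit$diagnostics
  diag$vif <- as.list(stats::setNames(diag$vif$vif, diag$vif$predictor))
  jsonlite::write_json(diag, file.path(config$output_dir,
                                       "paleo_diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_metadata(config, config$output_dir, stages)
  invisible(fit)
}
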