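#' Geometric-mean regression of log relative volume on log relative frequency
#'
#' Symmetric line fit appropriate when both variables carry measurement
#' error: the slope is \eqn{\mathrm{sign}(\sigma_{FV})\sqrt{\sigma^2_V /
#' \sigma^2_F}} and the intercept \eqn{\bar V - \bar F \cdot} slope, both on
#' the (natural) log scale. Items reported absent (F = 0 or V = 0) are
#' excluded, as the log is undefined there.
#'
#' @param data Item-level data frame with columns `dataset_id`, `F`, `V`.
#' @param min_items Minimum paired positive observations per dataset (3).
#' @return A tibble with one row per dataset: `dataset_id`, `intercept`,
#'   `slope`, `n_items`.
#' @export
gm_regression <- function(data, min_items = 3) {
  stopifnot(all(c("dataset_id", "F", "V") %in% names(data)))
  data |>
    dplyr::filter(!is.na(.data$F), !is.na(.data$V),
                  .data$F > 0, .data$V > 0) |>
    dplyr::group_by(dataset_id = .data$dataset_id) |>
    dplyr::summarise(
      fit = list(gmr_fit(log(.data$F), log(.data$V), min_items = min_items)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("fit")
}

#' Geometric-mean line for one pair of numeric vectors
#'
#' @param x,y Numeric vectors (already on the scale to be fitted, e.g. logs).
#' @param min_items Minimum number of pairs.
#' @return List with `intercept`, `slope`, `n_items`.
#' @export
gmr_fit <- function(x, y, min_items = 3) {
  stopifnot(length(x) == length(y))
  if (length(x) < min_items) {
    stop("geometric mean regression needs at least ", min_items,
         " paired observations", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) {
    stop("degenerate regression: zero variance in x or y", call. = FALSE)
  }
  slope <- sign(stats::cov(x, y)) * sqrt(vy / vx)
  list(intercept = mean(y) - mean(x) * slope, slope = slope,
       n_items = length(x))
}

#' Split predictors into species-level and within-species components
#'
#' Group-mean centering used to separate a species-occurrence effect (do
#' species with a given trophic position occur where a predictor is high?)
#' from a population effect (do populations shift their trophic position with
#' the predictor?). Each predictor is replaced by the species mean
#' (`<var>_between`) and the within-species deviation (`<var>_within`);
#' deviations sum to zero within each species and `between + within`
#' reconstructs the original values exactly.
#'
#' @param data Data frame containing the predictors and a grouping column.
#' @param vars Character vector of predictor column names.
#' @param group Grouping column name (default `"species"`).
#' @return The input tibble with two new columns per predictor. Species
#'   represented by a single observation get deviation 0 (with a message).
#' @export
two_component_centering <- function(data, vars = c("npp_s", "gsl_s"),
                                    group = "species") {
  stopifnot(group %in% names(data), all(vars %in% names(data)))
  singletons <- data |>
    dplyr::count(.data[[group]]) |>
    dplyr::filter(.data$n == 1)
  if (nrow(singletons) > 0) {
    message("group(s) with a single observation get within-component 0: ",
            paste(singletons[[group]], collapse = ", "))
  }
  out <- data
  for (v in vars) {
    gm <- stats::ave(out[[v]], out[[group]])
    out[[paste0(v, "_between")]] <- gm
    out[[paste0(v, "_within")]] <- out[[v]] - gm
  }
  tibble::as_tibble(out)
}

#' Specification of the macroecological trophic-position model
#'
#' @param standardize Standardise the continuous predictors (log10 NPP and
#'   GSL) to zero mean and unit variance before fitting; coefficient scales
#'   then match the partial-residual plots.
#' @param two_component Split NPP and GSL into species-mean and
#'   within-species components via [two_component_centering()].
#' @param impute Include the hierarchical imputation layer for datasets
#'   without relative volumes.
#' @param n_compress Number of observations `n` used in the probit
#'   compression; default (`NULL`) is the number of datasets being fitted.
#' @param lambda_zeros Constant of the Poisson-zeros device linking derived
#'   probit responses of imputed datasets to the regression likelihood.
#' @return A `macro_model_spec` list.
#' @export
macro_model_spec <- function(standardize = TRUE, two_component = FALSE,
                             impute = TRUE, n_compress = NULL,
                             lambda_zeros = 1e5) {
  structure(list(standardize = standardize, two_component = two_component,
                 impute = impute, n_compress = n_compress,
                 lambda_zeros = lambda_zeros),
            class = "macro_model_spec")
}

#' Build the fixed-effect design for the macro model
#' @keywords internal
macro_design <- function(meta, spec) {
  meta$npp_s <- log10(meta$npp)
  meta$gsl_s <- as.numeric(meta$gsl)
  if (spec$standardize) {
    meta$npp_s <- as.numeric(scale(meta$npp_s))
    meta$gsl_s <- as.numeric(scale(meta$gsl_s))
  }
  meta$co_occurrence <- factor(meta$co_occurrence,
                               levels = c("none", "subordinate", "dominant"))
  if (spec$two_component) {
    meta <- two_component_centering(meta, vars = c("npp_s", "gsl_s"))
    X <- stats::model.matrix(
      ~ npp_s_between + npp_s_within + gsl_s_between + gsl_s_within +
        co_occurrence, data = meta)
  } else {
    X <- stats::model.matrix(~ npp_s + gsl_s + co_occurrence, data = meta)
  }
  colnames(X) <- sub("^co_occurrence", "", colnames(X))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient fixed-effect design", call. = FALSE)
  }
  X
}

macro_model_string <- function(has_missing) {
  imput <- if (has_missing) "
  for (j in 1:Jmis) { b_mis[j, 1:2] ~ dmnorm(mu_b[], Omega_b[,]) }
  for (i in 1:Imis) {
    muLV[i] <- b_mis[mis_ds[i], 1] + b_mis[mis_ds[i], 2] * logF[i]
    logV[i] ~ dnorm(muLV[i], tau_V)
    ev[i] <- w[i] * exp(logV[i])
    eva[i] <- ev[i] * anim[i]
  }
  for (j in 1:Jmis) {
    Pm[j] <- sum(eva[ist[j]:ien[j]]) / sum(ev[ist[j]:ien[j]])
    ym[j] <- qnorm((Pm[j] * (ncomp - 1) + 0.5) / ncomp, 0, 1)
    zeros[j] ~ dpois(Cz - logdensity.norm(ym[j], mu[mis_idx[j]], tau_eps))
  }
" else ""
  paste0("
model {
  # process model: probit-scale trophic position on environment
  for (k in 1:P) { beta[k] ~ dnorm(0, 1.0E-4) }
  sig_eps ~ dt(0, 1, 2) T(0,)
  sig_gam ~ dt(0, 1, 2) T(0,)
  sig_del ~ dt(0, 1, 2) T(0,)
  tau_eps <- pow(sig_eps, -2)
  for (l in 1:L) { gamma[l] ~ dnorm(0, pow(sig_gam, -2)) }
  for (m in 1:M) { delta[m] ~ dnorm(0, pow(sig_del, -2)) }
  for (j in 1:J) {
    mu[j] <- inprod(X[j, ], beta[]) + gamma[study[j]] + delta[species[j]]
  }
  for (j in 1:Jobs) { y_obs[j] ~ dnorm(mu[obs_idx[j]], tau_eps) }

  # hierarchy of per-dataset frequency-volume lines
  for (k in 1:2) {
    mu_b[k] ~ dnorm(0, 1.0E-4)
    sig_b[k] ~ dt(0, 1, 2) T(0,)
  }
  rho_b ~ dunif(-1, 1)
  Sig_b[1, 1] <- sig_b[1] * sig_b[1]
  Sig_b[2, 2] <- sig_b[2] * sig_b[2]
  Sig_b[1, 2] <- rho_b * sig_b[1] * sig_b[2]
  Sig_b[2, 1] <- Sig_b[1, 2]
  Omega_b <- inverse(Sig_b)
  for (j in 1:Jgmr) { b_obs[j, 1:2] ~ dmnorm(mu_b[], Omega_b[,]) }
  sig_V ~ dt(0, 1, 2) T(0,)
  tau_V <- pow(sig_V, -2)
", imput, "}
")
}

#' Fit the macroecological Bayesian hierarchical model
#'
#' Joint model over two sub-models. Sub-model I: per-dataset geometric-mean
#' lines relating log relative frequency to log relative volume follow a
#' bivariate normal hierarchy; datasets without volumes get volumes imputed
#' from their observed frequencies through that hierarchy, with the
#' imputation uncertainty carried into the response. Sub-model II: the
#' animal-prey energy share, compressed and probit-transformed, is regressed
#' on log10 NPP, growing season length and co-occurrence dummies with study
#' and species random intercepts. Priors: Normal(0, variance 1e4) on
#' location parameters, half-t(df 2, scale 1) on every SD (the marginal of
#' the scaled inverse gamma / Wishart priors with s = 1, df = 2), marginal
#' uniform on the hierarchy correlation.
#'
#' @param data Item-level diet table as returned by [read_diet_table()] /
#'   [validate_diet_table()] or [simulate_macro()].
#' @param spec A [macro_model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param categories Category reference table.
#' @param monitor_imputed Also keep draws of each imputed animal-prey share.
#' @param rhat_warn Split-Rhat threshold above which a convergence warning
#'   names the offending parameters.
#' @return A `macro_fit` object with elements `draws` (long tibble),
#'   `summary`, `diagnostics`, `imputed`, `design`, `response`, `beta_draws`,
#'   `ranef_offset`, `meta`.
#' @export
fit_macro <- function(data, spec = macro_model_spec(),
                      mcmc = mcmc_config(), categories = default_diet_categories(),
                      monitor_imputed = TRUE, rhat_warn = 1.01) {
  validate_categories(categories)
  data <- validate_diet_table(data, categories = categories)

  meta <- data |>
    dplyr::distinct(.data$dataset_id, .data$study_id, .data$species,
                    .data$npp, .data$gsl, .data$co_occurrence,
                    .data$needs_imputation)
  if (anyDuplicated(meta$dataset_id)) {
    stop("dataset metadata (npp/gsl/co_occurrence/...) must be constant ",
         "within dataset_id", call. = FALSE)
  }
  J <- nrow(meta)
  if (all(meta$needs_imputation)) {
    stop("at least one dataset with observed volumes is required",
         call. = FALSE)
  }
  X <- macro_design(meta, spec)
  study <- as.integer(factor(meta$study_id))
  species <- as.integer(factor(meta$species))
  ncomp <- spec$n_compress %||% J

  # responses for datasets with observed volumes
  obs_ids <- meta$dataset_id[!meta$needs_imputation]
  e_tab <- data |>
    dplyr::filter(.data$dataset_id %in% obs_ids) |>
    dplyr::select("dataset_id", "category", "V") |>
    energy_contribution(categories = categories)
  p_obs <- e_tab |> dplyr::distinct(.data$dataset_id, .data$P)
  p_obs <- p_obs[match(obs_ids, p_obs$dataset_id), ]
  y_obs <- probit_compress(p_obs$P, n = ncomp)
  obs_idx <- match(obs_ids, meta$dataset_id)

  # geometric-mean lines for datasets where both F and V were reported
  gmr <- tryCatch(
    gm_regression(dplyr::filter(data, .data$dataset_id %in% obs_ids)),
    error = function(e) stop("geometric mean regression failed: ",
                             conditionMessage(e), call. = FALSE))
  b_obs <- cbind(gmr$intercept, gmr$slope)

  jdata <- list(
    J = J, P = ncol(X), L = max(study), M = max(species),
    X = X, study = study, species = species,
    Jobs = length(obs_idx), obs_idx = obs_idx, y_obs = as.numeric(y_obs),
    Jgmr = nrow(b_obs), b_obs = b_obs
  )

  mis_ids <- meta$dataset_id[meta$needs_imputation]
  has_missing <- spec$impute && length(mis_ids) > 0
  if (length(mis_ids) > 0 && !spec$impute) {
    stop("datasets without volumes present but imputation disabled",
         call. = FALSE)
  }
  if (has_missing) {
    items <- data |>
      dplyr::filter(.data$dataset_id %in% mis_ids, .data$F > 0) |>
      dplyr::left_join(categories, by = "category") |>
      dplyr::mutate(mis_ds = match(.data$dataset_id, mis_ids)) |>
      dplyr::arrange(.data$mis_ds)
    run_len <- as.integer(table(factor(items$mis_ds, levels = seq_along(mis_ids))))
    if (any(run_len == 0)) {
      stop("dataset(s) flagged for imputation have no items with F > 0",
           call. = FALSE)
    }
    ien <- cumsum(run_len)
    jdata <- c(jdata, list(
      Jmis = length(mis_ids), mis_idx = match(mis_ids, meta$dataset_id),
      Imis = nrow(items), mis_ds = items$mis_ds, logF = log(items$F),
      w = items$c_D * items$c_E,
      anim = as.numeric(items$trophic_class %in% animal_classes()),
      ist = c(1L, utils::head(ien, -1) + 1L), ien = ien,
      ncomp = ncomp, Cz = spec$lambda_zeros,
      zeros = rep(0, length(mis_ids))
    ))
  }

  monitor <- c("beta", "sig_eps", "sig_gam", "sig_del", "mu_b", "sig_b",
               "rho_b", "sig_V", "mu", "gamma", "delta")
  if (has_missing && monitor_imputed) monitor <- c(monitor, "Pm", "ym")

  inits <- function(ch) {
    ini <- list(beta = rep(0, ncol(X)), sig_eps = 0.5 + 0.2 * ch,
                sig_gam = 0.5, sig_del = 0.5,
                mu_b = c(mean(b_obs[, 1]), mean(b_obs[, 2])),
                sig_b = pmax(apply(b_obs, 2, stats::sd), 0.05),
                rho_b = 0, sig_V = 0.5)
    if (has_missing) {
      ini$logV <- pmin(jdata$logF, -0.1)  # start imputed volumes near F
    }
    ini
  }
  draws <- run_jags(macro_model_string(has_missing), jdata, monitor, mcmc,
                    inits = inits)

  fixed_pars <- paste0("beta[", seq_len(ncol(X)), "]")
  label <- stats::setNames(colnames(X), fixed_pars)
  core <- dplyr::filter(
    draws, !grepl("^(mu|gamma|delta|ym|Pm)\\[", .data$parameter))
  summ <- summarize_posterior(core) |>
    dplyr::mutate(term = dplyr::coalesce(label[.data$parameter],
                                         .data$parameter), .before = 1)

  beta_draws <- draw_matrix(draws, "beta", ncol(X))
  colnames(beta_draws) <- colnames(X)
  mu_draws <- draw_matrix(draws, "mu", J)
  sig_eps <- draw_vector(draws, "sig_eps")
  sig_gam <- draw_vector(draws, "sig_gam")
  sig_del <- draw_vector(draws, "sig_del")

  fixed_draws <- beta_draws %*% t(X)
  r2 <- r2_mixed(fixed_draws, cbind(sig_gam^2, sig_del^2), sig_eps^2)
  ppp <- ppp_rss(y_obs, mu_draws[, obs_idx, drop = FALSE], sig_eps)

  gamma_med <- apply(draw_matrix(draws, "gamma", max(study)), 2, stats::median)
  delta_med <- apply(draw_matrix(draws, "delta", max(species)), 2, stats::median)
  ranef_offset <- gamma_med[study] + delta_med[species]

  y_full <- rep(NA_real_, J)
  y_full[obs_idx] <- y_obs
  imputed <- NULL
  if (has_missing && monitor_imputed) {
    ym_med <- apply(draw_matrix(draws, "ym", length(mis_ids)), 2, stats::median)
    y_full[jdata$mis_idx] <- ym_med
    imputed <- summarize_posterior(
      dplyr::filter(draws, grepl("^Pm\\[", .data$parameter))) |>
      dplyr::mutate(dataset_id = mis_ids[as.integer(
        sub("^Pm\\[(\\d+)\\]$", "\\1", .data$parameter))], .before = 1)
  }

  check_pars <- c(fixed_pars, "sig_eps", "sig_gam", "sig_del",
                  "mu_b[1]", "mu_b[2]")
  conv <- summ |> dplyr::filter(.data$parameter %in% check_pars)
  bad <- conv$term[!is.na(conv$rhat) & conv$rhat > rhat_warn]
  if (length(bad) > 0) {
    warning("split-Rhat above ", rhat_warn, " for: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  vif_tab <- vif(X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE])

  structure(list(
    draws = draws, summary = summ,
    diagnostics = list(
      ppp = ppp,
      r2_marginal = stats::median(r2$r2_marginal),
      r2_conditional = stats::median(r2$r2_conditional),
      vif = vif_tab,
      rhat = stats::setNames(conv$rhat, conv$term),
      ess = stats::setNames(conv$ess, conv$term)
    ),
    imputed = imputed, gmr = gmr,
    design = X, response = y_full, beta_draws = beta_draws,
    ranef_offset = ranef_offset, meta = meta,
    n_compress = ncomp, spec = spec, mcmc = mcmc
  ), class = "macro_fit")
}

#' @export
print.macro_fit <- function(x, ...) {
  cat("Macroecological trophic-position model\n")
  cat("  datasets:", nrow(x$meta), " (", sum(x$meta$needs_imputation),
      "with imputed volumes )\n")
  cat("  PPP:", signif(x$diagnostics$ppp, 3),
      " r2m:", signif(x$diagnostics$r2_marginal, 3),
      " r2c:", signif(x$diagnostics$r2_conditional, 3), "\n\n")
  fixed <- dplyr::filter(x$summary, grepl("^beta\\[", x$summary$parameter))
  print(as.data.frame(fixed[, c("term", "median", "eti90_lo", "eti90_hi", "pd")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}
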