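#' MCMC configuration
#'
#' Chain settings for the JAGS samplers. The defaults mirror the settings
#' used for the full analyses (5 chains of 201,000 iterations, adaptive
#' burn-in of 1000, thinning interval 100, i.e. 2000 kept draws per chain and
#' 10,000 in total). Simulation studies and tests use [mcmc_config_reduced()].
#'
#' @param chains Number of parallel chains.
#' @param iterations Iterations per chain (post-adaptation, including
#'   burn-in).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; per-chain RNG seeds are derived from it, so a
#'   fixed seed gives bit-identical draws.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 5, iterations = 201000, burn_in = 1000,
                        thin = 100, seed = 1L) {
  stopifnot(chains >= 1, iterations > burn_in, burn_in >= 0, thin >= 1)
  structure(
    list(chains = as.integer(chains), iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @param ... Overrides passed to [mcmc_config()].
#' @export
mcmc_config_reduced <- function(seed = 1L, ...) {
  mcmc_config(chains = 2, iterations = 3000, burn_in = 500, thin = 2,
              seed = seed, ...)
}

#' Kept draws implied by a configuration
#' @param config An [mcmc_config()].
#' @return Integer draws per chain.
#' @export
kept_per_chain <- function(config) {
  as.integer(floor((config$iterations - config$burn_in) / config$thin))
}

#' Equal-tailed credible interval
#'
#' Quantiles at `(1 - level)/2` and `1 - (1 - level)/2` of the posterior
#' draws, using linear interpolation of order statistics
#' ([stats::quantile()] type 7).
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Interval mass in (0, 1).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' eti(1:100, 0.9)
eti <- function(draws, level = 0.9) {
  if (length(draws) < 1 || all(is.na(draws))) {
    stop("eti() needs at least one non-missing draw", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  q <- stats::quantile(draws, probs = c(a, 1 - a), names = FALSE,
                       na.rm = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Probability of direction
#'
#' Fraction of posterior draws sharing the sign of the posterior median.
#' Exactly-zero draws are counted with the median's sign; when the median is
#' itself zero the larger of the two sign shares is returned. By construction
#' the result lies in \[0.5, 1\].
#'
#' @param draws Numeric vector of posterior draws.
#' @return A single probability in \[0.5, 1\].
#' @export
#' @examples
#' direction_probability(c(-1, 1, 2, 3))
direction_probability <- function(draws) {
  if (length(draws) < 1) stop("no draws", call. = FALSE)
  med <- stats::median(draws)
  s <- sign(med)
  if (s == 0) {
    return(max(mean(draws >= 0), mean(draws <= 0)))
  }
  mean(sign(draws) == s | draws == 0)
}

#' Posterior predictive p-value from residual sums of squares
#'
#' For each posterior draw, simulates a replicated response vector from the
#' normal likelihood and compares its residual sum of squares around the
#' draw's fitted means to the observed RSS. The PPP is the share of draws
#' where the replicated RSS is at least the observed RSS; values near 0.5
#' indicate adequate global fit, values near 0 or 1 indicate misfit.
#'
#' In the degenerate zero-noise case both sums are 0 for every draw and the
#' `>=` convention yields PPP = 1.
#'
#' @param observed Numeric response vector (length n).
#' @param mu_draws Matrix of fitted means, draws x n.
#' @param sigma_draws Numeric vector of residual SDs, one per draw.
#' @return A single PPP in \[0, 1\].
#' @export
ppp_rss <- function(observed, mu_draws, sigma_draws) {
  mu_draws <- as.matrix(mu_draws)
  n <- length(observed)
  if (ncol(mu_draws) != n || nrow(mu_draws) != length(sigma_draws)) {
    stop("dimension mismatch between observed, mu_draws and sigma_draws",
         call. = FALSE)
  }
  ndraw <- nrow(mu_draws)
  rep_mat <- mu_draws +
    matrix(stats::rnorm(ndraw * n), ndraw, n) * sigma_draws
  rss_obs <- rowSums((matrix(observed, ndraw, n, byrow = TRUE) - mu_draws)^2)
  rss_rep <- rowSums((rep_mat - mu_draws)^2)
  mean(rss_rep >= rss_obs)
}

#' Marginal and conditional variance explained in a mixed model
#'
#' Per-draw variance decomposition: the marginal R-squared is the variance of
#' the fixed-effect linear predictor over the total (fixed + random + residual)
#' variance; the conditional R-squared adds the random-effect variances to the
#' numerator.
#'
#' @param fixed_draws Matrix, draws x n observations, of the fixed-effect
#'   linear predictor.
#' @param random_var_draws Matrix (draws x n components) or vector of
#'   random-effect variances per draw; use `NULL` for none.
#' @param resid_var_draws Numeric vector of residual variances per draw.
#' @return A tibble with per-draw `r2_marginal` and `r2_conditional`.
#' @export
r2_mixed <- function(fixed_draws, random_var_draws, resid_var_draws) {
  fixed_draws <- as.matrix(fixed_draws)
  ndraw <- nrow(fixed_draws)
  if (is.null(random_var_draws)) {
    random_var_draws <- matrix(0, ndraw, 1)
  }
  random_var_draws <- as.matrix(random_var_draws)
  stopifnot(nrow(random_var_draws) == ndraw,
            length(resid_var_draws) == ndraw)
  if (any(random_var_draws < 0) || any(resid_var_draws < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  var_fixed <- apply(fixed_draws, 1, stats::var)
  var_random <- rowSums(random_var_draws)
  total <- var_fixed + var_random + resid_var_draws
  if (all(total == 0)) stop("all variance components are zero", call. = FALSE)
  tibble::tibble(
    r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + var_random) / total
  )
}

#' Variance inflation factors
#'
#' For each non-intercept column of a design, 1 / (1 - R^2) from regressing
#' that column on all the others.
#'
#' @param design Data frame or matrix of predictor columns (no intercept).
#' @return A tibble with `predictor` and `vif`; perfectly collinear columns
#'   get `Inf` with a warning.
#' @export
#' @examples
#' vif(data.frame(a = rnorm(20), b = rnorm(20)))
vif <- function(design) {
  x <- as.matrix(design)
  stopifnot(ncol(x) >= 1)
  if (ncol(x) == 1) {
    return(tibble::tibble(predictor = colnames(x) %||% "x1", vif = 1))
  }
  nm <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  out <- vapply(seq_len(ncol(x)), function(k) {
    fit <- stats::lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, k] - mean(x[, k]))^2)
    if (r2 >= 1 - 1e-12) return(Inf)
    1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(out))) {
    warning("perfect collinearity detected; VIF reported as Inf",
            call. = FALSE)
  }
  tibble::tibble(predictor = nm, vif = out)
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so stationarity within chains is checked even for single-chain runs.
#'
#' @param draws Matrix of draws, iterations x chains (or a vector for one
#'   chain).
#' @return A single Rhat value; `NA` if fewer than 4 draws.
#' @export
rhat_split <- function(draws) {
  x <- as.matrix(draws)
  niter <- nrow(x)
  if (niter < 4) return(NA_real_)
  half <- floor(niter / 2)
  split <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(niter - half + 1):niter, , drop = FALSE])
  m <- ncol(split); n <- nrow(split)
  mu <- colMeans(split)
  s2 <- apply(split, 2, stats::var)
  w <- mean(s2)
  b <- n * stats::var(mu)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Summarise posterior draws
#'
#' Median, 50% and 90% equal-tailed intervals, probability of direction, and
#' convergence diagnostics (split-Rhat, effective sample size via
#' [coda::effectiveSize()]) for each parameter of a long draw table.
#'
#' @param draws A tibble in the package's long draw format: columns `chain`,
#'   `iteration`, `parameter`, `value`.
#' @return A tibble with one row per parameter.
#' @export
summarize_posterior <- function(draws) {
  stopifnot(all(c("chain", "iteration", "parameter", "value") %in% names(draws)))
  draws |>
    dplyr::group_by(parameter = .data$parameter) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      eti50_lo = eti(.data$value, 0.5)[["lo"]],
      eti50_hi = eti(.data$value, 0.5)[["hi"]],
      eti90_lo = eti(.data$value, 0.9)[["lo"]],
      eti90_hi = eti(.data$value, 0.9)[["hi"]],
      pd = direction_probability(.data$value),
      rhat = rhat_split(matrix(.data$value,
                               ncol = length(unique(.data$chain)))),
      ess = as.numeric(coda::effectiveSize(.data$value)),
      .groups = "drop"
    )
}

#' Convert coda samples to the long draw table
#' @keywords internal
draws_from_coda <- function(samples) {
  purrr::imap_dfr(as.list(samples), function(chain_mat, idx) {
    m <- as.matrix(chain_mat)
    tibble::tibble(
      chain = as.integer(idx),
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m)
    )
  })
}

#' Extract a draws-by-n matrix for an indexed parameter from a long table
#' @keywords internal
draw_matrix <- function(draws, stem, n) {
  cols <- paste0(stem, "[", seq_len(n), "]")
  wide <- draws |>
    dplyr::filter(.data$parameter %in% cols) |>
    dplyr::arrange(.data$chain, .data$iteration)
  m <- matrix(NA_real_, nrow = nrow(wide) / n, ncol = n)
  for (k in seq_len(n)) {
    m[, k] <- wide$value[wide$parameter == cols[k]]
  }
  colnames(m) <- cols
  m
}

#' Extract a single parameter's draws as a vector
#' @keywords internal
draw_vector <- function(draws, parameter) {
  out <- draws |>
    dplyr::filter(.data$parameter == !!parameter) |>
    dplyr::arrange(.data$chain, .data$iteration)
  if (nrow(out) == 0) stop("no draws for parameter ", parameter, call. = FALSE)
  out$value
}

#' Partial (component + residual) values for one predictor
#'
#' For a fitted model with posterior draws of fixed effects, computes the
#' per-observation component + residual values for a chosen predictor: the
#' component is that predictor's coefficient (posterior median) times its
#' column, the residual is the observed response minus the full fitted mean
#' (fixed effects at posterior medians, other predictors at their observed
#' values, random effects at posterior medians). Also returns a grid of
#' fitted component lines with 50%/90% ETIs, conditioning the other
#' predictors on 0 (their mean after standardisation).
#'
#' @param fit A `macro_fit` or `paleo_fit` object.
#' @param predictor Name of a fixed-effect design column.
#' @return A list with tibbles `points` (observation-level component +
#'   residual) and `line` (grid of the fitted partial relationship with ETIs).
#' @export
partial_residuals <- function(fit, predictor) {
  X <- fit$design
  y <- fit$response
  if (!predictor %in% colnames(X)) {
    stop("unknown predictor: ", predictor, "; available: ",
         paste(setdiff(colnames(X), "(Intercept)"), collapse = ", "),
         call. = FALSE)
  }
  beta_draws <- fit$beta_draws          # draws x p, columns named as design
  beta_med <- apply(beta_draws, 2, stats::median)
  full_mu <- drop(X %*% beta_med) + fit$ranef_offset
  comp_obs <- X[, predictor] * beta_med[predictor]
  points <- tibble::tibble(
    x = X[, predictor],
    partial = comp_obs + (y - full_mu)
  )
  grid <- seq(min(points$x), max(points$x), length.out = 50)
  comp_draws <- outer(beta_draws[, predictor], grid)   # draws x grid
  line <- tibble::tibble(
    x = grid,
    median = apply(comp_draws, 2, stats::median),
    eti50_lo = apply(comp_draws, 2, function(d) eti(d, 0.5)[["lo"]]),
    eti50_hi = apply(comp_draws, 2, function(d) eti(d, 0.5)[["hi"]]),
    eti90_lo = apply(comp_draws, 2, function(d) eti(d, 0.9)[["lo"]]),
    eti90_hi = apply(comp_draws, 2, function(d) eti(d, 0.9)[["hi"]])
  )
  list(points = points, line = line)
}
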