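#' Trophic position from baseline-referenced delta-15N
#'
#' \deqn{TP = (consumer - baseline)/TDF + \lambda,} where the consumer and
#' baseline values are bias-corrected mean collagen d15N (per mil), the
#' trophic discrimination factor (TDF) is the per-trophic-level d15N
#' enrichment, and \eqn{\lambda} is the trophic level of the baseline
#' (2 for a strict herbivore such as red deer). Vectorised, so it applies
#' drawwise to posterior samples. Draws with non-positive TDF are returned as
#' `NA` with a warning.
#'
#' @param consumer,baseline d15N values (per mil).
#' @param tdf Trophic discrimination factor (per mil, > 0).
#' @param lambda Trophic level of the baseline.
#' @return Trophic position (trophic-level units).
#' @export
#' @examples
#' trophic_position(7.3, 4.0, tdf = 3.3)
trophic_position <- function(consumer, baseline, tdf, lambda = 2) {
  stopifnot(lambda > 0)
  bad <- !is.na(tdf) & tdf <= 0
  if (any(bad)) {
    warning(sum(bad), " draw(s) with non-positive TDF set to NA",
            call. = FALSE)
    tdf[bad] <- NA_real_
  }
  (consumer - baseline) / tdf + lambda
}

#' Specification of the paleoecological trophic-position model
#'
#' @param lambda Trophic level of the baseline species (red deer, a strict
#'   herbivore: 2).
#' @param standardize Standardise log10 NPP and GSL across the identified
#'   periods before the period-level regression.
#' @param lambda_zeros Constant of the Poisson-zeros device linking the
#'   derived trophic positions to the regression likelihood.
#' @return A `paleo_model_spec` list.
#' @export
paleo_model_spec <- function(lambda = 2, standardize = TRUE,
                             lambda_zeros = 1e5) {
  stopifnot(lambda > 0)
  structure(list(lambda = lambda, standardize = standardize,
                 lambda_zeros = lambda_zeros),
            class = "paleo_model_spec")
}

offset_model_string <- "
model {
  muT ~ dnorm(0, 1.0E-4)
  sigT ~ dt(0, 1, 2) T(0,)
  tauT <- pow(sigT, -2)
  for (i in 1:N) { Td[i] ~ dnorm(muT, tauT) }
}
"

#' Posterior of the tooth-bone delta-15N offset
#'
#' Dentine collagen forms early in life, partly during lactation, and so runs
#' higher in d15N than bone collagen from the same individual. This sub-model
#' fits a normal mean to paired tooth-minus-bone differences.
#'
#' @param pairs Data frame with a `difference` column (tooth minus bone,
#'   per mil), or a numeric vector; >= 2 pairs.
#' @param mcmc An [mcmc_config()].
#' @return An `offset_fit` with `draws` (long tibble) and `summary`.
#' @export
fit_offset_submodel <- function(pairs, mcmc = mcmc_config_reduced()) {
  d <- if (is.data.frame(pairs)) pairs$difference else pairs
  d <- d[!is.na(d)]
  if (length(d) < 2) {
    stop("insufficient data: need at least 2 tooth-bone pairs", call. = FALSE)
  }
  draws <- run_jags(offset_model_string, list(Td = d, N = length(d)),
                    c("muT", "sigT"), mcmc,
                    inits = function(ch) list(muT = mean(d), sigT = max(stats::sd(d), 0.1)))
  structure(list(draws = draws, summary = summarize_posterior(draws),
                 n = length(d)),
            class = "offset_fit")
}

elevation_model_string <- "
model {
  betaE ~ dnorm(0, 1.0E-4)
  for (t in 1:Ntype) { typeI[t] ~ dnorm(0, 1.0E-4) }
  sigN ~ dt(0, 1, 2) T(0,)
  tauN <- pow(sigN, -2)
  for (i in 1:N) {
    Nr[i] ~ dnorm(typeI[mat[i]] + betaE * elev[i], tauN)
  }
}
"

#' Posterior of the elevation effect on delta-15N
#'
#' Linear model for reference d15N of plants and herbivore tissues
#' (vegetation, sheep wool, cattle hair, goat hair) with a separate intercept
#' per material type and a shared elevation slope.
#'
#' @param refs Data frame with columns `d15N`, `elevation` (m a.s.l.) and
#'   `type` (material type label; a single type is allowed).
#' @param mcmc An [mcmc_config()].
#' @return An `elevation_fit` with `draws`, `summary` and the type levels.
#' @export
fit_elevation_submodel <- function(refs, mcmc = mcmc_config_reduced()) {
  stopifnot(all(c("d15N", "elevation", "type") %in% names(refs)))
  refs <- refs[stats::complete.cases(refs[, c("d15N", "elevation", "type")]), ]
  if (nrow(refs) < 3 || stats::var(refs$elevation) == 0) {
    stop("degenerate design: need >= 3 references spanning an elevation range",
         call. = FALSE)
  }
  type <- factor(refs$type)
  jd <- list(Nr = refs$d15N, elev = refs$elevation,
             mat = as.integer(type), Ntype = nlevels(type), N = nrow(refs))
  draws <- run_jags(elevation_model_string, jd,
                    c("betaE", "typeI", "sigN"), mcmc,
                    inits = function(ch) list(betaE = 0, sigN = max(stats::sd(refs$d15N), 0.1)))
  summ <- summarize_posterior(draws) |>
    dplyr::mutate(term = dplyr::recode(
      .data$parameter,
      !!!stats::setNames(as.list(paste0("type:", levels(type))),
                         paste0("typeI[", seq_len(nlevels(type)), "]"))),
      .before = 1)
  structure(list(draws = draws, summary = summ, types = levels(type)),
            class = "elevation_fit")
}

paleo_model_string <- "
model {
  # tooth-bone offset
  muT ~ dnorm(0, 1.0E-4)
  sigT ~ dt(0, 1, 2) T(0,)
  tauT <- pow(sigT, -2)
  for (i in 1:Npair) { Td[i] ~ dnorm(muT, tauT) }

  # elevation effect on reference material
  betaE ~ dnorm(0, 1.0E-4)
  for (t in 1:Ntype) { typeI[t] ~ dnorm(0, 1.0E-4) }
  sigN ~ dt(0, 1, 2) T(0,)
  tauN <- pow(sigN, -2)
  for (i in 1:Nref) { Nr[i] ~ dnorm(typeI[mat[i]] + betaE * elevR[i], tauN) }

  # trophic discrimination factor
  muD ~ dnorm(0, 1.0E-4)
  sigD ~ dt(0, 1, 2) T(0,)
  tauD <- pow(sigD, -2)
  for (i in 1:Ntdf) { Dl[i] ~ dnorm(muD, tauD) }

  # bias-corrected period means: bone-equivalent, elevation-zero
  sigB ~ dt(0, 1, 2) T(0,)
  tauB <- pow(sigB, -2)
  sigC ~ dt(0, 1, 2) T(0,)
  tauC <- pow(sigC, -2)
  for (j in 1:Jb) { baseline[j] ~ dnorm(0, 1.0E-4) }
  for (j in 1:Jc) { consumer[j] ~ dnorm(0, 1.0E-4) }
  for (i in 1:Ndeer) {
    B[i] ~ dnorm(baseline[perB[i]] + betaE * elevB[i] + muT * toothB[i], tauB)
  }
  for (i in 1:Nbear) {
    C[i] ~ dnorm(consumer[perC[i]] + betaE * elevC[i] + muT * toothC[i], tauC)
  }

  # trophic position and its regression on period environment
  for (k in 1:Preg) { betaP[k] ~ dnorm(0, 1.0E-4) }
  sigTP ~ dt(0, 1, 2) T(0,)
  tauTP <- pow(sigTP, -2)
  for (j in 1:Jtp) {
    TP[j] <- (consumer[cidx[j]] - baseline[bidx[j]]) / muD + lambda
    muP[j] <- inprod(Xp[j, ], betaP[])
    zeros[j] ~ dpois(Cz - logdensity.norm(TP[j], muP[j], tauTP))
  }
}
"

#' Fit the paleoecological Bayesian hierarchical model
#'
#' One joint posterior over five coupled sub-models: (i) the tooth-bone
#' d15N offset from paired samples; (ii) the elevation effect on d15N from
#' reference material; (iii) bias-corrected per-period mean d15N of red deer
#' (baseline) and brown bear (consumer), with the tooth and elevation terms
#' in the observation mean so the period means are bone-equivalent,
#' elevation-zero quantities; (iv) the trophic discrimination factor from
#' predator-prey pairs; (v) the drawwise trophic position
#' `(consumer - baseline)/TDF + lambda` per period, regressed on log10 NPP
#' and growing season length. All uncertainty is propagated through the joint
#' posterior. Priors: Normal(0, variance 1e4) on locations, half-t(2, 1) on
#' SDs.
#'
#' Periods with samples of only one taxon have no identified trophic
#' position; they are kept in the period table but excluded from the
#' regression (with a message).
#'
#' @param samples Isotope table as from [validate_isotope_table()] or
#'   [simulate_paleo()]; only `qc_pass` rows with an assigned period are
#'   used (dropped rows are counted in a message).
#' @param refs A list with data frames `tooth_bone` (column `difference`),
#'   `elevation` (`d15N`, `elevation`, `type`) and `tdf` (column
#'   `difference`, predator minus prey d15N).
#' @param period_env Data frame `period`, `npp`, `gsl`: per-period
#'   environmental covariates (e.g. means across that period's samples).
#' @param spec A [paleo_model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param rhat_warn Split-Rhat warning threshold.
#' @return A `paleo_fit` with `draws`, `summary`, `periods` (per-period
#'   estimates), `diagnostics`, `design`, `response`, `beta_draws`,
#'   `ranef_offset`.
#' @export
fit_paleo <- function(samples, refs, period_env,
                      spec = paleo_model_spec(), mcmc = mcmc_config(),
                      rhat_warn = 1.01) {
  stopifnot(is.list(refs),
            all(c("tooth_bone", "elevation", "tdf") %in% names(refs)))
  for (nm in c("tooth_bone", "elevation", "tdf")) {
    if (nrow(refs[[nm]]) == 0) {
      stop("reference table '", nm, "' is empty", call. = FALSE)
    }
  }
  if (!"qc_pass" %in% names(samples)) samples <- qc_collagen(samples)
  if (!"period" %in% names(samples)) {
    samples$period <- assign_period(samples$age)
  }
  n0 <- nrow(samples)
  use <- samples |>
    dplyr::filter(.data$qc_pass, !is.na(.data$period))
  if (nrow(use) < n0) {
    message(n0 - nrow(use), " of ", n0,
            " samples dropped (failed QC or outside the time bins)")
  }
  deer <- dplyr::filter(use, .data$taxon == "red_deer")
  bear <- dplyr::filter(use, .data$taxon == "brown_bear")
  per_b <- sort(unique(deer$period))
  per_c <- sort(unique(bear$period))
  tp_periods <- intersect(per_b, per_c)
  if (length(tp_periods) < 2) {
    stop("both taxa must be present in at least 2 periods", call. = FALSE)
  }
  dropped <- setdiff(union(per_b, per_c), tp_periods)
  if (length(dropped) > 0) {
    message("trophic position not identified (single taxon) in: ",
            paste(dropped, collapse = ", "), "; excluded from the regression")
  }

  env <- period_env[match(tp_periods, period_env$period), ]
  if (anyNA(env$npp) || anyNA(env$gsl)) {
    stop("period_env lacks npp/gsl for: ",
         paste(tp_periods[is.na(env$npp) | is.na(env$gsl)], collapse = ", "),
         call. = FALSE)
  }
  npp_s <- log10(env$npp)
  gsl_s <- as.numeric(env$gsl)
  if (spec$standardize) {
    npp_s <- as.numeric(scale(npp_s))
    gsl_s <- as.numeric(scale(gsl_s))
  }
  Xp <- cbind("(Intercept)" = 1, npp_s = npp_s, gsl_s = gsl_s)

  jd <- list(
    Td = refs$tooth_bone$difference, Npair = nrow(refs$tooth_bone),
    Nr = refs$elevation$d15N, elevR = refs$elevation$elevation,
    mat = as.integer(factor(refs$elevation$type)),
    Ntype = nlevels(factor(refs$elevation$type)),
    Nref = nrow(refs$elevation),
    Dl = refs$tdf$difference, Ntdf = nrow(refs$tdf),
    B = deer$d15N, elevB = deer$elevation,
    toothB = as.numeric(deer$material == "tooth"),
    perB = match(deer$period, per_b), Ndeer = nrow(deer), Jb = length(per_b),
    C = bear$d15N, elevC = bear$elevation,
    toothC = as.numeric(bear$material == "tooth"),
    perC = match(bear$period, per_c), Nbear = nrow(bear), Jc = length(per_c),
    Jtp = length(tp_periods),
    bidx = match(tp_periods, per_b), cidx = match(tp_periods, per_c),
    Xp = Xp, Preg = ncol(Xp), lambda = spec$lambda,
    Cz = spec$lambda_zeros, zeros = rep(0, length(tp_periods))
  )
  inits <- function(ch) {
    list(muT = mean(jd$Td), betaE = 0,
         muD = max(mean(jd$Dl), 0.5),
         sigT = max(stats::sd(jd$Td), 0.1), sigN = 1, sigD = 0.5,
         sigB = 1, sigC = 1,
         baseline = as.numeric(tapply(deer$d15N, factor(deer$period, per_b), mean)),
         consumer = as.numeric(tapply(bear$d15N, factor(bear$period, per_c), mean)),
         betaP = c(2.5, 0, 0), sigTP = 0.3 + 0.1 * ch)
  }
  monitor <- c("muT", "sigT", "betaE", "typeI", "sigN", "muD", "sigD",
               "baseline", "consumer", "sigB", "sigC", "betaP", "sigTP", "TP")
  draws <- run_jags(paleo_model_string, jd, monitor, mcmc, inits = inits)

  labels <- c(
    stats::setNames(paste0("baseline:", per_b),
                    paste0("baseline[", seq_along(per_b), "]")),
    stats::setNames(paste0("consumer:", per_c),
                    paste0("consumer[", seq_along(per_c), "]")),
    stats::setNames(paste0("TP:", tp_periods),
                    paste0("TP[", seq_along(tp_periods), "]")),
    stats::setNames(colnames(Xp), paste0("betaP[", seq_len(ncol(Xp)), "]")),
    stats::setNames(paste0("type:", levels(factor(refs$elevation$type))),
                    paste0("typeI[", seq_len(jd$Ntype), "]"))
  )
  summ <- summarize_posterior(draws) |>
    dplyr::mutate(term = dplyr::coalesce(labels[.data$parameter],
                                         .data$parameter), .before = 1)

  pick <- function(term_name, col) {
    i <- match(term_name, summ$term)
    if (is.na(i)) NA_real_ else summ[[col]][i]
  }
  all_periods <- sort(unique(c(per_b, per_c)))
  periods <- tibble::tibble(
    period = all_periods,
    n_deer = as.integer(table(factor(deer$period, all_periods))),
    n_bear = as.integer(table(factor(bear$period, all_periods))),
    baseline = vapply(paste0("baseline:", all_periods), pick, 1, col = "median"),
    consumer = vapply(paste0("consumer:", all_periods), pick, 1, col = "median"),
    tp_median = vapply(paste0("TP:", all_periods), pick, 1, col = "median"),
    tp_eti50_lo = vapply(paste0("TP:", all_periods), pick, 1, col = "eti50_lo"),
    tp_eti50_hi = vapply(paste0("TP:", all_periods), pick, 1, col = "eti50_hi"),
    tp_eti90_lo = vapply(paste0("TP:", all_periods), pick, 1, col = "eti90_lo"),
    tp_eti90_hi = vapply(paste0("TP:", all_periods), pick, 1, col = "eti90_hi"),
    identified = all_periods %in% tp_periods
  )

  # diagnostics: observation-level PPP per taxon, regression r2
  betaE_d <- draw_vector(draws, "betaE")
  muT_d <- draw_vector(draws, "muT")
  muD_d <- draw_vector(draws, "muD")
  base_d <- draw_matrix(draws, "baseline", length(per_b))
  cons_d <- draw_matrix(draws, "consumer", length(per_c))
  mu_deer <- base_d[, jd$perB, drop = FALSE] +
    outer(betaE_d, jd$elevB) + outer(muT_d, jd$toothB)
  mu_bear <- cons_d[, jd$perC, drop = FALSE] +
    outer(betaE_d, jd$elevC) + outer(muT_d, jd$toothC)
  ppp_base <- ppp_rss(deer$d15N, mu_deer, draw_vector(draws, "sigB"))
  ppp_cons <- ppp_rss(bear$d15N, mu_bear, draw_vector(draws, "sigC"))
  betaP_draws <- draw_matrix(draws, "betaP", ncol(Xp))
  colnames(betaP_draws) <- colnames(Xp)
  sigTP_d <- draw_vector(draws, "sigTP")
  r2 <- r2_mixed(betaP_draws %*% t(Xp), NULL, sigTP_d^2)

  tp_draws <- draw_matrix(draws, "TP", length(tp_periods))
  colnames(tp_draws) <- tp_periods
  tp_med <- apply(tp_draws, 2, stats::median)

  if (any(muD_d <= 0)) {
    warning(sum(muD_d <= 0),
            " posterior draw(s) with non-positive TDF", call. = FALSE)
  }

  check <- summ |> dplyr::filter(.data$parameter %in% c(
    "muT", "betaE", "muD", "sigTP",
    paste0("betaP[", seq_len(ncol(Xp)), "]")))
  bad <- check$term[!is.na(check$rhat) & check$rhat > rhat_warn]
  if (length(bad) > 0) {
    warning("split-Rhat above ", rhat_warn, " for: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  structure(list(
    draws = draws, summary = summ, periods = periods,
    diagnostics = list(
      ppp_baseline = ppp_base, ppp_consumer = ppp_cons,
      r2_marginal = stats::median(r2$r2_marginal),
      r2_conditional = stats::median(r2$r2_conditional),
      vif = vif(Xp[, -1, drop = FALSE]),
      rhat = stats::setNames(check$rhat, check$term),
      ess = stats::setNames(check$ess, check$term),
      n_dropped = n0 - nrow(use)
    ),
    design = Xp, response = tp_med, beta_draws = betaP_draws,
    ranef_offset = rep(0, nrow(Xp)),
    tp_draws = tp_draws, tp_periods = tp_periods,
    spec = spec, mcmc = mcmc
  ), class = "paleo_fit")
}

#' @export
print.paleo_fit <- function(x, ...) {
  cat("Paleoecological trophic-position model\n")
  cat("  identified periods:", sum(x$periods$identified), "of",
      nrow(x$periods), "\n")
  cat("  PPP (baseline, consumer):",
      signif(x$diagnostics$ppp_baseline, 3),
      signif(x$diagnostics$ppp_consumer, 3), "\n\n")
  print(as.data.frame(
    x$periods[, c("period", "n_bear", "n_deer", "tp_median",
                  "tp_eti90_lo", "tp_eti90_hi")]),
    row.names = FALSE, digits = 3)
  invisible(x)
}
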