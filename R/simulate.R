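#' Ground truth for the macroecological generator
#'
#' Defaults mirror the macroecological study conditions: 210 diet records
#' from 155 studies of 7 bear species, roughly half the records lacking
#' relative volumes, and NPP correlated with growing season length at
#' Pearson r = 0.61. Fixed effects are on the probit scale of the compressed
#' animal-prey energy share, for standardised predictors; their default
#' values are the fitted macroecological effects (NPP -0.18, GSL -0.41,
#' subordinate -0.50, dominant 0.059).
#'
#' @param beta Named fixed effects: `intercept`, `npp`, `gsl`,
#'   `subordinate`, `dominant`.
#' @param sigma_study,sigma_species,sigma_resid Random-effect and residual
#'   SDs on the probit scale.
#' @param mu_b Mean intercept and slope of the per-dataset log
#'   frequency-volume lines.
#' @param sigma_b SDs of the line intercept and slope across datasets.
#' @param rho_b Correlation between line intercept and slope.
#' @param sigma_V Residual SD of log relative volume around a dataset's line.
#' @param missingness Fraction of datasets whose volumes are masked.
#' @param n_obs,n_studies,n_species Problem sizes.
#' @param npp_gsl_cor Correlation between log10 NPP and GSL.
#' @param n_animal_items,n_plant_items Food categories drawn per dataset from
#'   the animal and non-animal pools.
#' @param concentration Symmetric Dirichlet concentration used to split
#'   energy within the animal and non-animal pools.
#' @param cooc_probs Probabilities of co-occurrence classes
#'   (none/subordinate/dominant).
#' @param seed Integer seed.
#' @return A `macro_truth` list.
#' @export
macro_truth <- function(beta = c(intercept = -0.5, npp = -0.18, gsl = -0.41,
                                 subordinate = -0.50, dominant = 0.059),
                        sigma_study = 0.4, sigma_species = 0.3,
                        sigma_resid = 0.3,
                        mu_b = c(intercept = -0.2, slope = 1.1),
                        sigma_b = c(0.25, 0.2), rho_b = -0.2,
                        sigma_V = 0.3, missingness = 107 / 210,
                        n_obs = 210, n_studies = 155, n_species = 7,
                        npp_gsl_cor = 0.61,
                        n_animal_items = 3, n_plant_items = 5,
                        concentration = 1,
                        cooc_probs = c(none = 0.5, subordinate = 0.25,
                                       dominant = 0.25),
                        seed = 1L) {
  stopifnot(sigma_study > 0, sigma_species > 0, sigma_resid > 0,
            all(sigma_b > 0), sigma_V > 0,
            missingness >= 0, missingness < 1,
            abs(rho_b) < 1, abs(npp_gsl_cor) <= 1,
            n_obs >= n_species, n_studies <= n_obs,
            n_studies >= n_species)
  structure(as.list(environment()), class = "macro_truth")
}

rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration)
  g / sum(g)
}

#' Simulate a macroecological diet dataset with known ground truth
#'
#' Generates diet records with exactly the statistical structure the
#' macroecological model assumes: environmental covariates with a
#' controllable NPP-GSL correlation, a probit-scale linear predictor with
#' study and species random intercepts, energy compositions allocated to
#' animal and plant categories by symmetric Dirichlet splits, volumes
#' recovered by inverting the energy correction, frequencies generated from
#' volumes through per-dataset log-scale lines drawn from the bivariate
#' normal hierarchy (then renormalised), and volumes masked at the
#' missingness fraction.
#'
#' @param truth A [macro_truth()].
#' @param categories Category reference table.
#' @param seed Optional override of `truth$seed`.
#' @return A list with `data` (item-level tibble in the [read_diet_table()]
#'   layout) and `truth` (the ground-truth record, including the realised
#'   per-dataset animal-prey shares `P` and probit responses `y`).
#' @export
simulate_macro <- function(truth = macro_truth(),
                           categories = default_diet_categories(),
                           seed = NULL) {
  validate_categories(categories)
  set.seed(seed %||% truth$seed)
  n <- truth$n_obs
  # each record belongs to a study; each study concerns one species
  study <- sort(c(seq_len(truth$n_studies),
                  sample(truth$n_studies, n - truth$n_studies, replace = TRUE)))
  species_of_study <- c(seq_len(truth$n_species),
                        sample(truth$n_species,
                               truth$n_studies - truth$n_species,
                               replace = TRUE))
  species <- species_of_study[study]

  z <- MASS::mvrnorm(n, mu = c(0, 0),
                     Sigma = matrix(c(1, truth$npp_gsl_cor,
                                      truth$npp_gsl_cor, 1), 2))
  npp <- 10^(-0.4 + 0.35 * z[, 1])           # ~0.1 .. 2 kg C m-2 a-1
  gsl <- pmin(12, pmax(0, round(6.5 + 2.5 * z[, 2])))
  cooc <- sample(names(truth$cooc_probs), n, replace = TRUE,
                 prob = truth$cooc_probs)

  npp_s <- as.numeric(scale(log10(npp)))
  gsl_s <- as.numeric(scale(gsl))
  gamma <- stats::rnorm(truth$n_studies, 0, truth$sigma_study)
  delta <- stats::rnorm(truth$n_species, 0, truth$sigma_species)
  mu <- truth$beta[["intercept"]] + truth$beta[["npp"]] * npp_s +
    truth$beta[["gsl"]] * gsl_s +
    truth$beta[["subordinate"]] * (cooc == "subordinate") +
    truth$beta[["dominant"]] * (cooc == "dominant") +
    gamma[study] + delta[species]
  y <- mu + stats::rnorm(n, 0, truth$sigma_resid)
  P <- pmin(1, pmax(0, probit_expand(y, n)))

  anim_pool <- categories$category[categories$trophic_class %in% animal_classes()]
  plant_pool <- setdiff(categories$category, anim_pool)
  Sigma_b <- diag(truth$sigma_b) %*%
    matrix(c(1, truth$rho_b, truth$rho_b, 1), 2) %*% diag(truth$sigma_b)
  b <- MASS::mvrnorm(n, mu = c(truth$mu_b[["intercept"]],
                               truth$mu_b[["slope"]]), Sigma = Sigma_b)
  missing_v <- seq_len(n) %in%
    sample(n, size = round(truth$missingness * n))

  w <- stats::setNames(categories$c_D * categories$c_E, categories$category)
  items <- purrr::map_dfr(seq_len(n), function(j) {
    cats_a <- sample(anim_pool, truth$n_animal_items)
    cats_p <- sample(plant_pool, truth$n_plant_items)
    E <- c(P[j] * rdirichlet1(length(cats_a), truth$concentration),
           (1 - P[j]) * rdirichlet1(length(cats_p), truth$concentration))
    cats <- c(cats_a, cats_p)
    V <- E / w[cats]
    V <- V / sum(V)                      # invert the energy correction
    e_fv <- stats::rnorm(length(V), 0, truth$sigma_V)
    logF <- (log(V) - e_fv - b[j, 1]) / b[j, 2]
    F_ <- exp(logF)
    F_ <- F_ / sum(F_)
    tibble::tibble(
      dataset_id = sprintf("ds%03d", j), study_id = sprintf("st%03d", study[j]),
      species = sprintf("species%d", species[j]),
      lat = stats::runif(1, -40, 70), lon = stats::runif(1, -180, 180),
      sample_type = sample(c("scat", "stomach"), 1, prob = c(0.8, 0.2)),
      n_samples = sample(20:400, 1),
      category = cats, F = F_, V = if (missing_v[j]) NA_real_ else V,
      npp = npp[j], gsl = gsl[j], co_occurrence = cooc[j]
    )
  })
  truth_out <- c(truth, list(
    realised = tibble::tibble(
      dataset_id = sprintf("ds%03d", seq_len(n)),
      P = P, y = y, missing_v = missing_v,
      b_intercept = b[, 1], b_slope = b[, 2]
    )))
  list(data = items, truth = truth_out)
}

#' Ground truth for the paleoecological generator
#'
#' Defaults mirror the paleoecological study conditions: 219 brown bear and
#' 372 red deer collagen samples spread over the eight time bins, reference
#' tables of 35 tooth-bone pairs, 69 elevation references and 10
#' predator-prey TDF pairs, and period-level regression effects of NPP and
#' GSL equal to the fitted paleoecological values (-0.17, -0.19).
#'
#' @param beta_reg Named period-level regression effects on trophic position
#'   (standardised predictors): `intercept`, `npp`, `gsl`.
#' @param sigma_tp Period-level residual SD of trophic position.
#' @param baseline_mean,baseline_sd Distribution of per-period baseline (red
#'   deer) mean d15N, per mil.
#' @param mu_T Tooth-bone offset (per mil), `sigma_T` its SD across pairs.
#' @param beta_E Elevation effect on d15N (per mil per m), `sigma_N` the
#'   reference-model residual SD.
#' @param mu_delta Trophic discrimination factor (per mil, > 0),
#'   `sigma_delta` its SD across predator-prey pairs.
#' @param sigma_B,sigma_C Residual SDs of deer and bear d15N.
#' @param sigma_T,sigma_N,sigma_delta See above.
#' @param n_bear,n_deer Total sample sizes, allocated over periods
#'   proportionally (at least 2 each per period).
#' @param n_pairs,n_elev_refs,n_tdf Reference-table sizes.
#' @param tooth_fraction Fraction of samples that are teeth.
#' @param elev_shape,elev_scale Gamma distribution of sample elevations (m).
#' @param contamination Fraction of samples generated with failing QC
#'   chemistry.
#' @param npp_gsl_cor Correlation of the period-level covariates.
#' @param seed Integer seed.
#' @return A `paleo_truth` list.
#' @export
paleo_truth <- function(beta_reg = c(intercept = 2.5, npp = -0.17, gsl = -0.19),
                        sigma_tp = 0.08,
                        baseline_mean = 4, baseline_sd = 0.8,
                        mu_T = 0.9, sigma_T = 0.5,
                        beta_E = -0.0015, sigma_N = 1.2,
                        mu_delta = 3.3, sigma_delta = 0.8,
                        sigma_B = 1, sigma_C = 1,
                        n_bear = 219, n_deer = 372,
                        n_pairs = 35, n_elev_refs = 69, n_tdf = 10,
                        tooth_fraction = 0.3,
                        elev_shape = 2, elev_scale = 250,
                        contamination = 0,
                        npp_gsl_cor = -0.06, seed = 1L) {
  stopifnot(mu_delta > 0, sigma_tp > 0, n_bear >= 16, n_deer >= 16,
            contamination >= 0, contamination < 1)
  structure(as.list(environment()), class = "paleo_truth")
}

split_n <- function(total, k) {
  base <- rep(floor(total / k), k)
  extra <- total - sum(base)
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

#' Simulate a paleoecological isotope dataset with known ground truth
#'
#' Generates per-period environmental covariates, draws per-period trophic
#' positions from the period-level regression, converts them to consumer
#' (brown bear) mean d15N via the baseline and the trophic discrimination
#' factor, and simulates individual collagen samples with elevation and
#' tooth biases plus residual noise. Reference tables (tooth-bone pairs,
#' elevation references over four material types, TDF pairs) and marine
#' references are drawn at the configured sizes. QC chemistry passes by
#' default; a configurable contamination fraction is drawn with failing
#' chemistry.
#'
#' @param truth A [paleo_truth()].
#' @param bins Time-bin table.
#' @param seed Optional override of `truth$seed`.
#' @return A list with `samples`, `refs` (list of `tooth_bone`, `elevation`,
#'   `tdf`, `marine`), `period_env` and `truth` (including realised
#'   per-period baselines, consumers and trophic positions).
#' @export
simulate_paleo <- function(truth = paleo_truth(), bins = default_time_bins(),
                           seed = NULL) {
  set.seed(seed %||% truth$seed)
  J <- nrow(bins)
  z <- MASS::mvrnorm(J, mu = c(0, 0),
                     Sigma = matrix(c(1, truth$npp_gsl_cor,
                                      truth$npp_gsl_cor, 1), 2))
  npp <- 10^(-0.5 + 0.25 * z[, 1])
  gsl <- pmin(12, pmax(1, round(6 + 2 * z[, 2])))
  npp_s <- as.numeric(scale(log10(npp)))
  gsl_s <- as.numeric(scale(gsl))
  tp <- truth$beta_reg[["intercept"]] + truth$beta_reg[["npp"]] * npp_s +
    truth$beta_reg[["gsl"]] * gsl_s + stats::rnorm(J, 0, truth$sigma_tp)
  baseline <- stats::rnorm(J, truth$baseline_mean, truth$baseline_sd)
  consumer <- baseline + (tp - 2) * truth$mu_delta

  nb <- split_n(truth$n_bear, J)
  nd <- split_n(truth$n_deer, J)
  gen_taxon <- function(taxon, counts, means, sigma) {
    purrr::map_dfr(seq_len(J), function(j) {
      k <- counts[j]
      elev <- pmin(3000, stats::rgamma(k, truth$elev_shape,
                                       scale = truth$elev_scale))
      tooth <- stats::runif(k) < truth$tooth_fraction
      d15N <- means[j] + truth$beta_E * elev + truth$mu_T * tooth +
        stats::rnorm(k, 0, sigma)
      contaminated <- stats::runif(k) < truth$contamination
      tibble::tibble(
        taxon = taxon, period_true = bins$period[j],
        age = stats::runif(k, bins$lower[j], bins$upper[j] - 1e-9),
        d15N = d15N, d13C = stats::rnorm(k, -21, 1),
        elevation = elev,
        material = ifelse(tooth, "tooth", "bone"),
        cn_atomic = ifelse(contaminated, stats::runif(k, 3.8, 4.5),
                           stats::runif(k, 3.0, 3.5)),
        pctC = ifelse(contaminated, stats::runif(k, 2, 7),
                      stats::runif(k, 30, 45)),
        pctN = ifelse(contaminated, stats::runif(k, 0.5, 2.5),
                      stats::runif(k, 10, 16)),
        lat = stats::runif(k, 36, 60), lon = stats::runif(k, -9, 30)
      )
    })
  }
  samples <- dplyr::bind_rows(
    gen_taxon("brown_bear", nb, consumer, truth$sigma_C),
    gen_taxon("red_deer", nd, baseline, truth$sigma_B)
  ) |>
    dplyr::mutate(sample_id = sprintf("iso%04d", dplyr::row_number()),
                  .before = 1)

  type_levels <- c("vegetation", "sheep wool", "cattle hair", "goat hair")
  type_int <- stats::setNames(c(2, 5, 5.5, 6), type_levels)
  type <- sample(type_levels, truth$n_elev_refs, replace = TRUE)
  elev_r <- stats::runif(truth$n_elev_refs, 0, 3000)
  refs <- list(
    tooth_bone = tibble::tibble(
      difference = stats::rnorm(truth$n_pairs, truth$mu_T, truth$sigma_T)),
    elevation = tibble::tibble(
      type = type, elevation = elev_r,
      d15N = type_int[type] + truth$beta_E * elev_r +
        stats::rnorm(truth$n_elev_refs, 0, truth$sigma_N)),
    tdf = tibble::tibble(
      difference = stats::rnorm(truth$n_tdf, truth$mu_delta,
                                truth$sigma_delta)),
    marine = tibble::tibble(
      d13C = stats::rnorm(20, -13, 1), d15N = stats::rnorm(20, 15, 1.5))
  )
  period_env <- tibble::tibble(period = bins$period, npp = npp, gsl = gsl)
  truth_out <- c(truth, list(
    realised = tibble::tibble(period = bins$period, baseline = baseline,
                              consumer = consumer, tp = tp,
                              n_bear = nb, n_deer = nd)))
  list(samples = samples, refs = refs, period_env = period_env,
       truth = truth_out)
}
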