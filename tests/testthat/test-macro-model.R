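# Reduced-size fits: these check wiring, determinism and design handling.
# Calibration-grade recovery runs live in test-acceptance.R.

sim_small <- function(seed = 101, missingness = 0.4, n_obs = 50) {
  simulate_macro(macro_truth(n_obs = n_obs, n_studies = 30, n_species = 4,
                             missingness = missingness, seed = seed))
}

fast_mcmc <- function(seed) {
  mcmc_config(chains = 1, iterations = 1200, burn_in = 300, thin = 1,
              seed = seed)
}

test_that("the macro fit returns a coherent posterior object", {
  sim <- sim_small()
  fit <- quiet_fit(fit_macro(sim$data, mcmc = fast_mcmc(1)))
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "npp_s", "gsl_s",
                             "subordinate", "dominant"))
  expect_true(all(td$eti50_lo >= td$eti90_lo & td$eti50_hi <= td$eti90_hi))
  expect_true(all(td$pd >= 0.5 & td$pd <= 1))
  g <- glance(fit)
  expect_equal(g$n_draws, 900)
  expect_gte(g$ppp, 0); expect_lte(g$ppp, 1)
  expect_gte(g$r2_conditional, g$r2_marginal)
  # imputed shares are proportions with one row per masked dataset
  expect_equal(nrow(fit$imputed), sum(fit$meta$needs_imputation))
  expect_true(all(fit$imputed$median >= 0 & fit$imputed$median <= 1))
})

test_that("macro fits are bit-reproducible for a fixed seed", {
  sim <- sim_small(seed = 7, n_obs = 30)
  f1 <- quiet_fit(fit_macro(sim$data, mcmc = fast_mcmc(3)))
  f2 <- quiet_fit(fit_macro(sim$data, mcmc = fast_mcmc(3)))
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_fit(fit_macro(sim$data, mcmc = fast_mcmc(4)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the two-component design splits NPP and GSL and reconstructs the
           one-component predictor", {
  sim <- sim_small(seed = 5)
  fit <- quiet_fit(fit_macro(sim$data,
                             spec = macro_model_spec(two_component = TRUE),
                             mcmc = fast_mcmc(5)))
  nm <- colnames(fit$design)
  expect_true(all(c("npp_s_between", "npp_s_within",
                    "gsl_s_between", "gsl_s_within") %in% nm))
  meta <- fit$meta
  meta$npp_chk <- as.numeric(scale(log10(meta$npp)))
  expect_equal(fit$design[, "npp_s_between"] + fit$design[, "npp_s_within"],
               meta$npp_chk, ignore_attr = TRUE)
})

test_that("degenerate inputs raise informative errors", {
  sim <- sim_small(seed = 6)
  all_missing <- dplyr::mutate(sim$data, V = NA_real_)
  expect_error(quiet_fit(fit_macro(all_missing, mcmc = fast_mcmc(1))),
               "observed volumes")
  expect_error(
    quiet_fit(fit_macro(sim$data, spec = macro_model_spec(impute = FALSE),
                        mcmc = fast_mcmc(1))),
    "imputation disabled")
  one_level <- dplyr::mutate(sim$data, npp = 1)
  expect_error(quiet_fit(fit_macro(one_level, mcmc = fast_mcmc(1))))
})

test_that("partial residuals reduce to ordinary residuals plus the component
           in a single-predictor setting", {
  sim <- sim_small(seed = 8)
  fit <- quiet_fit(fit_macro(sim$data, mcmc = fast_mcmc(2)))
  pr <- partial_residuals(fit, "gsl_s")
  beta_med <- apply(fit$beta_draws, 2, stats::median)
  manual <- fit$design[, "gsl_s"] * beta_med[["gsl_s"]] +
    fit$response - (drop(fit$design %*% beta_med) + fit$ranef_offset)
  expect_equal(pr$points$partial, manual, ignore_attr = TRUE)
  expect_error(partial_residuals(fit, "elevation"), "unknown predictor")
  p <- plot_partial(fit, "npp_s")
  expect_s3_class(p, "ggplot")
})
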