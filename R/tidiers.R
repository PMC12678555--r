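#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

fixed_effect_rows <- function(summary, stem = "beta") {
  summary |>
    dplyr::filter(grepl(paste0("^", stem, "\\["), .data$parameter)) |>
    dplyr::transmute(term = .data$term, estimate = .data$median,
                     eti50_lo = .data$eti50_lo, eti50_hi = .data$eti50_hi,
                     eti90_lo = .data$eti90_lo, eti90_hi = .data$eti90_hi,
                     pd = .data$pd, rhat = .data$rhat, ess = .data$ess)
}

#' Tidy posterior summaries of a macroecological fit
#'
#' @param x A `macro_fit`.
#' @param ... Unused.
#' @return A tibble of fixed effects with posterior medians, 50%/90%
#'   equal-tailed intervals, probability of direction and convergence
#'   diagnostics.
#' @method tidy macro_fit
#' @export
tidy.macro_fit <- function(x, ...) fixed_effect_rows(x$summary, "beta")

#' @rdname tidy.macro_fit
#' @method glance macro_fit
#' @export
glance.macro_fit <- function(x, ...) {
  tibble::tibble(
    n_datasets = nrow(x$meta),
    n_imputed = sum(x$meta$needs_imputation),
    ppp = x$diagnostics$ppp,
    r2_marginal = x$diagnostics$r2_marginal,
    r2_conditional = x$diagnostics$r2_conditional,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    n_draws = x$mcmc$chains * kept_per_chain(x$mcmc)
  )
}

#' Tidy posterior summaries of a paleoecological fit
#'
#' @param x A `paleo_fit`.
#' @param type `"regression"` for the period-level NPP/GSL effects,
#'   `"periods"` for the per-period trophic-position estimates,
#'   `"corrections"` for the offset, elevation and TDF parameters.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy paleo_fit
#' @export
tidy.paleo_fit <- function(x, type = c("regression", "periods",
                                       "corrections"), ...) {
  type <- match.arg(type)
  switch(type,
    regression = fixed_effect_rows(x$summary, "betaP"),
    periods = x$periods,
    corrections = x$summary |>
      dplyr::filter(.data$parameter %in% c("muT", "sigT", "betaE", "muD",
                                           "sigD") |
                      grepl("^typeI\\[", .data$parameter)) |>
      dplyr::select(-"parameter")
  )
}

#' @rdname tidy.paleo_fit
#' @method glance paleo_fit
#' @export
glance.paleo_fit <- function(x, ...) {
  tibble::tibble(
    n_periods = nrow(x$periods),
    n_identified = sum(x$periods$identified),
    ppp_baseline = x$diagnostics$ppp_baseline,
    ppp_consumer = x$diagnostics$ppp_consumer,
    r2_marginal = x$diagnostics$r2_marginal,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    n_draws = x$mcmc$chains * kept_per_chain(x$mcmc)
  )
}

#' Component + residual plot for a fitted model
#'
#' Observation-level partial residuals for one predictor, with the posterior
#' median partial relationship and its 50% and 90% equal-tailed bands.
#'
#' @param object A `macro_fit` or `paleo_fit`.
#' @param predictor Design column to display (e.g. `"npp_s"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_partial <- function(object, predictor, ...) {
  pr <- partial_residuals(object, predictor)
  ggplot2::ggplot(pr$line, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eti90_lo,
                                      ymax = .data$eti90_hi),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eti50_lo,
                                      ymax = .data$eti50_hi),
                         fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(data = pr$points,
                        ggplot2::aes(x = .data$x, y = .data$partial),
                        alpha = 0.6) +
    ggplot2::labs(x = predictor, y = "component + residual")
}

#' @rdname plot_partial
#' @method autoplot macro_fit
#' @export
autoplot.macro_fit <- function(object, predictor = "npp_s", ...) {
  plot_partial(object, predictor)
}

#' Trophic position through time
#'
#' Per-period posterior medians with 50% and 90% equal-tailed intervals,
#' plotted against period midpoint age (reversed axis, present on the
#' right).
#'
#' @param object A `paleo_fit`.
#' @param bins Time-bin table used to place period midpoints.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paleo_fit
#' @export
autoplot.paleo_fit <- function(object, bins = default_time_bins(), ...) {
  d <- object$periods |>
    dplyr::left_join(bins, by = "period") |>
    dplyr::mutate(mid = (.data$lower + .data$upper) / 2) |>
    dplyr::filter(.data$identified)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$tp_median)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$tp_eti90_lo,
                                         ymax = .data$tp_eti90_hi),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$tp_eti50_lo,
                                         ymax = .data$tp_eti50_hi),
                            linewidth = 1.1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (ka BP)", y = "trophic position")
}
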