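#' Run a JAGS model deterministically
#'
#' Compiles and samples a JAGS model with per-chain Mersenne-Twister RNGs
#' seeded from the configuration seed, so identical inputs give bit-identical
#' draws.
#'
#' @param model_string JAGS model code.
#' @param data Named list of data.
#' @param monitor Character vector of nodes to monitor.
#' @param config An [mcmc_config()].
#' @param inits Optional function(chain) returning a named list of initial
#'   values (RNG settings are added automatically).
#' @return A tibble in the long draw format (`chain`, `iteration`,
#'   `parameter`, `value`).
#' @keywords internal
run_jags <- function(model_string, data, monitor, config,
                     inits = NULL) {
  init_list <- lapply(seq_len(config$chains), function(ch) {
    ini <- if (is.null(inits)) list() else inits(ch)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (config$seed * 1000L + ch) %% .Machine$integer.max
    ini
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = init_list, n.chains = config$chains,
                          n.adapt = config$burn_in, quiet = TRUE)
  niter <- config$iterations - config$burn_in
  samples <- rjags::coda.samples(jm, variable.names = monitor,
                                 n.iter = niter, thin = config$thin)
  draws_from_coda(samples)
}

# Common prior fragments: variance-scale priors are parameterised through a
# half-t(df = 2, scale = 1) on the SD, the stated marginal of the scaled
# inverse gamma / scaled inverse Wishart priors with s = 1, df = 2.
jags_half_t <- function(sd_node) {
  paste0(sd_node, " ~ dt(0, 1, 2) T(0,)\n")
}
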