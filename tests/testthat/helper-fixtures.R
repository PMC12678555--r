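# Small in-code fixtures shared across test files.

# Item-level diet table with three datasets: two fully observed, one with
# volumes missing (flagged for imputation by the reader).
toy_diet_table <- function() {
  tibble::tibble(
    dataset_id = rep(c("d1", "d2", "d3"), each = 2),
    study_id = rep(c("s1", "s1", "s2"), each = 2),
    species = rep(c("sp1", "sp1", "sp2"), each = 2),
    lat = 45, lon = 10,
    sample_type = "scat",
    n_samples = 50L,
    category = rep(c("ungulates", "graminoids"), 3),
    F = c(0.4, 0.6, 0.3, 0.7, 0.5, 0.5),
    V = c(0.5, 0.5, 0.2, 0.8, NA, NA),
    npp = rep(c(0.5, 0.8, 1.2), each = 2),
    gsl = rep(c(6L, 8L, 10L), each = 2),
    co_occurrence = rep(c("none", "subordinate", "dominant"), each = 2)
  )
}

# Six isotope samples with hand-set QC chemistry; the expected pass set is
# counted by hand in the tests.
toy_isotope_qc <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:6),
    cn_atomic = c(3.2, 2.8, 3.0, 3.6, 3.7, NA),
    pctC = c(40, 40, 8, 35, 41, 38),
    pctN = c(15, 15, 3.0, 12, 14, 13)
  )
}

quiet_fit <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

# suppress convergence warnings but let messages through
quiet_fit2 <- function(expr) {
  suppressWarnings(expr)
}
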