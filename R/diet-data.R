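#' Default diet-category reference table
#'
#' The 20 controlled food-item categories used to describe annual bear diets
#' from micro-histological scat and stomach-content analyses, together with
#' their trophic class and the correction factors applied when converting
#' relative volumes into relative dietary energy contributions:
#' `c_D` corrects for digestibility of the ingested material and `c_E` for
#' its energy content.
#'
#' The shipped `c_D`/`c_E` values are placeholders in literature-plausible
#' ranges (animal tissue digestible and energy dense, graminoids and browse
#' much less so). Analyses of real data should supply a calibrated table via
#' the `categories` argument of [energy_contribution()] and the fitting
#' functions; every function in the package treats this table as
#' configuration, not as a constant.
#'
#' @return A tibble with columns `category`, `trophic_class` (one of
#'   `animal_vertebrate`, `animal_invertebrate`, `plant`, `fungi`, `other`),
#'   `c_D` and `c_E` (both positive, dimensionless).
#' @export
#' @examples
#' default_diet_categories()
default_diet_categories <- function() {
  tibble::tribble(
    ~category,             ~trophic_class,        ~c_D, ~c_E,
    "ungulates",           "animal_vertebrate",   0.90, 2.0,
    "small_mammals",       "animal_vertebrate",   0.90, 2.0,
    "carrion",             "animal_vertebrate",   0.90, 2.0,
    "fish",                "animal_vertebrate",   0.90, 2.2,
    "birds",               "animal_vertebrate",   0.90, 2.0,
    "herptiles",           "animal_vertebrate",   0.90, 1.8,
    "social_insects",      "animal_invertebrate", 0.80, 1.6,
    "other_insects",       "animal_invertebrate", 0.80, 1.6,
    "other_invertebrates", "animal_invertebrate", 0.80, 1.5,
    "fleshy_fruits",       "plant",               0.65, 1.0,
    "hard_mast",           "plant",               0.70, 1.5,
    "seeds",               "plant",               0.70, 1.4,
    "graminoids",          "plant",               0.30, 0.8,
    "forbs",               "plant",               0.35, 0.8,
    "browse_foliage",      "plant",               0.30, 0.8,
    "roots_tubers",        "plant",               0.55, 1.0,
    "bamboo",              "plant",               0.25, 0.7,
    "crops",               "plant",               0.75, 1.3,
    "fungi",               "fungi",               0.45, 0.7,
    "other_debris",        "other",               0.30, 0.5
  )
}

#' Trophic classes counted as animal prey
#'
#' Vertebrate and invertebrate prey both contribute to the animal-prey energy
#' share; carrion is classed with vertebrates.
#' @keywords internal
animal_classes <- function() c("animal_vertebrate", "animal_invertebrate")

validate_categories <- function(categories) {
  stopifnot(is.data.frame(categories))
  needed <- c("category", "trophic_class", "c_D", "c_E")
  missing <- setdiff(needed, names(categories))
  if (length(missing) > 0) {
    stop("categories table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(categories$category)) {
    stop("categories table has duplicated category names", call. = FALSE)
  }
  bad_class <- setdiff(
    unique(categories$trophic_class),
    c("animal_vertebrate", "animal_invertebrate", "plant", "fungi", "other")
  )
  if (length(bad_class) > 0) {
    stop("unknown trophic_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(categories$c_D)) || any(categories$c_D <= 0) ||
      any(!is.finite(categories$c_E)) || any(categories$c_E <= 0)) {
    stop("correction factors c_D and c_E must be finite and > 0",
         call. = FALSE)
  }
  invisible(categories)
}

#' Normalise occurrence counts to relative frequencies
#'
#' Converts per-category occurrence counts into relative frequencies of
#' occurrence: each count divided by the total number of occurrences.
#'
#' @param counts Named numeric vector of non-negative occurrence counts (or
#'   already-proportional quantities), one element per food category.
#' @return Named numeric vector of proportions summing to 1; zero-count
#'   categories map to 0.
#' @export
#' @examples
#' normalize_frequencies(c(a = 3, b = 1, c = 4))
normalize_frequencies <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0) {
    stop("counts must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("invalid composition: all counts are zero", call. = FALSE)
  }
  counts / total
}

#' Relative dietary energy contribution and animal-prey energy share
#'
#' Converts relative volumes of food items into relative dietary energy
#' contributions by weighting each item's volume with its digestibility
#' (`c_D`) and energy-content (`c_E`) correction factors and renormalising:
#' \deqn{E_i = c_{D_i} c_{E_i} V_i / \sum_i c_{D_i} c_{E_i} V_i.}
#' The animal-prey energy share \eqn{P} is the sum of \eqn{E_i} over
#' categories whose trophic class is vertebrate or invertebrate prey.
#'
#' @param data Data frame with columns `dataset_id`, `category` and `V`
#'   (relative volume; must sum to 1 within each dataset).
#' @param categories Category reference table, see
#'   [default_diet_categories()].
#' @param tol Tolerance for the compositional sum check.
#' @return A tibble with one row per `dataset_id` x `category` carrying `E`,
#'   plus the per-dataset animal-prey share `P` (repeated within a dataset).
#' @export
#' @examples
#' d <- tibble::tibble(dataset_id = "d1",
#'                     category = c("ungulates", "graminoids"),
#'                     V = c(0.5, 0.5))
#' energy_contribution(d, default_diet_categories())
energy_contribution <- function(data, categories = default_diet_categories(),
                                tol = 1e-9) {
  validate_categories(categories)
  stopifnot(is.data.frame(data), all(c("dataset_id", "category", "V") %in% names(data)))
  unknown <- setdiff(unique(data$category), categories$category)
  if (length(unknown) > 0) {
    stop("no correction factors configured for category: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sums <- tapply(data$V, data$dataset_id, sum)
  off <- names(sums)[abs(sums - 1) > tol]
  if (length(off) > 0) {
    stop("relative volumes do not sum to 1 in dataset(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::left_join(categories, by = "category") |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(
      E = .data$c_D * .data$c_E * .data$V /
        sum(.data$c_D * .data$c_E * .data$V),
      P = sum(.data$E[.data$trophic_class %in% animal_classes()])
    ) |>
    dplyr::ungroup() |>
    dplyr::select("dataset_id", "category", "trophic_class", "V", "E", "P")
}

#' Compress proportions away from 0/1 and probit-transform
#'
#' Proportions on the closed interval \[0, 1\] are first compressed into the
#' open interval with \eqn{(P(n - 1) + 0.5)/n}, where `n` is the number of
#' observations in the modelled dataset, and then probit-transformed. The
#' compression is required because the probit function is undefined at 0
#' and 1.
#'
#' Note that with boundary values `P = 0` or `P = 1` the compressed value is
#' `0.5/n` (resp. `1 - 0.5/n`), so the attainable probit range depends on
#' `n`; `n` is therefore an explicit argument rather than a constant.
#'
#' @param p Numeric vector of proportions in \[0, 1\].
#' @param n Number of observations used in the compression (>= 2).
#' @return Numeric vector of finite probit-scale values.
#' @seealso [probit_expand()] for the exact inverse.
#' @export
#' @examples
#' probit_compress(c(0, 0.5, 1), n = 210)
probit_compress <- function(p, n) {
  stopifnot(length(n) == 1, is.finite(n), n >= 2)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  stats::qnorm((p * (n - 1) + 0.5) / n)
}

#' Invert the probit compression
#'
#' @param y Numeric vector on the probit scale.
#' @inheritParams probit_compress
#' @return Proportions on the original scale.
#' @export
probit_expand <- function(y, n) {
  stopifnot(length(n) == 1, is.finite(n), n >= 2)
  (stats::pnorm(y) * n - 0.5) / (n - 1)
}

#' Read a diet-composition table
#'
#' Reads a delimited table with one row per `dataset_id` x `category` and
#' validates it into per-dataset diet records. Expected columns:
#' `dataset_id`, `study_id`, `species`, `lat`, `lon`, `sample_type`,
#' `n_samples`, `category`, `F`, `V` (may be empty), `npp`, `gsl`,
#' `co_occurrence`. Datasets whose `V` column is entirely missing are flagged
#' `needs_imputation`.
#'
#' @param path Path to a CSV (or TSV, auto-detected by [readr::read_delim()]
#'   conventions via [readr::read_csv()] / [readr::read_tsv()]).
#' @param categories Category reference table used to validate category
#'   labels.
#' @param tol Tolerance for compositional sum checks.
#' @return A tibble of item-level rows (validated), with per-dataset metadata
#'   repeated and a logical `needs_imputation` column.
#' @export
#' @examples
#' path <- system.file("extdata", "example_diet_synthetic.csv",
#'                     package = "beartroph")
#' read_diet_table(path)
read_diet_table <- function(path, categories = default_diet_categories(),
                            tol = 1e-9) {
  validate_categories(categories)
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE)
  validate_diet_table(raw, categories = categories, tol = tol)
}

#' Validate an in-memory diet-composition table
#'
#' @param data Data frame in the layout documented in [read_diet_table()].
#' @inheritParams read_diet_table
#' @return Validated tibble with a `needs_imputation` flag per dataset.
#' @export
validate_diet_table <- function(data, categories = default_diet_categories(),
                                tol = 1e-9) {
  needed <- c("dataset_id", "study_id", "species", "sample_type", "n_samples",
              "category", "F", "npp", "gsl", "co_occurrence")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("diet table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"V" %in% names(data)) data$V <- NA_real_
  unknown <- setdiff(unique(data$category), categories$category)
  if (length(unknown) > 0) {
    bad_rows <- which(data$category %in% unknown)
    stop("unknown category at row(s) ", paste(utils::head(bad_rows, 5), collapse = ", "),
         ": ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_cooc <- setdiff(unique(data$co_occurrence), c("none", "subordinate", "dominant"))
  if (length(bad_cooc) > 0) {
    stop("co_occurrence must be none/subordinate/dominant, got: ",
         paste(bad_cooc, collapse = ", "), call. = FALSE)
  }
  if (any(!data$gsl %in% 0:12)) {
    stop("gsl must be an integer number of months in 0..12", call. = FALSE)
  }
  if (any(!is.finite(data$npp)) || any(data$npp <= 0)) {
    stop("npp must be finite and > 0", call. = FALSE)
  }
  out <- data |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(needs_imputation = all(is.na(.data$V))) |>
    dplyr::ungroup()

  check_comp <- function(x, label, id) {
    if (all(is.na(x))) return(invisible(NULL))
    if (any(is.na(x))) {
      stop("dataset ", id, ": ", label,
           " is partially missing (must be all present or all missing)",
           call. = FALSE)
    }
    if (any(x < 0 | x > 1)) {
      stop("dataset ", id, ": ", label, " outside [0, 1]", call. = FALSE)
    }
    if (abs(sum(x) - 1) > tol) {
      stop("dataset ", id, ": ", label, " sums to ", signif(sum(x), 6),
           ", not 1", call. = FALSE)
    }
  }
  split_idx <- split(seq_len(nrow(out)), out$dataset_id)
  for (id in names(split_idx)) {
    i <- split_idx[[id]]
    check_comp(out$F[i], "relative frequency F", id)
    check_comp(out$V[i], "relative volume V", id)
  }
  tibble::as_tibble(out)
}
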