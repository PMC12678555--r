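#' Collagen quality control
#'
#' Reliability screen for collagen isotope measurements: a sample passes when
#' the atomic C/N ratio lies in the well-preserved-collagen range 2.9-3.6
#' (endpoints included) and the carbon and nitrogen contents are above 8% and
#' 3% respectively (strict). Samples missing any QC field fail with reason
#' `"missing QC field"`.
#'
#' @param samples Data frame with columns `sample_id`, `cn_atomic`, `pctC`,
#'   `pctN` (other columns are carried through untouched).
#' @return The input as a tibble with logical `qc_pass` and a character
#'   `qc_reasons` column (`""` for passing samples; failed criteria are
#'   `;`-separated).
#' @export
#' @examples
#' qc_collagen(data.frame(sample_id = "s1", cn_atomic = 3.2,
#'                        pctC = 40, pctN = 15))
qc_collagen <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("cn_atomic", "pctC", "pctN") %in% names(samples)))
  reasons <- purrr::pmap_chr(
    samples[c("cn_atomic", "pctC", "pctN")],
    function(cn_atomic, pctC, pctN) {
      if (anyNA(c(cn_atomic, pctC, pctN))) return("missing QC field")
      r <- character()
      if (cn_atomic < 2.9) r <- c(r, "C/N below 2.9")
      if (cn_atomic > 3.6) r <- c(r, "C/N above 3.6")
      if (pctC <= 8) r <- c(r, "%C not above 8")
      if (pctN <= 3) r <- c(r, "%N not above 3")
      paste(r, collapse = ";")
    })
  samples |>
    tibble::as_tibble() |>
    dplyr::mutate(qc_pass = reasons == "", qc_reasons = reasons)
}

#' Default time bins for the paleoecological analysis
#'
#' Eight periods covering the last 55 ka BP, from the Meghalayan back to
#' Greenland Stadial 9 - Greenland Interstadial 14, following current
#' stratigraphic stage definitions. Note the unbinned dating gap at
#' 38.2-43.8 ka BP.
#'
#' @return A tibble with columns `period`, `lower`, `upper` (ka BP).
#' @export
default_time_bins <- function() {
  tibble::tribble(
    ~period,         ~lower, ~upper,
    "Meghalayan",       0,      4.2,
    "Northgrippian",    4.2,    8.2,
    "Greenlandian",     8.2,   11.7,
    "GS-1",            11.7,   12.8,
    "GI-1",            12.8,   14.6,
    "GS-2 to GI-2",    14.6,   23.3,
    "GS-3 to GI-8",    23.3,   38.2,
    "GS-9 to GI-14",   43.8,   54.2
  )
}

#' Assign calibrated ages to time bins
#'
#' Each age (point value, ka BP) is assigned to the bin whose half-open
#' interval `[lower, upper)` contains it, so a boundary age belongs to the
#' younger-bounded bin (e.g. 11.7 ka falls in GS-1, not the Greenlandian).
#' Ages in the 38.2-43.8 ka gap or beyond the oldest bin map to `NA`.
#'
#' @param age Numeric vector of calibrated ages in ka BP (>= 0).
#' @param bins Bin table as in [default_time_bins()].
#' @return Character vector of period names (`NA` where unbinned).
#' @export
#' @examples
#' assign_period(c(10, 40, 11.7))
assign_period <- function(age, bins = default_time_bins()) {
  stopifnot(all(c("period", "lower", "upper") %in% names(bins)))
  if (any(age < 0, na.rm = TRUE)) stop("ages must be >= 0", call. = FALSE)
  ord <- bins[order(bins$lower), ]
  if (any(utils::head(ord$upper, -1) > utils::tail(ord$lower, -1) + 1e-12)) {
    stop("configuration error: overlapping time bins", call. = FALSE)
  }
  vapply(age, function(a) {
    if (is.na(a)) return(NA_character_)
    hit <- which(a >= ord$lower & a < ord$upper)
    if (length(hit) == 0) NA_character_ else ord$period[hit[1]]
  }, character(1))
}

#' Screen bear samples for a marine isotopic signature
#'
#' Flags samples whose (d13C, d15N) values fall inside a marine envelope
#' built from reference measurements of marine mammals: the convex hull of
#' the reference points, expanded outward by `expand` per mil in both axes.
#' This is a diagnostic screen, not a mixing model: consumers of marine
#' resources (e.g. anadromous fish) show much higher d13C and d15N than
#' terrestrial herbivores, so terrestrial samples should sit far outside the
#' envelope.
#'
#' @param samples Data frame with columns `sample_id`, `d13C`, `d15N`.
#' @param marine_refs Data frame of marine reference values with columns
#'   `d13C`, `d15N` (>= 3 points).
#' @param expand Envelope expansion in per mil applied to both axes.
#' @return A list with `samples` (input plus logical `marine_flag`) and
#'   `summary` (tibble with `n`, `n_flagged`, `flagged_fraction`).
#' @export
marine_screen <- function(samples, marine_refs, expand = 1) {
  stopifnot(all(c("d13C", "d15N") %in% names(samples)),
            all(c("d13C", "d15N") %in% names(marine_refs)),
            nrow(marine_refs) >= 3)
  pts <- as.matrix(marine_refs[, c("d13C", "d15N")])
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ctr <- colMeans(hull)
  hull_exp <- sweep(hull, 2, ctr) |>
    apply(2, function(v) v + expand * sign(v)) |>
    sweep(2, ctr, FUN = "+")
  bnd <- rbind(hull_exp, hull_exp[1, ])
  flag <- mgcv::in.out(bnd, as.matrix(samples[, c("d13C", "d15N")]))
  out <- dplyr::mutate(tibble::as_tibble(samples), marine_flag = flag)
  list(
    samples = out,
    summary = tibble::tibble(n = nrow(out), n_flagged = sum(flag),
                             flagged_fraction = mean(flag))
  )
}

#' Read and validate an isotope sample table
#'
#' Expected columns: `sample_id`, `taxon` (`brown_bear` or `red_deer`),
#' `d15N`, `d13C`, `pctC`, `pctN`, `cn_atomic`, `material` (`bone` or
#' `tooth`), `elevation`, `age` (calibrated ka BP). QC flags and period
#' assignments are added.
#'
#' @param path CSV path.
#' @param bins Time-bin table.
#' @return Validated tibble with `qc_pass`, `qc_reasons` and `period`.
#' @export
#' @examples
#' path <- system.file("extdata", "example_isotopes_synthetic.csv",
#'                     package = "beartroph")
#' read_isotope_table(path)
read_isotope_table <- function(path, bins = default_time_bins()) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  validate_isotope_table(raw, bins = bins)
}

#' @rdname read_isotope_table
#' @param data In-memory data frame in the same layout.
#' @export
validate_isotope_table <- function(data, bins = default_time_bins()) {
  needed <- c("sample_id", "taxon", "d15N", "pctC", "pctN", "cn_atomic",
              "material", "elevation", "age")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("isotope table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_taxon <- setdiff(unique(data$taxon), c("brown_bear", "red_deer"))
  if (length(bad_taxon) > 0) {
    stop("taxon must be brown_bear or red_deer, got: ",
         paste(bad_taxon, collapse = ", "), call. = FALSE)
  }
  bad_mat <- setdiff(unique(data$material), c("bone", "tooth"))
  if (length(bad_mat) > 0) {
    stop("material must be bone or tooth, got: ",
         paste(bad_mat, collapse = ", "), call. = FALSE)
  }
  data |>
    qc_collagen() |>
    dplyr::mutate(period = assign_period(.data$age, bins = bins))
}
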