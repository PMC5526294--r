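#' Assay panel QC thresholds
#'
#' Per-analyte acceptance thresholds for the five multiplexed
#' electrochemiluminescence panels: dilution factor, maximum allowable
#' duplicate CV, Hill-slope limits, and the observed lower/upper limits of
#' quantitation (LLoQ/ULoQ, on the diluted-sample scale). Shipped as a
#' packaged config pre-filled with the study panel's values; any column can
#' be overridden.
#'
#' @param overrides optional data frame with an `analyte` column plus any
#'   subset of the threshold columns; matching rows replace packaged values.
#' @param r2_min minimum weighted R-squared for standard-curve acceptance.
#' @param pqc_ranges optional tibble (`analyte`, `pqc_lo`, `pqc_hi`) of
#'   process-quality-control concentration acceptance ranges (diluted scale).
#'   When absent, ranges are derived by [simulate_plates()] provenance or can
#'   be attached later with [pqc_ranges_from_pool()].
#'
#' @return A tibble of class `qc_thresholds` with one row per analyte and
#'   columns `panel`, `protein`, `analyte`, `dilution_factor`, `cv_max`,
#'   `hill_min`, `hill_max`, `lloq`, `uloq`, plus attributes `r2_min` and
#'   (optionally) `pqc_ranges`.
#' @export
#' @examples
#' th <- qc_thresholds()
#' dplyr::filter(th, analyte == "TFRC")
qc_thresholds <- function(overrides = NULL, r2_min = 0.95, pqc_ranges = NULL) {
  path <- system.file("extdata", "panel_thresholds.csv", package = "seropanel")
  th <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "analyte" %in% names(overrides))
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$analyte[i], th$analyte)
      if (is.na(j)) abort(sprintf("unknown analyte '%s'", overrides$analyte[i]))
      for (col in setdiff(names(overrides), "analyte")) {
        th[[col]][j] <- overrides[[col]][i]
      }
    }
  }
  bad <- th$hill_min >= th$hill_max | th$lloq >= th$uloq | th$cv_max <= 0
  if (any(bad)) abort("invalid thresholds: need hill_min < hill_max, lloq < uloq, cv_max > 0")
  attr(th, "r2_min") <- r2_min
  attr(th, "pqc_ranges") <- pqc_ranges
  class(th) <- c("qc_thresholds", class(th))
  th
}

#' Derive PQC acceptance ranges from a pooled-plasma concentration
#'
#' PQC (process quality control) wells contain a fixed pooled-plasma sample;
#' a plate passes only if its measured PQC concentrations fall inside
#' pre-established ranges. With no published ranges, the default is the
#' central interval of the measurement distribution implied by the pool
#' concentration and the assay's duplicate noise.
#'
#' @param pool tibble (`analyte`, `pqc_conc`) of pool concentrations on the
#'   diluted scale.
#' @param noise_cv expected duplicate coefficient of variation (fraction).
#' @param coverage central coverage of the acceptance interval.
#' @return tibble (`analyte`, `pqc_lo`, `pqc_hi`).
#' @export
pqc_ranges_from_pool <- function(pool, noise_cv, coverage = 0.99) {
  z <- qnorm(1 - (1 - coverage) / 2)
  # Back-calculated concentration inherits (to first order) the response CV
  # at unit local slope; allow 3x headroom for curve-slope amplification.
  half <- pmax(3 * z * noise_cv, 0.02)
  tibble::tibble(
    analyte = pool$analyte,
    pqc_lo = pool$pqc_conc * (1 - half),
    pqc_hi = pool$pqc_conc * (1 + half)
  )
}
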