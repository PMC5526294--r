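#' Fit a four-parameter logistic standard curve
#'
#' Weighted least-squares fit of `y = d + (a - d) / (1 + (x/c)^b)` with
#' `1/y^2` weighting (observed response), the standard reduction used for
#' immunoassay calibration where the response CV, not the response SD, is
#' roughly constant. Initialization: `a` = minimum response, `d` = maximum
#' response, `b = 1`, `c` = concentration nearest the half-range response;
#' Levenberg-Marquardt iteration to relative tolerance 1e-10.
#'
#' @param standards data frame with columns `concentration` (diluted scale,
#'   pg/mL; the blank is concentration 0) and `response` (ECL counts),
#'   duplicates as separate rows.
#' @param panel_id optional identifier carried on the result.
#' @return object of class `standard_curve`: parameters `a`, `d`, `c`, `b`,
#'   the weighted `r_squared`, and the standards used.
#' @export
#' @examples
#' std <- data.frame(concentration = c(0, 10, 100, 1000, 10000),
#'                   response = fourpl(c(0, 10, 100, 1000, 10000),
#'                                     50, 30000, 500, 1))
#' fit_standard_curve(std)
fit_standard_curve <- function(standards, panel_id = NA) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "response") %in% names(standards)))
  x <- standards$concentration
  y <- standards$response
  if (length(unique(x)) < 5L) {
    abort("need at least 5 distinct standard levels spanning the response range")
  }
  w <- 1 / y^2
  a0 <- min(y); d0 <- max(y)
  half <- (a0 + d0) / 2
  pos <- x > 0
  c0 <- x[pos][which.min(abs(y[pos] - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (x / c)^b),
      start = list(a = a0, d = d0, c = c0, b = 1),
      weights = w,
      lower = c(a = -Inf, d = -Inf, c = 1e-12, b = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                           ptol = 1e-10)
    ),
    error = function(e) {
      abort(sprintf("4PL fit did not converge: %s", conditionMessage(e)))
    }
  )
  p <- as.list(coef(fit))
  yhat <- fourpl(x, p$a, p$d, p$c, p$b)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
  structure(
    list(a = p$a, d = p$d, c = p$c, b = p$b, r_squared = r2,
         panel_id = panel_id, n_levels = length(unique(x)),
         standards = tibble(concentration = x, response = y)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> 4PL: a=%.4g d=%.4g c=%.4g b=%.4g  (weighted R^2 = %.4f)\n",
    x$a, x$d, x$c, x$b, x$r_squared))
  invisible(x)
}

#' Back-calculate concentrations from assay responses
#'
#' Inverts the 4PL to a diluted-scale concentration, flags values outside
#' the quantitation limits (clamping to the violated limit rather than
#' dropping, so downstream stages can choose exclusion), and multiplies by
#' the panel's dilution factor for the reported sample-scale value.
#' Responses outside the open response range `(min(a,d), max(a,d))` cannot
#' be inverted and come back unquantifiable.
#'
#' @param curve a [fit_standard_curve()] result (or list with `a,d,c,b`).
#' @param response numeric vector of ECL responses.
#' @param dilution_factor panel dilution factor (>= 1).
#' @param lloq,uloq quantitation limits on the diluted scale.
#' @return tibble with `response`, `conc_diluted` (clamped), `conc`
#'   (sample scale), and flags `below_lloq`, `above_uloq`, `quantifiable`.
#' @export
backcalculate <- function(curve, response, dilution_factor, lloq, uloq) {
  if (dilution_factor < 1) abort("`dilution_factor` must be >= 1")
  a <- curve$a; d <- curve$d; c <- curve$c; b <- curve$b
  lo <- min(a, d); hi <- max(a, d)
  ok <- is.finite(response) & response > lo & response < hi
  x <- rep(NA_real_, length(response))
  r <- (a - d) / (response[ok] - d) - 1
  x[ok] <- c * r^(1 / b)
  below <- ok & x < lloq
  above <- ok & x > uloq
  xc <- pmin(pmax(x, lloq), uloq)
  xc[!ok] <- NA_real_
  tibble(
    response = response,
    conc_diluted = xc,
    conc = xc * dilution_factor,
    below_lloq = below,
    above_uloq = above,
    quantifiable = ok
  )
}

#' Duplicate coefficient of variation
#'
#' Percent CV of a duplicate pair with the n-1 denominator (bioanalytical
#' convention): `100 * |r1 - r2| / (sqrt(2) * mean)`. Scale-invariant.
#'
#' @param reading1,reading2 paired readings in the same units (positive).
#' @return percent CV, vectorized.
#' @export
#' @examples
#' duplicate_cv(90, 110)   # 14.14
duplicate_cv <- function(reading1, reading2) {
  m <- (reading1 + reading2) / 2
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("duplicate CV undefined: non-positive or non-finite mean reading")
  }
  100 * abs(reading1 - reading2) / (sqrt(2) * m)
}

#' Plate acceptance decision
#'
#' A plate is accepted iff, for every analyte on it: (1) the standard curve
#' is sound (Hill slope within the analyte's limits and weighted
#' R^2 >= `r2_min`), (2) PQC concentrations fall within pre-established
#' ranges, and (3) PQC duplicate CVs are below the CV maxima. Reasons list
#' every failed criterion.
#'
#' @param curves named list of [fit_standard_curve()] results, one per
#'   analyte on the plate.
#' @param pqc_records data frame with columns `analyte`, `response_1`,
#'   `response_2`, `conc_1`, `conc_2` (diluted-scale back-calculations of
#'   the duplicate PQC wells).
#' @param thresholds a [qc_thresholds()] table.
#' @param pqc_ranges tibble (`analyte`, `pqc_lo`, `pqc_hi`); defaults to
#'   the ranges attached to `thresholds`.
#' @return list with `accept` (logical) and `reasons` (character vector,
#'   empty when accepted).
#' @export
accept_plate <- function(curves, pqc_records, thresholds,
                         pqc_ranges = attr(thresholds, "pqc_ranges")) {
  analytes <- names(curves)
  if (is.null(pqc_records) || nrow(pqc_records) == 0L) {
    abort("cannot evaluate plate: PQC records missing")
  }
  if (!all(analytes %in% pqc_records$analyte)) {
    abort(sprintf("cannot evaluate plate: PQC records missing for %s",
                  paste(setdiff(analytes, pqc_records$analyte), collapse = ", ")))
  }
  if (is.null(pqc_ranges)) {
    abort("no PQC acceptance ranges available (see `pqc_ranges_from_pool()`)")
  }
  r2_min <- attr(thresholds, "r2_min") %||% 0.95
  reasons <- character()
  for (an in analytes) {
    th <- thresholds[thresholds$analyte == an, ]
    cu <- curves[[an]]
    if (cu$b < th$hill_min || cu$b > th$hill_max) {
      reasons <- c(reasons, sprintf("%s: Hill slope %.3f outside [%.2f, %.2f]",
                                    an, cu$b, th$hill_min, th$hill_max))
    }
    if (cu$r_squared < r2_min) {
      reasons <- c(reasons, sprintf("%s: R^2 %.4f below %.2f", an,
                                    cu$r_squared, r2_min))
    }
    pq <- pqc_records[pqc_records$analyte == an, ]
    rng <- pqc_ranges[pqc_ranges$analyte == an, ]
    pqc_conc <- mean(c(pq$conc_1, pq$conc_2))
    if (nrow(rng) && (!is.finite(pqc_conc) || pqc_conc < rng$pqc_lo ||
                      pqc_conc > rng$pqc_hi)) {
      reasons <- c(reasons, sprintf("%s: PQC concentration outside range", an))
    }
    if (duplicate_cv(pq$response_1, pq$response_2) >= th$cv_max) {
      reasons <- c(reasons, sprintf("%s: PQC duplicate CV above %.0f%%",
                                    an, th$cv_max))
    }
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Sample-level measure acceptance
#'
#' Sample measures from accepted plates are retained when their duplicate
#' CV is at or below the analyte's maximum; the retained concentration is
#' the mean of the duplicate back-calculations. Rejected measures are
#' logged with the reason. Never invents rows.
#'
#' @param records data frame with columns `subject_id`, `analyte`,
#'   `response_1`, `response_2`, `conc_1`, `conc_2` (sample scale) and
#'   optionally flag columns `below_lloq`, `above_uloq`.
#' @param thresholds a [qc_thresholds()] table.
#' @return list with `accepted` (wide tibble, `subject_id` x analytes;
#'   long flags in attribute `"flags"`) and `rejections` (tibble
#'   `subject_id`, `analyte`, `cv`, `reason`).
#' @export
accept_measures <- function(records, thresholds) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(accepted = tibble(subject_id = character()),
                rejections = tibble(subject_id = character(),
                                    analyte = character(), cv = numeric(),
                                    reason = character())))
  }
  cv <- duplicate_cv(records$response_1, records$response_2)
  cv_max <- thresholds$cv_max[match(records$analyte, thresholds$analyte)]
  keep <- cv <= cv_max
  quant <- if ("quantifiable" %in% names(records)) {
    records$quantifiable
  } else {
    rep(TRUE, nrow(records))
  }
  keep <- keep & quant
  rejections <- tibble(
    subject_id = records$subject_id[!keep],
    analyte = records$analyte[!keep],
    cv = cv[!keep],
    reason = ifelse(!quant[!keep], "unquantifiable", "cv_fail")
  )
  acc <- records[keep, ]
  acc$conc <- (acc$conc_1 + acc$conc_2) / 2
  wide <- tidyr::pivot_wider(
    dplyr::select(acc, "subject_id", "analyte", "conc"),
    names_from = "analyte", values_from = "conc"
  )
  flags <- dplyr::select(acc, dplyr::any_of(
    c("subject_id", "analyte", "below_lloq", "above_uloq")))
  attr(wide, "flags") <- flags
  list(accepted = wide, rejections = rejections)
}

#' Run the full plate QC workflow on a simulated (or imported) plate set
#'
#' Per plate and analyte: fits the 4PL standard curve from the duplicate
#' standards, back-calculates PQC and sample wells, applies
#' [accept_plate()]; samples from accepted plates then pass through
#' [accept_measures()]. Out-of-quantitation values are clamped and flagged,
#' not dropped.
#'
#' @param plates a [simulate_plates()] table (long format).
#' @param thresholds a [qc_thresholds()] table; PQC ranges default to the
#'   central 99% interval implied by the plate set's pool and noise.
#' @return list: `concentrations` (wide tibble of accepted means,
#'   sample scale), `plate_log` (per plate/analyte-set acceptance with
#'   reasons), `rejections` (sample-level log), `curves` (per-plate fits).
#' @export
run_qc <- function(plates, thresholds = attr(plates, "thresholds") %||% qc_thresholds()) {
  pqc_ranges <- attr(thresholds, "pqc_ranges")
  if (is.null(pqc_ranges) && !is.null(attr(plates, "pqc_pool"))) {
    pqc_ranges <- pqc_ranges_from_pool(attr(plates, "pqc_pool"),
                                       attr(plates, "noise_cv") %||% 0.05)
  }
  plate_ids <- unique(plates$plate_id)
  plate_log <- vector("list", length(plate_ids))
  all_records <- vector("list", length(plate_ids))
  all_curves <- list()
  for (k in seq_along(plate_ids)) {
    pid <- plate_ids[k]
    pd <- plates[plates$plate_id == pid, ]
    analytes <- unique(pd$analyte)
    curves <- list()
    pqc_list <- list()
    rec_list <- list()
    for (an in analytes) {
      th <- thresholds[thresholds$analyte == an, ]
      ad <- pd[pd$analyte == an, ]
      std <- ad[ad$role == "standard", ]
      curve <- fit_standard_curve(
        data.frame(concentration = std$true_conc, response = std$response),
        panel_id = th$panel
      )
      curves[[an]] <- curve
      bc <- function(resp) backcalculate(curve, resp, th$dilution_factor,
                                         th$lloq, th$uloq)
      pq <- ad[ad$role == "pqc", ]
      pq1 <- bc(pq$response[pq$replicate == 1])
      pq2 <- bc(pq$response[pq$replicate == 2])
      pqc_list[[an]] <- tibble(analyte = an,
                               response_1 = pq1$response, response_2 = pq2$response,
                               conc_1 = pq1$conc_diluted, conc_2 = pq2$conc_diluted)
      sa <- ad[ad$role == "sample", ]
      s1 <- sa[sa$replicate == 1, ]
      s2 <- sa[sa$replicate == 2, ]
      b1 <- bc(s1$response)
      b2 <- bc(s2$response)
      rec_list[[an]] <- tibble(
        subject_id = s1$subject_id, analyte = an,
        response_1 = b1$response, response_2 = b2$response,
        conc_1 = b1$conc, conc_2 = b2$conc,
        below_lloq = b1$below_lloq | b2$below_lloq,
        above_uloq = b1$above_uloq | b2$above_uloq,
        quantifiable = b1$quantifiable & b2$quantifiable
      )
    }
    pqc_records <- dplyr::bind_rows(pqc_list)
    dec <- accept_plate(curves, pqc_records, thresholds, pqc_ranges)
    plate_log[[k]] <- tibble(plate_id = pid, accept = dec$accept,
                             reasons = paste(dec$reasons, collapse = "; "))
    all_curves[[pid]] <- curves
    if (dec$accept) all_records[[k]] <- dplyr::bind_rows(rec_list)
  }
  records <- dplyr::bind_rows(all_records)
  am <- accept_measures(records, thresholds)
  list(
    concentrations = am$accepted,
    plate_log = dplyr::bind_rows(plate_log),
    rejections = am$rejections,
    curves = all_curves
  )
}
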