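#' Default forward 4PL response curves for plate simulation
#'
#' One four-parameter logistic curve per analyte, parameterized so the
#' inflection sits at the geometric midpoint of the quantitation range and
#' the Hill slope at the midpoint of the allowed limits; the response spans
#' a typical electrochemiluminescence dynamic range (~50 counts at blank to
#' 3e4 at saturation).
#'
#' @param thresholds a [qc_thresholds()] table.
#' @return tibble (`analyte`, `a`, `d`, `c`, `b`).
#' @export
default_curves <- function(thresholds = qc_thresholds()) {
  tibble(
    analyte = thresholds$analyte,
    a = 50,
    d = 30000,
    c = sqrt(thresholds$lloq * thresholds$uloq),
    b = (thresholds$hill_min + thresholds$hill_max) / 2
  )
}

#' Forward four-parameter logistic response
#'
#' `y = d + (a - d) / (1 + (x/c)^b)`: `a` is the response at zero
#' concentration, `d` the response at saturation, `c` the inflection
#' concentration and `b` the Hill slope.
#'
#' @param x concentration (diluted scale, pg/mL).
#' @param a,d,c,b curve parameters.
#' @export
fourpl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)

standard_series <- function(uloq, n_standards = 7L, step = 4) {
  c(uloq / step^(seq_len(n_standards) - 1), 0)
}

#' Simulate multiplexed assay plates for a concentration table
#'
#' Lays subjects out on 96-well plates per panel, mirroring the assay
#' workflow: a standard curve (seven 4-fold standards and a blank) in
#' duplicate, process quality controls (pooled plasma) in duplicate, and
#' patient samples in duplicate. Readings are generated through each
#' analyte's forward 4PL response at the panel's dilution factor, with
#' multiplicative Gaussian noise whose expected duplicate CV is `noise_cv`.
#'
#' @param conc a [sample_concentrations()] table (sample-scale pg/mL).
#' @param thresholds a [qc_thresholds()] table (dilution factors, panels).
#' @param noise_cv expected duplicate coefficient of variation (fraction).
#' @param samples_per_plate subjects per plate; at most 39 fit beside the
#'   16 standard and 2 PQC wells of a 96-well plate.
#' @param curves forward response curves, as [default_curves()].
#' @param pqc_pool optional tibble (`analyte`, `pqc_conc`), diluted scale;
#'   defaults to each curve's inflection concentration (mid-curve pool).
#' @param seed RNG seed.
#' @return A long tibble of class `plate_set` with columns `panel`,
#'   `plate_id`, `well`, `role` (`standard`/`pqc`/`sample`), `analyte`,
#'   `subject_id`, `standard_level`, `true_conc` (diluted scale),
#'   `replicate`, `response`; attributes carry the generating curves, the
#'   PQC pool, `noise_cv` and the thresholds used.
#' @export
simulate_plates <- function(conc, thresholds = qc_thresholds(),
                            noise_cv = 0.05, samples_per_plate = 39L,
                            curves = default_curves(thresholds),
                            pqc_pool = NULL, seed = 1L) {
  if (noise_cv < 0) abort("`noise_cv` must be non-negative")
  if (samples_per_plate > 39L || samples_per_plate < 1L) {
    abort("plate capacity exceeded: 96 wells hold at most 39 duplicate samples plus standards and PQCs")
  }
  analytes <- intersect(thresholds$analyte, setdiff(names(conc), c("subject_id", "label")))
  if (!length(analytes)) abort("no panel analytes found in `conc`")
  th <- thresholds[match(analytes, thresholds$analyte), ]
  cv <- curves[match(analytes, curves$analyte), ]
  if (is.null(pqc_pool)) {
    pqc_pool <- tibble(analyte = analytes, pqc_conc = cv$c)
  }
  subjects <- conc$subject_id
  n <- length(subjects)
  n_plates <- ceiling(n / samples_per_plate)

  # Well map: columns 1-2 standards (8 levels x 2), A3/B3 PQCs, rest samples.
  wells <- as.vector(outer(LETTERS[1:8], 1:12, function(r, c) sprintf("%s%02d", r, c)))
  std_wells <- wells[1:16]
  pqc_wells <- wells[17:18]
  sample_wells <- wells[-(1:18)]

  out <- vector("list", 0L)
  for (panel in unique(th$panel)) {
    pa <- analytes[th$panel == panel]
    for (pl in seq_len(n_plates)) {
      idx <- ((pl - 1L) * samples_per_plate + 1L):min(pl * samples_per_plate, n)
      plate_id <- sprintf("P%d-%03d", panel, pl)
      for (an in pa) {
        i <- match(an, analytes)
        std <- standard_series(th$uloq[i])
        dil <- th$dilution_factor[i]
        samp_diluted <- conc[[an]][idx] / dil
        grid <- dplyr::bind_rows(
          tibble(role = "standard", well = std_wells,
                 subject_id = NA_character_,
                 standard_level = rep(seq_along(std), 2L),
                 true_conc = rep(std, 2L),
                 replicate = rep(1:2, each = length(std))),
          tibble(role = "pqc", well = pqc_wells,
                 subject_id = NA_character_, standard_level = NA_integer_,
                 true_conc = pqc_pool$pqc_conc[match(an, pqc_pool$analyte)],
                 replicate = 1:2),
          tibble(role = "sample",
                 well = sample_wells[rep(seq_along(idx) * 2L, each = 2L) - rep(c(1L, 0L), length(idx))],
                 subject_id = rep(subjects[idx], each = 2L),
                 standard_level = NA_integer_,
                 true_conc = rep(samp_diluted, each = 2L),
                 replicate = rep(1:2, length(idx)))
        )
        grid$panel <- panel
        grid$plate_id <- plate_id
        grid$analyte <- an
        out[[length(out) + 1L]] <- grid
      }
    }
  }
  res <- dplyr::bind_rows(out)
  mu <- fourpl(res$true_conc, cv$a[match(res$analyte, cv$analyte)],
               cv$d[match(res$analyte, cv$analyte)],
               cv$c[match(res$analyte, cv$analyte)],
               cv$b[match(res$analyte, cv$analyte)])
  with_seed(seed_stream(seed, "plates"), {
    res$response <- mu * (1 + noise_cv * rnorm(nrow(res)))
  })
  res <- dplyr::select(res, "panel", "plate_id", "well", "role", "analyte",
                       "subject_id", "standard_level", "true_conc",
                       "replicate", "response")
  attr(res, "curves") <- cv
  attr(res, "pqc_pool") <- pqc_pool
  attr(res, "noise_cv") <- noise_cv
  attr(res, "thresholds") <- thresholds
  class(res) <- c("plate_set", class(res))
  res
}
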