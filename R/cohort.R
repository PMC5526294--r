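#' @importFrom tibble tibble as_tibble
NULL

crc_groups <- c("colon cancer", "rectal cancer")

all_groups <- c(
  "colon cancer", "rectal cancer", "adenoma colon", "adenoma rectum",
  "no comorbidity-no finding", "comorbidity-no finding",
  "other cancer", "other finding"
)

# Diagnostic-group mix of the full symptomatic intent-to-test sample set
# (raw counts out of 4698; percentages as printed round to a sum of 100.1%,
# counts are exact).
default_group_proportions <- function() {
  setNames(c(319, 193, 515, 174, 1164, 814, 177, 1342) / 4698, all_groups)
}

# Stage mix among CRC subjects (counts over the 511 staged cancers).
default_stage_proportions <- function() {
  setNames(c(101, 163, 139, 108) / 511, c("I", "II", "III", "IV"))
}

#' Cohort simulation specification
#'
#' Describes the intent-to-test (ITT) symptomatic population the synthetic
#' cohort generator draws from: diagnostic-group proportions,
#' within-CRC stage proportions, and class-conditional demographic models.
#' The defaults reproduce the study population the pipeline was designed
#' around: ~10.9% CRC prevalence, cases a decade older and more often male
#' than controls (the design deliberately does not balance demographics,
#' mirroring a true ITT population).
#'
#' @param n_subjects number of subjects to draw.
#' @param group_proportions named fractions over the eight diagnostic groups
#'   (must sum to 1).
#' @param stage_proportions named fractions over CRC stages I-IV.
#' @param age_model per-class mean/SD of age in years,
#'   `list(control = c(mean, sd), disease = c(mean, sd))`.
#' @param gender_model per-class female fraction.
#' @param bmi_model per-class mean/SD of BMI (kg/m^2).
#' @param age_range,bmi_range plausible truncation ranges.
#' @param seed RNG seed; all sampling from this object is deterministic
#'   given the seed.
#' @return object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 500, seed = 1)
#' cohort <- sample_cohort(spec)
cohort_spec <- function(n_subjects,
                        group_proportions = default_group_proportions(),
                        stage_proportions = default_stage_proportions(),
                        age_model = list(control = c(62.7, 12.6),
                                         disease = c(69.7, 10.6)),
                        gender_model = list(control = 0.534, disease = 0.424),
                        bmi_model = list(control = c(25.6, 4.7),
                                         disease = c(25.5, 4.7)),
                        age_range = c(18, 96),
                        bmi_range = c(10, 60),
                        seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 0 ||
      n_subjects != round(n_subjects)) {
    abort("`n_subjects` must be a single non-negative integer")
  }
  if (!setequal(names(group_proportions), all_groups)) {
    abort("`group_proportions` must be named with the eight diagnostic groups")
  }
  group_proportions <- group_proportions[all_groups]
  assert_fraction(unname(group_proportions), "group_proportions")
  assert_fraction(unname(stage_proportions), "stage_proportions")
  if (abs(sum(group_proportions) - 1) > 1e-9) {
    abort("`group_proportions` must sum to 1")
  }
  if (abs(sum(stage_proportions) - 1) > 1e-9) {
    abort("`stage_proportions` must sum to 1")
  }
  assert_fraction(gender_model$control, "gender_model$control")
  assert_fraction(gender_model$disease, "gender_model$disease")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      group_proportions = group_proportions,
      stage_proportions = stage_proportions,
      age_model = age_model, gender_model = gender_model,
      bmi_model = bmi_model, age_range = age_range, bmi_range = bmi_range,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Draw a synthetic ITT cohort
#'
#' Group membership is multinomial with the spec's proportions; age, gender
#' and BMI are drawn from class-conditional (CRC vs non-CRC) models with
#' truncation to plausible ranges; stages are assigned to CRC subjects only.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `subject_id`, `age`, `gender`
#'   (`"female"`/`"male"`), `bmi`, `diagnostic_group`, `crc_stage`
#'   (`"I"`..`"IV"` or `NA` for non-CRC), `label` (`"CRC"`/`"non-CRC"`).
#'   Deterministic given `spec$seed`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (n == 0L) {
    return(tibble(
      subject_id = character(), age = numeric(), gender = character(),
      bmi = numeric(), diagnostic_group = character(),
      crc_stage = character(), label = character()
    ))
  }
  with_seed(seed_stream(spec$seed, "cohort"), {
    counts <- drop(rmultinom(1, n, spec$group_proportions))
    group <- sample(rep(names(counts), counts))
    is_crc <- group %in% crc_groups
    stage <- rep(NA_character_, n)
    if (any(is_crc)) {
      stage[is_crc] <- sample(names(spec$stage_proportions), sum(is_crc),
                              replace = TRUE, prob = spec$stage_proportions)
    }
    cls <- ifelse(is_crc, "disease", "control")
    draw2 <- function(model, range) {
      m <- do.call(rbind, model[cls])
      rtruncn(n, m[, 1], m[, 2], range[1], range[2])
    }
    age <- draw2(spec$age_model, spec$age_range)
    bmi <- draw2(spec$bmi_model, spec$bmi_range)
    p_female <- unlist(spec$gender_model)[cls]
    gender <- ifelse(runif(n) < p_female, "female", "male")
    tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age, gender = gender, bmi = bmi,
      diagnostic_group = group, crc_stage = stage,
      label = ifelse(is_crc, "CRC", "non-CRC")
    )
  })
}

#' Read/write cohort and concentration tables as CSV
#'
#' Fixed-column CSV with a header row; gender serialized as
#' `"female"`/`"male"`; a missing CRC stage (non-CRC subjects) as an empty
#' field.
#'
#' @param cohort,conc tables as produced by [sample_cohort()] /
#'   [sample_concentrations()] (or QC acceptance).
#' @param path file path.
#' @return the read table (readers) or `path`, invisibly (writers).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("subject_id", "age", "gender", "bmi", "diagnostic_group",
            "crc_stage", "label")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    abort(sprintf("cohort file is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out$crc_stage <- as.character(out$crc_stage)
  out
}

#' @rdname write_cohort
#' @export
write_concentrations <- function(conc, path) {
  readr::write_csv(conc, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_concentrations <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  if (!"subject_id" %in% names(out)) {
    abort("concentration file needs a subject_id column")
  }
  out
}

#' Log-scale shift achieving a target univariate AUC
#'
#' For two equal-variance normal score distributions on the log scale
#' separated by `delta`, the ROC AUC is `pnorm(delta / (sigma * sqrt(2)))`.
#' This inverts that relation, turning a target single-marker AUC into the
#' additive log-scale class shift the concentration generator applies to
#' disease subjects. Negative shifts (markers lower in cases, AUC < 0.5)
#' are allowed.
#'
#' @param target_auc target univariate AUC in (0, 1).
#' @param sigma log-scale SD of the marker (common to both classes).
#' @return the log-scale shift `delta`; vectorized over both arguments.
#' @export
#' @examples
#' effect_size_for_auc(0.725)      # ~0.845
#' effect_size_for_auc(0.493)      # slightly negative
effect_size_for_auc <- function(target_auc, sigma = 1) {
  assert_fraction(target_auc, "target_auc", open = TRUE)
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  qnorm(target_auc) * sigma * sqrt(2)
}

#' @rdname effect_size_for_auc
#' @param delta log-scale class shift.
#' @export
auc_for_effect_size <- function(delta, sigma = 1) {
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  pnorm(delta / (sigma * sqrt(2)))
}

default_target_aucs <- function(analytes) {
  # Univariate electrochemiluminescence AUC anchors where printed; all
  # remaining analytes default to a weak 0.55.
  auc <- setNames(rep(0.55, length(analytes)), analytes)
  for (a in intersect(names(auc), c("CEA", "CO9", "MIF"))) {
    auc[a] <- c(CEA = 0.725, CO9 = 0.742, MIF = 0.493)[a]
  }
  auc
}

acute_phase_analytes <- c("A1AG", "SAA", "CRP", "HPT", "AACT")

#' Protein panel simulation specification
#'
#' Class-conditional multivariate log-normal model for the 27-analyte
#' concentration panel (pg/mL, sample scale). Each analyte has a baseline
#' log-mean and log-SD; CRC subjects receive an additive log-scale shift
#' `delta`, by default calibrated so each marker's univariate AUC matches
#' its target (via [effect_size_for_auc()]). Baseline log-means default to
#' the geometric midpoint of each assay's quantitation range scaled back to
#' the sample scale, so simulated plates land mid-curve.
#'
#' @param analytes character vector of analyte abbreviations.
#' @param log_sd log-scale SD (recycled).
#' @param target_auc named target univariate AUCs; ignored when `delta`
#'   given.
#' @param delta optional named log-scale shifts overriding the calibration.
#' @param log_mean optional named baseline log-means.
#' @param correlation inter-analyte log-scale correlation matrix, or the
#'   string `"acute_phase"` for the default block of +0.3 among the
#'   acute-phase proteins (A1AG, SAA, CRP, HPT, AACT), or `NULL` for
#'   independence.
#' @param thresholds a [qc_thresholds()] table used for default log-means.
#' @param seed RNG seed for concentration draws.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(analytes = qc_thresholds()$analyte,
                       log_sd = 1,
                       target_auc = default_target_aucs(analytes),
                       delta = NULL,
                       log_mean = NULL,
                       correlation = NULL,
                       thresholds = qc_thresholds(),
                       seed = 1L) {
  p <- length(analytes)
  log_sd <- setNames(rep_len(log_sd, p), analytes)
  if (any(log_sd <= 0)) abort("`log_sd` must be positive")
  if (is.null(log_mean)) {
    j <- match(analytes, thresholds$analyte)
    if (anyNA(j)) {
      abort(sprintf("no thresholds for analyte(s): %s",
                    paste(analytes[is.na(j)], collapse = ", ")))
    }
    log_mean <- setNames(
      log(thresholds$dilution_factor[j] *
            sqrt(thresholds$lloq[j] * thresholds$uloq[j])),
      analytes
    )
  } else {
    log_mean <- log_mean[analytes]
  }
  if (is.null(delta)) {
    target_auc <- target_auc[analytes]
    delta <- effect_size_for_auc(target_auc, log_sd)
  } else {
    full <- setNames(rep(0, p), analytes)
    full[names(delta)] <- delta
    delta <- full
  }
  if (is.character(correlation) && identical(correlation, "acute_phase")) {
    correlation <- diag(p)
    dimnames(correlation) <- list(analytes, analytes)
    blk <- intersect(analytes, acute_phase_analytes)
    correlation[blk, blk] <- 0.3
    diag(correlation) <- 1
  }
  if (!is.null(correlation)) {
    if (!isSymmetric(unname(correlation)) ||
        any(abs(diag(correlation) - 1) > 1e-12) ||
        min(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8) {
      abort("`correlation` must be symmetric PSD with unit diagonal")
    }
  }
  structure(
    list(analytes = analytes, log_mean = log_mean, log_sd = log_sd,
         delta = setNames(as.numeric(delta), analytes),
         correlation = correlation, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Plant a known logistic disease model in a synthetic cohort
#'
#' Replaces the cohort's labels with draws from a known logistic
#' regression on log2 protein concentrations plus age and gender. Used for
#' method-validation studies of the discovery engine: when the generating
#' model is known, feature-set and coefficient recovery can be scored
#' exactly. The intercept is set so the expected disease prevalence
#' matches `prevalence` at the cohort's mean linear predictor.
#'
#' @param conc concentration table (`subject_id` + analyte columns).
#' @param cohort cohort table (demographics are kept; `label`,
#'   `diagnostic_group` and `crc_stage` are overwritten to match the
#'   planted outcome).
#' @param coefficients named vector: log-odds per unit log2 concentration
#'   for protein terms, per year for `age`, and for `gender` (male = 1).
#' @param prevalence target disease prevalence.
#' @param seed RNG seed.
#' @return list: `cohort` (with planted labels), `truth` (the full
#'   coefficient vector including the intercept), `linear_predictor`.
#' @export
plant_logistic_labels <- function(conc, cohort, coefficients,
                                  prevalence = 0.109, seed = 1L) {
  feats <- names(coefficients)
  protein <- setdiff(feats, c("age", "gender"))
  missing <- setdiff(protein, names(conc))
  if (length(missing)) {
    abort(sprintf("planted model names analytes absent from `conc`: %s",
                  paste(missing, collapse = ", ")))
  }
  j <- match(conc$subject_id, cohort$subject_id)
  X <- cbind(
    log2(as.matrix(conc[protein])),
    age = if ("age" %in% feats) cohort$age[j] else NULL,
    gender = if ("gender" %in% feats) {
      as.numeric(cohort$gender[j] == "male")
    } else NULL
  )
  lp <- drop(X[, feats, drop = FALSE] %*% coefficients)
  # solve mean(plogis(c + lp)) = prevalence exactly (Jensen's inequality
  # makes the naive logit-offset miss at large linear-predictor variance)
  intercept <- stats::uniroot(
    function(c0) mean(plogis(c0 + lp)) - prevalence,
    interval = -mean(lp) + c(-30, 30), tol = 1e-10
  )$root
  p <- plogis(intercept + lp)
  out <- cohort[j, ]
  with_seed(seed_stream(seed, "plant"), {
    y <- rbinom(length(p), 1, p)
  })
  out$label <- ifelse(y == 1, "CRC", "non-CRC")
  out$diagnostic_group <- ifelse(y == 1, "colon cancer",
                                 "no comorbidity-no finding")
  out$crc_stage <- ifelse(y == 1, "II", NA_character_)
  list(cohort = out,
       truth = c("(Intercept)" = intercept, coefficients),
       linear_predictor = intercept + lp)
}

#' Draw synthetic protein concentrations for a cohort
#'
#' Concentrations are multivariate log-normal on the sample scale (pg/mL):
#' strictly positive, with CRC rows shifted by each analyte's `delta` on
#' the log scale and the panel's correlation structure honored.
#'
#' @param cohort a [sample_cohort()] table (non-empty).
#' @param panel a [panel_spec()].
#' @param analytes subset of panel analytes to draw (default all).
#' @return tibble `subject_id`, `label`, then one column per analyte.
#'   Deterministic given `panel$seed`.
#' @export
sample_concentrations <- function(cohort, panel,
                                  analytes = panel$analytes) {
  stopifnot(inherits(panel, "panel_spec"))
  if (nrow(cohort) == 0L) abort("`cohort` must be non-empty")
  missing <- setdiff(analytes, panel$analytes)
  if (length(missing)) {
    abort(sprintf("analyte(s) missing from panel: %s",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(cohort)
  p <- length(analytes)
  is_crc <- cohort$label == "CRC"
  with_seed(seed_stream(panel$seed, "concentrations"), {
    if (is.null(panel$correlation)) {
      z <- matrix(rnorm(n * p), n, p)
    } else {
      z <- MASS::mvrnorm(n, mu = rep(0, p),
                         Sigma = panel$correlation[analytes, analytes])
      if (n == 1L) z <- matrix(z, 1L)
    }
    logc <- sweep(z, 2, panel$log_sd[analytes], `*`)
    logc <- sweep(logc, 2, panel$log_mean[analytes], `+`)
    logc <- logc + outer(as.numeric(is_crc), panel$delta[analytes])
    conc <- exp(logc)
    colnames(conc) <- analytes
    dplyr::bind_cols(
      tibble(subject_id = cohort$subject_id, label = cohort$label),
      as_tibble(conc)
    )
  })
}
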