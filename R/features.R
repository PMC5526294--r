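#' Build a predictor matrix from concentrations and demographics
#'
#' Applies the pre-treatment options to a concentration table and appends
#' demographics: optional log2 transform of concentrations (always applied
#' before standardization), optional standardization (zero mean, unit
#' variance) with parameters estimated on `fit_rows` only — the training
#' fold in cross-validation — and applied to all rows, so no information
#' leaks from held-out subjects. Age and gender are appended as numeric
#' columns, gender coded female = 0 / male = 1; demographics are never
#' standardized by default.
#'
#' @param conc concentration table (`subject_id` plus analyte columns,
#'   sample-scale pg/mL).
#' @param cohort cohort table supplying `age` and `gender` (may be `NULL`
#'   to omit demographics).
#' @param log2 apply log2 to concentrations (and ratio features).
#' @param standardize standardize concentration-derived features.
#' @param fit_rows subject ids on which standardization parameters are
#'   estimated; default all rows.
#' @param data_types any of `"concentrations"`, `"ratios"`, `"age"`,
#'   `"gender"`.
#' @param standardize_demographics also standardize age/gender when
#'   `standardize` is set (off by default).
#' @param ordered_ratios when ratio features are built, add both A/B and
#'   B/A instead of one per unordered pair.
#' @return tibble of class `feature_matrix`: `subject_id` plus one numeric
#'   column per feature, no missing values. Attributes: `params`
#'   (standardization parameters when learned), `recipe` (the options),
#'   `conc` (original-scale concentrations, used by
#'   [add_ratio_features()]).
#' @export
#' @examples
#' spec <- cohort_spec(50, seed = 1)
#' coh <- sample_cohort(spec)
#' conc <- sample_concentrations(coh, panel_spec(c("CEA", "MIF"), seed = 1))
#' fm <- pretreat(conc, coh, log2 = TRUE)
pretreat <- function(conc, cohort = NULL, log2 = TRUE, standardize = FALSE,
                     fit_rows = NULL,
                     data_types = c("concentrations", "age", "gender"),
                     standardize_demographics = FALSE,
                     ordered_ratios = FALSE) {
  analytes <- setdiff(names(conc), c("subject_id", "label"))
  stopifnot(length(analytes) > 0L, "subject_id" %in% names(conc))
  x <- as.matrix(conc[analytes])
  if (anyNA(x)) abort("concentration table has missing values; run QC acceptance first")
  if (is.null(fit_rows)) fit_rows <- conc$subject_id
  fit_idx <- match(fit_rows, conc$subject_id)
  if (anyNA(fit_idx) || length(fit_idx) == 0L) {
    abort("`fit_rows` must be a non-empty subset of `conc$subject_id`")
  }
  if ("ratios" %in% data_types) {
    x <- cbind(x, ratio_columns(x, ordered = ordered_ratios))
  }
  if (!"concentrations" %in% data_types) {
    x <- x[, setdiff(colnames(x), analytes), drop = FALSE]
  }
  if (log2) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf("log2 undefined: non-positive concentration for subject %s, feature %s",
                    conc$subject_id[bad[1, 1]], colnames(x)[bad[1, 2]]))
    }
    x <- log2(x)
  }
  params <- NULL
  if (standardize && ncol(x) > 0L) {
    m <- colMeans(x[fit_idx, , drop = FALSE])
    s <- apply(x[fit_idx, , drop = FALSE], 2, sd)
    s[s == 0 | !is.finite(s)] <- 1
    x <- sweep(sweep(x, 2, m), 2, s, `/`)
    params <- tibble(feature = colnames(x), mean = unname(m), sd = unname(s))
  }
  out <- dplyr::bind_cols(tibble(subject_id = conc$subject_id), as_tibble(x))
  demo <- intersect(c("age", "gender"), data_types)
  if (length(demo)) {
    if (is.null(cohort)) abort("`cohort` needed to append age/gender")
    j <- match(conc$subject_id, cohort$subject_id)
    if (anyNA(j)) abort("cohort is missing some subjects present in `conc`")
    if ("age" %in% demo) out$age <- cohort$age[j]
    if ("gender" %in% demo) out$gender <- as.numeric(cohort$gender[j] == "male")
    if (standardize && standardize_demographics) {
      for (cn in demo) {
        m <- mean(out[[cn]][fit_idx]); s <- sd(out[[cn]][fit_idx])
        if (!is.finite(s) || s == 0) s <- 1
        out[[cn]] <- (out[[cn]] - m) / s
        params <- dplyr::bind_rows(params,
                                   tibble(feature = cn, mean = m, sd = s))
      }
    }
  }
  if (anyNA(out)) abort("feature matrix has missing values")
  attr(out, "params") <- params
  attr(out, "recipe") <- list(log2 = log2, standardize = standardize,
                              data_types = data_types,
                              standardize_demographics = standardize_demographics,
                              ordered_ratios = ordered_ratios)
  attr(out, "conc") <- conc[c("subject_id", analytes)]
  attr(out, "fit_rows") <- fit_rows
  class(out) <- c("feature_matrix", class(out))
  out
}

ratio_columns <- function(x, ordered = FALSE) {
  p <- ncol(x)
  if (p < 2L) abort("need at least 2 analytes to form ratios")
  pairs <- utils::combn(p, 2)
  num <- pairs[1, ]; den <- pairs[2, ]
  if (ordered) {
    num <- c(num, pairs[2, ]); den <- c(den, pairs[1, ])
  }
  r <- x[, num, drop = FALSE] / x[, den, drop = FALSE]
  colnames(r) <- paste0(colnames(x)[num], "_over_", colnames(x)[den])
  r
}

#' Append all pairwise concentration-ratio features
#'
#' Adds one feature per unordered analyte pair, computed as the ratio on
#' the original concentration scale and then passed through the same
#' pre-treatments as the base features (so on the log2 scale a ratio is
#' exactly the difference of the two log2 features). Ratios of an analyte
#' with itself are never created; `ordered = TRUE` adds both directions
#' (reciprocal pairs), off by default since on the explored model families
#' a reciprocal carries no extra information.
#'
#' @param matrix a [pretreat()] feature matrix.
#' @param ordered add both A/B and B/A.
#' @return a `feature_matrix` with `p*(p-1)/2` ratio columns appended.
#' @export
add_ratio_features <- function(matrix, ordered = FALSE) {
  stopifnot(inherits(matrix, "feature_matrix"))
  recipe <- attr(matrix, "recipe")
  conc <- attr(matrix, "conc")
  types <- unique(c(recipe$data_types, "ratios"))
  pretreat(conc,
           cohort = rebuild_cohort_stub(matrix),
           log2 = recipe$log2, standardize = recipe$standardize,
           fit_rows = attr(matrix, "fit_rows"),
           data_types = types,
           standardize_demographics = recipe$standardize_demographics,
           ordered_ratios = ordered)
}

# add_ratio_features needs age/gender back; they are already numeric columns
# of the matrix, so reconstruct a minimal cohort stub from them.
rebuild_cohort_stub <- function(matrix) {
  if (!any(c("age", "gender") %in% names(matrix))) return(NULL)
  tibble(
    subject_id = matrix$subject_id,
    age = if ("age" %in% names(matrix)) matrix$age else NA_real_,
    gender = if ("gender" %in% names(matrix)) {
      ifelse(matrix$gender == 1, "male", "female")
    } else "female"
  )
}

feature_columns <- function(fm) setdiff(names(fm), "subject_id")

feature_matrix_as_matrix <- function(fm, features = feature_columns(fm)) {
  m <- as.matrix(fm[features])
  rownames(m) <- fm$subject_id
  m
}
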