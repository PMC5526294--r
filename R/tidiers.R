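#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a grid result into one row per cell
#'
#' @param x a [run_grid()] result.
#' @param ... unused.
#' @return tibble without list columns: cell coordinates, summary AUC,
#'   protein-predictor count, error.
#' @export
tidy.grid_result <- function(x, ...) {
  tibble(
    cell_id = x$cell_id,
    fs_method = x$fs_method,
    classifier = x$classifier,
    n_predictors = x$n_predictors,
    log2 = x$log2,
    standardize = x$standardize,
    n_protein = x$n_protein,
    summary_auc = x$summary_auc,
    error = x$error
  )
}

#' @export
glance.grid_result <- function(x, ...) {
  ok <- is.na(x$error)
  tibble(
    n_cells = nrow(x), n_failed = sum(!ok),
    best_auc = max(x$summary_auc[ok], na.rm = TRUE),
    best_cell = x$cell_id[ok & x$summary_auc == max(x$summary_auc[ok])][1]
  )
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble(replicate = seq_along(x$replicate_aucs), auc = x$replicate_aucs)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(summary_auc = x$summary_auc, folds = x$folds, repeats = x$repeats,
         min_auc = min(x$replicate_aucs), max_auc = max(x$replicate_aucs))
}

#' Tidy a candidate model's coefficients
#'
#' @param x a [select_candidate()] result (refit, for coefficient output).
#' @param ... unused.
#' @return tibble (`term`, `estimate`) for coefficient-based families,
#'   otherwise one row per selected feature.
#' @export
tidy.candidate_model <- function(x, ...) {
  if (!is.null(x$coefficients)) {
    tibble(term = names(x$coefficients),
           estimate = as.numeric(x$coefficients))
  } else {
    tibble(term = x$features, estimate = NA_real_)
  }
}

#' @export
glance.candidate_model <- function(x, ...) {
  tibble(classifier = x$recipe$classifier, fs_method = x$recipe$fs_method,
         n_predictors = length(x$features), n_protein = x$n_protein,
         cv_auc = x$summary_auc)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_lower = x$ci[1], ci_upper = x$ci[2],
         level = x$level, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
tidy.confusion <- function(x, ...) {
  tibble(
    patient_status = c("CRC", "CRC", "non-CRC", "non-CRC"),
    call = c("positive", "negative", "positive", "negative"),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @export
glance.confusion <- function(x, ...) {
  tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
         sensitivity = x$sensitivity, specificity = x$specificity,
         n_indeterminate = x$n_indeterminate)
}

#' @export
tidy.indeterminate_range <- function(x, ...) {
  tibble(lo = x$lo, hi = x$hi, fraction = x$fraction, k = x$k,
         sensitivity = x$sensitivity, specificity = x$specificity,
         feasible = x$feasible)
}

#' Flatten a performance summary to one row
#'
#' @param x a [performance_summary()].
#' @param ... unused.
#' @return single-row tibble with all headline fields.
#' @export
glance.performance_summary <- function(x, ...) {
  tibble(
    n = x$n, n_called = x$n_called,
    sensitivity = x$sensitivity, specificity = x$specificity,
    auc = x$roc$auc, auc_lower = x$roc$ci[1], auc_upper = x$roc$ci[2],
    indeterminate_rate = x$indeterminate_rate,
    indeterminate_lower = x$indeterminate_ci[1],
    indeterminate_upper = x$indeterminate_ci[2],
    ppv = x$ppv, npv = x$npv, prevalence = x$prevalence,
    stage_fisher_p = if (!is.null(x$stage_table)) {
      attr(x$stage_table, "fisher_p")
    } else NA_real_
  )
}

#' @export
tidy.performance_summary <- function(x, ...) {
  long <- tidyr::pivot_longer(glance(x), dplyr::everything(),
                              names_to = "metric", values_to = "value")
  long
}
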