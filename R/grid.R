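pretreat_label <- function(data_types, log2, standardize) {
  sprintf("%s|log2=%d|std=%d", paste(sort(data_types), collapse = "+"),
          as.integer(log2), as.integer(standardize))
}

params_label <- function(params) {
  if (!length(params)) return("default")
  paste(sprintf("%s=%s", names(params), unlist(params)), collapse = ",")
}

cell_seed_key <- function(pt_id, fs, k, classifier, params) {
  paste(pt_id, fs, k, classifier, params_label(params), sep = "::")
}

#' Grid-search specification for classifier discovery
#'
#' Defines the discovery grid: data types, pre-treatments, predictor
#' counts, feature-selection methods, classifier families with their
#' hyperparameter lattices, and the repeated cross-validation settings.
#' Every combination is one grid cell, evaluated with stratified
#' `cv_folds`-fold cross-validation repeated `cv_repeats` times and
#' summarized as the median of replicate pooled-fold AUCs.
#'
#' @param data_types list of character vectors drawn from
#'   `"concentrations"`, `"ratios"`, `"age"`, `"gender"`.
#' @param pretreatments list of `list(log2 =, standardize =)` flag pairs.
#' @param predictor_counts integer vector (all `>= 2`).
#' @param fs_methods subset of the seven ranking methods.
#' @param classifiers named list: classifier family -> list of parameter
#'   lists (the lattice for that family).
#' @param cv_folds,cv_repeats cross-validation geometry.
#' @param fs_num_trees forest size used by the forest-based rankers.
#' @param seed master seed; fold assignments, forests and stochastic
#'   learners all derive deterministic substreams from it.
#' @return object of class `grid_spec`.
#' @seealso [grid_preset()] for ready-made grids, [run_grid()].
#' @export
grid_spec <- function(data_types = list(c("concentrations", "age", "gender")),
                      pretreatments = list(list(log2 = TRUE, standardize = FALSE)),
                      predictor_counts = c(4L, 8L, 16L),
                      fs_methods = fs_methods_all,
                      classifiers = list(logistic = list(list())),
                      cv_folds = 10L, cv_repeats = 10L,
                      fs_num_trees = 500L, seed = 1L) {
  if (any(predictor_counts < 2L)) abort("`predictor_counts` must be >= 2")
  if (cv_folds < 2L) abort("`cv_folds` must be >= 2")
  fs_methods <- match.arg(fs_methods, fs_methods_all, several.ok = TRUE)
  bad <- setdiff(names(classifiers), classifiers_all)
  if (length(bad)) {
    abort(sprintf("unregistered classifier(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(data_types = data_types, pretreatments = pretreatments,
         predictor_counts = as.integer(predictor_counts),
         fs_methods = fs_methods, classifiers = classifiers,
         cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
         fs_num_trees = as.integer(fs_num_trees), seed = as.integer(seed)),
    class = "grid_spec"
  )
}

#' Ready-made discovery grids
#'
#' `"desk"` is the package's reduced-scale working grid: every
#' feature-selection method crossed with every classifier family at one
#' hyperparameter setting each, predictor counts 3/10/16,
#' log2-unscaled concentrations plus age and gender, 10-fold CV repeated
#' twice, 100-tree forests. `"full"` spans predictor counts 2-29 with
#' denser lattices, 10x10 CV and 500-tree forests (hours of compute; the
#' desk grid is the default working scale).
#'
#' @param preset `"desk"` or `"full"`.
#' @param seed master seed.
#' @return a [grid_spec()].
#' @export
grid_preset <- function(preset = c("desk", "full"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    grid_spec(
      data_types = list(c("concentrations", "age", "gender")),
      pretreatments = list(list(log2 = TRUE, standardize = FALSE)),
      predictor_counts = c(3L, 10L, 16L),
      fs_methods = fs_methods_all,
      classifiers = list(
        logistic = list(list()),
        elastic_net_regression = list(list(alpha = 0.5, lambda = 0.01)),
        svm = list(list(kernel = "radial", cost = 1)),
        boosting = list(list(nrounds = 50, max_depth = 3, eta = 0.3)),
        random_forest = list(list(num_trees = 100)),
        knn = list(list(k = 25))
      ),
      cv_folds = 10L, cv_repeats = 2L, fs_num_trees = 100L, seed = seed
    )
  } else {
    grid_spec(
      data_types = list(c("concentrations", "age", "gender"),
                        c("concentrations", "ratios", "age", "gender")),
      pretreatments = list(list(log2 = TRUE, standardize = FALSE),
                           list(log2 = TRUE, standardize = TRUE),
                           list(log2 = FALSE, standardize = TRUE)),
      predictor_counts = 2:29,
      fs_methods = fs_methods_all,
      classifiers = list(
        logistic = list(list()),
        elastic_net_regression = list(list(alpha = 0.25, lambda = 0.01),
                                      list(alpha = 0.5, lambda = 0.01),
                                      list(alpha = 0.9, lambda = 0.001)),
        svm = list(list(kernel = "linear", cost = 1),
                   list(kernel = "radial", cost = 1),
                   list(kernel = "radial", cost = 10)),
        boosting = list(list(nrounds = 50, max_depth = 3, eta = 0.3),
                        list(nrounds = 200, max_depth = 2, eta = 0.1)),
        random_forest = list(list(num_trees = 500)),
        knn = list(list(k = 11), list(k = 25), list(k = 51))
      ),
      cv_folds = 10L, cv_repeats = 10L, fs_num_trees = 500L, seed = seed
    )
  }
}

grid_cells <- function(grid) {
  rows <- list()
  i <- 0L
  for (di in seq_along(grid$data_types)) {
    for (pi in seq_along(grid$pretreatments)) {
      pt <- grid$pretreatments[[pi]]
      for (k in grid$predictor_counts) {
        for (fs in grid$fs_methods) {
          for (cl in names(grid$classifiers)) {
            for (qi in seq_along(grid$classifiers[[cl]])) {
              i <- i + 1L
              rows[[i]] <- tibble(
                cell_id = sprintf("dt%d.pt%d.%s.k%02d.%s.par%d",
                                  di, pi, fs, k, cl, qi),
                data_types = list(grid$data_types[[di]]),
                log2 = isTRUE(pt$log2), standardize = isTRUE(pt$standardize),
                n_predictors = as.integer(k), fs_method = fs,
                classifier = cl,
                params = list(grid$classifiers[[cl]][[qi]])
              )
            }
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Shared cross-validation engine. `cells` is a tibble as built by
# grid_cells(); rankings and fold partitions are computed once per
# (pretreatment, fs_method, replicate, fold) and shared across cells, with
# all substream seeds derived from cell content so a single-cell run
# reproduces the corresponding grid cell exactly.
cv_engine <- function(conc, cohort, cells, folds, repeats, seed,
                      fs_num_trees = 500L, keep_scores = FALSE) {
  y <- as_binary(cohort$label[match(conc$subject_id, cohort$subject_id)])
  n <- nrow(conc)
  if (n < folds) abort("fewer subjects than folds")
  cells$pt_id <- mapply(function(dt, l2, st) pretreat_label(dt, l2, st),
                        cells$data_types, cells$log2, cells$standardize)
  res_auc <- matrix(NA_real_, nrow(cells), repeats)
  res_err <- rep(NA_character_, nrow(cells))
  scores_out <- if (keep_scores) {
    replicate(nrow(cells), vector("list", repeats), simplify = FALSE)
  }
  fold_ids <- lapply(seq_len(repeats), function(r) {
    stratified_folds(y, folds, seed_stream(seed, paste0("folds:", r)))
  })
  for (pt_id in unique(cells$pt_id)) {
    sel <- which(cells$pt_id == pt_id)
    c1 <- cells[sel[1], ]
    fm_full <- NULL
    if (!c1$standardize) {
      fm_full <- pretreat(conc, cohort, log2 = c1$log2, standardize = FALSE,
                          data_types = c1$data_types[[1]])
    }
    for (r in seq_len(repeats)) {
      fold_id <- fold_ids[[r]]
      scores <- matrix(NA_real_, n, length(sel))
      for (f in seq_len(folds)) {
        test <- fold_id == f
        fm <- if (is.null(fm_full)) {
          pretreat(conc, cohort, log2 = c1$log2, standardize = TRUE,
                   fit_rows = conc$subject_id[!test],
                   data_types = c1$data_types[[1]])
        } else fm_full
        X <- feature_matrix_as_matrix(fm)
        Xtr <- X[!test, , drop = FALSE]
        ytr <- y[!test]
        rankings <- list()
        for (fs in unique(cells$fs_method[sel])) {
          rankings[[fs]] <- tryCatch(
            rank_features(Xtr, ytr, fs, k = ncol(Xtr),
                          seed = seed_stream(seed, paste("rank", pt_id, fs,
                                                         r, f, sep = ":")),
                          num_trees = fs_num_trees),
            error = function(e) e
          )
        }
        for (j in seq_along(sel)) {
          ci <- cells[sel[j], ]
          if (!is.na(res_err[sel[j]])) next
          rk <- rankings[[ci$fs_method]]
          out <- tryCatch({
            if (inherits(rk, "error")) stop(conditionMessage(rk))
            if (ci$n_predictors > length(rk)) {
              stop(sprintf("cell needs %d predictors but only %d features exist",
                           ci$n_predictors, length(rk)))
            }
            feats <- rk[seq_len(ci$n_predictors)]
            m <- fit_classifier(
              Xtr[, feats, drop = FALSE], ytr, ci$classifier, ci$params[[1]],
              seed = seed_stream(seed, paste(
                "fit", cell_seed_key(pt_id, ci$fs_method, ci$n_predictors,
                                     ci$classifier, ci$params[[1]]),
                r, f, sep = ":"))
            )
            predict(m, X[test, feats, drop = FALSE])
          }, error = function(e) e)
          if (inherits(out, "error")) {
            res_err[sel[j]] <- conditionMessage(out)
          } else {
            scores[test, j] <- out
          }
        }
      }
      for (j in seq_along(sel)) {
        if (is.na(res_err[sel[j]])) {
          res_auc[sel[j], r] <- auc_mw(scores[, j], y)
          if (keep_scores) {
            scores_out[[sel[j]]][[r]] <- tibble(
              subject_id = conc$subject_id, score = scores[, j], fold = fold_id)
          }
        }
      }
    }
  }
  list(auc = res_auc, error = res_err, scores = scores_out, y = y)
}

#' Strict repeated stratified cross-validation of one classifier recipe
#'
#' Per replicate: a stratified random fold partition; per fold, feature
#' ranking and any standardization are fit on the training rows only, the
#' classifier is fit and the hold-out fold scored. The pooled hold-out
#' scores of the ten folds give one AUC per replicate; the summary is the
#' median across replicates.
#'
#' @param conc accepted concentration table (`subject_id` + analytes).
#' @param cohort cohort table with `label` (and demographics).
#' @param recipe list with `data_types`, `log2`, `standardize`,
#'   `fs_method`, `n_predictors`, `classifier`, `params`.
#' @param folds,repeats CV geometry (defaults 10 x 10).
#' @param seed master seed.
#' @param fs_num_trees forest size for forest-based rankers.
#' @return object of class `cv_result`: `replicate_aucs`, `summary_auc`
#'   (their median), and per-replicate pooled hold-out `scores`.
#' @export
cross_validate <- function(conc, cohort, recipe, folds = 10L, repeats = 10L,
                           seed = 1L, fs_num_trees = 500L) {
  cells <- tibble(
    cell_id = "cell",
    data_types = list(recipe$data_types %||% c("concentrations", "age", "gender")),
    log2 = isTRUE(recipe$log2 %||% TRUE),
    standardize = isTRUE(recipe$standardize %||% FALSE),
    n_predictors = as.integer(recipe$n_predictors),
    fs_method = recipe$fs_method,
    classifier = recipe$classifier,
    params = list(recipe$params %||% list())
  )
  eng <- cv_engine(conc, cohort, cells, folds, repeats, seed,
                   fs_num_trees = fs_num_trees, keep_scores = TRUE)
  if (!is.na(eng$error[1])) abort(eng$error[1])
  aucs <- eng$auc[1, ]
  structure(
    list(replicate_aucs = aucs, summary_auc = median(aucs),
         scores = eng$scores[[1]], recipe = recipe, folds = folds,
         repeats = repeats, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> median pooled-fold AUC %.4f over %d replicates (%d-fold)\n",
              x$summary_auc, x$repeats, x$folds))
  invisible(x)
}

#' Run the discovery grid search
#'
#' Evaluates every grid cell with the shared repeated-CV engine (fold
#' partitions and per-fold feature rankings are computed once and shared
#' across the cells they feed, so results are identical to running
#' [cross_validate()] per cell). Each cell also records the feature list a
#' full-data ranking selects, used later for candidate filtering and
#' refitting. Cell errors are recorded per cell and do not abort the grid.
#'
#' @param grid a [grid_spec()] or [grid_preset()].
#' @param conc accepted concentration table.
#' @param cohort cohort table.
#' @param progress print per-pretreatment progress lines.
#' @return tibble of class `grid_result`, one row per cell, sorted by
#'   `summary_auc` descending: cell coordinates, `summary_auc`,
#'   `replicate_aucs` (list), `features` (list; full-data selection),
#'   `n_protein` (protein-derived predictors, excluding age/gender),
#'   `error`.
#' @export
run_grid <- function(grid, conc, cohort, progress = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- grid_cells(grid)
  if (nrow(cells) == 0L) abort("empty grid")
  t0 <- Sys.time()
  eng <- cv_engine(conc, cohort, cells, grid$cv_folds, grid$cv_repeats,
                   grid$seed, fs_num_trees = grid$fs_num_trees)
  if (progress) {
    message(sprintf("[%s] evaluated %d cells in %.1f s",
                    format(Sys.time(), "%H:%M:%S"), nrow(cells),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  # full-data selection per (pretreatment, fs), shared across counts
  y <- cohort$label[match(conc$subject_id, cohort$subject_id)]
  cells$pt_id <- mapply(function(dt, l2, st) pretreat_label(dt, l2, st),
                        cells$data_types, cells$log2, cells$standardize)
  final_rank <- list()
  for (key in unique(paste(cells$pt_id, cells$fs_method, sep = "@"))) {
    i <- match(TRUE, paste(cells$pt_id, cells$fs_method, sep = "@") == key)
    fm <- pretreat(conc, cohort, log2 = cells$log2[i],
                   standardize = cells$standardize[i],
                   data_types = cells$data_types[[i]])
    final_rank[[key]] <- tryCatch(
      rank_features(fm, y, cells$fs_method[i],
                    k = length(feature_columns(fm)),
                    seed = seed_stream(grid$seed,
                                       paste("rank-final", key, sep = ":")),
                    num_trees = grid$fs_num_trees),
      error = function(e) character()
    )
  }
  cells$features <- lapply(seq_len(nrow(cells)), function(i) {
    rk <- final_rank[[paste(cells$pt_id[i], cells$fs_method[i], sep = "@")]]
    head(rk, cells$n_predictors[i])
  })
  cells$n_protein <- vapply(cells$features, function(f) {
    sum(!f %in% c("age", "gender"))
  }, integer(1))
  cells$replicate_aucs <- lapply(seq_len(nrow(cells)), function(i) eng$auc[i, ])
  cells$summary_auc <- apply(eng$auc, 1, median)
  cells$error <- eng$error
  cells <- dplyr::arrange(cells, dplyr::desc(.data$summary_auc))
  cells$pt_id <- NULL
  attr(cells, "grid") <- grid
  class(cells) <- c("grid_result", class(cells))
  cells
}

features_involve <- function(features, assays) {
  if (!length(assays)) return(rep(FALSE, length(features)))
  vapply(features, function(fl) {
    parts <- unique(unlist(strsplit(fl, "_over_", fixed = TRUE)))
    any(parts %in% assays)
  }, logical(1))
}

#' Select the top candidate model from a grid result
#'
#' Applies the discovery filtering rule: keep cells whose median CV AUC
#' meets the floor, drop any whose selected features involve an excluded
#' assay (directly or inside a ratio), and among the survivors pick the
#' one with the fewest protein-derived predictors (ties: higher summary
#' AUC, then lexicographic cell id). When discovery data are supplied the
#' winning recipe is refit on all rows, yielding the locked candidate.
#'
#' @param grid_result a [run_grid()] table.
#' @param auc_floor minimum median CV AUC.
#' @param excluded_assays analyte abbreviations to exclude.
#' @param conc,cohort optional discovery data for the final refit.
#' @return object of class `candidate_model` (with `model = NULL` when no
#'   data were supplied).
#' @export
select_candidate <- function(grid_result, auc_floor = 0.84,
                             excluded_assays = character(),
                             conc = NULL, cohort = NULL) {
  if (nrow(grid_result) == 0L) abort("empty grid result")
  ok <- is.na(grid_result$error) & !is.na(grid_result$summary_auc) &
    grid_result$summary_auc >= auc_floor
  ok <- ok & !features_involve(grid_result$features, excluded_assays)
  if (!any(ok)) {
    abort(sprintf("no candidate: no cell reached median CV AUC %.2f%s",
                  auc_floor,
                  if (length(excluded_assays)) " after assay exclusions" else ""))
  }
  surv <- grid_result[ok, ]
  surv <- surv[order(surv$n_protein, -surv$summary_auc, surv$cell_id), ]
  top <- surv[1, ]
  cand <- list(
    cell_id = top$cell_id,
    recipe = list(data_types = top$data_types[[1]], log2 = top$log2,
                  standardize = top$standardize,
                  fs_method = top$fs_method,
                  n_predictors = top$n_predictors,
                  classifier = top$classifier, params = top$params[[1]]),
    features = top$features[[1]],
    n_protein = top$n_protein,
    summary_auc = top$summary_auc,
    replicate_aucs = top$replicate_aucs[[1]],
    model = NULL, coefficients = NULL, pretreat_params = NULL
  )
  if (!is.null(conc)) {
    if (is.null(cohort)) abort("`cohort` required to refit the candidate")
    fm <- pretreat(conc, cohort, log2 = top$log2,
                   standardize = top$standardize,
                   data_types = top$data_types[[1]])
    y <- cohort$label[match(conc$subject_id, cohort$subject_id)]
    grid <- attr(grid_result, "grid")
    seed <- if (!is.null(grid)) grid$seed else 1L
    m <- fit_classifier(
      feature_matrix_as_matrix(fm, cand$features), y,
      top$classifier, top$params[[1]],
      seed = seed_stream(seed, paste("refit", top$cell_id, sep = ":")))
    cand$model <- m
    cand$pretreat_params <- attr(fm, "params")
    if (top$classifier == "logistic" && !inherits(m$fit, "glmnet")) {
      cand$coefficients <- coef(m$fit)
    } else if (inherits(m$fit, "glmnet")) {
      s <- if (!is.null(top$params[[1]]$lambda)) top$params[[1]]$lambda
      b <- coef(m$fit, s = s)
      cand$coefficients <- setNames(as.numeric(b), rownames(b))
    }
  }
  structure(cand, class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(sprintf("<candidate_model> %s | %d features (%d protein) | median CV AUC %.4f\n",
              x$recipe$classifier, length(x$features), x$n_protein,
              x$summary_auc))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Score subjects with a locked candidate model
#'
#' Rebuilds the candidate's feature recipe on new data — reusing the
#' standardization parameters learned at refit time, never re-estimating
#' them — and emits the continuous CRC score.
#'
#' @param object a refit [select_candidate()] model.
#' @param conc concentration table for the subjects to score.
#' @param cohort matching cohort table.
#' @param ... unused.
#' @return tibble (`subject_id`, `score`).
#' @export
predict.candidate_model <- function(object, conc, cohort, ...) {
  if (is.null(object$model)) {
    abort("candidate has no refit model; pass discovery data to select_candidate()")
  }
  r <- object$recipe
  fm <- pretreat(conc, cohort, log2 = r$log2, standardize = FALSE,
                 data_types = r$data_types)
  X <- feature_matrix_as_matrix(fm, object$features)
  if (r$standardize && !is.null(object$pretreat_params)) {
    pp <- object$pretreat_params
    j <- match(colnames(X), pp$feature)
    use <- !is.na(j)
    X[, use] <- sweep(sweep(X[, use, drop = FALSE], 2, pp$mean[j[use]]),
                      2, pp$sd[j[use]], `/`)
  }
  tibble(subject_id = conc$subject_id,
         score = predict(object$model, X))
}
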