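#' Pipeline run configuration
#'
#' Bundles every knob of the discover-lock-validate flow: the cohort and
#' panel simulation specs, QC thresholds, the discovery grid, the
#' indeterminate-range search settings, candidate filtering, the clinical
#' prevalence used for predictive values, and the discovery/validation
#' split sizes. The discovery and validation sets are completely
#' independent (disjoint subjects); the split sizes default to 3099/1336.
#'
#' @param n_discovery,n_validation split sizes.
#' @param panel a [panel_spec()].
#' @param thresholds a [qc_thresholds()] table.
#' @param grid a [grid_spec()]; default the desk preset.
#' @param indeterminate_fractions fractions explored by the gray-zone
#'   search.
#' @param final_fraction the fraction whose optimized range is locked.
#' @param sens_floor sensitivity floor of the gray-zone search.
#' @param auc_floor candidate AUC floor.
#' @param excluded_assays analytes excluded at candidate selection.
#' @param prevalence CRC prevalence for PPV/NPV (default 0.109, the
#'   symptomatic-population rate).
#' @param noise_cv duplicate noise CV of the plate simulation.
#' @param simulate_plate_qc run the plate simulation + QC stage (TRUE) or
#'   feed generated concentrations directly to discovery (FALSE).
#' @param seed master seed; all stages derive substreams.
#' @param cohort_args extra arguments passed to [cohort_spec()].
#' @param yaml optional path to a YAML file whose fields override the
#'   defaults above (scalar fields only).
#' @return object of class `run_config`.
#' @export
run_config <- function(n_discovery = 3099L, n_validation = 1336L,
                       panel = NULL, thresholds = qc_thresholds(),
                       grid = NULL,
                       indeterminate_fractions = c(0.15, 0.20, 0.25),
                       final_fraction = 0.25, sens_floor = 0.80,
                       auc_floor = 0.84, excluded_assays = character(),
                       prevalence = 0.109, noise_cv = 0.05,
                       simulate_plate_qc = TRUE, seed = 1L,
                       cohort_args = list(), yaml = NULL) {
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    for (f in intersect(names(ov), c("n_discovery", "n_validation",
                                     "final_fraction", "sens_floor",
                                     "auc_floor", "prevalence", "noise_cv",
                                     "simulate_plate_qc", "seed",
                                     "indeterminate_fractions",
                                     "excluded_assays"))) {
      assign(f, ov[[f]])
    }
  }
  if (n_discovery < 1 || n_validation < 1) {
    abort("both split sizes must be positive")
  }
  assert_fraction(prevalence, "prevalence")
  if (is.null(panel)) panel <- panel_spec(thresholds = thresholds, seed = seed)
  if (is.null(grid)) grid <- grid_preset("desk", seed = seed)
  structure(
    list(n_discovery = as.integer(n_discovery),
         n_validation = as.integer(n_validation),
         panel = panel, thresholds = thresholds, grid = grid,
         indeterminate_fractions = indeterminate_fractions,
         final_fraction = final_fraction, sens_floor = sens_floor,
         auc_floor = auc_floor, excluded_assays = excluded_assays,
         prevalence = prevalence, noise_cv = noise_cv,
         simulate_plate_qc = isTRUE(simulate_plate_qc),
         seed = as.integer(seed), cohort_args = cohort_args),
    class = "run_config"
  )
}

#' Summarize locked-model performance on a scored sample set
#'
#' Combines the evaluation statistics into one report object: confusion
#' counts over called subjects, sensitivity/specificity, AUC with DeLong
#' CI (computed on all scores, indeterminates included, as for a
#' continuous marker), indeterminate rate with Clopper-Pearson CI,
#' PPV/NPV at the stated prevalence, and the stage-stratified sensitivity
#' table with its Fisher p-value.
#'
#' @param scores numeric scores for every subject.
#' @param labels binary labels (`"CRC"` positive).
#' @param range a locked [optimize_range()] result.
#' @param prevalence prevalence for predictive values.
#' @param stages optional CRC stages for the stage breakdown.
#' @param level confidence level.
#' @return object of class `performance_summary`.
#' @export
performance_summary <- function(scores, labels, range, prevalence = 0.109,
                                stages = NULL, level = 0.95) {
  calls <- apply_calls(scores, range)
  cm <- confusion(calls, labels)
  roc <- roc_auc(scores, labels, level = level)
  n <- length(scores)
  n_ind <- cm$n_indeterminate
  ind_ci <- exact_binomial_ci(n_ind, n, level)
  pv <- predictive_values(cm$sensitivity, cm$specificity, prevalence)
  stage_tab <- if (!is.null(stages)) stage_breakdown(calls, labels, stages)
  structure(
    list(confusion = cm, sensitivity = cm$sensitivity,
         specificity = cm$specificity, roc = roc,
         indeterminate_rate = n_ind / n, indeterminate_ci = ind_ci,
         n = n, n_called = n - n_ind,
         ppv = pv$ppv, npv = pv$npv, prevalence = prevalence,
         stage_table = stage_tab, range = range, calls = calls),
    class = "performance_summary"
  )
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary>\n")
  cat(sprintf("  called %d of %d (indeterminate rate %.1f%%, %d%% CI %.1f-%.1f%%)\n",
              x$n_called, x$n, 100 * x$indeterminate_rate,
              round(100 * x$roc$level),
              100 * x$indeterminate_ci[1], 100 * x$indeterminate_ci[2]))
  cat(sprintf("  sensitivity %.2f  specificity %.2f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  AUC %.2f (%.2f-%.2f)\n", x$roc$auc, x$roc$ci[1], x$roc$ci[2]))
  cat(sprintf("  PPV %.1f%%  NPV %.1f%% at prevalence %.1f%%\n",
              100 * x$ppv, 100 * x$npv, 100 * x$prevalence))
  if (!is.null(x$stage_table)) {
    cat(sprintf("  stage association Fisher p = %.3f\n",
                attr(x$stage_table, "fisher_p")))
  }
  invisible(x)
}

#' Run the full discover-lock-validate pipeline
#'
#' Executes, under one master seed: cohort + concentration simulation for
#' the disjoint discovery and validation sets; optionally the plate
#' simulation and QC acceptance workflow; grid-search discovery with
#' repeated stratified CV; candidate filtering and the full-data refit;
#' the indeterminate-range search over the configured fractions; LOCK
#' (model + range serialized with a content fingerprint); application of
#' the locked artifact — and nothing else — to the validation set; and the
#' validation performance summary. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, [write_report()] is
#'   called on the result.
#' @param progress emit stage messages.
#' @return object of class `pipeline_result` with elements `cohort`
#'   (split-labelled), `concentrations`, `qc` (logs or NULL), `grid_result`,
#'   `candidate`, `ranges` (per explored fraction), `locked`,
#'   `discovery_summary`, `validation_summary`, `config`.
#' @export
run_pipeline <- function(config, output_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) message(sprintf("[%s] %s",
                                                     format(Sys.time(), "%H:%M:%S"),
                                                     sprintf(...)))
  n_total <- config$n_discovery + config$n_validation
  cspec <- do.call(cohort_spec, c(list(n_subjects = n_total,
                                       seed = seed_stream(config$seed, "cohort")),
                                  config$cohort_args))
  say("simulate: drawing cohort of %d subjects", n_total)
  cohort <- sample_cohort(cspec)
  split <- with_seed(seed_stream(config$seed, "split"), {
    sample(rep(c("discovery", "validation"),
               c(config$n_discovery, config$n_validation)))
  })
  cohort$split <- split
  if (anyDuplicated(cohort$subject_id)) {
    abort("discovery/validation overlap: duplicated subject ids")
  }
  panel <- config$panel
  panel$seed <- seed_stream(config$seed, "panel")
  conc_true <- sample_concentrations(cohort, panel)
  qc <- NULL
  if (config$simulate_plate_qc) {
    say("qc: simulating plates and running acceptance")
    plates <- simulate_plates(conc_true, config$thresholds,
                              noise_cv = config$noise_cv,
                              seed = seed_stream(config$seed, "plates"))
    qc <- run_qc(plates, config$thresholds)
    conc <- qc$concentrations
    keep <- complete.cases(conc)
    conc <- conc[keep, ]
  } else {
    conc <- dplyr::select(conc_true, -"label")
  }
  disc_ids <- intersect(conc$subject_id,
                        cohort$subject_id[cohort$split == "discovery"])
  val_ids <- intersect(conc$subject_id,
                       cohort$subject_id[cohort$split == "validation"])
  conc_d <- conc[match(disc_ids, conc$subject_id), ]
  conc_v <- conc[match(val_ids, conc$subject_id), ]
  say("discover: grid of %d cells on %d discovery subjects",
      nrow(grid_cells(config$grid)), length(disc_ids))
  grid <- config$grid
  grid$seed <- seed_stream(config$seed, "grid")
  gr <- run_grid(grid, conc_d, cohort, progress = progress)
  candidate <- select_candidate(gr, auc_floor = config$auc_floor,
                                excluded_assays = config$excluded_assays,
                                conc = conc_d, cohort = cohort)
  say("lock: candidate %s (%d protein predictors)", candidate$cell_id,
      candidate$n_protein)
  disc_scores <- predict(candidate, conc_d, cohort)
  yd <- cohort$label[match(disc_ids, cohort$subject_id)]
  ranges <- lapply(config$indeterminate_fractions, function(f) {
    optimize_range(disc_scores$score, yd, f, config$sens_floor)
  })
  names(ranges) <- sprintf("f%.2f", config$indeterminate_fractions)
  fi <- which.min(abs(config$indeterminate_fractions - config$final_fraction))
  final_range <- ranges[[fi]]
  if (!final_range$feasible) {
    abort("no indeterminate range at the final fraction met the sensitivity floor")
  }
  locked <- lock_model(candidate, final_range, config)
  disc_summary <- performance_summary(
    disc_scores$score, yd, final_range, config$prevalence,
    stages = cohort$crc_stage[match(disc_ids, cohort$subject_id)])
  say("validate: applying locked model to %d subjects", length(val_ids))
  val <- validate_locked(locked, conc_v, cohort, config$prevalence)
  res <- structure(
    list(cohort = cohort, concentrations = conc, qc = qc,
         grid_result = gr, candidate = candidate, ranges = ranges,
         locked = locked, discovery_summary = disc_summary,
         validation_summary = val, config = config),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) write_report(res, output_dir)
  res
}

# Serializable locked artifact: recipe, features, coefficients where the
# family has them, the indeterminate range, and a content fingerprint.
lock_model <- function(candidate, range, config) {
  payload <- list(
    cell_id = candidate$cell_id,
    recipe = candidate$recipe[c("data_types", "log2", "standardize",
                                "fs_method", "n_predictors", "classifier")],
    params = candidate$recipe$params,
    features = candidate$features,
    coefficients = as.list(candidate$coefficients),
    pretreat_params = if (!is.null(candidate$pretreat_params)) {
      as.list(candidate$pretreat_params)
    },
    indeterminate = list(lo = range$lo, hi = range$hi,
                         fraction = range$fraction, k = range$k,
                         sensitivity = range$sensitivity,
                         specificity = range$specificity),
    seed = config$seed
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  structure(
    list(candidate = candidate, range = range, payload = payload,
         json = as.character(json),
         fingerprint = text_fingerprint(as.character(json))),
    class = "locked_model"
  )
}

#' @export
print.locked_model <- function(x, ...) {
  cat(sprintf("<locked_model> %s  fingerprint %s\n",
              x$candidate$cell_id, x$fingerprint))
  print(x$range)
  invisible(x)
}

# Validation refuses to run anything but the locked artifact: scores come
# from the locked candidate, calls from the locked range, no re-fitting.
validate_locked <- function(locked, conc, cohort, prevalence) {
  stopifnot(inherits(locked, "locked_model"))
  sc <- predict(locked$candidate, conc, cohort)
  j <- match(conc$subject_id, cohort$subject_id)
  performance_summary(sc$score, cohort$label[j], locked$range, prevalence,
                      stages = cohort$crc_stage[j])
}

#' Write pipeline report files
#'
#' Emits, under `dir`: a human-readable `report.txt`, machine-readable
#' `summary.json`, the validation ROC points as `roc_points.csv`, the
#' sample-level QC rejection log as `rejections.tsv`, the locked model as
#' `locked_model.json`, and a provenance block (config fingerprint, seed).
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vs <- result$validation_summary
  paths <- c(
    report = file.path(dir, "report.txt"),
    summary = file.path(dir, "summary.json"),
    roc = file.path(dir, "roc_points.csv"),
    rejections = file.path(dir, "rejections.tsv"),
    locked = file.path(dir, "locked_model.json")
  )
  writeLines(result$locked$json, paths["locked"])
  readr::write_csv(vs$roc$curve, paths["roc"])
  rej <- if (!is.null(result$qc)) result$qc$rejections else {
    tibble(subject_id = character(), analyte = character(),
           cv = numeric(), reason = character())
  }
  readr::write_tsv(rej, paths["rejections"])
  summary_list <- list(
    validation = summary_fields(vs),
    discovery = summary_fields(result$discovery_summary),
    locked_fingerprint = result$locked$fingerprint,
    seed = result$config$seed,
    n_discovery = result$config$n_discovery,
    n_validation = result$config$n_validation
  )
  jsonlite::write_json(summary_list, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  txt <- c(
    "Locked-model validation report",
    "==============================",
    "",
    sprintf("Locked model: %s (fingerprint %s)", result$candidate$cell_id,
            result$locked$fingerprint),
    sprintf("Features (%d protein + demographics): %s",
            result$candidate$n_protein,
            paste(result$candidate$features, collapse = ", ")),
    sprintf("Indeterminate range: [%.4g, %.4g] (target fraction %.2f)",
            result$locked$range$lo, result$locked$range$hi,
            result$locked$range$fraction),
    "",
    report_block("Validation", vs),
    "",
    report_block("Discovery (optimization set, resubstitution)",
                 result$discovery_summary),
    "",
    sprintf("Provenance: master seed %d; %d grid cells; %d/%d split",
            result$config$seed, nrow(result$grid_result),
            result$config$n_discovery, result$config$n_validation)
  )
  writeLines(txt, paths["report"])
  invisible(paths)
}

summary_fields <- function(s) {
  list(
    sensitivity = s$sensitivity, specificity = s$specificity,
    auc = s$roc$auc, auc_ci = as.numeric(s$roc$ci),
    indeterminate_rate = s$indeterminate_rate,
    indeterminate_ci = as.numeric(s$indeterminate_ci),
    ppv = s$ppv, npv = s$npv, prevalence = s$prevalence,
    tp = s$confusion$tp, fn = s$confusion$fn,
    fp = s$confusion$fp, tn = s$confusion$tn,
    stage_fisher_p = if (!is.null(s$stage_table)) {
      attr(s$stage_table, "fisher_p")
    },
    stage_sensitivity = if (!is.null(s$stage_table)) {
      setNames(as.list(s$stage_table$sensitivity), s$stage_table$stage_group)
    }
  )
}

report_block <- function(title, s) {
  st <- if (is.null(s$stage_table)) {
    "  stage breakdown: not available"
  } else {
    paste(sprintf("  stage %-7s incorrect %3d  correct %3d  sensitivity %s",
                  s$stage_table$stage_group, s$stage_table$incorrect,
                  s$stage_table$correct,
                  ifelse(is.na(s$stage_table$sensitivity), "NA",
                         sprintf("%.2f", s$stage_table$sensitivity))),
          collapse = "\n")
  }
  paste(c(
    sprintf("%s (n = %d)", title, s$n),
    sprintf("  indeterminate rate %.1f%% (CI %.1f-%.1f%%)",
            100 * s$indeterminate_rate, 100 * s$indeterminate_ci[1],
            100 * s$indeterminate_ci[2]),
    sprintf("  sensitivity %.2f  specificity %.2f", s$sensitivity,
            s$specificity),
    sprintf("  AUC %.2f (%.2f-%.2f)", s$roc$auc, s$roc$ci[1], s$roc$ci[2]),
    sprintf("  PPV %.1f%%  NPV %.1f%%  (prevalence %.1f%%)",
            100 * s$ppv, 100 * s$npv, 100 * s$prevalence),
    st
  ), collapse = "\n")
}
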