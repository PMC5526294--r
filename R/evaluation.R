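#' Confusion matrix over called subjects
#'
#' Indeterminate calls are excluded from the counts; sensitivity and
#' specificity are computed from the remaining two-way calls. With zero
#' called cases (or controls) the corresponding rate is reported as `NA`.
#'
#' @param calls factor/character of `positive` / `negative` /
#'   `indeterminate` calls.
#' @param labels binary labels (`"CRC"` positive).
#' @return object of class `confusion`: counts `tp`, `fn`, `fp`, `tn`,
#'   `n_indeterminate`, and derived `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion(c("positive", "negative", "indeterminate"),
#'           c("CRC", "non-CRC", "CRC"))
confusion <- function(calls, labels) {
  calls <- as.character(calls)
  stopifnot(all(calls %in% c("positive", "negative", "indeterminate")))
  pos <- if (is.numeric(labels)) labels != 0 else as.character(labels) == "CRC"
  called <- calls != "indeterminate"
  tp <- sum(called & pos & calls == "positive")
  fn <- sum(called & pos & calls == "negative")
  fp <- sum(called & !pos & calls == "positive")
  tn <- sum(called & !pos & calls == "negative")
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn,
         n_indeterminate = sum(!called),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "confusion"
  )
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fn=%d fp=%d tn=%d (indeterminate %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$n_indeterminate))
  cat(sprintf("  sensitivity %.4f  specificity %.4f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

# DeLong placement variance of the Mann-Whitney AUC.
delong_components <- function(scores, y) {
  xs <- scores[y == 1]
  ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  # placements via midranks (O((m+n) log(m+n)))
  r_all <- rank(c(xs, ys))
  r_x <- rank(xs)
  r_y <- rank(ys)
  v10 <- (r_all[seq_len(m)] - r_x) / n            # P(X_i > Y) + half ties
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n,
       var = var(v10) / m + var(v01) / n)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney statistic (ties half-credited); the default
#' confidence interval uses the DeLong placement variance, with a
#' stratified bootstrap available.
#'
#' @param scores numeric scores (higher = positive class).
#' @param labels binary labels (`"CRC"` positive); both classes required.
#' @param level confidence level.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot number of stratified bootstrap replicates.
#' @param seed bootstrap seed.
#' @return object of class `roc_result`: `auc`, `var`, `ci`, `n_pos`,
#'   `n_neg`, and the ROC `curve` (tibble of threshold/FPR/TPR).
#' @export
roc_auc <- function(scores, labels, level = 0.95,
                    ci_method = c("delong", "bootstrap"), boot = 2000L,
                    seed = 1L) {
  ci_method <- match.arg(ci_method)
  y <- as_binary(labels)
  dc <- delong_components(scores, y)
  if (ci_method == "delong") {
    z <- qnorm(1 - (1 - level) / 2)
    ci <- pmin(pmax(dc$auc + c(-1, 1) * z * sqrt(dc$var), 0), 1)
  } else {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    ci <- with_seed(seed, {
      reps <- vapply(seq_len(boot), function(i) {
        s <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
        auc_mw(scores[s], y[s])
      }, numeric(1))
      quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    })
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(
    list(auc = dc$auc, var = dc$var, ci = ci, level = level,
         ci_method = ci_method, n_pos = dc$m, n_neg = dc$n, curve = curve),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d%% CI %.4f-%.4f, %s), %d cases / %d controls\n",
              x$auc, round(100 * x$level), x$ci[1], x$ci[2], x$ci_method,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two AUCs with DeLong's test
#'
#' Paired mode is the classical DeLong correlated-ROC test (two score sets
#' on the same subjects, identical labels). Unpaired mode — the
#' discovery-versus-validation use case — is a z-test on the AUC
#' difference with summed DeLong variances. When the combined variance is
#' zero the p-value is reported as 1 with a `degenerate` flag.
#'
#' @param scores_a,labels_a first ROC input.
#' @param scores_b,labels_b second ROC input; in paired mode `labels_b`
#'   must equal `labels_a`.
#' @param paired are the two score sets measured on the same subjects?
#' @return list: `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`,
#'   `paired`, `degenerate`.
#' @export
delong_compare <- function(scores_a, labels_a, scores_b, labels_b = labels_a,
                           paired = FALSE) {
  ya <- as_binary(labels_a)
  yb <- as_binary(labels_b)
  da <- delong_components(scores_a, ya)
  db <- delong_components(scores_b, yb)
  if (paired) {
    if (!identical(ya, yb)) {
      abort("paired comparison requires identical subjects and labels")
    }
    s10 <- cov(da$v10, db$v10)
    s01 <- cov(da$v01, db$v01)
    v <- da$var + db$var - 2 * (s10 / da$m + s01 / da$n)
  } else {
    v <- da$var + db$var
  }
  diff <- da$auc - db$auc
  degenerate <- !is.finite(v) || v <= 0
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = da$auc, auc_b = db$auc, difference = diff,
       se = if (degenerate) 0 else sqrt(v), z = z, p_value = p,
       paired = paired, degenerate = degenerate)
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' identities for the post-test probabilities at a stated pre-test
#' prevalence: `ppv = se*pi / (se*pi + (1-sp)*(1-pi))` and
#' `npv = sp*(1-pi) / (sp*(1-pi) + (1-se)*pi)`; `0/0` yields `NA`.
#'
#' @param sensitivity,specificity,prevalence all in `[0, 1]`.
#' @return tibble (`ppv`, `npv`).
#' @export
#' @examples
#' predictive_values(0.80, 0.83, 0.109)
predictive_values <- function(sensitivity, specificity, prevalence) {
  assert_fraction(sensitivity, "sensitivity")
  assert_fraction(specificity, "specificity")
  assert_fraction(prevalence, "prevalence")
  num_p <- sensitivity * prevalence
  den_p <- num_p + (1 - specificity) * (1 - prevalence)
  num_n <- specificity * (1 - prevalence)
  den_n <- num_n + (1 - sensitivity) * prevalence
  tibble(
    ppv = ifelse(den_p > 0, num_p / den_p, NA_real_),
    npv = ifelse(den_n > 0, num_n / den_n, NA_real_)
  )
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from beta quantiles: lower
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param level confidence level in (0, 1).
#' @return named numeric `c(lower, upper)`.
#' @export
#' @examples
#' exact_binomial_ci(310, 1336)   # ~ (0.210, 0.256)
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) abort("`n` must be positive")
  if (successes < 0 || successes > n) abort("`successes` must be in [0, n]")
  assert_fraction(level, "level", open = TRUE)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass convention (the sum of
#' hypergeometric probabilities, at fixed margins, of tables no more
#' probable than the observed one) — the convention of
#' [stats::fisher.test()], which performs the computation. A zero margin
#' makes every admissible table identical; p is then 1 with a flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `p_value`, `odds_ratio`, `degenerate`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  ft <- fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       degenerate = FALSE)
}

#' Stage-stratified sensitivity with association test
#'
#' Groups CRC subjects into early (stages I-II) and late (III-IV) disease,
#' counts incorrect/correct calls per group (indeterminates excluded),
#' computes per-group sensitivities, and tests group-by-correctness
#' association with Fisher's exact test.
#'
#' @param calls three-way calls as from [apply_calls()].
#' @param labels binary labels (`"CRC"` positive).
#' @param stages CRC stage (`"I"`..`"IV"`) per subject; must be present
#'   for every CRC subject.
#' @return tibble of class `stage_table` with rows `I-II`, `III-IV`,
#'   `Total` and columns `stage_group`, `incorrect`, `correct`,
#'   `sensitivity`; the Fisher p-value is in attribute `"fisher_p"`.
#' @export
stage_breakdown <- function(calls, labels, stages) {
  calls <- as.character(calls)
  pos <- if (is.numeric(labels)) labels != 0 else as.character(labels) == "CRC"
  if (any(pos & (is.na(stages) | !stages %in% c("I", "II", "III", "IV")))) {
    abort("every CRC subject needs a stage in I-IV")
  }
  use <- pos & calls != "indeterminate"
  grp <- ifelse(stages %in% c("I", "II"), "I-II", "III-IV")
  counts <- function(sel) {
    c(incorrect = sum(use & sel & calls == "negative"),
      correct = sum(use & sel & calls == "positive"))
  }
  early <- counts(grp == "I-II")
  late <- counts(grp == "III-IV")
  tot <- early + late
  sens <- function(x) if (sum(x) > 0) x["correct"] / sum(x) else NA_real_
  out <- tibble(
    stage_group = c("I-II", "III-IV", "Total"),
    incorrect = unname(c(early["incorrect"], late["incorrect"],
                         tot["incorrect"])),
    correct = unname(c(early["correct"], late["correct"], tot["correct"])),
    sensitivity = unname(c(sens(early), sens(late), sens(tot)))
  )
  fp <- fisher_exact(rbind(early, late))
  attr(out, "fisher_p") <- fp$p_value
  class(out) <- c("stage_table", class(out))
  out
}
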