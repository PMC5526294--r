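# A small validation-shaped call/label set with known confusion counts:
# tp = 87, fn = 22, fp = 159, tn = 758, 310 indeterminate.
validation_calls <- function() {
  calls <- c(rep("positive", 87), rep("negative", 22),
             rep("positive", 159), rep("negative", 758),
             rep("indeterminate", 310))
  labels <- c(rep("CRC", 109), rep("non-CRC", 917),
              rep("CRC", 37), rep("non-CRC", 273))
  list(calls = calls, labels = labels)
}

test_that("confusion counts and rates match hand-tallied values", {
  v <- validation_calls()
  cm <- confusion(v$calls, v$labels)
  expect_equal(cm$tp, 87); expect_equal(cm$fn, 22)
  expect_equal(cm$fp, 159); expect_equal(cm$tn, 758)
  expect_equal(cm$sensitivity, 87 / 109)
  expect_equal(cm$specificity, 758 / 917)
  expect_equal(round(cm$sensitivity, 2), 0.80)
  expect_equal(round(cm$specificity, 2), 0.83)
  # degenerate: everything indeterminate
  cm0 <- confusion(rep("indeterminate", 5), c("CRC", "CRC", rep("non-CRC", 3)))
  expect_true(is.na(cm0$sensitivity))
  expect_true(is.na(cm0$specificity))
  perfect <- confusion(c("positive", "negative"), c("CRC", "non-CRC"))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("AUC equals concordant-pair counting with half-credit ties", {
  # positives {3, 1}, negatives {2, 0}: 3 of 4 pairs concordant
  r <- roc_auc(c(3, 1, 2, 0), c("CRC", "CRC", "non-CRC", "non-CRC"))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c("CRC", "CRC", "non-CRC", "non-CRC"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("CRC", "non-CRC"), 3))$auc, 0.5)
  # exhaustive pair-counting oracle on random instances
  withr::with_seed(55, {
    for (i in 1:15) {
      n <- sample(8:30, 1)
      s <- sample(1:10, n, replace = TRUE)  # forces ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
      oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                            ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
      expect_equal(roc_auc(s, y)$auc, oracle)
    }
  })
  expect_error(roc_auc(1:4, rep("CRC", 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(3, {
    s <- rnorm(60); y <- rbinom(60, 1, 0.4)
  })
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(2 * s - 7, y)$auc, a0)
  expect_equal(roc_auc(plogis(s), y)$auc, a0)
})

test_that("DeLong AUC variance and CI agree with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    s <- rnorm(150) + 0.8 * rep(c(1, 0), c(40, 110))
    y <- rep(c(1, 0), c(40, 110))
  })
  ours <- roc_auc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  expect_equal(as.numeric(ours$ci),
               as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-8)
  # paired DeLong test cross-check
  withr::with_seed(14, s2 <- s + rnorm(150, sd = 0.8))
  ours2 <- delong_compare(s, y, s2, y, paired = TRUE)
  ref2 <- pROC::roc.test(ref, pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
  expect_equal(ours2$p_value, as.numeric(ref2$p.value), tolerance = 1e-8)
})

test_that("paired DeLong comparison is exactly zero against itself and rank-invariant", {
  withr::with_seed(2, {
    s <- rnorm(80); y <- rbinom(80, 1, 0.3)
  })
  self <- delong_compare(s, y, s, y, paired = TRUE)
  expect_equal(self$difference, 0)
  expect_true(self$degenerate)
  expect_equal(self$p_value, 1)
  mono <- delong_compare(s, y, exp(s), y, paired = TRUE)
  expect_equal(mono$difference, 0)
})

test_that("unpaired DeLong p-value agrees with a permutation oracle on toys", {
  mk_arm <- function(seed, shift, n1 = 12, n0 = 12) {
    withr::with_seed(seed, {
      list(s = c(rnorm(n1) + shift, rnorm(n0)),
           y = rep(c(1, 0), c(n1, n0)))
    })
  }
  perm_p <- function(a, b, n_perm = 20000, seed = 5) {
    obs <- abs(seropanel:::auc_mw(a$s, a$y) - seropanel:::auc_mw(b$s, b$y))
    pool_s <- c(a$s, b$s); pool_y <- c(a$y, b$y)
    na <- length(a$s)
    withr::with_seed(seed, {
      reps <- vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(pool_s), na)
        ya <- pool_y[idx]; yb <- pool_y[-idx]
        if (length(unique(ya)) < 2 || length(unique(yb)) < 2) return(NA_real_)
        abs(seropanel:::auc_mw(pool_s[idx], ya) -
              seropanel:::auc_mw(pool_s[-idx], yb))
      }, numeric(1))
    })
    mean(reps >= obs - 1e-12, na.rm = TRUE)
  }
  # moderate separation: p should be unremarkable in both constructions
  a <- mk_arm(101, shift = 1.6)
  b <- mk_arm(202, shift = 0.6)
  got <- delong_compare(a$s, a$y, b$s, b$y, paired = FALSE)
  expect_equal(got$p_value, perm_p(a, b), tolerance = 0.1)
  # near-null case
  a2 <- mk_arm(301, shift = 1.0)
  b2 <- mk_arm(302, shift = 1.0)
  got2 <- delong_compare(a2$s, a2$y, b2$s, b2$y, paired = FALSE)
  expect_equal(got2$p_value, perm_p(a2, b2), tolerance = 0.12)
  expect_gt(got2$p_value, 0.2)
})

test_that("predictive values satisfy the Bayes identities and monotonicity", {
  pv <- predictive_values(0.80, 0.83, 0.109)
  expect_equal(round(100 * pv$ppv, 1), 36.5)
  expect_equal(round(100 * pv$npv, 1), 97.1)
  expect_equal(predictive_values(0.7, 0.9, 1)$ppv, 1)
  expect_equal(predictive_values(0.7, 0.9, 1)$npv, 0)
  expect_equal(predictive_values(0.7, 1, 0.3)$ppv, 1)
  # pi = 0.5 reduces to se / (se + 1 - sp)
  pv5 <- predictive_values(0.73, 0.81, 0.5)
  expect_equal(pv5$ppv, 0.73 / (0.73 + 1 - 0.81), tolerance = 1e-12)
  # monotone non-decreasing in prevalence, sensitivity and specificity
  grid <- seq(0.05, 0.95, by = 0.1)
  expect_false(is.unsorted(predictive_values(0.8, 0.8, grid)$ppv))
  expect_false(is.unsorted(predictive_values(grid, 0.8, 0.2)$ppv))
  expect_false(is.unsorted(predictive_values(0.8, grid, 0.2)$ppv))
  expect_error(predictive_values(1.2, 0.8, 0.1), "\\[0, 1\\]")
})

test_that("Clopper-Pearson interval matches the exact binomial reference", {
  ci <- exact_binomial_ci(310, 1336)
  expect_equal(round(100 * ci, 1), c(lower = 21.0, upper = 25.6))
  ref <- binom.test(310, 1336)$conf.int
  expect_equal(as.numeric(ci), as.numeric(ref), tolerance = 1e-10)
  expect_equal(unname(exact_binomial_ci(0, 50)[1]), 0)
  expect_equal(unname(exact_binomial_ci(50, 50)[2]), 1)
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(5:200, 1); x <- sample(0:n, 1)
      expect_equal(as.numeric(exact_binomial_ci(x, n, 0.9)),
                   as.numeric(binom.test(x, n, conf.level = 0.9)$conf.int),
                   tolerance = 1e-10)
    }
  })
  expect_error(exact_binomial_ci(1, 0), "positive")
})

test_that("exact interval covers the truth at the nominal rate", {
  # coverage at p = 0.23, n = 1336 over simulated binomials
  p <- 0.23; n <- 1336; nsim <- 4000
  withr::with_seed(123, x <- rbinom(nsim, n, p))
  lo <- qbeta(0.025, x, n - x + 1)
  hi <- qbeta(0.975, x + 1, n - x)
  cover <- mean(lo <= p & p <= hi)
  mc_se <- sqrt(0.95 * 0.05 / nsim)
  expect_gte(cover, 0.95 - 3 * mc_se)
})

test_that("Fisher's exact matches hypergeometric enumeration", {
  # probability-mass two-sided convention, enumerated directly
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  withr::with_seed(17, {
    for (i in 1:25) {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab)$p_value, enum_fisher(tab),
                   tolerance = 1e-7)
    }
  })
  deg <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("stage breakdown reproduces hand-tallied sensitivities and Fisher p", {
  # early incorrect/correct 12/36, late 10/51
  calls <- c(rep(c("negative", "positive"), c(12, 36)),
             rep(c("negative", "positive"), c(10, 51)),
             rep("negative", 40))
  labels <- c(rep("CRC", 109), rep("non-CRC", 40))
  stages <- c(rep("I", 6), rep("II", 6), rep("I", 18), rep("II", 18),
              rep("III", 5), rep("IV", 5), rep("III", 26), rep("IV", 25),
              rep(NA, 40))
  st <- stage_breakdown(calls, labels, stages)
  expect_equal(st$incorrect, c(12, 10, 22))
  expect_equal(st$correct, c(36, 51, 87))
  expect_equal(round(st$sensitivity, 2), c(0.75, 0.84, 0.80))
  expect_equal(round(attr(st, "fisher_p"), 3), 0.338)
  # conservation: group sums equal the CRC row totals
  cm <- confusion(calls, labels)
  expect_equal(sum(st$correct[1:2]), cm$tp)
  expect_equal(sum(st$incorrect[1:2]), cm$fn)
  # balanced groups: no association, p = 1
  calls_b <- rep(c("positive", "negative"), 20)
  stages_b <- rep(c("I", "I", "III", "III"), 10)
  st_b <- stage_breakdown(calls_b, rep("CRC", 40), stages_b)
  expect_equal(attr(st_b, "fisher_p"), 1)
  expect_error(stage_breakdown("positive", "CRC", NA), "stage")
})
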