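# Small builders shared across tests. Everything is generated in code;
# fixtures are deliberately tiny.

tiny_cohort <- function(n = 80, seed = 42) {
  sample_cohort(cohort_spec(n, seed = seed))
}

tiny_panel <- function(analytes = c("CEA", "MIF", "CO9", "TFRC"), seed = 42,
                       ...) {
  panel_spec(analytes = analytes, seed = seed, ...)
}

# Noise-free standards through a known 4PL curve (duplicates included).
make_standards <- function(a = 50, d = 30000, c = 500, b = 1,
                           uloq = 100000, n_levels = 7) {
  conc <- c(uloq / 4^(seq_len(n_levels) - 1), 0)
  conc <- rep(conc, 2)
  data.frame(concentration = conc, response = fourpl(conc, a, d, c, b))
}

# Labels + scores instance for indeterminate-range tests.
random_score_instance <- function(n, seed) {
  withr::with_seed(seed, {
    list(scores = rnorm(n),
         labels = ifelse(runif(n) < 0.3, "CRC", "non-CRC"))
  })
}

# Brute-force gray-zone search: enumerate every contiguous window of k
# order statistics, compute sens/spec over called subjects by direct
# comparison, apply the package's tie-break rule by explicit sorting.
brute_force_range <- function(scores, labels, fraction, sens_floor = 0.8) {
  y <- as.integer(labels == "CRC")
  n <- length(scores)
  k <- round(fraction * n)
  ord <- order(scores)
  s <- scores[ord]
  ys <- y[ord]
  rows <- list()
  for (i in seq_len(n - k + 1)) {
    inside <- if (k > 0) seq(i, i + k - 1) else integer()
    above <- setdiff(seq_len(n), seq_len(i + k - 1))
    below <- setdiff(seq_len(n), union(inside, above))
    tp <- sum(ys[above] == 1); fn <- sum(ys[below] == 1)
    tn <- sum(ys[below] == 0); fp <- sum(ys[above] == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA
    lo <- if (k > 0) s[i] else {
      mean(c(if (i == 1) s[1] - 1 else s[i - 1],
             if (i > n) s[n] + 1 else s[i]))
    }
    hi <- if (k > 0) s[i + k - 1] else lo
    rows[[i]] <- data.frame(lo = lo, hi = hi, sens = sens, spec = spec)
  }
  df <- do.call(rbind, rows)
  feas <- !is.na(df$sens) & df$sens >= sens_floor
  if (!any(feas)) return(NULL)
  df <- df[feas, ]
  df <- df[order(-df$spec, -df$sens, df$hi - df$lo, df$lo), ]
  df[1, ]
}

# The planted-model study condition used by the recovery tests: eight
# proteins at equal standardized log-odds contribution 0.7, plus age and
# gender.
planted_truth <- function() {
  proteins <- c("A1AG", "CEA", "CO9", "DPPIV", "MIF", "PKM2", "SAA", "TFRC")
  b <- 0.70
  beta <- c(setNames(rep(b * log(2), 8), proteins),
            age = b / 12.6, gender = b / 0.4987)
  beta[c("MIF", "DPPIV")] <- -beta[c("MIF", "DPPIV")]
  beta
}
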