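#' @importFrom rlang %||% abort warn .data
#' @importFrom stats qnorm pnorm rnorm runif rbinom rmultinom median sd var cor
#'   quantile setNames predict coef glm binomial plogis qbeta fisher.test
#'   complete.cases cov
#' @importFrom utils head
NULL

# Deterministic substream seed derivation: one master seed fans out to named
# streams so pipeline stages can be re-run independently. Keeps results inside
# 32-bit integer range.
seed_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 5381
  for (k in utf8ToInt(name)) h <- (h * 33 + k) %% 2147483563
  as.integer((abs(seed) %% 2147483563 * 40014 + h * 40692 + 1) %% 2147483563)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by inverse-CDF; used for age and BMI models.
rtruncn <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

assert_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must lie in %s", name,
                  if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

# Short content fingerprint (djb2 over the serialized text) used to stamp
# locked-model files; not cryptographic, just a tamper tell-tale.
text_fingerprint <- function(x) {
  h <- 5381
  for (k in utf8ToInt(paste(x, collapse = "\n"))) h <- (h * 33 + k) %% 2^31
  sprintf("%08x", h)
}
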