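#' Optimize an indeterminate (gray-zone) score range
#'
#' Exhaustively evaluates every contiguous window of `k = round(fraction * n)`
#' consecutive order statistics of the score vector. For each window,
#' subjects above it are called positive and subjects below it negative
#' (windowed subjects receive no call); sensitivity and specificity are
#' computed over called subjects only. The window returned maximizes
#' specificity among windows whose sensitivity meets the floor;
#' ties break on higher sensitivity, then narrower width, then smaller
#' lower bound. With `fraction = 0` the search degenerates to the best
#' single threshold meeting the floor. Deterministic; ties in score are
#' resolved by stable order, so a window may split tied scores.
#'
#' @param scores numeric CRC scores (higher = more CRC-like), finite.
#' @param labels binary labels (`"CRC"` positive); both classes required.
#' @param fraction fraction of samples to leave uncalled, in `[0, 1)`.
#' @param sens_floor sensitivity floor; windows below it are infeasible.
#' @param strict require sensitivity strictly above the floor instead of
#'   at-or-above.
#' @return object of class `indeterminate_range`: `lo`, `hi`, `fraction`,
#'   `k`, achieved `sensitivity` and `specificity` on the optimization
#'   set, and `feasible`. When no window meets the floor, `feasible` is
#'   `FALSE` and the bounds are `NA` (an explicit infeasible result, not
#'   an error).
#' @export
#' @examples
#' sc <- 1:10
#' lab <- ifelse(sc %in% c(6, 8, 9, 10), "CRC", "non-CRC")
#' optimize_range(sc, lab, fraction = 0.2, sens_floor = 0.75)
optimize_range <- function(scores, labels, fraction, sens_floor = 0.80,
                           strict = FALSE) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1)")
  if (any(!is.finite(scores))) abort("scores must be finite")
  y <- as_binary(labels)
  n <- length(scores)
  k <- round(fraction * n)
  ord <- order(scores)  # stable in R
  s <- scores[ord]
  ys <- y[ord]
  cum_pos <- cumsum(ys)
  total_pos <- cum_pos[n]
  starts <- seq_len(n - k + 1L)
  pos_below <- c(0, cum_pos)[starts]              # positives below window
  pos_above <- total_pos - c(0, cum_pos)[starts + k]
  neg_below <- (starts - 1L) - pos_below
  neg_above <- (n - (starts + k - 1L)) - pos_above
  sens <- ifelse(pos_above + pos_below > 0,
                 pos_above / (pos_above + pos_below), NA_real_)
  spec <- ifelse(neg_above + neg_below > 0,
                 neg_below / (neg_above + neg_below), NA_real_)
  feas <- !is.na(sens) & (if (strict) sens > sens_floor else sens >= sens_floor)
  if (!any(feas)) {
    return(structure(
      list(lo = NA_real_, hi = NA_real_, fraction = fraction, k = k,
           sensitivity = NA_real_, specificity = NA_real_,
           feasible = FALSE, n = n, sens_floor = sens_floor),
      class = "indeterminate_range"
    ))
  }
  spec_f <- ifelse(feas, spec, -Inf)
  lo_v <- window_lo(s, starts, k)
  hi_v <- window_hi(s, starts, k)
  # lexicographic: max spec, max sens, min width, min lo
  key <- order(-spec_f, -ifelse(feas, sens, -Inf), hi_v - lo_v, lo_v)
  best <- key[1]
  structure(
    list(lo = lo_v[best], hi = hi_v[best], fraction = fraction, k = k,
         sensitivity = sens[best], specificity = spec[best],
         feasible = TRUE, n = n, sens_floor = sens_floor),
    class = "indeterminate_range"
  )
}

# Window bounds in score space. For k > 0 these are the first and last
# order statistics inside the window; for k = 0 the empty window collapses
# to a threshold placed midway between the adjacent scores.
window_lo <- function(s, starts, k) {
  n <- length(s)
  if (k > 0L) return(s[starts])
  gap_lo <- c(s[1] - 1, s)
  gap_hi <- c(s, s[n] + 1)
  (gap_lo[starts] + gap_hi[starts]) / 2
}

window_hi <- function(s, starts, k) {
  n <- length(s)
  if (k > 0L) return(s[starts + k - 1L])
  window_lo(s, starts, k)
}

#' @export
print.indeterminate_range <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<indeterminate_range> INFEASIBLE at fraction %.2f (no window with sensitivity >= %.2f)\n",
                x$fraction, x$sens_floor))
  } else {
    cat(sprintf("<indeterminate_range> [%.4g, %.4g] removing %d/%d (%.1f%%): sens %.3f spec %.3f\n",
                x$lo, x$hi, x$k, x$n, 100 * x$k / x$n,
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' Apply a locked indeterminate range as three-way calls
#'
#' Scores strictly above the range are called positive, strictly below
#' negative, and scores inside `[lo, hi]` receive no call. The range is
#' applied as locked: no re-optimization happens here, so on a new sample
#' set the realized indeterminate rate may differ from the optimization
#' fraction.
#'
#' @param scores numeric scores.
#' @param range an [optimize_range()] result (must be feasible).
#' @return factor with levels `negative`, `indeterminate`, `positive`;
#'   every sample receives exactly one call.
#' @export
apply_calls <- function(scores, range) {
  stopifnot(inherits(range, "indeterminate_range"))
  if (!range$feasible) abort("cannot apply an infeasible indeterminate range")
  out <- ifelse(scores > range$hi, "positive",
                ifelse(scores < range$lo, "negative", "indeterminate"))
  factor(out, levels = c("negative", "indeterminate", "positive"))
}
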