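#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired comparison: zero differences are dropped (classical Wilcoxon
#' treatment), absolute differences are ranked with midranks for ties, and
#' the statistic W is the sum of ranks of the positive differences. For
#' n <= `exact_max` the two-sided p-value is exact, computed from the full
#' null distribution of W over all 2^n sign assignments (enumerated by
#' dynamic programming over the observed ranks, so ties are handled
#' exactly); above that a normal approximation with tie correction is used.
#' The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))` — the null
#' distribution is symmetric under sign flips even with ties.
#'
#' @param a,b paired numeric vectors (or `b` omitted and `a` the
#'   differences).
#' @param exact_max largest n for which the exact distribution is used.
#' @return List with `statistic` (W), `p_value`, `n` (non-zero pairs),
#'   `method`.
#' @export
wilcoxon_signed_rank_exact <- function(a, b = NULL, exact_max = 25) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; the test is undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W over all sign assignments: DP over doubled ranks
    # (midranks are multiples of 1/2, so 2*r are integers)
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    prob <- numeric(tot + 1)  # index k+1 <-> doubled statistic k
    prob[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), prob[seq_len(tot + 1 - ri)])
      prob <- (prob + shifted) / 2
    }
    w2 <- round(2 * w)
    lo <- sum(prob[seq_len(w2 + 1)])              # P(W <= w)
    hi <- sum(prob[seq.int(w2 + 1, tot + 1)])     # P(W >= w)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Paired cohort comparison table
#'
#' Compares two cohorts of per-case metric values (e.g. two planning
#' techniques over the same cases), metric by metric, with mean, SD, and
#' the exact two-sided Wilcoxon signed-rank p-value.
#'
#' @param tbl_a,tbl_b data frames with identical `metric` ordering and a
#'   `value` column, or matrices/data frames whose columns are metrics and
#'   rows are cases.
#' @return Tibble with `metric`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p_value`.
#' @export
compare_cohorts <- function(tbl_a, tbl_b) {
  ma <- as.data.frame(tbl_a)
  mb <- as.data.frame(tbl_b)
  stopifnot(identical(colnames(ma), colnames(mb)), nrow(ma) == nrow(mb))
  num <- vapply(ma, is.numeric, logical(1))
  rows <- lapply(colnames(ma)[num], function(m) {
    x <- ma[[m]]; y <- mb[[m]]
    p <- if (all(x == y)) NA_real_
         else wilcoxon_signed_rank_exact(x, y)$p_value
    tibble::tibble(metric = m, mean_a = mean(x), sd_a = stats::sd(x),
                   mean_b = mean(y), sd_b = stats::sd(y), p_value = p)
  })
  do.call(rbind, rows)
}
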