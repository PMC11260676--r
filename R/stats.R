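#' Paired discrepancy summary
#'
#' Elementwise `a - b` with mean and sample standard deviation, the
#' discrepancy convention used throughout the comparison tables
#' (e.g. 3D static minus 4D dynamic).
#'
#' @param values_a,values_b equal-length numeric vectors (one entry per
#'   subject).
#' @return list with `diffs`, `mean`, `sd`, `n`.
#' @export
paired_discrepancy <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 1)
    stop("inputs must be equal-length, non-empty vectors")
  d <- values_a - values_b
  list(diffs = d, mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else NA_real_,
       n = length(d))
}

#' Wilcoxon signed-rank test (exact enumeration for small n)
#'
#' Zero differences are dropped (Wilcoxon's original policy) and tied
#' absolute differences receive mid-ranks. For n <= `exact_max` the
#' two-sided p-value is computed by exact enumeration of all 2^n sign
#' assignments of the observed ranks; above that, a normal approximation
#' with tie-corrected variance and continuity correction is used. All-zero
#' input returns p = 1.
#'
#' @param diffs numeric vector of paired differences.
#' @param exact_max largest n for which the exact null distribution is
#'   enumerated.
#' @return list with `statistic` (W+, the positive-rank sum), `p.value`,
#'   and `n` (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 12L) {
  if (length(diffs) < 1) stop("empty input")
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p.value = 1, n = 0L))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # subset sums of the rank multiset = all 2^n equally likely W+ values
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    m <- sum(r)
    w_lo <- min(w, m - w)
    p <- (sum(sums <= w_lo + 1e-9) + sum(sums >= m - w_lo - 1e-9)) /
      length(sums)
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-z)
    p <- min(1, max(0, p))
  }
  list(statistic = w, p.value = p, n = n)
}

#' Significance flag
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise (strict
#' inequalities).
#'
#' @param p p-value in [0, 1] (vectorized).
#' @return character vector of flags.
#' @export
flag_significance <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p must be in [0, 1]")
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Paired cohort comparison table
#'
#' Compares two arms of per-subject metric values metric by metric:
#' mean +/- SD per arm, discrepancy (a - b) mean +/- SD, Wilcoxon
#' signed-rank W and p, and the significance flag. This is the layout of
#' the dose-metric comparison tables (3D static vs 4D dynamic;
#' 4D accumulated vs 4D dynamic for interplay).
#'
#' @param values_a,values_b data.frames or matrices, one row per subject
#'   and one column per metric, with identical column names.
#' @param label_a,label_b arm labels recorded in the output.
#' @return data.frame with one row per metric.
#' @export
cohort_compare <- function(values_a, values_b,
                           label_a = "A", label_b = "B") {
  a <- as.data.frame(values_a); b <- as.data.frame(values_b)
  if (!identical(sort(names(a)), sort(names(b))))
    stop("the two arms report different metric sets")
  if (nrow(a) != nrow(b) || nrow(a) < 2)
    stop("need >= 2 subjects with paired values")
  b <- b[names(a)]
  out <- lapply(names(a), function(nm) {
    pd <- paired_discrepancy(a[[nm]], b[[nm]])
    wt <- wilcoxon_signed_rank(pd$diffs)
    data.frame(metric = nm,
               mean_a = mean(a[[nm]]), sd_a = stats::sd(a[[nm]]),
               mean_b = mean(b[[nm]]), sd_b = stats::sd(b[[nm]]),
               mean_diff = pd$mean, sd_diff = pd$sd,
               W = wt$statistic, p = wt$p.value,
               flag = flag_significance(wt$p.value))
  })
  out <- do.call(rbind, out)
  attr(out, "labels") <- c(a = label_a, b = label_b)
  out
}
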