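#' Wilcoxon rank-sum test (shared routine)
#'
#' Single rank-sum entry point used by MR validation, the synergy test and the
#' clinical association battery, so every stage of the pipeline applies the
#' same convention: the p-value is exact (full enumeration of rank
#' assignments) when both groups have at most 12 observations and the pooled
#' sample is tie-free, and otherwise uses the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y numeric vectors, the two groups; both must be nonempty and
#'   finite.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger than y) or
#'   `"less"`.
#' @return list with `W` (Mann-Whitney statistic for `x`), `p`, and `exact`
#'   (logical, whether the exact distribution was used).
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("rank_sum_test: both groups must be numeric")
  }
  if (length(x) == 0L || length(y) == 0L) {
    stop("rank_sum_test: both groups must be nonempty")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("rank_sum_test: values must be finite")
  }
  exact <- length(x) <= 12L && length(y) <= 12L &&
    !as.logical(anyDuplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  list(W = unname(ht$statistic), p = ht$p.value, exact = exact)
}
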