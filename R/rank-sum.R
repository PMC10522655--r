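#' One-sided rank-sum test for UMI count vectors
#'
#' Tests whether the values in `x` are stochastically greater than those in
#' `y` (Wilcoxon rank-sum / Mann-Whitney). UMI counts are small integers, so
#' ties are the rule rather than the exception; for small samples
#' (`n1 + n2 <= exact_limit`) the p-value is computed exactly by enumerating
#' every assignment of the pooled mid-ranks to the two groups, which remains
#' valid under ties. Larger samples use the tie-corrected normal
#' approximation with continuity correction (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_limit Maximum pooled size for exact enumeration.
#' @return The one-sided (greater) p-value.
#' @export
rank_sum_test <- function(x, y, exact_limit = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  if (n1 + n2 <= exact_limit) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    idx <- combn(n1 + n2, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    return(mean(sums >= w_obs - 1e-9))
  }
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  )
}
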