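#' Paired Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on paired observations. Zero
#' differences are dropped; with 25 or fewer non-zero differences and no
#' tied absolute differences the exact distribution is used, otherwise the
#' normal approximation with continuity correction. If all differences are
#' zero the test is undefined and flagged.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (V), `p`, `n` (non-zero pairs) and
#'   `undefined` (logical flag).
#' @examples
#' pairedWilcoxon(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))$p  # 0.03125
#' @export
pairedWilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) < 1L) {
    return(list(statistic = NA_real_, p = NA_real_, n = 0L,
                undefined = TRUE))
  }
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  res <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided", mu = 0,
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p = res$p.value,
       n = length(nz), undefined = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving in its input.
#'
#' @param pvals p-values in \[0, 1\].
#' @return adjusted p-values, elementwise >= the raw values.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling; `NA` with a warning for
#' constant input (undefined correlation).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Spearman's rho.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
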