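#' Shannon diversity index
#'
#' \eqn{-\sum_i p_i \ln p_i} in nats, with \eqn{0 \ln 0 \equiv 0}. Applied to
#' clonotype, lineage, or gene-usage frequency vectors.
#'
#' @param freqs frequency vector; must be non-negative and sum to 1
#'   (tolerance 1e-6).
#' @return Shannon index (nats), non-negative.
#' @examples
#' shannonIndex(rep(0.25, 4))  # ln 4
#' @export
shannonIndex <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' Gini index of a non-negative abundance vector
#'
#' The mean-absolute-difference form
#' \eqn{\sum_i\sum_j |x_i - x_j| / (2 n \sum_j x_j)}: 0 for perfectly even
#' abundances, approaching 1 as mass concentrates on one unit. Scale- and
#' permutation-invariant.
#'
#' @param values non-negative abundances (counts or frequencies), at least
#'   one positive.
#' @return Gini index in \[0, 1).
#' @export
giniIndex <- function(values) {
  if (any(values < 0)) stop("negative value")
  total <- sum(values)
  if (total == 0) stop("all-zero vector")
  n <- length(values)
  x <- sort(values)
  ## sum_i sum_j |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i) for sorted x
  sum((2 * seq_len(n) - n - 1) * x) / (n * total)
}

#' Cumulative frequency of the top N units
#'
#' Sum of the `n` largest frequencies (clonotypes or lineages), a clonality
#' measure that moves opposite to Shannon diversity. If fewer than `n` units
#' exist the result is the full sum (1 for a complete frequency vector).
#'
#' @param freqs frequency vector.
#' @param n number of top units (default 100).
#' @return cumulative frequency in (0, 1].
#' @export
topNCumulative <- function(freqs, n = 100L) {
  if (n < 1) stop("n must be >= 1")
  if (any(freqs < 0)) stop("negative frequency")
  sum(sort(freqs, decreasing = TRUE)[seq_len(min(n, length(freqs)))])
}

#' Per-sample diversity table
#'
#' Computes Shannon, Gini and top-N cumulative frequency per (animal,
#' timepoint, chain-group) at a chosen unit level, optionally after
#' subsampling to fixed depth.
#'
#' @param x a [Repertoire-class].
#' @param level `"clonotype"` or `"lineage"`; lineage-level diversity uses
#'   lineage cumulative frequencies in place of clonotype frequencies and
#'   requires `lineageSet`.
#' @param lineageSet a [LineageSet-class] (required for `level = "lineage"`).
#' @param topN N for the cumulative-frequency metric.
#' @param depth optional named subsampling depths passed to
#'   [subsampleRepertoire()]; `NULL` skips subsampling.
#' @param seed seed for the subsampling draw.
#' @return long-format `data.table`: `animal_id`, `timepoint_hr`,
#'   `chain_group`, `metric`, `level`, `value`, `n_units`, `depth`, `seed`.
#' @export
diversityTable <- function(x, level = c("clonotype", "lineage"),
                           lineageSet = NULL, topN = 100L,
                           depth = NULL, seed = 1L) {
  level <- match.arg(level)
  if (!is.null(depth)) x <- subsampleRepertoire(x, n = depth, seed = seed)
  if (level == "clonotype") {
    cl <- buildClonotypes(x)
    grp <- cl[, .(freqs = list(frequency)),
              by = .(animal_id, timepoint_hr, chain_group)]
  } else {
    if (is.null(lineageSet)) stop("lineage-level diversity needs a LineageSet")
    met <- merge(lineageSet@metrics,
                 lineageSet@lineages[, .(lineage_id, animal_id, chain_group)],
                 by = "lineage_id")
    met <- met[!is.na(cum_frequency) & cum_frequency > 0]
    grp <- met[, .(freqs = list(cum_frequency)),
               by = .(animal_id, timepoint_hr, chain_group)]
  }
  out <- grp[, {
    f <- freqs[[1]]
    ## lineage cumulative frequencies need not sum exactly to 1 (lineages
    ## absent at a timepoint carry no mass); renormalise for Shannon
    p <- f / sum(f)
    data.table(
      metric = c("shannon", "gini", sprintf("top%d", topN)),
      value = c(shannonIndex(p), giniIndex(f), topNCumulative(p, topN)),
      n_units = length(f)
    )
  }, by = .(animal_id, timepoint_hr, chain_group)]
  out[, `:=`(level = level,
             depth = if (is.null(depth)) NA_real_ else sum(unlist(depth)),
             seed = if (is.null(depth)) NA_integer_ else as.integer(seed))]
  out[]
}
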