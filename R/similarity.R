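#' Morisita-Horn similarity index
#'
#' Abundance-weighted similarity between two count vectors aligned on a
#' common label space:
#' \deqn{C_H = \frac{2 \sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\, X Y}}
#' where \eqn{X = \sum_i x_i}, \eqn{Y = \sum_i y_i}. 0 for disjoint supports,
#' 1 for proportionally identical composition; invariant to proportional
#' scaling of either vector.
#'
#' @param a,b numeric count vectors. Either both named (aligned on the union
#'   of names, absent labels counting 0) or unnamed of equal length.
#' @return similarity in \[0, 1\].
#' @examples
#' morisitaHorn(c(2, 2), c(1, 3))  # 8/9
#' @export
morisitaHorn <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    labs <- union(names(a), names(b))
    x <- ifelse(is.na(a[labs]), 0, a[labs])
    y <- ifelse(is.na(b[labs]), 0, b[labs])
  } else {
    if (length(a) != length(b)) stop("unnamed vectors must have equal length")
    x <- a; y <- b
  }
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("zero total count")
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Lineage overlap index between two timepoints
#'
#' Overlap coefficient \eqn{|A \cap B| / \min(|A|, |B|)} between two sets of
#' lineage identifiers (default), robust to large size asymmetry between
#' lineage pools; the Jaccard index \eqn{|A \cap B| / |A \cup B|} is
#' available via `method`.
#'
#' @param a,b character vectors of lineage IDs (non-empty).
#' @param method `"overlap"` (default) or `"jaccard"`.
#' @return overlap in \[0, 1\].
#' @export
overlapIndex <- function(a, b, method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty lineage set")
  inter <- length(intersect(a, b))
  switch(method,
    overlap = inter / min(length(a), length(b)),
    jaccard = inter / length(union(a, b)))
}

#' Spearman correlation of gene usage between two samples
#'
#' Rank correlation (average-rank ties) of gene frequencies aligned on the
#' union of gene labels, the inter-individual gene-usage similarity measure.
#'
#' @param a,b named frequency vectors (gene -> frequency), aligned on the
#'   union of names with absent genes counting 0; or unnamed equal-length
#'   vectors.
#' @return Spearman's rho, or `NA` with a warning when either aligned vector
#'   is constant (undefined correlation).
#' @export
geneUsageCorrelation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    labs <- union(names(a), names(b))
    x <- ifelse(is.na(a[labs]), 0, a[labs])
    y <- ifelse(is.na(b[labs]), 0, b[labs])
  } else {
    if (length(a) != length(b)) stop("unnamed vectors must have equal length")
    x <- a; y <- b
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Pairwise timepoint overlap matrix for a lineage set
#'
#' For one animal and chain-group, computes the [overlapIndex()] between the
#' sets of lineages present (unique CDR3 count >= 1) at every pair of
#' timepoints, optionally restricted to a subset of lineage IDs (e.g. the
#' expanded set).
#'
#' @param ls a [LineageSet-class].
#' @param animal animal ID.
#' @param chainGroup `"IGH"` or `"IgKL"`.
#' @param ids optional character vector restricting the lineage universe.
#' @param method passed to [overlapIndex()].
#' @return symmetric matrix of overlap indices, dimnames = timepoints.
#' @export
timepointOverlapMatrix <- function(ls, animal, chainGroup = "IgKL",
                                   ids = NULL, method = "overlap") {
  lin <- ls@lineages[animal_id == animal & chain_group == chainGroup]
  keep <- if (is.null(ids)) lin$lineage_id else intersect(lin$lineage_id, ids)
  met <- ls@metrics[lineage_id %in% keep & unique_cdr3 >= 1L]
  tps <- sort(unique(met$timepoint_hr))
  sets <- lapply(tps, function(t) met[timepoint_hr == t, lineage_id])
  m <- diag(1, length(tps))
  dimnames(m) <- list(tps, tps)
  if (length(tps) >= 2L) {
    for (i in seq_along(tps)[-length(tps)]) {
      for (j in (i + 1L):length(tps)) {
        m[i, j] <- m[j, i] <- overlapIndex(sets[[i]], sets[[j]], method)
      }
    }
  }
  m
}
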