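#' Cluster clonotypes into clonal lineages
#'
#' Lineages group clonotypes presumed to descend from one ancestral B cell:
#' clonotypes sharing the same V gene, J gene and CDR3 length, whose CDR3
#' amino-acid sequences are connected under single linkage with hamming
#' distance at most 1 (so two CDR3s two mismatches apart may co-cluster via
#' an intermediate). Clustering is per animal and per chain-group, pooling
#' clonotypes from all timepoints; per-lineage per-timepoint metrics
#' (cumulative frequency, unique CDR3 count, pooled mean mutation rate) are
#' computed afterwards by regrouping members by timepoint.
#'
#' The hamming-1 graph is built with a masked-position hash: two distinct
#' equal-length CDR3s are hamming-1 neighbours iff they agree after masking
#' some single position, so scanning each position once finds all edges in
#' O(n L) hash operations without an all-pairs comparison.
#'
#' Lineage IDs are deterministic:
#' `animal|chain_group|v|j|len|<lexicographically smallest member CDR3>`.
#'
#' @param clonotypes clonotype table from [buildClonotypes()] covering all
#'   timepoints of the animals to cluster (the per-timepoint `frequency`,
#'   `mm_sum`, `len_sum` columns feed the metrics).
#' @param timepoints integer vector of timepoints the metrics table should
#'   cover; defaults to those observed.
#' @return a [LineageSet-class].
#' @export
clusterLineages <- function(clonotypes, timepoints = NULL) {
  cl <- as.data.table(clonotypes)
  need <- c("animal_id", "chain_group", "chain", "v_call", "j_call",
            "cdr3_aa", "timepoint_hr", "count", "frequency", "mm_sum",
            "len_sum")
  missing_cols <- setdiff(need, names(cl))
  if (length(missing_cols)) {
    stop("clonotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(timepoints)) timepoints <- sort(unique(cl$timepoint_hr))
  timepoints <- as.integer(timepoints)
  cl <- copy(cl)[, cdr3_len := nchar(cdr3_aa)]

  keys <- unique(cl[, .(animal_id, chain_group, chain, v_call, j_call,
                        cdr3_len, cdr3_aa)])
  keys[, gkey := paste(animal_id, chain_group, v_call, j_call, cdr3_len,
                       sep = "\r")]
  keys[, idx := .I]
  n <- nrow(keys)
  comp <- .singleLinkageComponents(keys, n)
  keys[, comp := comp]
  keys[, lineage_id := paste(animal_id, chain_group, v_call, j_call,
                             cdr3_len, min(cdr3_aa), sep = "|"),
       by = comp]

  members <- merge(
    cl,
    keys[, .(animal_id, chain_group, chain, v_call, j_call, cdr3_aa,
             lineage_id)],
    by = c("animal_id", "chain_group", "chain", "v_call", "j_call",
           "cdr3_aa"))
  members <- members[, .(lineage_id, animal_id, chain_group, chain, v_call,
                         j_call, cdr3_aa, timepoint_hr, count, frequency,
                         mm_sum, len_sum)]
  setorderv(members, c("lineage_id", "timepoint_hr", "cdr3_aa"))

  lin <- keys[, .(
    animal_id = animal_id[1L], chain_group = chain_group[1L],
    v_call = v_call[1L], j_call = j_call[1L], cdr3_len = cdr3_len[1L],
    n_clonotypes = length(unique(cdr3_aa))
  ), by = lineage_id]
  setorderv(lin, "lineage_id")

  observed <- members[, .(
    cum_frequency = sum(frequency),
    unique_cdr3 = length(unique(cdr3_aa)),
    mean_mutation_rate = 100 * sum(mm_sum) / sum(len_sum)
  ), by = .(lineage_id, timepoint_hr)]
  grid <- CJ(lineage_id = lin$lineage_id, timepoint_hr = timepoints)
  metrics <- merge(grid, observed, by = c("lineage_id", "timepoint_hr"),
                   all.x = TRUE)
  metrics[is.na(cum_frequency), `:=`(cum_frequency = 0, unique_cdr3 = 0L)]
  setorderv(metrics, c("lineage_id", "timepoint_hr"))

  new("LineageSet", lineages = lin, members = members, metrics = metrics,
      timepoints = timepoints)
}

## Connected components of the <=1-mismatch single-linkage graph over the
## `keys` table (one row per distinct clonotype). Union-find over edges
## discovered by masking one CDR3 position at a time.
.singleLinkageComponents <- function(keys, n) {
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    edges <- vector("list", max(keys$cdr3_len))
    for (p in seq_len(max(keys$cdr3_len))) {
      sub <- keys[cdr3_len >= p]
      if (nrow(sub) < 2L) next
      mk <- paste(sub$gkey,
                  substr(sub$cdr3_aa, 1L, p - 1L),
                  substring(sub$cdr3_aa, p + 1L), sep = "\r")
      e <- data.table(idx = sub$idx, mk = mk)[
        , if (.N > 1L) list(a = idx[1L], b = idx[-1L]), by = mk]
      if (nrow(e)) edges[[p]] <- e[, .(a, b)]
    }
    edges <- rbindlist(edges[!vapply(edges, is.null, TRUE)])
    if (nrow(edges)) {
      for (k in seq_len(nrow(edges))) {
        ra <- findRoot(edges$a[k]); rb <- findRoot(edges$b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  vapply(seq_len(n), findRoot, integer(1))
}
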