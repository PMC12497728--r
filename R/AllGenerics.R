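#' @rdname Repertoire-class
#' @param x a `Repertoire` or `LineageSet`.
#' @export
setGeneric("rearrangements", function(x) standardGeneric("rearrangements"))

#' @rdname Repertoire-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname Repertoire-class
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname Repertoire-class
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname LineageSet-class
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname LineageSet-class
#' @export
setGeneric("lineageMembers", function(x) standardGeneric("lineageMembers"))

#' @rdname LineageSet-class
#' @export
setGeneric("lineageMetrics", function(x) standardGeneric("lineageMetrics"))

#' @describeIn Repertoire-class the rearrangement records as a `data.table`
#'   (a copy; mutating it does not alter the object).
#' @export
setMethod("rearrangements", "Repertoire", function(x) copy(x@rearrangements))

#' @describeIn Repertoire-class total sequence count (sum of
#'   `duplicate_count`).
#' @export
setMethod("nSequences", "Repertoire", function(x) {
  sum(as.numeric(x@rearrangements$duplicate_count))
})

#' @describeIn Repertoire-class animal identifiers present.
#' @export
setMethod("animalIds", "Repertoire", function(x) {
  sort(unique(x@rearrangements$animal_id))
})

#' @describeIn Repertoire-class timepoints (hours) present.
#' @export
setMethod("timepoints", "Repertoire", function(x) {
  sort(unique(x@rearrangements$timepoint_hr))
})

setMethod("show", "Repertoire", function(object) {
  dt <- object@rearrangements
  cat("Repertoire with", nrow(dt), "records,",
      format(sum(as.numeric(dt$duplicate_count)), big.mark = ","),
      "sequences\n")
  if (nrow(dt)) {
    cat("  animals:   ", paste(sort(unique(dt$animal_id)), collapse = ", "), "\n")
    cat("  timepoints:", paste(sort(unique(dt$timepoint_hr)), collapse = ", "),
        "hr\n")
    cat("  chains:    ", paste(sort(unique(dt$chain)), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @describeIn LineageSet-class one-row-per-lineage summary table.
#' @export
setMethod("lineages", "LineageSet", function(x) copy(x@lineages))

#' @describeIn LineageSet-class clonotype-to-lineage membership with
#'   per-timepoint counts.
#' @export
setMethod("lineageMembers", "LineageSet", function(x) copy(x@members))

#' @describeIn LineageSet-class per-lineage per-timepoint metrics
#'   (cumulative frequency, unique CDR3 count, mean mutation rate).
#' @export
setMethod("lineageMetrics", "LineageSet", function(x) copy(x@metrics))

#' @describeIn Repertoire-class timepoints covered by a `LineageSet`.
#' @export
setMethod("timepoints", "LineageSet", function(x) x@timepoints)

setMethod("show", "LineageSet", function(object) {
  cat("LineageSet with", nrow(object@lineages), "lineages over",
      length(object@timepoints), "timepoints\n")
  if (nrow(object@lineages)) {
    tab <- object@lineages[, .N, by = c("animal_id", "chain_group")]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %s / %s: %d lineages\n",
                  tab$animal_id[i], tab$chain_group[i], tab$N[i]))
    }
  }
  invisible(NULL)
})
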