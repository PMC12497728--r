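#' Run the longitudinal expansion-detection pipeline
#'
#' Clonotype aggregation, per-animal lineage clustering pooled across
#' timepoints, per-lineage per-timepoint metrics, fold-change computation
#' and expanded-lineage calling — the full analysis chain from a cohort
#' [Repertoire-class] to expansion calls.
#'
#' @param x a [Repertoire-class] covering one or more animals and
#'   timepoints.
#' @param thresholds expansion thresholds, see [defaultThresholds()].
#' @param triggers trigger timepoints (hours).
#' @param baseline baseline timepoint (hours).
#' @param literalDecreased passed to [classifyFoldChange()].
#' @return list with `clonotypes` (table), `lineages` (a
#'   [LineageSet-class]), `foldChanges` (table) and `calls`
#'   (expansion calls from [identifyExpanded()]).
#' @export
analyzeCohort <- function(x, thresholds = defaultThresholds(),
                          triggers = c(48L, 72L), baseline = 0L,
                          literalDecreased = FALSE) {
  stopifnot(is(x, "Repertoire"))
  cl <- buildClonotypes(x)
  ls <- clusterLineages(cl)
  fc <- foldChanges(ls, baseline = baseline)
  calls <- identifyExpanded(ls, thresholds = thresholds, triggers = triggers,
                            baseline = baseline,
                            literalDecreased = literalDecreased)
  list(clonotypes = cl, lineages = ls, foldChanges = fc, calls = calls)
}

#' Map planted-truth lineages to detected lineages
#'
#' Each planted lineage is identified in the clustered [LineageSet-class]
#' by the lineage containing its founder clonotype (animal, chain, V, J,
#' founder CDR3).
#'
#' @param truth planted-truth table from [generateCohort()].
#' @param ls a [LineageSet-class].
#' @return `truth` with a `lineage_id` column (`NA` when the planted
#'   founder was never observed).
#' @export
mapTruthToLineages <- function(truth, ls) {
  mem <- unique(ls@members[, .(animal_id, chain, v_call, j_call, cdr3_aa,
                               lineage_id)])
  out <- merge(as.data.table(truth), mem,
               by = c("animal_id", "chain", "v_call", "j_call", "cdr3_aa"),
               all.x = TRUE)
  setorderv(out, "planted_id")
  out[]
}

#' Recall and precision of planted-expansion recovery
#'
#' Compares expansion calls against the generator's planted ground truth:
#' recall is the fraction of planted lineages called expanded; precision is
#' the fraction of expanded calls that correspond to a planted lineage.
#'
#' @param calls expansion calls from [identifyExpanded()].
#' @param ls the [LineageSet-class] the calls derive from.
#' @param truth planted-truth table from [generateCohort()].
#' @return list with `recall`, `precision`, `nExpanded`, `nPlanted`,
#'   `truthCalls` (the truth table with `lineage_id` and `detected`).
#' @export
evaluateRecovery <- function(calls, ls, truth) {
  tm <- mapTruthToLineages(truth, ls)
  exp_ids <- calls[status == "expanded", lineage_id]
  tm[, detected := !is.na(lineage_id) & lineage_id %in% exp_ids]
  planted_ids <- unique(tm[!is.na(lineage_id), lineage_id])
  tp <- sum(exp_ids %in% planted_ids)
  list(
    recall = if (nrow(tm)) mean(tm$detected) else NA_real_,
    precision = if (length(exp_ids)) tp / length(exp_ids) else NA_real_,
    nExpanded = length(exp_ids),
    nPlanted = nrow(tm),
    truthCalls = tm[]
  )
}

#' Export pipeline result tables as TSV
#'
#' Writes the clonotype table, lineage table with per-timepoint metrics,
#' fold changes, and expansion calls (with a JSON summary of counts per
#' status and per criterion combination) into a directory.
#'
#' @param result list from [analyzeCohort()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the written file paths.
#' @export
exportResults <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    clonotypes = file.path(dir, "clonotypes.tsv"),
    lineages = file.path(dir, "lineages.tsv"),
    metrics = file.path(dir, "lineage_metrics.tsv"),
    fold_changes = file.path(dir, "fold_changes.tsv"),
    calls = file.path(dir, "expansion_calls.tsv"),
    summary = file.path(dir, "expansion_summary.json")
  )
  fwrite(result$clonotypes, paths[["clonotypes"]], sep = "\t")
  fwrite(lineages(result$lineages), paths[["lineages"]], sep = "\t")
  fwrite(lineageMetrics(result$lineages), paths[["metrics"]], sep = "\t")
  fwrite(result$foldChanges, paths[["fold_changes"]], sep = "\t")
  fwrite(result$calls, paths[["calls"]], sep = "\t")
  calls <- result$calls
  summary <- list(
    n_lineages = nrow(calls),
    by_status = as.list(table(calls$status)),
    expanded_by_criteria = as.list(table(
      calls[status == "expanded", criteria_met]))
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths[["summary"]])
  invisible(paths)
}
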