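#' Default expanded-lineage thresholds
#'
#' Chain-group-specific criterion pairs for calling agonist-induced expanded
#' lineages at a trigger timepoint: a log2 fold-change threshold over the
#' 0 hr baseline plus an absolute threshold on the post-stimulation value.
#' Light chains (IgKL): frequency log2FC > 3 with frequency > 0.001%
#' (1e-5 as a fraction); unique CDR3 count log2FC > 2 with count > 5;
#' mutation rate log2FC > 1.3 with rate > 6%. Heavy chain (IGH): frequency
#' log2FC > 3 with frequency > 0.001%; mutation rate log2FC > 1.5 with
#' rate > 5%.
#'
#' @return nested list `thresholds[[chain_group]][[index]] = list(log2fc, abs)`.
#' @export
defaultThresholds <- function() {
  list(
    IgKL = list(
      frequency = list(log2fc = 3, abs = 1e-5),
      unique_cdr3 = list(log2fc = 2, abs = 5),
      mutation_rate = list(log2fc = 1.3, abs = 6)
    ),
    IGH = list(
      frequency = list(log2fc = 3, abs = 1e-5),
      mutation_rate = list(log2fc = 1.5, abs = 5)
    )
  )
}

.INDICES <- c("frequency", "unique_cdr3", "mutation_rate")

#' Per-lineage log2 fold changes vs the pre-stimulation baseline
#'
#' For each lineage and each of the three indices (cumulative frequency,
#' unique CDR3 count, mean mutation rate), computes
#' `log2(value at t / value at baseline)` for every post-baseline timepoint.
#' The fold change is defined only when baseline and post values are both
#' present and positive; a lineage absent at baseline or absent at the post
#' timepoint gets `NA` (it is excluded from increased/decreased/expanded
#' classification rather than treated as an infinite fold change).
#'
#' @param ls a [LineageSet-class].
#' @param baseline baseline timepoint in hours (default 0).
#' @return a `data.table`: `lineage_id`, `animal_id`, `chain_group`,
#'   `index`, `timepoint_hr`, `baseline_value`, `post_value`, `log2_fc`.
#' @export
foldChanges <- function(ls, baseline = 0L) {
  stopifnot(is(ls, "LineageSet"))
  met <- copy(ls@metrics)
  long <- rbindlist(list(
    met[, .(lineage_id, timepoint_hr, index = "frequency",
            value = cum_frequency)],
    met[, .(lineage_id, timepoint_hr, index = "unique_cdr3",
            value = as.numeric(unique_cdr3))],
    met[, .(lineage_id, timepoint_hr, index = "mutation_rate",
            value = mean_mutation_rate)]
  ))
  base <- long[timepoint_hr == baseline,
               .(lineage_id, index, baseline_value = value)]
  post <- long[timepoint_hr != baseline]
  fc <- merge(post, base, by = c("lineage_id", "index"), all.x = TRUE)
  fc[, log2_fc := ifelse(!is.na(baseline_value) & baseline_value > 0 &
                           !is.na(value) & value > 0,
                         log2(value / baseline_value), NA_real_)]
  setnames(fc, "value", "post_value")
  fc <- merge(fc, ls@lineages[, .(lineage_id, animal_id, chain_group)],
              by = "lineage_id")
  setorderv(fc, c("lineage_id", "index", "timepoint_hr"))
  fc[, .(lineage_id, animal_id, chain_group, index, timepoint_hr,
         baseline_value, post_value, log2_fc)]
}

#' Classify a fold change as increased / decreased / neither
#'
#' A lineage is increased on an index when log2(FC) > 1 (at least 2-fold
#' increase) and decreased when FC < 0.5, i.e. log2(FC) < -1, the
#' fold-scale-symmetric counterpart. The literal threshold
#' `log2(FC) < 0.5` is available via `literalDecreased = TRUE`.
#' Classification is per index and per timepoint; undefined fold changes
#' give `"neither"`.
#'
#' @param log2fc numeric vector of log2 fold changes (`NA` = undefined).
#' @param literalDecreased use the literal `log2(FC) < 0.5` decreased rule.
#' @return character vector: `"increased"`, `"decreased"` or `"neither"`.
#' @export
classifyFoldChange <- function(log2fc, literalDecreased = FALSE) {
  dec_cut <- if (literalDecreased) 0.5 else -1
  out <- rep("neither", length(log2fc))
  out[!is.na(log2fc) & log2fc > 1] <- "increased"
  out[!is.na(log2fc) & log2fc < dec_cut & !(!is.na(log2fc) & log2fc > 1)] <-
    "decreased"
  out
}

#' Counts of increased and decreased lineages per sample and index
#'
#' @param fc fold-change table from [foldChanges()].
#' @param literalDecreased passed to [classifyFoldChange()].
#' @return `data.table`: `animal_id`, `chain_group`, `index`,
#'   `timepoint_hr`, `n_increased`, `n_decreased`, `n_undefined`.
#' @export
countIncreasedDecreased <- function(fc, literalDecreased = FALSE) {
  fc <- copy(as.data.table(fc))
  fc[, cls := classifyFoldChange(log2_fc, literalDecreased)]
  fc[, .(n_increased = sum(cls == "increased"),
         n_decreased = sum(cls == "decreased"),
         n_undefined = sum(is.na(log2_fc))),
     by = .(animal_id, chain_group, index, timepoint_hr)]
}

#' Identify agonist-induced expanded lineages
#'
#' A lineage is called expanded when, at either trigger timepoint (48 or
#' 72 hr by default), at least one criterion pair of its chain-group holds:
#' the index's log2 fold change over baseline exceeds the fold-change
#' threshold AND the post-stimulation value at that same timepoint exceeds
#' the absolute threshold (see [defaultThresholds()]). Criteria are combined
#' with OR; `criteria_met` records which indices fired. Non-expanded
#' lineages are labelled `increased` / `decreased` / `unchanged` from their
#' per-index fold-change classes at the trigger timepoints (increased wins
#' over decreased when both occur on different indices).
#'
#' @param ls a [LineageSet-class].
#' @param thresholds nested threshold list, see [defaultThresholds()].
#' @param triggers trigger timepoints (hours).
#' @param baseline baseline timepoint (hours).
#' @param literalDecreased passed to [classifyFoldChange()].
#' @return a `data.table`, one row per lineage: `lineage_id`, `animal_id`,
#'   `chain_group`, `status`, `criteria_met` (comma-separated),
#'   `n_criteria`, `trigger_timepoint` (`NA` unless expanded), and
#'   `log2fc_<index>_<tp>` columns for the trigger timepoints.
#' @export
identifyExpanded <- function(ls, thresholds = defaultThresholds(),
                             triggers = c(48L, 72L), baseline = 0L,
                             literalDecreased = FALSE) {
  fc <- foldChanges(ls, baseline = baseline)
  fc <- fc[timepoint_hr %in% triggers]
  fc[, `:=`(crit_log2 = NA_real_, crit_abs = NA_real_)]
  for (cg in names(thresholds)) {
    for (idx in names(thresholds[[cg]])) {
      th <- thresholds[[cg]][[idx]]
      fc[chain_group == cg & index == idx,
         `:=`(crit_log2 = th$log2fc, crit_abs = th$abs)]
    }
  }
  fc[, met := !is.na(log2_fc) & !is.na(crit_log2) &
       log2_fc > crit_log2 & post_value > crit_abs]
  fc[, cls := classifyFoldChange(log2_fc, literalDecreased)]

  calls <- fc[, {
    tp_met <- sort(unique(timepoint_hr[met]))
    crits <- sort(unique(index[met]))
    status <- if (length(crits)) "expanded"
              else if (any(cls == "increased")) "increased"
              else if (any(cls == "decreased")) "decreased"
              else "unchanged"
    list(status = status,
         criteria_met = paste(crits, collapse = ","),
         n_criteria = length(crits),
         trigger_timepoint = if (length(tp_met)) tp_met[1L] else NA_integer_)
  }, by = .(lineage_id, animal_id, chain_group)]

  wide <- dcast(fc, lineage_id ~ index + timepoint_hr, value.var = "log2_fc")
  setnames(wide, setdiff(names(wide), "lineage_id"),
           paste0("log2fc_", setdiff(names(wide), "lineage_id")))
  calls <- merge(calls, wide, by = "lineage_id")
  setorderv(calls, "lineage_id")
  calls[]
}

#' Constant lineages among the expanded set
#'
#' Expanded lineages present (unique CDR3 count >= 1) at every timepoint the
#' lineage set covers, and the percentage of constant lineages among the
#' expanded set.
#'
#' @param calls expansion calls from [identifyExpanded()].
#' @param ls the [LineageSet-class] the calls derive from.
#' @return list with `ids` (constant expanded lineage IDs), `n_expanded`,
#'   `n_constant` and `pct` (percentage of expanded lineages that are
#'   constant).
#' @export
constantLineages <- function(calls, ls) {
  exp_ids <- calls[status == "expanded", lineage_id]
  if (length(exp_ids) == 0L) {
    return(list(ids = character(0), n_expanded = 0L, n_constant = 0L,
                pct = NA_real_))
  }
  present <- ls@metrics[lineage_id %in% exp_ids,
                        .(all_present = all(unique_cdr3 >= 1L)),
                        by = lineage_id]
  ids <- present[all_present == TRUE, lineage_id]
  list(ids = ids, n_expanded = length(exp_ids), n_constant = length(ids),
       pct = 100 * length(ids) / length(exp_ids))
}

#' Baseline members of expanded lineages (origin tracing)
#'
#' Returns the 0 hr (pre-stimulation) rearrangement records of each expanded
#' lineage — the "original-expanded" view used to infer the state of the B
#' cells the expansion started from — annotated with per-sequence mutation
#' rate and mutation class. Expanded lineages with no baseline members are
#' excluded and counted.
#'
#' @param calls expansion calls from [identifyExpanded()].
#' @param ls the [LineageSet-class].
#' @param x the [Repertoire-class] holding the underlying records.
#' @param ids optional explicit lineage IDs (overrides the expanded set in
#'   `calls`; used for control comparisons).
#' @param baseline baseline timepoint (hours).
#' @return list with `records` (a `data.table` of baseline records with
#'   `lineage_id`, `rate`, `class`), `classFractions` (duplicate-weighted
#'   fractions per mutation class), and `nExcluded` (expanded lineages
#'   absent at baseline).
#' @export
originalExpanded <- function(calls, ls, x, ids = NULL, baseline = 0L) {
  if (is.null(ids)) ids <- calls[status == "expanded", lineage_id]
  mem <- unique(ls@members[lineage_id %in% ids,
                           .(lineage_id, animal_id, chain, v_call, j_call,
                             cdr3_aa)])
  rec <- copy(x@rearrangements)[timepoint_hr == baseline]
  rec[, `:=`(v_call = .stripAllele(v_call), j_call = .stripAllele(j_call))]
  hits <- merge(rec, mem,
                by = c("animal_id", "chain", "v_call", "j_call", "cdr3_aa"))
  hits[, rate := 100 * (v_mismatches + j_mismatches) /
         (v_aligned_len + j_aligned_len)]
  hits[, class := classifyMutation(chain, isotype, rate)]
  present <- unique(hits$lineage_id)
  fr <- hits[, .(count = sum(as.numeric(duplicate_count))), by = class]
  fr[, fraction := count / sum(count)]
  list(records = hits[], classFractions = fr[],
       nExcluded = length(setdiff(ids, present)))
}

#' Sample control lineages matched to a reference set
#'
#' Draws a control set from the non-reference lineage pool of the same
#' animal and chain-group, either matching the reference's frequency
#' distribution (stratified draw over 10 log10-spaced frequency bins
#' spanning the pool's nonzero range, falling back to the nearest
#' non-exhausted stratum with a warning) or matching the reference's size
#' and kappa:lambda lineage-count split.
#'
#' @param ls a [LineageSet-class].
#' @param reference character vector of reference (e.g. expanded) lineage
#'   IDs.
#' @param mode `"match_frequency_distribution"` or
#'   `"match_kl_ratio_and_count"`.
#' @param timepoint timepoint (hours) whose cumulative frequencies are
#'   matched in frequency mode.
#' @param nBins number of log10-spaced frequency bins.
#' @param seed integer seed.
#' @return character vector of control lineage IDs.
#' @export
sampleControlLineages <- function(ls, reference,
                                  mode = c("match_frequency_distribution",
                                           "match_kl_ratio_and_count"),
                                  timepoint = 72L, nBins = 10L, seed = 1L) {
  mode <- match.arg(mode)
  lin <- ls@lineages
  ref <- lin[lineage_id %in% reference]
  if (nrow(ref) == 0L) stop("empty reference set")
  groups <- unique(ref[, .(animal_id, chain_group)])
  out <- character(0)
  .withSeed(seed, {
    for (g in seq_len(nrow(groups))) {
      ref_g <- ref[animal_id == groups$animal_id[g] &
                     chain_group == groups$chain_group[g], lineage_id]
      pool <- lin[animal_id == groups$animal_id[g] &
                    chain_group == groups$chain_group[g] &
                    !lineage_id %in% reference, lineage_id]
      if (length(pool) < length(ref_g)) stop("control pool too small")
      picked <- if (mode == "match_frequency_distribution") {
        .matchFrequencyDraw(ls, ref_g, pool, timepoint, nBins)
      } else {
        .matchKlCountDraw(ls, ref_g, pool)
      }
      out <- c(out, picked)
    }
  })
  out
}

.lineageChain <- function(ls, ids) {
  mem <- unique(ls@members[lineage_id %in% ids, .(lineage_id, chain)])
  stats::setNames(mem$chain, mem$lineage_id)[ids]
}

.matchFrequencyDraw <- function(ls, ref_ids, pool_ids, timepoint, nBins) {
  met <- ls@metrics[timepoint_hr == timepoint & cum_frequency > 0]
  freqs <- stats::setNames(met$cum_frequency, met$lineage_id)
  pool_f <- freqs[pool_ids]
  pool_ids <- pool_ids[!is.na(pool_f)]
  pool_f <- pool_f[!is.na(pool_f)]
  ref_f <- freqs[ref_ids]
  ref_f <- ref_f[!is.na(ref_f)]
  if (length(ref_f) == 0L) return(character(0))
  rng <- log10(range(pool_f))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  binOf <- function(f) {
    pmin(pmax(findInterval(log10(f), breaks, rightmost.closed = TRUE), 1L),
         nBins)
  }
  ref_bin <- binOf(ref_f)
  pool_bin <- binOf(pool_f)
  picked <- character(0)
  avail <- split(pool_ids, factor(pool_bin, levels = seq_len(nBins)))
  for (b in seq_len(nBins)) {
    need <- sum(ref_bin == b)
    if (need == 0L) next
    take_bin <- b
    while (need > 0L) {
      have <- setdiff(avail[[take_bin]], picked)
      k <- min(need, length(have))
      if (k > 0L) {
        picked <- c(picked, if (length(have) == 1L) have
                            else sample(have, k))
        need <- need - k
      }
      if (need > 0L) {
        ## nearest non-exhausted stratum fallback
        order_b <- order(abs(seq_len(nBins) - b))
        nxt <- NULL
        for (cand in seq_len(nBins)[order_b]) {
          if (length(setdiff(avail[[cand]], picked))) { nxt <- cand; break }
        }
        if (is.null(nxt)) stop("control pool exhausted")
        warning(sprintf("frequency stratum %d exhausted; borrowing from stratum %d",
                        b, nxt))
        take_bin <- nxt
      }
    }
  }
  picked
}

.matchKlCountDraw <- function(ls, ref_ids, pool_ids) {
  ref_chain <- .lineageChain(ls, ref_ids)
  pool_chain <- .lineageChain(ls, pool_ids)
  picked <- character(0)
  for (ch in unique(ref_chain)) {
    need <- sum(ref_chain == ch)
    have <- pool_ids[pool_chain == ch]
    if (length(have) < need) stop("control pool too small for chain ", ch)
    picked <- c(picked, if (length(have) == 1L) have else sample(have, need))
  }
  picked
}

#' Kappa/lambda composition of a lineage subset
#'
#' Sequence-count kappa/lambda ratio (and lineage-count split) of a set of
#' light-chain lineages at one timepoint.
#'
#' @param ls a [LineageSet-class].
#' @param ids lineage IDs (light-chain).
#' @param timepoint timepoint (hours); `NULL` pools all timepoints.
#' @return list with `ratio` (IGK/IGL summed member counts; `Inf` when no
#'   IGL), `nKappa`, `nLambda` (lineage counts by chain).
#' @export
kappaLambdaOfLineages <- function(ls, ids, timepoint = 72L) {
  mem <- ls@members[lineage_id %in% ids]
  if (!is.null(timepoint)) mem <- mem[timepoint_hr == timepoint]
  counts <- mem[, .(n = sum(count)), by = chain]
  k <- sum(counts[chain == "IGK", n])
  l <- sum(counts[chain == "IGL", n])
  chains <- .lineageChain(ls, unique(mem$lineage_id))
  list(ratio = if (l > 0) k / l else Inf,
       nKappa = sum(chains == "IGK"), nLambda = sum(chains == "IGL"))
}
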