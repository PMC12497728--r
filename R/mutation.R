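#' Somatic hypermutation rate (pooled, percent)
#'
#' \eqn{100 (\sum_i v_i + \sum_i j_i) / (\sum_i V_i + \sum_i J_i)} over the
#' given sequences: mismatch counts in the V and J regions summed over
#' sequences, divided by the summed aligned region lengths. Pooling is
#' additive in numerator and denominator, so the rate of a group equals the
#' rate computed from its concatenated members.
#'
#' @param vMismatches,jMismatches per-sequence mismatch counts.
#' @param vLen,jLen per-sequence aligned V/J region lengths (nt, positive).
#' @param weights sequence multiplicities (e.g. `duplicate_count`);
#'   default 1.
#' @return pooled mutation rate in percent.
#' @examples
#' shmRate(2, 1, 90, 30)  # 2.5
#' @export
shmRate <- function(vMismatches, jMismatches, vLen, jLen, weights = 1) {
  den <- sum(weights * (vLen + jLen))
  if (den <= 0) stop("zero total aligned length")
  100 * sum(weights * (vMismatches + jMismatches)) / den
}

.MUTATION_CLASSES_IGH <- c("IgMD_nonmutated", "IgAGE_mutated", "IgM_mutated",
                           "other")
.MUTATION_CLASSES_IGKL <- c("IgKL_nonmutated", "IgKL_intermediate",
                            "IgKL_mutated")

#' Classify sequences into mutation/isotype classes
#'
#' Partition used as a proxy for B-cell state. Heavy chain: IgM/IgD with
#' mutation rate < 0.5% -> `IgMD_nonmutated` (naive-like); IgA/IgG/IgE with
#' rate > 3% -> `IgAGE_mutated` (memory/effector-like); IgM with rate > 3%
#' -> `IgM_mutated` (IgM-memory-like); everything else -> `other`. Light
#' chains: rate < 0.5% -> `IgKL_nonmutated`; rate > 4% -> `IgKL_mutated`;
#' otherwise `IgKL_intermediate`. Thresholds are strict inequalities;
#' boundary values fall into the intermediate/other classes.
#'
#' @param chain chain labels ("IGH", "IGK", "IGL").
#' @param isotype isotype labels (`NA` for light chains).
#' @param rate per-sequence mutation rates in percent.
#' @return character vector of class labels.
#' @export
classifyMutation <- function(chain, isotype, rate) {
  n <- max(length(chain), length(isotype), length(rate))
  chain <- rep_len(chain, n); isotype <- rep_len(isotype, n)
  rate <- rep_len(rate, n)
  out <- character(n)
  heavy <- chain == "IGH"
  out[!heavy] <- ifelse(rate[!heavy] < 0.5, "IgKL_nonmutated",
                 ifelse(rate[!heavy] > 4, "IgKL_mutated", "IgKL_intermediate"))
  iso <- isotype[heavy]; r <- rate[heavy]
  out[heavy] <- ifelse(iso %in% c("IgM", "IgD") & r < 0.5, "IgMD_nonmutated",
                ifelse(iso %in% c("IgA", "IgG", "IgE") & r > 3, "IgAGE_mutated",
                ifelse(iso == "IgM" & r > 3, "IgM_mutated", "other")))
  out
}

#' Mutation-class proportions per sample
#'
#' Duplicate-count-weighted fraction of sequences in each mutation class,
#' within each (animal, timepoint, chain-group). The classes form an
#' exhaustive partition per chain-group, so fractions sum to 1.
#'
#' @param x a [Repertoire-class].
#' @return a `data.table`: `animal_id`, `timepoint_hr`, `chain_group`,
#'   `class`, `count`, `fraction`.
#' @export
mutationClassProportions <- function(x) {
  stopifnot(is(x, "Repertoire"))
  dt <- copy(x@rearrangements)
  if (nrow(dt) == 0L) stop("empty repertoire")
  dt[, chain_group := chainGroup(chain)]
  dt[, rate := 100 * (v_mismatches + j_mismatches) /
       (v_aligned_len + j_aligned_len)]
  dt[, class := classifyMutation(chain, isotype, rate)]
  out <- dt[, .(count = sum(as.numeric(duplicate_count))),
            by = .(animal_id, timepoint_hr, chain_group, class)]
  out[, fraction := count / sum(count),
      by = .(animal_id, timepoint_hr, chain_group)]
  ## emit zero rows for unobserved classes so the partition is explicit
  full <- out[, {
    classes <- if (chain_group == "IGH") .MUTATION_CLASSES_IGH
               else .MUTATION_CLASSES_IGKL
    miss <- setdiff(classes, class)
    rbind(.SD, data.table(class = miss, count = 0, fraction = 0))
  }, by = .(animal_id, timepoint_hr, chain_group)]
  setorderv(full, c("animal_id", "timepoint_hr", "chain_group", "class"))
  full[]
}
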