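#' Aggregate rearrangement records into clonotypes
#'
#' A clonotype is a unique combination of V gene, J gene and CDR3 amino-acid
#' sequence (within a chain). Counts are summed `duplicate_count`s;
#' frequencies are normalised within each (animal, timepoint, chain-group),
#' where the chain-group is IGH alone or IGK+IGL pooled. The per-clonotype
#' mean mutation rate is the pooled somatic hypermutation rate of its member
#' sequences (mismatch sums over aligned-length sums, duplicate-weighted).
#'
#' @param x a [Repertoire-class].
#' @param stripAlleles drop IMGT allele suffixes (`*01`) from V/J calls
#'   before grouping (default `TRUE`).
#' @return a `data.table`, one row per clonotype per sample:
#'   `animal_id`, `species`, `timepoint_hr`, `chain_group`, `chain`,
#'   `v_call`, `j_call`, `cdr3_aa`, `count`, `frequency`,
#'   `mean_mutation_rate` (percent), `n_cdr3_nt` (distinct nucleotide
#'   variants), `mm_sum`, `len_sum` (pooled mismatch / aligned-length sums,
#'   duplicate-weighted, for downstream pooling).
#' @export
buildClonotypes <- function(x, stripAlleles = TRUE) {
  stopifnot(is(x, "Repertoire"))
  dt <- copy(x@rearrangements)
  if (nrow(dt) == 0L) return(dt[, .(animal_id, timepoint_hr)][0])
  if (stripAlleles) {
    dt[, `:=`(v_call = .stripAllele(v_call), j_call = .stripAllele(j_call))]
  }
  dt[, chain_group := chainGroup(chain)]
  cl <- dt[, .(
    count = sum(as.numeric(duplicate_count)),
    mm_sum = sum(as.numeric(duplicate_count) * (v_mismatches + j_mismatches)),
    len_sum = sum(as.numeric(duplicate_count) * (v_aligned_len + j_aligned_len)),
    n_cdr3_nt = length(unique(cdr3_nt))
  ), by = .(animal_id, species, timepoint_hr, chain_group, chain,
            v_call, j_call, cdr3_aa)]
  cl[, frequency := count / sum(count),
     by = .(animal_id, timepoint_hr, chain_group)]
  cl[, mean_mutation_rate := 100 * mm_sum / len_sum]
  setorderv(cl, c("animal_id", "timepoint_hr", "chain_group", "chain",
                  "v_call", "j_call", "cdr3_aa"))
  cl[]
}

#' Subsample a repertoire to a fixed sequencing depth
#'
#' Draws exactly `min(n, total)` sequences without replacement from the
#' count-expanded multiset of each (animal, timepoint, chain-group) sample —
#' a multivariate hypergeometric draw over records — and re-aggregates
#' duplicate counts. Samples already at or below the target depth are
#' returned whole with a warning. Used to equalise sequencing depth before
#' diversity estimation (defaults follow the 400k heavy / 500k light
#' convention).
#'
#' @param x a [Repertoire-class].
#' @param n target depths, a named vector with entries `IGH` and `IgKL`
#'   (or a single number applied to both chain-groups).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [Repertoire-class] with reduced duplicate counts.
#' @export
subsampleRepertoire <- function(x, n = c(IGH = 4e5, IgKL = 5e5), seed = 1L) {
  stopifnot(is(x, "Repertoire"))
  if (length(n) == 1L && is.null(names(n))) n <- c(IGH = n, IgKL = n)
  dt <- copy(x@rearrangements)
  dt[, .grp := chainGroup(chain)]
  dt[, .row := .I]
  .withSeed(seed, {
    keys <- unique(dt[, .(animal_id, timepoint_hr, .grp)])
    pieces <- vector("list", nrow(keys))
    for (i in seq_len(nrow(keys))) {
      sub <- dt[animal_id == keys$animal_id[i] &
                  timepoint_hr == keys$timepoint_hr[i] & .grp == keys$.grp[i]]
      target <- n[[keys$.grp[i]]]
      total <- sum(sub$duplicate_count)
      if (total <= target) {
        if (total < target) {
          warning(sprintf("sample %s/%s/%s has %d < %d sequences; returned whole",
                          keys$animal_id[i], keys$timepoint_hr[i], keys$.grp[i],
                          as.integer(total), as.integer(target)))
        }
        pieces[[i]] <- sub
      } else {
        expanded <- rep(seq_len(nrow(sub)), sub$duplicate_count)
        drawn <- tabulate(sample(expanded, size = target, replace = FALSE),
                          nbins = nrow(sub))
        keep <- drawn > 0L
        piece <- sub[keep]
        piece[, duplicate_count := drawn[keep]]
        pieces[[i]] <- piece
      }
    }
    out <- rbindlist(pieces)
  })
  setorderv(out, ".row")
  out[, c(".grp", ".row") := NULL]
  Repertoire(out)
}

#' V/J gene usage
#'
#' Sequence-weighted (duplicate-count) usage frequencies of V genes, J genes
#' or V-J pairings, normalised within each (animal, timepoint, chain-group).
#'
#' @param x a [Repertoire-class].
#' @param level `"V"`, `"J"` or `"VJ"`.
#' @param stripAlleles drop allele suffixes before tabulating.
#' @return a `data.table` with `animal_id`, `timepoint_hr`, `chain_group`,
#'   `label` (gene or "V|J" pairing), `count`, `frequency`.
#' @export
geneUsage <- function(x, level = c("V", "J", "VJ"), stripAlleles = TRUE) {
  stopifnot(is(x, "Repertoire"))
  level <- match.arg(level)
  dt <- copy(x@rearrangements)
  if (nrow(dt) == 0L) stop("empty repertoire")
  if (stripAlleles) {
    dt[, `:=`(v_call = .stripAllele(v_call), j_call = .stripAllele(j_call))]
  }
  dt[, chain_group := chainGroup(chain)]
  dt[, label := switch(level,
    V = v_call, J = j_call, VJ = paste(v_call, j_call, sep = "|"))]
  us <- dt[, .(count = sum(as.numeric(duplicate_count))),
           by = .(animal_id, timepoint_hr, chain_group, label)]
  us[, frequency := count / sum(count),
     by = .(animal_id, timepoint_hr, chain_group)]
  setorderv(us, c("animal_id", "timepoint_hr", "chain_group", "label"))
  us[]
}

#' Kappa/lambda light-chain ratio
#'
#' Ratio of summed IGK duplicate counts to summed IGL duplicate counts per
#' (animal, timepoint). A shift of this ratio downward marks preferential
#' lambda-chain usage.
#'
#' @param x a [Repertoire-class] containing light-chain records.
#' @return a `data.table` with `animal_id`, `timepoint_hr`, `igk`, `igl`,
#'   `ratio`.
#' @export
kappaLambdaRatio <- function(x) {
  stopifnot(is(x, "Repertoire"))
  dt <- x@rearrangements[chain %in% c("IGK", "IGL")]
  if (nrow(dt) == 0L) stop("no light-chain records")
  out <- dt[, .(
    igk = sum(as.numeric(duplicate_count[chain == "IGK"])),
    igl = sum(as.numeric(duplicate_count[chain == "IGL"]))
  ), by = .(animal_id, timepoint_hr)]
  if (any(out$igl == 0)) {
    stop("undefined kappa/lambda ratio: zero IGL count in at least one sample")
  }
  out[, ratio := igk / igl]
  setorderv(out, c("animal_id", "timepoint_hr"))
  out[]
}
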