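#' @import methods
#' @importFrom data.table data.table as.data.table setDT setkeyv copy rbindlist
#'   fwrite fread setorderv setnames setcolorder CJ dcast := .N .SD .I
NULL

setOldClass(c("data.table", "data.frame"))

## Canonical column set of a rearrangement table. AIRR-style names plus the
## alignment-mismatch extension columns this pipeline needs for SHM rates and
## for fixed-length subsequence phylogenies.
.REARRANGEMENT_COLS <- c(
  "sequence_id", "animal_id", "species", "timepoint_hr", "chain",
  "v_call", "j_call", "cdr3_aa", "cdr3_nt", "isotype",
  "v_mismatches", "j_mismatches", "v_aligned_len", "j_aligned_len",
  "duplicate_count", "v_tail_nt", "j_region_nt"
)

.CHAINS <- c("IGH", "IGK", "IGL")
.ISOTYPES <- c("IgM", "IgD", "IgG", "IgA", "IgE")
.TIMEPOINTS <- c(0L, 8L, 24L, 48L, 72L, 168L)

#' Repertoire: a set of annotated BCR rearrangement records
#'
#' An S4 container for annotated immunoglobulin rearrangement records
#' (one row per distinct sequence variant, with a `duplicate_count` giving
#' its sequence multiplicity). A `Repertoire` may hold one sample
#' (one animal at one timepoint) or a whole longitudinal cohort; most
#' downstream operations group internally by animal, timepoint and
#' chain-group (IGH alone; IGK and IGL pooled as "IgKL").
#'
#' @slot rearrangements a `data.table` with the canonical columns
#'   (`sequence_id`, `animal_id`, `species`, `timepoint_hr`, `chain`,
#'   `v_call`, `j_call`, `cdr3_aa`, `cdr3_nt`, `isotype`, `v_mismatches`,
#'   `j_mismatches`, `v_aligned_len`, `j_aligned_len`, `duplicate_count`,
#'   `v_tail_nt`, `j_region_nt`).
#'
#' @seealso [readRearrangements()], [buildClonotypes()], [clusterLineages()]
#' @export
setClass("Repertoire", representation(rearrangements = "data.table"))

setValidity("Repertoire", function(object) {
  dt <- object@rearrangements
  missing_cols <- setdiff(.REARRANGEMENT_COLS, names(dt))
  if (length(missing_cols)) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(dt) == 0L) return(TRUE)
  probs <- .recordProblems(dt)
  if (any(probs != "")) {
    bad <- which(probs != "")
    return(sprintf("%d invalid record(s), first: %s (row %d)",
                   length(bad), probs[bad[1L]], bad[1L]))
  }
  TRUE
})

## Vector of per-row invariant violations ("" = valid). Used both by the class
## validity method and by the row-rejection path in readRearrangements().
.recordProblems <- function(dt) {
  n <- nrow(dt)
  prob <- character(n)
  flag <- function(bad, msg) {
    bad <- bad & prob == ""
    prob[bad] <<- msg
  }
  flag(!dt$chain %in% .CHAINS, "unknown chain")
  flag(is.na(dt$timepoint_hr) | dt$timepoint_hr < 0, "bad timepoint")
  flag(is.na(dt$cdr3_aa) | !nzchar(dt$cdr3_aa), "empty cdr3_aa")
  flag(!is.na(dt$cdr3_nt) & nzchar(dt$cdr3_nt) &
         nchar(dt$cdr3_nt) != 3L * nchar(dt$cdr3_aa),
       "cdr3_nt length != 3 x cdr3_aa length")
  flag(is.na(dt$duplicate_count) | dt$duplicate_count < 1, "duplicate_count < 1")
  flag(is.na(dt$v_aligned_len) | dt$v_aligned_len < 1 |
         is.na(dt$j_aligned_len) | dt$j_aligned_len < 1,
       "non-positive aligned length")
  flag(is.na(dt$v_mismatches) | dt$v_mismatches < 0 |
         dt$v_mismatches > dt$v_aligned_len,
       "v_mismatches outside [0, v_aligned_len]")
  flag(is.na(dt$j_mismatches) | dt$j_mismatches < 0 |
         dt$j_mismatches > dt$j_aligned_len,
       "j_mismatches outside [0, j_aligned_len]")
  flag(dt$chain != "IGH" & !is.na(dt$isotype), "light-chain record with isotype")
  flag(dt$chain == "IGH" & (is.na(dt$isotype) | !dt$isotype %in% .ISOTYPES),
       "IGH record without a valid isotype")
  flag(!is.na(dt$v_tail_nt) & nzchar(dt$v_tail_nt) & nchar(dt$v_tail_nt) != 10L,
       "v_tail_nt present but not 10 nt")
  prob
}

#' Construct a Repertoire from a rearrangement table
#'
#' @param rearrangements a data.frame or data.table carrying the canonical
#'   rearrangement columns. Coerced to `data.table`; validated.
#' @return a [Repertoire-class] object.
#' @export
Repertoire <- function(rearrangements) {
  dt <- as.data.table(rearrangements)
  if ("timepoint_hr" %in% names(dt)) {
    dt[, timepoint_hr := as.integer(timepoint_hr)]
  }
  new("Repertoire", rearrangements = dt)
}

#' LineageSet: clonal lineages of one or more animals
#'
#' Result container for [clusterLineages()]. Lineages are clusters of
#' clonotypes from one animal (pooled across timepoints) sharing V gene,
#' J gene and CDR3 length, connected under single linkage with amino-acid
#' hamming distance less than or equal to 1 on the CDR3.
#'
#' @slot lineages `data.table`, one row per lineage: `lineage_id`,
#'   `animal_id`, `chain_group`, `v_call`, `j_call`, `cdr3_len`,
#'   `n_clonotypes`.
#' @slot members `data.table` mapping clonotypes to lineages, with
#'   per-timepoint counts and frequencies: `lineage_id`, `animal_id`,
#'   `chain_group`, `chain`, `v_call`, `j_call`, `cdr3_aa`, `timepoint_hr`,
#'   `count`, `frequency`, `mm_sum`, `len_sum`.
#' @slot metrics `data.table`, one row per lineage x timepoint:
#'   `lineage_id`, `timepoint_hr`, `cum_frequency`, `unique_cdr3`,
#'   `mean_mutation_rate` (percent; `NA` where the lineage is absent).
#' @slot timepoints integer vector of the timepoints the metrics cover.
#' @export
setClass("LineageSet", representation(
  lineages = "data.table",
  members = "data.table",
  metrics = "data.table",
  timepoints = "integer"
))

setValidity("LineageSet", function(object) {
  if (!all(c("lineage_id", "animal_id", "chain_group", "v_call", "j_call",
             "cdr3_len") %in% names(object@lineages))) {
    return("lineages table lacks required columns")
  }
  if (anyDuplicated(object@lineages$lineage_id)) {
    return("duplicated lineage_id")
  }
  TRUE
})
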