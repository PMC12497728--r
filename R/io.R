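#' Read an annotated rearrangement table
#'
#' Reads a tab-separated rearrangement table in the package's AIRR-style
#' dialect (see [Repertoire-class] for the canonical columns), validates each
#' row against the record invariants, and returns the accepted records as a
#' [Repertoire-class]. Rows violating an invariant (e.g. more V mismatches
#' than aligned V length, a light-chain record carrying an isotype) are
#' rejected and counted; the rejection report is attached as the
#' `"rejection"` attribute and summarised with a message.
#'
#' @param path path to a TSV file with a header row.
#' @param columnMap optional named character vector mapping file column names
#'   to canonical names, e.g. `c(junction_aa = "cdr3_aa")` declares that the
#'   file column `junction_aa` holds `cdr3_aa`.
#' @return a [Repertoire-class]; attribute `"rejection"` holds a `data.table`
#'   of rejected rows with a `reason` column.
#' @examples
#' rep <- generateCohort(cohortConfig(nAnimals = 1, sequencesPerSample = 500,
#'                                    nBaselineLineages = 50, nPlanted = 0,
#'                                    seed = 1))$repertoire
#' tf <- tempfile(fileext = ".tsv")
#' writeRearrangements(rep, tf)
#' rep2 <- readRearrangements(tf)
#' nSequences(rep2) == nSequences(rep)
#' @export
readRearrangements <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
              colClasses = list(character = "sequence_id"))
  if (!is.null(columnMap)) {
    present <- intersect(names(columnMap), names(dt))
    if (length(present)) setnames(dt, present, unname(columnMap[present]))
  }
  missing_cols <- setdiff(.REARRANGEMENT_COLS, names(dt))
  if (length(missing_cols)) {
    stop("required column(s) missing: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(dt) == 0L) stop("empty sample: no data rows in ", path)
  dt <- dt[, .REARRANGEMENT_COLS, with = FALSE]
  for (col in c("cdr3_nt", "isotype", "v_tail_nt", "j_region_nt")) {
    if (!is.character(dt[[col]])) dt[, (col) := as.character(get(col))]
  }
  dt[, timepoint_hr := as.integer(timepoint_hr)]
  probs <- .recordProblems(dt)
  rejected <- dt[probs != ""]
  if (nrow(rejected)) {
    rejected[, reason := probs[probs != ""]]
    message(nrow(rejected), " record(s) rejected (",
            paste(unique(rejected$reason), collapse = "; "), ")")
  } else {
    rejected[, reason := character(0)]
  }
  out <- Repertoire(dt[probs == ""])
  attr(out, "rejection") <- rejected
  out
}

#' Write a rearrangement table
#'
#' Writes the records of a [Repertoire-class] as a TSV with a stable column
#' order, such that `readRearrangements(writeRearrangements(x))` reproduces
#' the record set exactly. `NA` fields (light-chain isotypes) are written as
#' empty strings.
#'
#' @param x a [Repertoire-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRearrangements <- function(x, path) {
  stopifnot(is(x, "Repertoire"))
  dt <- x@rearrangements
  if (nrow(dt)) {
    dt <- dt[, .REARRANGEMENT_COLS, with = FALSE]
  } else {
    dt <- setDT(lapply(.REARRANGEMENT_COLS, function(z) character(0)))
    setnames(dt, .REARRANGEMENT_COLS)
  }
  fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
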