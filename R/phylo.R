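#' Fixed-length subsequence for lineage phylogenies
#'
#' Concatenates, per record, the 10-nt non-CDR3 V-region tail immediately
#' 5' of the CDR3, the CDR3 nucleotide sequence, and the J-region
#' nucleotides. Because lineage members share V gene, J gene and CDR3
#' length, all subsequences within a lineage have equal length, so no
#' multiple sequence alignment is needed before tree building.
#'
#' @param vTailNt 10-nt V-region tail(s).
#' @param cdr3Nt CDR3 nucleotide sequence(s).
#' @param jRegionNt J-region nucleotide sequence(s).
#' @return character vector of concatenated subsequences; `NA` where any
#'   segment is missing.
#' @export
extractSubsequence <- function(vTailNt, cdr3Nt, jRegionNt) {
  ok <- !is.na(vTailNt) & nzchar(vTailNt) &
        !is.na(cdr3Nt) & nzchar(cdr3Nt) &
        !is.na(jRegionNt) & nzchar(jRegionNt)
  out <- rep(NA_character_, length(ok))
  out[ok] <- paste0(vTailNt[ok], cdr3Nt[ok], jRegionNt[ok])
  out
}

#' Build the taxon set of one lineage for tree construction
#'
#' Extracts the fixed-length subsequence of every record of one lineage,
#' skips records with missing segments (with a warning), collapses duplicate
#' subsequences to a single taxon with a multiplicity annotation, and
#' returns the taxa with their display annotations (frequency, mutation
#' rate, isotype, sample).
#'
#' @param ls a [LineageSet-class].
#' @param lineageId a lineage ID.
#' @param x the [Repertoire-class] holding the records.
#' @return a `data.table`: `taxon`, `subsequence`, `multiplicity`,
#'   `frequency` (summed duplicate-count fraction within lineage),
#'   `mutation_rate` (pooled, percent), `isotypes`, `samples`.
#' @export
lineageAlignment <- function(ls, lineageId, x) {
  mem <- unique(ls@members[lineage_id == lineageId,
                           .(animal_id, chain, v_call, j_call, cdr3_aa)])
  if (nrow(mem) == 0L) stop("unknown lineage: ", lineageId)
  rec <- copy(x@rearrangements)
  rec[, `:=`(v_call = .stripAllele(v_call), j_call = .stripAllele(j_call))]
  rec <- merge(rec, mem,
               by = c("animal_id", "chain", "v_call", "j_call", "cdr3_aa"))
  rec[, subsequence := extractSubsequence(v_tail_nt, cdr3_nt, j_region_nt)]
  nskip <- sum(is.na(rec$subsequence))
  if (nskip > 0L) {
    warning(nskip, " record(s) skipped: missing subsequence segment")
    rec <- rec[!is.na(subsequence)]
  }
  if (nrow(rec) == 0L) stop("no usable records for lineage ", lineageId)
  total <- sum(as.numeric(rec$duplicate_count))
  aln <- rec[, .(
    multiplicity = .N,
    frequency = sum(as.numeric(duplicate_count)) / total,
    mutation_rate = shmRate(v_mismatches, j_mismatches, v_aligned_len,
                            j_aligned_len, duplicate_count),
    isotypes = paste(sort(unique(stats::na.omit(isotype))), collapse = ","),
    samples = paste(sort(unique(paste0(animal_id, "_", timepoint_hr, "hr"))),
                    collapse = ",")
  ), by = subsequence]
  setorderv(aln, "subsequence")
  aln[, taxon := sprintf("seq%03d", .I)]
  setcolorder(aln, "taxon")
  aln[]
}

#' Pairwise p-distance matrix of equal-length sequences
#'
#' Uncorrected p-distances (hamming mismatch count / sequence length)
#' between all pairs; symmetric with zero diagonal. A Jukes-Cantor
#' correction `-3/4 log(1 - 4d/3)` is available via `model`.
#'
#' @param sequences character vector of equal-length nucleotide sequences.
#' @param labels taxon labels (default names or seq index).
#' @param model `"p"` (default) or `"JC69"`.
#' @return symmetric numeric matrix with `labels` dimnames.
#' @export
pDistanceMatrix <- function(sequences, labels = NULL, model = c("p", "JC69")) {
  model <- match.arg(model)
  n <- length(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  if (is.null(labels)) {
    labels <- if (!is.null(names(sequences))) names(sequences)
              else as.character(seq_len(n))
  }
  m <- matrix(unlist(strsplit(sequences, "")), nrow = n, byrow = TRUE)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      diff <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                        matrix(m[i, ], n - i, lens[1L], byrow = TRUE))
      d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- diff / lens[1L]
    }
  }
  if (model == "JC69") {
    d[] <- ifelse(d >= 0.75, NA_real_, -0.75 * log1p(-4 * d / 3))
  }
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei Neighbor-Joining: iteratively joins the pair minimising the
#' Q-criterion \eqn{(n-2) d_{ij} - r_i - r_j}, assigns branch lengths from
#' the net divergences, and reduces the matrix, terminating in an unrooted
#' (trifurcating at the last join for n >= 3) tree. NJ is consistent on
#' additive matrices: it recovers the generating topology and branch
#' lengths exactly. Ties in the Q-criterion are broken deterministically by
#' lowest (row, column) index; negative branch lengths are clamped to zero
#' and reported via the `"clamped"` attribute.
#'
#' @param d square symmetric distance matrix (n >= 2) with zero diagonal.
#' @param labels taxon labels (default from `d` dimnames).
#' @return an unrooted `ape::phylo` tree with branch lengths; attribute
#'   `"clamped"` gives the number of negative branch lengths clamped to 0.
#' @export
njTree <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  nodes <- as.list(labels)  # newick fragment per active node
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    ## deterministic tie-break: lowest (row, col) with row < col
    Q[lower.tri(Q)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[1L]; j <- best[2L]
    ai <- active[i]; aj <- active[j]
    li <- clamp(Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(Dm[i, j] - (Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newick <- sprintf("(%s:%s,%s:%s)", nodes[[ai]], fmt(li),
                      nodes[[aj]], fmt(lj))
    ## reduced distances to the new node
    others <- active[-c(i, j)]
    newd <- (D[ai, others] + D[aj, others] - Dm[i, j]) / 2
    D <- rbind(cbind(D, 0), 0)
    new_id <- nrow(D)
    D[new_id, others] <- D[others, new_id] <- newd
    nodes[[new_id]] <- newick
    active <- c(others, new_id)
  }
  if (length(active) == 3L) {
    a <- active[1L]; b <- active[2L]; c3 <- active[3L]
    la <- clamp((D[a, b] + D[a, c3] - D[b, c3]) / 2)
    lb <- clamp((D[a, b] + D[b, c3] - D[a, c3]) / 2)
    lc <- clamp((D[a, c3] + D[b, c3] - D[a, b]) / 2)
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[a]], fmt(la),
                      nodes[[b]], fmt(lb), nodes[[c3]], fmt(lc))
  } else {
    a <- active[1L]; b <- active[2L]
    half <- D[a, b] / 2
    newick <- sprintf("(%s:%s,%s:%s);", nodes[[a]], fmt(half),
                      nodes[[b]], fmt(half))
  }
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  tree
}

#' Build the NJ tree of one expanded lineage
#'
#' Convenience wrapper: [lineageAlignment()] then [pDistanceMatrix()] then
#' [njTree()].
#'
#' @inheritParams lineageAlignment
#' @param model distance model, see [pDistanceMatrix()].
#' @return list with `tree` (`ape::phylo`) and `annotations`
#'   (the alignment table).
#' @export
lineageTree <- function(ls, lineageId, x, model = "p") {
  aln <- lineageAlignment(ls, lineageId, x)
  if (nrow(aln) < 2L) stop("lineage has fewer than 2 distinct subsequences")
  d <- pDistanceMatrix(aln$subsequence, labels = aln$taxon, model = model)
  list(tree = njTree(d), annotations = aln)
}

#' Write a lineage tree as Newick with an annotation sidecar
#'
#' Writes the tree in Newick format (with branch lengths) and, when
#' annotations are supplied, a tab-separated sidecar keyed by taxon label
#' carrying the display annotations (frequency, mutation rate, isotype,
#' sample).
#'
#' @param tree an `ape::phylo`.
#' @param path output Newick path.
#' @param annotations optional annotation `data.table` from
#'   [lineageAlignment()]; written to `<path>.annotations.tsv`.
#' @return `path`, invisibly.
#' @export
writeNewickAnnotated <- function(tree, path, annotations = NULL) {
  ape::write.tree(tree, file = path)
  if (!is.null(annotations)) {
    fwrite(as.data.table(annotations), paste0(path, ".annotations.tsv"),
           sep = "\t")
  }
  invisible(path)
}
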