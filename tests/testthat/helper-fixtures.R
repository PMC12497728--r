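library(data.table)

## build valid rearrangement rows with overridable fields
makeRecords <- function(n = 1L, ...) {
  base <- data.table(
    sequence_id = sprintf("seq%04d", seq_len(n)),
    animal_id = "IRM01",
    species = "IRM",
    timepoint_hr = 0L,
    chain = "IGK",
    v_call = "IGKV1",
    j_call = "IGKJ1",
    cdr3_aa = "CQQYNSYPT",
    cdr3_nt = NA_character_,
    isotype = NA_character_,
    v_mismatches = 0L,
    j_mismatches = 0L,
    v_aligned_len = 270L,
    j_aligned_len = 36L,
    duplicate_count = 1L,
    v_tail_nt = "ACGTACGTAC",
    j_region_nt = "TTTGGCCAAGGGACCAAGGTGGAAATCAAA"
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base[chain == "IGH" & is.na(isotype), isotype := "IgM"]
  base
}

makeRepertoire <- function(...) Repertoire(makeRecords(...))

## hand-rolled clonotype-table rows for lineage construction, bypassing
## buildClonotypes (frequency etc. given directly)
makeClonotypeRows <- function(cdr3, timepoint = 0L, frequency = 0.001,
                              count = 10, v = "IGKV1", j = "IGKJ1",
                              chain = "IGK", animal = "IRM01",
                              mm = 2, len = 300) {
  data.table(
    animal_id = animal, chain_group = ClonalKinetics::chainGroup(chain),
    chain = chain, v_call = v, j_call = j, cdr3_aa = cdr3,
    timepoint_hr = as.integer(timepoint), count = count,
    frequency = frequency, mm_sum = mm * count, len_sum = len * count
  )
}

## independent oracle: connected components of the <=1-mismatch graph by
## all-pairs comparison and breadth-first search
bruteForceLineages <- function(clonotypes) {
  cl <- as.data.table(clonotypes)
  keys <- unique(cl[, .(animal_id, chain_group, v_call, j_call,
                        len = nchar(cdr3_aa), cdr3_aa)])
  out <- list()
  groups <- split(keys, by = c("animal_id", "chain_group", "v_call",
                               "j_call", "len"))
  for (g in groups) {
    s <- g$cdr3_aa
    n <- length(s)
    m <- matrix(unlist(strsplit(s, "")), nrow = n, byrow = TRUE)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      d <- rowSums(m != matrix(m[i, ], n, ncol(m), byrow = TRUE))
      adj[i, ] <- d <= 1
    }
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (k in unique(comp)) {
      out[[length(out) + 1L]] <- sort(paste(
        g$animal_id[1L], g$chain_group[1L], g$v_call[1L], g$j_call[1L],
        s[comp == k], sep = "|"))
    }
  }
  ## canonical form: sorted list of sorted member-key vectors
  out[order(vapply(out, `[`, "", 1L))]
}

## canonicalise a LineageSet partition the same way
lineagePartition <- function(ls) {
  mem <- unique(lineageMembers(ls)[, .(lineage_id, animal_id, chain_group,
                                       v_call, j_call, cdr3_aa)])
  out <- lapply(split(mem, by = "lineage_id"), function(g) {
    sort(paste(g$animal_id, g$chain_group, g$v_call, g$j_call, g$cdr3_aa,
               sep = "|"))
  })
  out <- unname(out)
  out[order(vapply(out, `[`, "", 1L))]
}

## random clonotype instance concentrated on few V/J/length combinations so
## the hamming-1 graph has non-trivial components: half the CDR3s are fresh
## random strings, half are 1-2-position mutants of earlier rows (same V/J),
## which creates chains and two-step links
randomClonotypeInstance <- function(n = 200L) {
  alphabet <- c("A", "C", "D", "E")
  vs <- sample(c("IGKV1", "IGKV2", "IGKV3"), n, replace = TRUE)
  js <- sample(c("IGKJ1", "IGKJ2"), n, replace = TRUE)
  len <- sample(c(8L, 10L), n, replace = TRUE)
  cdr3 <- character(n)
  for (i in seq_len(n)) {
    if (i > 1L && stats::runif(1) < 0.5) {
      src <- sample.int(i - 1L, 1L)
      vs[i] <- vs[src]; js[i] <- js[src]; len[i] <- len[src]
      s <- cdr3[src]
      for (p in sample.int(len[i], sample(1:2, 1L))) {
        substr(s, p, p) <- sample(alphabet, 1L)
      }
      cdr3[i] <- s
    } else {
      cdr3[i] <- paste(sample(alphabet, len[i], replace = TRUE),
                       collapse = "")
    }
  }
  unique(data.table(
    animal_id = "IRM01",
    chain_group = "IgKL",
    chain = "IGK",
    v_call = vs,
    j_call = js,
    cdr3_aa = cdr3,
    timepoint_hr = 0L,
    count = 1,
    frequency = 1 / n,
    mm_sum = 1,
    len_sum = 300
  ))
}

## random unrooted binary tree with branch lengths bounded away from zero;
## returns list(tree, d = additive path-length matrix)
randomAdditiveTree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

tinyConfig <- function(seed, ...) {
  args <- list(nAnimals = 2L, sequencesPerSample = 5000L,
               nBaselineLineages = 400L, nPlanted = 8L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohortConfig, args)
}
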