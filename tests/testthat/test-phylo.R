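test_that("subsequence extraction concatenates tail, CDR3 and J region", {
  s <- extractSubsequence(strrep("A", 10), strrep("C", 36), strrep("G", 30))
  expect_equal(nchar(s), 76L)
  expect_equal(s, paste0(strrep("A", 10), strrep("C", 36), strrep("G", 30)))
  expect_true(is.na(extractSubsequence(NA, "CCC", "GGG")))
  expect_true(is.na(extractSubsequence("A", "CCC", "")))
})

test_that("p-distance matrix is hamming/length, symmetric, zero-diagonal", {
  d <- pDistanceMatrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(d["a", "b"], 0.25)
  s76 <- strrep("A", 76)
  s76b <- paste0(strrep("A", 74), "CT")
  expect_equal(pDistanceMatrix(c(s76, s76b))[1, 2], 2 / 76, tolerance = 1e-9)
  set.seed(20)
  seqs <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, "")
  d <- pDistanceMatrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 10))
  expect_error(pDistanceMatrix(c("AA", "AAA")), "equal length")
})

test_that("NJ recovers a 2-taxon and a hand-built additive 4-taxon tree", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- njTree(d2)
  expect_equal(unname(ape::cophenetic.phylo(t2)["A", "B"]), 0.3,
               tolerance = 1e-12)

  ## tree ((A:2,B:3):1,(C:4,D:5)): pairwise path lengths
  d4 <- matrix(c(0, 5, 7, 8,
                 5, 0, 8, 9,
                 7, 8, 0, 9,
                 8, 9, 9, 0), 4, byrow = TRUE,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- njTree(d4)
  co <- ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, d4, tolerance = 1e-9)
  ## unrooted fully resolved: n - 2 internal nodes
  expect_equal(t4$Nnode, 2L)
  ## AB vs CD split: A and B are sisters
  expect_lt(ape::cophenetic.phylo(t4)["A", "B"],
            min(co["A", "C"], co["A", "D"]))
})

test_that("NJ is exact on random additive matrices and matches ape::nj", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(5:8, 1)
    ref <- randomAdditiveTree(n)
    tr <- njTree(ref$d)
    co <- ape::cophenetic.phylo(tr)
    co <- co[rownames(ref$d), colnames(ref$d)]
    expect_equal(co, ref$d, tolerance = 1e-9)
    expect_equal(tr$Nnode, n - 2L)
    ## same unrooted topology as the generating tree and as ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(ref$tree), tr), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::dist.topo(ape::nj(ref$d), tr), 0, ignore_attr = TRUE)
  }
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(22)
  ref <- randomAdditiveTree(7)
  o <- sample(7)
  tr1 <- njTree(ref$d)
  tr2 <- njTree(ref$d[o, o])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
})

test_that("negative branch lengths are clamped and reported", {
  ## a strongly non-additive matrix can drive a branch estimate negative
  d <- matrix(c(0, 1, 1, 1.9,
                1, 0, 1.9, 1,
                1, 1.9, 0, 1,
                1.9, 1, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped") >= 0)
})

test_that("lineage trees round-trip through Newick with a sidecar", {
  gen <- generateCohort(tinyConfig(seed = 23))
  res <- analyzeCohort(gen$repertoire)
  ## pick an expanded lineage with several distinct subsequences
  exp_ids <- res$calls[status == "expanded", lineage_id]
  lid <- NULL
  for (cand in exp_ids) {
    aln <- lineageAlignment(res$lineages, cand, gen$repertoire)
    if (nrow(aln) >= 4L) { lid <- cand; break }
  }
  expect_false(is.null(lid))
  lt <- lineageTree(res$lineages, lid, gen$repertoire)
  ## all subsequences within a lineage share one length
  expect_equal(length(unique(nchar(lt$annotations$subsequence))), 1L)
  tf <- tempfile(fileext = ".nwk")
  writeNewickAnnotated(lt$tree, tf, lt$annotations)
  back <- ape::read.tree(tf)
  expect_equal(ape::dist.topo(back, lt$tree), 0, ignore_attr = TRUE)
  side <- fread(paste0(tf, ".annotations.tsv"))
  expect_equal(nrow(side), nrow(lt$annotations))
  expect_setequal(side$taxon, lt$tree$tip.label)
})
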