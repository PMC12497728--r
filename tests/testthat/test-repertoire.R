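test_that("clonotype aggregation merges by V/J/CDR3-aa and normalises per chain-group", {
  dt <- rbind(
    makeRecords(2L, cdr3_aa = "CAAAAAAAF", duplicate_count = c(2L, 2L),
                cdr3_nt = c(NA, NA)),
    makeRecords(1L, cdr3_aa = "CSSSSSSSF", duplicate_count = 1L),
    makeRecords(1L, cdr3_aa = "CTTTTTTTF", duplicate_count = 1L)
  )
  cl <- buildClonotypes(Repertoire(dt))
  expect_equal(nrow(cl), 3L)
  expect_equal(sort(cl$frequency), sort(c(4 / 6, 1 / 6, 1 / 6)))
  expect_equal(sum(cl$frequency), 1)
})

test_that("records differing only in cdr3_nt collapse to one clonotype", {
  aa <- "CQQSYSTPF"
  nt1 <- paste(rep("TGT", nchar(aa)), collapse = "")
  nt2 <- sub("^TGT", "TGC", nt1)
  dt <- makeRecords(2L, cdr3_aa = aa, cdr3_nt = c(nt1, nt2),
                    duplicate_count = c(3L, 2L))
  cl <- buildClonotypes(Repertoire(dt))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$count, 5)
  expect_equal(cl$frequency, 1)
  expect_equal(cl$n_cdr3_nt, 2L)
})

test_that("IGH and pooled IgKL frequencies each sum to 1", {
  dt <- rbind(
    makeRecords(3L, chain = "IGH", v_call = "IGHV1", j_call = "IGHJ1",
                isotype = "IgM", cdr3_aa = c("CARDYW", "CARDFW", "CTRDYW"),
                duplicate_count = c(5L, 3L, 2L)),
    makeRecords(2L, chain = c("IGK", "IGL"),
                v_call = c("IGKV1", "IGLV1"), cdr3_aa = "CQQYNSYPT",
                duplicate_count = c(7L, 3L))
  )
  cl <- buildClonotypes(Repertoire(dt))
  sums <- cl[, .(s = sum(frequency)), by = chain_group]
  expect_equal(sums$s, rep(1, nrow(sums)))
  ## IGK and IGL share one denominator
  expect_equal(cl[chain == "IGK", frequency], 0.7)
})

test_that("subsampling hits the target depth exactly and is seed-deterministic", {
  dt <- makeRecords(10L, cdr3_aa = sprintf("CAAAAAAW%s", LETTERS[1:10]),
                    duplicate_count = rep(100L, 10L))
  rep <- Repertoire(dt)
  s1 <- subsampleRepertoire(rep, n = 500, seed = 5)
  expect_equal(nSequences(s1), 500)
  s2 <- subsampleRepertoire(rep, n = 500, seed = 5)
  expect_equal(rearrangements(s1), rearrangements(s2))
  ## n >= total: unchanged, with warning below target
  expect_warning(s3 <- subsampleRepertoire(rep, n = 2000, seed = 1),
                 "returned whole")
  expect_equal(rearrangements(s3)$duplicate_count, dt$duplicate_count)
  s4 <- subsampleRepertoire(rep, n = 999, seed = 2)
  expect_equal(nSequences(s4), 999)
})

test_that("subsampled counts match the hypergeometric expectation", {
  ## uniform 10-clonotype sample, draw half; mean per-clonotype count over
  ## many seeds must sit within 3 standard errors of n/10
  dt <- makeRecords(10L, cdr3_aa = sprintf("CAAAAAAW%s", LETTERS[1:10]),
                    duplicate_count = rep(50L, 10L))
  rep <- Repertoire(dt)
  nrep <- 1000L
  draws <- matrix(0, nrep, 10L)
  for (k in seq_len(nrep)) {
    s <- rearrangements(subsampleRepertoire(rep, n = 250, seed = k))
    draws[k, match(s$cdr3_aa, dt$cdr3_aa)] <- s$duplicate_count
  }
  m <- colMeans(draws)
  ## variance of one multivariate hypergeometric component
  v <- 250 * (50 / 500) * (1 - 50 / 500) * (500 - 250) / (500 - 1)
  se <- sqrt(v / nrep)
  expect_true(all(abs(m - 25) < 3 * se + 1e-9))
})

test_that("gene usage is duplicate-weighted and VJ marginalises to V and J", {
  dt <- makeRecords(4L, v_call = c("IGKV1", "IGKV1", "IGKV2", "IGKV2"),
                    j_call = c("IGKJ1", "IGKJ2", "IGKJ1", "IGKJ1"),
                    cdr3_aa = sprintf("CAAAAAAW%s", LETTERS[1:4]),
                    duplicate_count = c(2L, 1L, 3L, 2L))
  rep <- Repertoire(dt)
  vj <- geneUsage(rep, "VJ")
  expect_equal(sum(vj$frequency), 1)
  v <- geneUsage(rep, "V")
  ## marginalise VJ over J
  marg <- vj[, .(frequency = sum(frequency)),
             by = .(label = sub("\\|.*$", "", label))]
  expect_equal(marg[order(label), frequency], v[order(label), frequency])
  expect_equal(v[label == "IGKV2", frequency], 5 / 8)

  simple <- geneUsage(Repertoire(makeRecords(2L,
    v_call = c("IGKV1", "IGKV2"), duplicate_count = c(3L, 1L),
    cdr3_aa = c("CAAAAAAWA", "CAAAAAAWB"))), "V")
  expect_equal(simple[order(-frequency), frequency], c(0.75, 0.25))
})

test_that("kappa/lambda ratio is the IGK:IGL duplicate-count ratio", {
  dt <- rbind(
    makeRecords(1L, chain = "IGK", duplicate_count = 300L),
    makeRecords(1L, chain = "IGL", v_call = "IGLV1", j_call = "IGLJ1",
                cdr3_aa = "CSSYAGSYTF", duplicate_count = 100L)
  )
  kl <- kappaLambdaRatio(Repertoire(dt))
  expect_equal(kl$ratio, 3)
  dt2 <- makeRecords(1L, chain = "IGK", duplicate_count = 10L)
  expect_error(kappaLambdaRatio(Repertoire(dt2)), "zero IGL")
})
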