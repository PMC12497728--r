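test_that("SHM rate pools mismatches over aligned lengths", {
  expect_equal(shmRate(0, 0, 90, 30), 0)
  expect_equal(shmRate(2, 1, 90, 30), 2.5)
  expect_equal(shmRate(c(2, 0), c(1, 0), c(90, 90), c(30, 30)), 1.25)
  expect_error(shmRate(0, 0, 0, 0), "zero total aligned length")
  ## order-invariant and additive under pooling
  set.seed(6)
  v <- stats::rpois(10, 3); j <- stats::rpois(10, 1)
  V <- rep(280, 10); J <- rep(40, 10)
  o <- sample(10)
  expect_equal(shmRate(v, j, V, J), shmRate(v[o], j[o], V[o], J[o]))
  expect_equal(shmRate(v, j, V, J),
               100 * (sum(v) + sum(j)) / (sum(V) + sum(J)))
  ## duplicate weights equal explicit repetition
  expect_equal(shmRate(c(2, 1), c(1, 0), c(90, 90), c(30, 30),
                       weights = c(3, 1)),
               shmRate(c(2, 2, 2, 1), c(1, 1, 1, 0), rep(90, 4), rep(30, 4)))
})

test_that("mutation classes follow the strict isotype/rate thresholds", {
  expect_equal(classifyMutation("IGH", "IgM", 0.2), "IgMD_nonmutated")
  expect_equal(classifyMutation("IGH", "IgA", 5.0), "IgAGE_mutated")
  expect_equal(classifyMutation("IGH", "IgM", 8.0), "IgM_mutated")
  expect_equal(classifyMutation("IGK", NA, 2.0), "IgKL_intermediate")
  expect_equal(classifyMutation("IGL", NA, 0.1), "IgKL_nonmutated")
  expect_equal(classifyMutation("IGL", NA, 6.0), "IgKL_mutated")
  ## boundary values fall inside intermediate/other (strict inequalities)
  expect_equal(classifyMutation("IGK", NA, 0.5), "IgKL_intermediate")
  expect_equal(classifyMutation("IGK", NA, 4.0), "IgKL_intermediate")
  expect_equal(classifyMutation("IGH", "IgM", 0.5), "other")
  expect_equal(classifyMutation("IGH", "IgA", 3.0), "other")
  expect_equal(classifyMutation("IGH", "IgD", 4.0), "other")
})

test_that("class proportions are count-weighted and sum to 1", {
  dt <- rbind(
    makeRecords(1L, cdr3_aa = "CAAAAAAWA", v_mismatches = 0L,
                j_mismatches = 0L, duplicate_count = 5L),
    makeRecords(1L, cdr3_aa = "CAAAAAAWB", v_mismatches = 14L,
                j_mismatches = 2L, duplicate_count = 5L)  # 16/306 = 5.2%
  )
  pr <- mutationClassProportions(Repertoire(dt))
  expect_equal(pr[class == "IgKL_nonmutated", fraction], 0.5)
  expect_equal(pr[class == "IgKL_mutated", fraction], 0.5)
  expect_equal(pr[, sum(fraction), by = .(animal_id, timepoint_hr)]$V1, 1)
})

test_that("generator recovers the configured mutation mixture approximately", {
  gen <- generateCohort(tinyConfig(seed = 8, sequencesPerSample = 10000L,
                                   nPlanted = 0L, nAnimals = 1L))
  pr <- mutationClassProportions(gen$repertoire)
  kl <- pr[chain_group == "IgKL" & timepoint_hr == 0L]
  ## weights (0.4, 0.3, 0.3); tolerance covers lineage-sampling noise plus
  ## binomial leakage across the 0.5%/4% class boundaries
  expect_equal(kl[class == "IgKL_nonmutated", fraction], 0.4,
               tolerance = 0.25)
  expect_equal(kl[class == "IgKL_intermediate", fraction], 0.3,
               tolerance = 0.3)
  expect_equal(kl[class == "IgKL_mutated", fraction], 0.3, tolerance = 0.25)
})

test_that("per-sequence mutation rates show the three configured peaks", {
  gen <- generateCohort(tinyConfig(seed = 9, sequencesPerSample = 20000L,
                                   nPlanted = 0L, nAnimals = 1L))
  dt <- rearrangements(gen$repertoire)
  dt <- dt[chain != "IGH" & timepoint_hr == 0L]
  rate <- 100 * (dt$v_mismatches + dt$j_mismatches) /
    (dt$v_aligned_len + dt$j_aligned_len)
  w <- rep(dt$duplicate_count, 1)
  ## mass near each configured peak (0.2, 2, 7 percent)
  total <- sum(w)
  m1 <- sum(w[rate < 0.5]) / total
  m2 <- sum(w[rate >= 0.8 & rate <= 4]) / total
  m3 <- sum(w[rate > 4.5]) / total
  expect_gt(m1, 0.1); expect_gt(m2, 0.1); expect_gt(m3, 0.1)
  ## the three class windows are separated by density dips on a sqrt-rate
  ## kernel density (sqrt stabilises the low-rate peak near zero)
  d <- stats::density(sqrt(rate), weights = w / total, bw = 0.08,
                      from = 0)
  inwin <- function(lo, hi) d$y[d$x >= sqrt(lo) & d$x <= sqrt(hi)]
  peak1 <- max(inwin(0, 0.45))
  dip12 <- min(inwin(0.45, 0.9))
  peak2 <- max(inwin(0.9, 3.9))
  dip23 <- min(inwin(3.9, 4.9))
  peak3 <- max(inwin(4.9, 14))
  expect_gt(peak1, dip12)
  expect_gt(peak2, max(dip12, dip23))
  expect_gt(peak3, dip23)
})
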