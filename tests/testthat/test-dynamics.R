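## a lineage with prescribed per-timepoint frequencies / CDR3s / rates
dynLineage <- function(freqs, rates = NULL, extraCdr3 = 0L) {
  tps <- c(0L, 8L, 24L, 48L, 72L, 168L)
  rows <- list()
  for (i in seq_along(tps)) {
    if (is.na(freqs[i]) || freqs[i] == 0) next
    mm <- if (is.null(rates)) 2 else rates[i] * 3  # len 300 -> rate = mm/3
    rows[[length(rows) + 1L]] <-
      makeClonotypeRows("CARDYAAAW", timepoint = tps[i],
                        frequency = freqs[i], count = 10, mm = mm)
    if (extraCdr3 > 0L && tps[i] %in% c(48L, 72L)) {
      for (k in seq_len(extraCdr3)) {
        rows[[length(rows) + 1L]] <-
          makeClonotypeRows(paste0("CARD", LETTERS[k], "AAAW"),
                            timepoint = tps[i], frequency = freqs[i] / 10,
                            count = 1, mm = mm)
      }
    }
  }
  rbindlist(rows)
}

test_that("log2 fold changes follow log2(post/baseline)", {
  cl <- dynLineage(c(5e-6, NA, NA, 4e-5, 1.5e-5, NA))
  ls <- clusterLineages(cl, timepoints = c(0L, 8L, 24L, 48L, 72L, 168L))
  fc <- foldChanges(ls)
  f48 <- fc[index == "frequency" & timepoint_hr == 48L]
  expect_equal(f48$log2_fc, 3)            # 0.004% vs 0.0005% = 8-fold
  f72 <- fc[index == "frequency" & timepoint_hr == 72L]
  expect_equal(f72$log2_fc, log2(3), tolerance = 1e-9)   # 1.585
  ## absent post timepoint: undefined, not -Inf
  f8 <- fc[index == "frequency" & timepoint_hr == 8L]
  expect_true(is.na(f8$log2_fc))
  ## equal values give 0
  cl2 <- dynLineage(c(1e-4, NA, NA, 1e-4, NA, NA))
  fc2 <- foldChanges(clusterLineages(cl2, timepoints = c(0L, 48L)))
  expect_equal(fc2[index == "frequency" & timepoint_hr == 48L, log2_fc], 0)
})

test_that("lineages absent at baseline are excluded from classification", {
  cl <- dynLineage(c(0, NA, NA, 4e-5, NA, NA))
  ls <- clusterLineages(cl, timepoints = c(0L, 48L))
  fc <- foldChanges(ls)
  expect_true(all(is.na(fc$log2_fc)))
  expect_true(all(classifyFoldChange(fc$log2_fc) == "neither"))
})

test_that("increased/decreased classification and the literal variant", {
  expect_equal(classifyFoldChange(1.5), "increased")
  expect_equal(classifyFoldChange(-2), "decreased")
  expect_equal(classifyFoldChange(0.5), "neither")
  expect_equal(classifyFoldChange(-0.5), "neither")
  expect_equal(classifyFoldChange(0.2, literalDecreased = TRUE), "decreased")
  ## exclusivity: no value is both
  x <- seq(-4, 4, by = 0.01)
  cls <- classifyFoldChange(x)
  expect_true(all(cls %in% c("increased", "decreased", "neither")))
  expect_true(all(x[cls == "increased"] > 1))
  expect_true(all(x[cls == "decreased"] < -1))
})

test_that("expanded calls require a criterion pair at a trigger timepoint", {
  ## frequency criterion: log2FC 3.5 at 48 hr with freq 2e-5 (> 0.001%)
  cl <- dynLineage(c(2e-5 / 2^3.5, NA, NA, 2e-5, NA, NA))
  ls <- clusterLineages(cl, timepoints = c(0L, 8L, 24L, 48L, 72L, 168L))
  calls <- identifyExpanded(ls)
  expect_equal(calls$status, "expanded")
  expect_equal(calls$criteria_met, "frequency")
  expect_equal(calls$trigger_timepoint, 48L)

  ## same fold change but absolute frequency below 0.001%: not expanded
  cl2 <- dynLineage(c(5e-7, NA, NA, 5e-6, NA, NA))
  calls2 <- identifyExpanded(clusterLineages(cl2, timepoints = c(0L, 48L)))
  expect_equal(calls2$status, "increased")

  ## mutation-rate-only criterion at 72 hr: log2FC 1.4 with rate 7%
  base_rate <- 7 / 2^1.4
  cl3 <- dynLineage(c(1e-4, NA, NA, NA, 1e-4, NA),
                    rates = c(base_rate, NA, NA, NA, 7, NA))
  calls3 <- identifyExpanded(clusterLineages(cl3, timepoints = c(0L, 72L)))
  expect_equal(calls3$status, "expanded")
  expect_equal(calls3$criteria_met, "mutation_rate")
  expect_equal(calls3$trigger_timepoint, 72L)
})

test_that("every expanded lineage is an increased lineage on some index", {
  gen <- generateCohort(tinyConfig(seed = 15))
  res <- analyzeCohort(gen$repertoire)
  fc <- res$foldChanges[timepoint_hr %in% c(48L, 72L)]
  fc[, cls := classifyFoldChange(log2_fc)]
  inc_ids <- unique(fc[cls == "increased", lineage_id])
  exp_ids <- res$calls[status == "expanded", lineage_id]
  expect_true(all(exp_ids %in% inc_ids))
})

test_that("constant lineages are the expanded lineages present at all timepoints", {
  always <- dynLineage(c(2e-6, 2e-6, 2e-6, 2e-5, 2e-5, 2e-6))
  gap <- dynLineage(c(2e-6, NA, 2e-6, 2e-5, 2e-5, 2e-6))
  gap[, cdr3_aa := sub("^CARDY", "CTTTT", cdr3_aa)]
  cl <- rbind(always, gap)
  ls <- clusterLineages(cl, timepoints = c(0L, 8L, 24L, 48L, 72L, 168L))
  calls <- identifyExpanded(ls)
  expect_equal(sort(unique(calls$status)), "expanded")
  cc <- constantLineages(calls, ls)
  expect_equal(cc$n_expanded, 2L)
  expect_equal(cc$n_constant, 1L)
  expect_equal(cc$pct, 50)
  expect_match(cc$ids, "CARDY")
})

test_that("origin tracing returns baseline members and excludes absentees", {
  gen <- generateCohort(tinyConfig(seed = 16))
  res <- analyzeCohort(gen$repertoire)
  orig <- originalExpanded(res$calls, res$lineages, gen$repertoire)
  expect_true(all(orig$records$timepoint_hr == 0L))
  expect_true(all(orig$records$class %in%
                    c("IgKL_nonmutated", "IgKL_intermediate", "IgKL_mutated",
                      "IgMD_nonmutated", "IgAGE_mutated", "IgM_mutated",
                      "other")))
  expect_equal(orig$classFractions[, sum(fraction)], 1)
  ## lineage IDs in the origin view are all expanded calls
  expect_true(all(orig$records$lineage_id %in%
                    res$calls[status == "expanded", lineage_id]))
})

test_that("control sampling matches size, kappa:lambda split and frequency bins", {
  gen <- generateCohort(tinyConfig(seed = 17))
  res <- analyzeCohort(gen$repertoire)
  exp_ids <- res$calls[status == "expanded" & chain_group == "IgKL",
                       lineage_id]
  expect_gte(length(exp_ids), 2L)

  ctrl <- sampleControlLineages(res$lineages, exp_ids,
                                mode = "match_kl_ratio_and_count", seed = 1)
  expect_equal(length(ctrl), length(exp_ids))
  expect_length(intersect(ctrl, exp_ids), 0L)
  ref_kl <- kappaLambdaOfLineages(res$lineages, exp_ids, timepoint = NULL)
  ctl_kl <- kappaLambdaOfLineages(res$lineages, ctrl, timepoint = NULL)
  expect_equal(ctl_kl$nKappa, ref_kl$nKappa)
  expect_equal(ctl_kl$nLambda, ref_kl$nLambda)

  ## expanded lineages dominate the top frequency bin at 72 hr, so the
  ## documented nearest-stratum fallback fires for some draws
  c1 <- suppressWarnings(sampleControlLineages(
    res$lineages, exp_ids, mode = "match_frequency_distribution", seed = 1))
  c2 <- suppressWarnings(sampleControlLineages(
    res$lineages, exp_ids, mode = "match_frequency_distribution", seed = 2))
  expect_equal(length(c1), length(exp_ids))
  ## different seeds draw different controls from the same strata
  expect_false(identical(sort(c1), sort(c2)))
  met <- lineageMetrics(res$lineages)[timepoint_hr == 72L & cum_frequency > 0]
  f <- stats::setNames(met$cum_frequency, met$lineage_id)
  ## matched controls live on the same order of magnitude as the reference
  expect_lt(abs(median(log10(f[c1])) - median(log10(f[exp_ids]))), 1)
})

test_that("increased and decreased counts balance on a null cohort", {
  gen <- generateCohort(tinyConfig(seed = 18, nPlanted = 0L))
  res <- analyzeCohort(gen$repertoire)
  cnt <- countIncreasedDecreased(res$foldChanges)
  w <- pairedWilcoxon(cnt$n_increased, cnt$n_decreased)
  expect_gt(w$p, 0.01)
})
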