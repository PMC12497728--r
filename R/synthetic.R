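#' Configuration for a synthetic longitudinal cohort
#'
#' Defines the statistical structure of the generated cohort: study design
#' (animals of two species, six timepoints over one week, heavy and pooled
#' light chain repertoires), power-law clonotype abundances, a three-peak
#' somatic-hypermutation mixture (naive-like, intermediate, memory/
#' effector-like) with isotype assignment conditional on mutation class, a
#' baseline kappa:lambda ratio, and planted expanded lineages at 48/72 hr
#' with configurable per-mechanism log2 fold-change targets, lambda-chain
#' bias, persistence to 1 week, and origin class.
#'
#' @param nAnimals number of animals (species alternate IRM/AGM).
#' @param timepoints sampling timepoints in hours (1 wk = 168).
#' @param sequencesPerSample sequencing depth per animal, timepoint and
#'   chain-group (each sample's total duplicate count equals this exactly).
#' @param chainGroups chain-groups to simulate (`"IgKL"`, `"IGH"`).
#' @param nBaselineLineages baseline lineages per animal per chain-group.
#' @param powerLawExponent exponent of the rank-abundance power law
#'   (lineage weight proportional to rank^-exponent).
#' @param mutationWeights mixture weights of the naive / intermediate /
#'   memory mutation classes (sum to 1).
#' @param mutationPeaks class peak mutation rates in percent; defaults put
#'   the naive peak below 0.5%, the memory peak above the 4% (light) and
#'   3% (heavy) mutated-class thresholds.
#' @param isotypeProbs per-class isotype probabilities (heavy chain only).
#' @param kappaLambdaBaseline baseline kappa:lambda sequence-count ratio.
#' @param nPlanted planted expanded light-chain lineages (whole cohort,
#'   distributed over animals).
#' @param nPlantedHeavy planted expanded heavy-chain lineages.
#' @param fcTargets named log2 fold-change targets for the light-chain
#'   mechanisms (`frequency`, `unique_cdr3`, `mutation_rate`).
#' @param fcTargetsHeavy targets for the heavy-chain mechanisms
#'   (`frequency`, `mutation_rate`).
#' @param mechanismProb probability each available mechanism is applied to
#'   a planted lineage (redrawn until at least one applies).
#' @param lambdaBias probability a planted light-chain lineage is assigned
#'   to IGL.
#' @param persistProb probability a planted expansion persists to 168 hr.
#' @param originMemoryProb probability a planted lineage originates from
#'   the memory-like (high-mutation) class; otherwise naive-like.
#' @param plantedBaselineCounts expected baseline count window (at the
#'   configured depth) from which planted lineages are drawn.
#' @param genePool sizes of the V/J gene label pools, a named list with
#'   `vHeavy`, `jHeavy`, `vKappa`, `vLambda`, `jLight`.
#' @param seed mandatory integer seed; the cohort is a deterministic
#'   function of the configuration.
#' @return a `cohortConfig` list.
#' @export
cohortConfig <- function(nAnimals = 6L,
                         timepoints = c(0L, 8L, 24L, 48L, 72L, 168L),
                         sequencesPerSample = 200000L,
                         chainGroups = c("IgKL", "IGH"),
                         nBaselineLineages = 4000L,
                         powerLawExponent = 0.8,
                         mutationWeights = c(naive = 0.4, intermediate = 0.3,
                                             memory = 0.3),
                         mutationPeaks = c(naive = 0.2, intermediate = 2,
                                           memory = 7),
                         isotypeProbs = list(
                           naive = c(IgM = 0.8, IgD = 0.2),
                           intermediate = c(IgM = 0.5, IgG = 0.3, IgA = 0.2),
                           memory = c(IgM = 0.2, IgG = 0.4, IgA = 0.35,
                                      IgE = 0.05)),
                         kappaLambdaBaseline = 2,
                         nPlanted = 50L,
                         nPlantedHeavy = 0L,
                         fcTargets = c(frequency = 4, unique_cdr3 = 3,
                                       mutation_rate = 2.3),
                         fcTargetsHeavy = c(frequency = 4,
                                            mutation_rate = 2.5),
                         mechanismProb = 0.7,
                         lambdaBias = 0.8,
                         persistProb = 0.6,
                         originMemoryProb = 0.8,
                         plantedBaselineCounts = c(15, 60),
                         genePool = list(vHeavy = 60L, jHeavy = 6L,
                                         vKappa = 40L, vLambda = 40L,
                                         jLight = 5L),
                         seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (abs(sum(mutationWeights) - 1) > 1e-9) {
    stop("mutationWeights must sum to 1")
  }
  if (any(fcTargets <= 0) || any(fcTargetsHeavy <= 0)) {
    stop("fold-change targets must be positive")
  }
  cfg <- list(nAnimals = as.integer(nAnimals),
              timepoints = as.integer(timepoints),
              sequencesPerSample = as.integer(sequencesPerSample),
              chainGroups = chainGroups,
              nBaselineLineages = as.integer(nBaselineLineages),
              powerLawExponent = powerLawExponent,
              mutationWeights = mutationWeights,
              mutationPeaks = mutationPeaks,
              isotypeProbs = isotypeProbs,
              kappaLambdaBaseline = kappaLambdaBaseline,
              nPlanted = as.integer(nPlanted),
              nPlantedHeavy = as.integer(nPlantedHeavy),
              fcTargets = fcTargets,
              fcTargetsHeavy = fcTargetsHeavy,
              mechanismProb = mechanismProb,
              lambdaBias = lambdaBias,
              persistProb = persistProb,
              originMemoryProb = originMemoryProb,
              plantedBaselineCounts = plantedBaselineCounts,
              genePool = genePool,
              seed = as.integer(seed))
  nPl <- cfg$nPlanted + cfg$nPlantedHeavy
  if (nPl > cfg$nAnimals * cfg$nBaselineLineages / 10) {
    stop("infeasible config: planted count too large for lineage pool")
  }
  class(cfg) <- "cohortConfig"
  cfg
}

## class-specific clamp windows (percent) keeping lineage rates inside their
## nominal mutation class
.RATE_CLAMP <- list(naive = c(0.05, 0.45), intermediate = c(0.8, 3.8),
                    memory = c(4.8, 14))

.randomCdr3 <- function(len) {
  paste(sample(.AA, len, replace = TRUE), collapse = "")
}

## `n` distinct single-position variants of `founder`, also distinct from
## `avoid`
.cdr3Variants <- function(founder, n, avoid = character(0)) {
  len <- nchar(founder)
  out <- character(0)
  seen <- c(founder, avoid)
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    pos <- sample.int(len, 1L)
    sub <- sample(.AA, 1L)
    cand <- founder
    substr(cand, pos, pos) <- sub
    if (!cand %in% seen) {
      out <- c(out, cand)
      seen <- c(seen, cand)
    }
  }
  out
}

#' Generate a synthetic longitudinal cohort with planted expansions
#'
#' Builds, per animal and chain-group, a baseline repertoire of clonal
#' lineages (power-law weights; one founder CDR3 per lineage plus
#' single-mismatch variants; per-lineage mutation class and rate; isotypes
#' conditional on class for IGH), then draws each timepoint's sample as a
#' multinomial of the configured depth over the clonotype weights. Planted
#' lineages are perturbed at 48/72 hr (and at 168 hr with the persistence
#' probability) by their mechanisms: `frequency` multiplies the lineage
#' weight by `2^target`; `unique_cdr3` activates new single-mismatch CDR3
#' variants so the variant count rises by `2^target` (which also raises the
#' lineage's sequence mass, as clonal expansion does); `mutation_rate`
#' multiplies the per-sequence mutation rate by `2^target` (capped at 45%).
#' Everything is a deterministic function of the configuration, including
#' its seed.
#'
#' @param config a [cohortConfig()].
#' @return list with `repertoire` (a [Repertoire-class] holding the whole
#'   cohort), `truth` (a `data.table` of planted-lineage ground truth:
#'   identity, mechanisms, targets, origin class, persistence), and
#'   `config`.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  .withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  species <- rep_len(c("IRM", "AGM"), cfg$nAnimals)
  animals <- sprintf("%s%02d", species, seq_len(cfg$nAnimals))

  ## germline-like shared resources: gene labels, per-gene J regions/tails
  pool <- cfg$genePool
  genes <- list(
    IGH = list(v = sprintf("IGHV%d", seq_len(pool$vHeavy)),
               j = sprintf("IGHJ%d", seq_len(pool$jHeavy))),
    IGK = list(v = sprintf("IGKV%d", seq_len(pool$vKappa)),
               j = sprintf("IGKJ%d", seq_len(pool$jLight))),
    IGL = list(v = sprintf("IGLV%d", seq_len(pool$vLambda)),
               j = sprintf("IGLJ%d", seq_len(pool$jLight)))
  )
  all_v <- unlist(lapply(genes, `[[`, "v"))
  all_j <- unlist(lapply(genes, `[[`, "j"))
  v_tail <- stats::setNames(.randNt(length(all_v), 10L), all_v)
  j_len <- stats::setNames(sample(30:45, length(all_j), replace = TRUE), all_j)
  j_region <- stats::setNames(
    vapply(all_j, function(j) .randNt(1L, j_len[[j]]), ""), all_j)

  ## planted allocation: round-robin over animals
  plantPerAnimal <- function(total) {
    n <- rep(total %/% cfg$nAnimals, cfg$nAnimals)
    extra <- total %% cfg$nAnimals
    if (extra > 0L) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
    n
  }
  n_pl_light <- plantPerAnimal(cfg$nPlanted)
  n_pl_heavy <- plantPerAnimal(cfg$nPlantedHeavy)

  rec_pieces <- list()
  truth_pieces <- list()
  planted_counter <- 0L

  for (a in seq_len(cfg$nAnimals)) {
    for (cg in cfg$chainGroups) {
      heavy <- cg == "IGH"
      n_pl <- if (heavy) n_pl_heavy[a] else n_pl_light[a]
      lin <- .buildBaselineLineages(cfg, genes, heavy)
      lin <- .plantExpansions(cfg, lin, genes, n_pl, heavy)
      if (n_pl > 0L) {
        pl <- lin[planted == TRUE]
        truth_pieces[[length(truth_pieces) + 1L]] <- data.table(
          planted_id = sprintf("P%04d", planted_counter + seq_len(nrow(pl))),
          animal_id = animals[a], species = species[a], chain_group = cg,
          chain = pl$chain, v_call = pl$v, j_call = pl$j,
          cdr3_aa = pl$founder, cdr3_len = pl$len,
          mechanisms = pl$mechanisms, origin_class = pl$class,
          persists = pl$persist,
          fc_frequency = pl$fc_freq, fc_unique_cdr3 = pl$fc_cdr3,
          fc_mutation_rate = pl$fc_mut)
        planted_counter <- planted_counter + nrow(pl)
      }
      samples <- .sampleTimepoints(cfg, lin, animals[a], species[a],
                                   j_len, j_region, v_tail)
      rec_pieces[[length(rec_pieces) + 1L]] <- samples
    }
  }

  records <- rbindlist(rec_pieces)
  setorderv(records, c("animal_id", "timepoint_hr", "chain", "v_call",
                       "j_call", "cdr3_aa", "v_mismatches", "j_mismatches"))
  records[, sequence_id := sprintf("S%08d", .I)]
  setcolorder(records, .REARRANGEMENT_COLS)
  truth <- if (length(truth_pieces)) rbindlist(truth_pieces) else
    data.table(planted_id = character(0))
  list(repertoire = Repertoire(records), truth = truth, config = cfg)
}

## one baseline lineage table for one animal x chain-group; list-columns
## hold the variant CDR3s and their within-lineage shares
.buildBaselineLineages <- function(cfg, genes, heavy) {
  L <- cfg$nBaselineLineages
  weight <- seq_len(L)^(-cfg$powerLawExponent)
  chain <- if (heavy) rep("IGH", L) else {
    pk <- cfg$kappaLambdaBaseline / (1 + cfg$kappaLambdaBaseline)
    ifelse(stats::runif(L) < pk, "IGK", "IGL")
  }
  ## per-animal Dirichlet gene usage
  usage <- lapply(genes, function(g) {
    list(v = {w <- stats::rgamma(length(g$v), 1); w / sum(w)},
         j = {w <- stats::rgamma(length(g$j), 1); w / sum(w)})
  })
  v <- character(L); j <- character(L)
  for (ch in unique(chain)) {
    i <- chain == ch
    v[i] <- sample(genes[[ch]]$v, sum(i), replace = TRUE,
                   prob = usage[[ch]]$v)
    j[i] <- sample(genes[[ch]]$j, sum(i), replace = TRUE,
                   prob = usage[[ch]]$j)
  }
  len <- sample(if (heavy) 8:30 else 8:24, L, replace = TRUE)
  founder <- vapply(len, .randomCdr3, "")
  cls_names <- names(cfg$mutationWeights)
  class <- sample(cls_names, L, replace = TRUE, prob = cfg$mutationWeights)
  rate <- cfg$mutationPeaks[class] * exp(stats::rnorm(L, 0, 0.25))
  for (cl in cls_names) {
    w <- .RATE_CLAMP[[cl]]
    i <- class == cl
    rate[i] <- pmin(pmax(rate[i], w[1]), w[2])
  }
  nvar <- pmin(1L + stats::rpois(L, 1.2), 6L)
  variants <- vector("list", L)
  shares <- vector("list", L)
  for (i in seq_len(L)) {
    vs <- c(founder[i],
            if (nvar[i] > 1L) .cdr3Variants(founder[i], nvar[i] - 1L))
    sh <- 0.5^(seq_along(vs) - 1L)
    variants[[i]] <- vs
    shares[[i]] <- sh / sum(sh)
  }
  data.table(
    lid = seq_len(L), chain = chain, v = v, j = j, len = len,
    founder = founder, class = class, rate = unname(rate),
    weight = weight, v_len = sample(240:300, L, replace = TRUE),
    variants = variants, shares = shares,
    planted = FALSE, mechanisms = NA_character_, persist = FALSE,
    fc_freq = NA_real_, fc_cdr3 = NA_real_, fc_mut = NA_real_,
    extra_variants = vector("list", L)
  )
}

## choose and configure planted lineages in a baseline table
.plantExpansions <- function(cfg, lin, genes, n_pl, heavy) {
  if (n_pl == 0L) return(lin)
  freq <- lin$weight / sum(lin$weight)
  expected <- freq * cfg$sequencesPerSample
  eligible <- which(expected >= cfg$plantedBaselineCounts[1] &
                      expected <= cfg$plantedBaselineCounts[2])
  if (length(eligible) < n_pl) {
    stop("infeasible config: not enough lineages in the planted baseline",
         " count window")
  }
  picked <- sample(eligible, n_pl)
  targets <- if (heavy) cfg$fcTargetsHeavy else cfg$fcTargets
  mech_names <- names(targets)
  for (i in picked) {
    ## lambda-chain bias: reassign planted light lineages to IGL
    if (!heavy && stats::runif(1) < cfg$lambdaBias) {
      lin$chain[i] <- "IGL"
      lin$v[i] <- sample(genes$IGL$v, 1L)
      lin$j[i] <- sample(genes$IGL$j, 1L)
    }
    ## origin class: memory-like vs naive-like, rate redrawn accordingly
    cls <- if (stats::runif(1) < cfg$originMemoryProb) "memory" else "naive"
    lin$class[i] <- cls
    w <- .RATE_CLAMP[[cls]]
    lin$rate[i] <- min(max(cfg$mutationPeaks[[cls]] *
                             exp(stats::rnorm(1, 0, 0.25)), w[1]), w[2])
    ## naive-origin lineages cannot reach the absolute mutation-rate
    ## threshold within days, so their expansion must involve a frequency
    ## or CDR3-diversification mechanism
    repeat {
      mech <- mech_names[stats::runif(length(mech_names)) < cfg$mechanismProb]
      if (length(mech) &&
          !(cls == "naive" && identical(mech, "mutation_rate"))) break
    }
    lin$planted[i] <- TRUE
    lin$mechanisms[i] <- paste(mech, collapse = ",")
    lin$persist[i] <- stats::runif(1) < cfg$persistProb
    if ("frequency" %in% mech) lin$fc_freq[i] <- targets[["frequency"]]
    if ("unique_cdr3" %in% mech) {
      fc <- targets[["unique_cdr3"]]
      lin$fc_cdr3[i] <- fc
      m0 <- length(lin$variants[[i]])
      extra <- max(0L, as.integer(round(m0 * (2^fc - 1))))
      lin$extra_variants[[i]] <- .cdr3Variants(lin$founder[i], extra,
                                               avoid = lin$variants[[i]])
    }
    if ("mutation_rate" %in% mech) lin$fc_mut[i] <- targets[["mutation_rate"]]
  }
  lin
}

## draw all timepoints of one animal x chain-group; returns the record rows.
## Mismatch profiles and isotypes are properties of a clone, so they are
## drawn once per variant and held fixed across timepoints; lineage-level
## mutation-rate changes arise from composition shifts (and from the planted
## mutation mechanism, which switches members to a boosted profile at the
## trigger timepoints).
.sampleTimepoints <- function(cfg, lin, animal, speciesLabel, j_len, j_region,
                              v_tail) {
  heavy <- lin$chain[1L] == "IGH"
  triggers <- c(48L, 72L)
  info <- lin[, .(lid, chain, v, j, len, class, rate, weight, v_len,
                  planted, mechanisms, persist, fc_freq, fc_cdr3, fc_mut)]
  ## flat base variant table
  base <- lin[, {
    vs <- variants[[1L]]
    data.table(variant = vs, share = shares[[1L]], extra = FALSE)
  }, by = .(lid)]
  ## planted extra variants (activated only while the expansion is on);
  ## they carry the mean base-variant weight share, so the variant count
  ## multiplies while per-variant abundance holds
  extra_src <- lin[planted == TRUE & lengths(extra_variants) > 0L]
  if (nrow(extra_src)) {
    extra <- extra_src[, {
      vs <- extra_variants[[1L]]
      data.table(variant = vs, share = 1 / length(variants[[1L]]),
                 extra = TRUE)
    }, by = .(lid)]
    tab <- rbind(base, extra)
  } else {
    tab <- base
  }
  tab <- merge(tab, info, by = "lid")
  setorderv(tab, c("lid", "extra", "variant"))

  ## fixed per-variant mismatch profiles; boosted profile for members of
  ## planted mutation-mechanism lineages
  jl <- j_len[tab$j]
  tab[, v_mm := stats::rbinom(.N, v_len, rate / 100)]
  tab[, j_mm := stats::rbinom(.N, jl, rate / 100)]
  tab[, rate_boost := ifelse(planted & !is.na(fc_mut),
                             pmin(rate * 2^fc_mut, 45), rate)]
  tab[, v_mm_b := v_mm]
  tab[, j_mm_b := j_mm]
  bo <- which(tab$rate_boost > tab$rate)
  if (length(bo)) {
    tab[bo, v_mm_b := stats::rbinom(length(bo), v_len, rate_boost / 100)]
    tab[bo, j_mm_b := stats::rbinom(length(bo), jl[bo], rate_boost / 100)]
  }
  tab[, j_aligned_len := as.integer(jl)]
  if (heavy) {
    iso <- character(nrow(tab))
    for (cl in unique(tab$class)) {
      i <- tab$class == cl
      pr <- cfg$isotypeProbs[[cl]]
      iso[i] <- sample(names(pr), sum(i), replace = TRUE, prob = pr)
    }
    tab[, isotype := iso]
  } else {
    tab[, isotype := NA_character_]
  }

  out <- vector("list", length(cfg$timepoints))
  for (ti in seq_along(cfg$timepoints)) {
    tp <- cfg$timepoints[ti]
    on <- tp %in% triggers | (tab$persist & tp == 168L)
    active <- !tab$extra | on
    w <- tab$weight * tab$share
    fboost <- tab$planted & !is.na(tab$fc_freq) & on
    w[fboost] <- w[fboost] * 2^tab$fc_freq[fboost]
    mboost <- tab$planted & !is.na(tab$fc_mut) & on
    w[!active] <- 0
    cnt <- as.vector(stats::rmultinom(1L, cfg$sequencesPerSample,
                                      w / sum(w)))
    keep <- cnt > 0L
    rows <- tab[keep]
    rows[, duplicate_count := cnt[keep]]
    mb <- mboost[keep]
    rows[, v_mismatches := ifelse(mb, v_mm_b, v_mm)]
    rows[, j_mismatches := ifelse(mb, j_mm_b, j_mm)]
    rows[, `:=`(
      animal_id = animal, species = speciesLabel, timepoint_hr = tp,
      cdr3_aa = variant, cdr3_nt = .aaToNt(variant),
      v_call = v, j_call = j, v_aligned_len = as.integer(v_len),
      v_tail_nt = unname(v_tail[v]), j_region_nt = unname(j_region[j]),
      sequence_id = NA_character_
    )]
    out[[ti]] <- rows[, .(sequence_id, animal_id, species, timepoint_hr,
                          chain, v_call, j_call, cdr3_aa, cdr3_nt, isotype,
                          v_mismatches, j_mismatches, v_aligned_len,
                          j_aligned_len, duplicate_count, v_tail_nt,
                          j_region_nt)]
  }
  rbindlist(out)
}

#' Write a packaged synthetic fixture to disk
#'
#' Generates a cohort at one of two scales and writes one rearrangement TSV
#' per (animal, timepoint), a planted-truth TSV and a JSON echo of the
#' configuration. `tiny` (2 animals, 5,000 sequences per chain-group sample)
#' is for fast tests; `default` approximates study depths.
#' Identical seed and scale give byte-identical files.
#'
#' @param scale `"tiny"` or `"default"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return (invisibly) list with `files`, `truth`, `config`.
#' @export
emitFixture <- function(scale = c("tiny", "default"), dir = tempfile("cohort"),
                        seed = 1L) {
  scale <- match.arg(scale)
  cfg <- switch(scale,
    tiny = cohortConfig(nAnimals = 2L, sequencesPerSample = 5000L,
                        nBaselineLineages = 400L, nPlanted = 8L,
                        plantedBaselineCounts = c(15, 60), seed = seed),
    default = cohortConfig(seed = seed))
  gen <- generateCohort(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- gen$repertoire@rearrangements
  keys <- unique(dt[, .(animal_id, timepoint_hr)])
  setorderv(keys, c("animal_id", "timepoint_hr"))
  files <- character(0)
  for (i in seq_len(nrow(keys))) {
    f <- file.path(dir, sprintf("%s_%03dhr.tsv", keys$animal_id[i],
                                keys$timepoint_hr[i]))
    writeRearrangements(
      Repertoire(dt[animal_id == keys$animal_id[i] &
                      timepoint_hr == keys$timepoint_hr[i]]), f)
    files <- c(files, f)
  }
  truth_file <- file.path(dir, "planted_truth.tsv")
  fwrite(gen$truth, truth_file, sep = "\t")
  cfg_file <- file.path(dir, "config.json")
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), cfg_file)
  invisible(list(files = files, truth = truth_file, config = cfg_file))
}
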