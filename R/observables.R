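#' Locate the front and core of the population
#'
#' The front is the forward-most habitable column whose census reaches
#' `threshold` individuals (falling back to the forward-most occupied
#' column if none does); the threshold avoids classifying a deme holding a
#' lone migrant as the front. The core is the rear-most occupied column for
#' shifts (the receding edge) and the forward-most column of the original
#' seed region for expansions.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param threshold Minimum census for a column to count as the front
#'   (default 10).
#' @return List with elements `front` and `core` (column indices), or
#'   `NULL` if the landscape is extinct.
#' @export
frontAndCore <- function(sim, threshold = 10) {
  cen <- columnCensus(sim)
  occ <- which(cen > 0)
  if (!length(occ)) return(NULL)
  big <- which(cen >= threshold)
  front <- if (length(big)) max(big) else max(occ)
  core <- if (sim@schedule@mode == "shift") min(occ)
          else min(max(occ), sim@schedule@windowWidth)
  list(front = front, core = core)
}

#' Fixed mutation counts in a column
#'
#' Counts selected loci of each class whose derived allele is fixed
#' (frequency 1) among the column's residents.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param col Column index.
#' @return Named integer vector `c(deleterious = , beneficial = )`.
#' @export
fixedCounts <- function(sim, col) {
  p <- demeFrequencies(sim, col)
  cls <- sim@loci$class
  c(deleterious = sum(p[cls == "deleterious"] == 1),
    beneficial = sum(p[cls == "beneficial"] == 1))
}

#' Expected neutral heterozygosity in a column
#'
#' Mean over the neutral loci of `2p(1-p)`, with `p` the derived-allele
#' frequency among the column's residents.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param col Column index.
#' @return Mean expected heterozygosity (in `[0, 0.5]`).
#' @export
heterozygosity <- function(sim, col) {
  neu <- sim@loci$class == "neutral"
  if (!any(neu))
    stop("no neutral loci configured; heterozygosity is unavailable")
  p <- demeFrequencies(sim, col)[neu]
  mean(2 * p * (1 - p))
}

#' Realized speed of the front
#'
#' Least-squares slope of the front column index against generation over
#' the supplied window.
#'
#' @param frontIndex Numeric vector of front column indices.
#' @param generation Matching generation numbers.
#' @return Speed in demes per generation (0, with attribute
#'   `stalled = TRUE`, if the front never advanced).
#' @examples
#' realizedSpeed(c(1, 1, 2, 2, 3), 1:5)  # 0.5
#' @export
realizedSpeed <- function(frontIndex, generation) {
  stopifnot(length(frontIndex) == length(generation),
            length(frontIndex) >= 2)
  if (max(frontIndex) - min(frontIndex) < 1) {
    out <- 0
    attr(out, "stalled") <- TRUE
    return(out)
  }
  unname(stats::coef(stats::lm(frontIndex ~ generation))[2])
}

# one full generation record (cadenced statistics)
generationRecord <- function(sim, generation, withNeutral) {
  fc <- frontAndCore(sim)
  if (is.null(fc))
    return(data.frame(generation = generation, frontIndex = NA,
                      frontCensus = NA, meanFrontFitness = NA,
                      meanCoreFitness = NA, nFixedDelFront = NA,
                      nFixedBenFront = NA, hetFront = NA, hetCore = NA,
                      totalCensus = 0, extinct = TRUE))
  cen <- columnCensus(sim)
  fx <- fixedCounts(sim, fc$front)
  data.frame(
    generation = generation,
    frontIndex = fc$front,
    frontCensus = cen[fc$front],
    meanFrontFitness = demeMeanFitness(sim, fc$front),
    meanCoreFitness = demeMeanFitness(sim, fc$core),
    nFixedDelFront = unname(fx["deleterious"]),
    nFixedBenFront = unname(fx["beneficial"]),
    hetFront = if (withNeutral) heterozygosity(sim, fc$front) else NA_real_,
    hetCore = if (withNeutral) heterozygosity(sim, fc$core) else NA_real_,
    totalCensus = sum(cen),
    extinct = FALSE)
}

#' Run the scheduled phase of a simulation
#'
#' Drives a burned-in simulation through its schedule: each generation the
#' habitability window is updated (shift mode) or held open (expansion
#' mode), then one life cycle is executed. Returns per-generation traces
#' of the front (index, census, mean relative fitness) plus full
#' generation records every `recordEvery` generations.
#'
#' @param sim A burned-in [`RangeSim`][RangeSim-class] (see
#'   [runBurnIn()]).
#' @param generations Number of post-burn-in generations (defaults to the
#'   schedule's `totalGenerations`).
#' @param recordEvery Cadence of full records (default 20).
#' @return A list of class `"shiftloadRun"`: `records` (data frame),
#'   `trace` (per-generation data frame with `generation`, `frontIndex`,
#'   `frontCensus`, `meanFrontFitness`, `totalCensus`),
#'   `extinctionGeneration` (`NA` if the run survived), `wRef`, and `sim`.
#' @export
runPhase <- function(sim, generations = sim@schedule@totalGenerations,
                     recordEvery = 20) {
  spec <- sim@schedule
  withNeutral <- any(sim@loci$class == "neutral")
  nGen <- as.integer(generations)
  trGen <- integer(nGen); trFront <- integer(nGen)
  trCen <- integer(nGen); trFit <- numeric(nGen); trTot <- numeric(nGen)
  records <- vector("list", nGen %/% recordEvery + 2L)
  nr <- 0L
  extinctionGen <- NA_integer_
  lastMask <- habitabilityAt(spec, spec@burnIn)
  applyHabitability(sim, lastMask)
  kept <- 0L
  for (t in seq_len(nGen)) {
    g <- spec@burnIn + t
    mask <- habitabilityAt(spec, g)
    if (!identical(mask, lastMask)) {
      applyHabitability(sim, mask)
      lastMask <- mask
    }
    tot <- eng_step(sim@ptr, FALSE, TRUE, TRUE, TRUE)
    sim@generation <- sim@generation + 1L
    if (tot == 0) {
      extinctionGen <- t
      nr <- nr + 1L
      records[[nr]] <- generationRecord(sim, g, withNeutral)
      break
    }
    kept <- kept + 1L
    fc <- frontAndCore(sim)
    cen <- columnCensus(sim)
    trGen[kept] <- g
    trFront[kept] <- fc$front
    trCen[kept] <- cen[fc$front]
    trFit[kept] <- demeMeanFitness(sim, fc$front)
    trTot[kept] <- tot
    if (t %% recordEvery == 0 || t == nGen) {
      nr <- nr + 1L
      records[[nr]] <- generationRecord(sim, g, withNeutral)
    }
  }
  structure(
    list(records = do.call(rbind, records[seq_len(nr)]),
         trace = data.frame(generation = trGen[seq_len(kept)],
                            frontIndex = trFront[seq_len(kept)],
                            frontCensus = trCen[seq_len(kept)],
                            meanFrontFitness = trFit[seq_len(kept)],
                            totalCensus = trTot[seq_len(kept)]),
         extinctionGeneration = extinctionGen,
         wRef = sim@wRef,
         sim = sim),
    class = "shiftloadRun")
}

#' @export
print.shiftloadRun <- function(x, ...) {
  cat("shiftload run:", nrow(x$trace), "generations traced\n")
  if (!is.na(x$extinctionGeneration))
    cat("  global extinction at post-burn-in generation",
        x$extinctionGeneration, "\n")
  else if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat("  final front: column", last$frontIndex, "| census",
        last$frontCensus, "| mean relative fitness",
        signif(last$meanFrontFitness, 4), "\n")
  }
  invisible(x)
}

#' End-to-end simulation of one replicate
#'
#' Initializes the landscape, runs the burn-in (beneficial mutations
#' suppressed, population confined to the seed region), re-references
#' fitness to 1, then runs the expansion or shift phase.
#'
#' @inheritParams simInit
#' @param recordEvery Cadence of full generation records.
#' @param ... Further arguments passed to [simInit()] (`hardGrowth`,
#'   `hardReference`).
#' @return A `"shiftloadRun"` list; see [runPhase()].
#' @examples
#' \donttest{
#' run <- simulateRange(schedule = scheduleSpec("shift", T = 5,
#'                      burnIn = 500, totalGenerations = 300,
#'                      landscapeLength = 80), seed = 1)
#' run
#' }
#' @export
simulateRange <- function(loci = buildLocusTable(),
                          model = mutationModel(),
                          schedule = scheduleSpec("expansion"),
                          K = 100, m = 0.1, R = 2,
                          selection = c("soft", "hard"),
                          recombination = c("free", "none"),
                          selfing = FALSE, seed = 1, recordEvery = 20,
                          ...) {
  sim <- simInit(loci, model, schedule, K = K, m = m, R = R,
                 selection = match.arg(selection),
                 recombination = match.arg(recombination),
                 selfing = selfing, seed = seed, ...)
  sim <- runBurnIn(sim)
  runPhase(sim, recordEvery = recordEvery)
}

#' Replicate simulations with aggregation
#'
#' Runs `nReps` independently seeded replicates of one configuration and
#' aggregates the cadenced records: per generation, the across-replicate
#' mean and twice the standard error of every statistic. Replicates that
#' go extinct contribute until their extinction (series truncation; the
#' `n` column records how many replicates were alive).
#'
#' @param config A run configuration from [loadConfig()] /
#'   [defaultConfig()].
#' @param nReps Number of replicates.
#' @param baseSeed Seed from which replicate seeds are derived.
#' @return List with `replicates` (list of `"shiftloadRun"`), `aggregate`
#'   (data frame of means and `2SE` columns), and `seeds`.
#' @export
runReplicates <- function(config = defaultConfig(), nReps = 3,
                          baseSeed = 1) {
  stopifnot(nReps >= 1)
  seeds <- replicateSeeds(baseSeed, nReps)
  runs <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    do.call(runSimulation, list(config = cfg))
  })
  list(replicates = runs, aggregate = aggregateRuns(runs), seeds = seeds)
}

# deterministic, collision-free replicate seeds below 2^31
replicateSeeds <- function(baseSeed, n) {
  as.integer((as.numeric(baseSeed) + 104729 * seq_len(n)) %% 2147483647)
}

#' Aggregate the records of several runs
#'
#' @param runs List of `"shiftloadRun"` objects.
#' @return Data frame keyed by generation with `mean_*` and `se2_*`
#'   columns for each recorded statistic and `n` alive replicates.
#' @export
aggregateRuns <- function(runs) {
  recs <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]$records
    r$replicate <- i
    r
  })
  all <- do.call(rbind, recs)
  all <- all[!all$extinct, , drop = FALSE]
  stats <- setdiff(names(all), c("generation", "replicate", "extinct"))
  gens <- sort(unique(all$generation))
  out <- lapply(gens, function(g) {
    sub <- all[all$generation == g, , drop = FALSE]
    row <- data.frame(generation = g, n = nrow(sub))
    for (st in stats) {
      x <- sub[[st]]
      row[[paste0("mean_", st)]] <- mean(x)
      row[[paste0("se2_", st)]] <-
        if (nrow(sub) > 1) 2 * stats::sd(x) / sqrt(nrow(sub)) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}
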