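#' Initialize a simulation
#'
#' Builds the compiled landscape state: a `landscapeWidth x landscapeLength`
#' grid of demes, with the seed region (the first `windowWidth` columns)
#' habitable and filled to carrying capacity with mutation-free
#' individuals. All stochastic draws of the run flow from `seed`.
#'
#' @param loci Locus table from [buildLocusTable()].
#' @param model A [`MutationModel`][MutationModel-class].
#' @param schedule A [`ScheduleSpec`][ScheduleSpec-class].
#' @param K Deme carrying capacity (default 100).
#' @param m Migration rate (default 0.1).
#' @param R Growth parameter (default 2).
#' @param selection `"soft"` or `"hard"`.
#' @param recombination `"free"` or `"none"`.
#' @param selfing Allow self-fertilization. With the default `FALSE`, the
#'   two parents of an offspring are distinct individuals and a lone
#'   colonist cannot found a deme; this calibration reproduces the
#'   realized dispersal-limited expansion speed of about 0.25 demes per
#'   generation at the default demography.
#' @param hardGrowth How the growth parameter scales with mean fitness
#'   under hard selection: `"linear"` (`R_eff = w * R`, the default) or
#'   `"log"` (`log R_eff = w * log R`).
#' @param hardReference Fitness reference of the hard-selection
#'   demographic scaling: `"absolute"` (the default; `w` is absolute mean
#'   fitness, so the standing mutation load depresses `K_eff` and `R_eff`
#'   already during the burn-in) or `"relative"` (`w` is re-referenced to
#'   1 at burn-in end). Reported fitness statistics are always relative.
#' @param seed Integer seed of the run's random stream.
#' @return A [`RangeSim`][RangeSim-class] handle.
#' @examples
#' sim <- simInit(buildLocusTable(9, 1, 0), mutationModel(),
#'                scheduleSpec("shift", T = 5, burnIn = 10,
#'                             landscapeLength = 20), seed = 1)
#' sim
#' @export
simInit <- function(loci, model = mutationModel(),
                    schedule = scheduleSpec("expansion"),
                    K = 100, m = 0.1, R = 2,
                    selection = c("soft", "hard"),
                    recombination = c("free", "none"),
                    selfing = FALSE, seed = 1,
                    hardGrowth = c("linear", "log"),
                    hardReference = c("absolute", "relative")) {
  selection <- match.arg(selection)
  recombination <- match.arg(recombination)
  hardGrowth <- match.arg(hardGrowth)
  hardReference <- match.arg(hardReference)
  validObject(model); validObject(schedule)
  stopifnot(K > 0, m >= 0, m <= 1, R > 1)
  sel <- loci$class != "neutral"
  # engine expects selected loci first; the table builder guarantees it
  if (any(which(sel) > sum(sel)))
    stop("locus table must list selected loci before neutral loci")
  ptr <- eng_create(schedule@landscapeWidth, schedule@landscapeLength,
                    loci$s[sel], loci$h[sel], sum(!sel),
                    model@U, model@neutralRate, m, R, K,
                    selection == "hard", hardGrowth == "linear",
                    recombination == "free", selfing, seed)
  sim <- new("RangeSim", ptr = ptr, loci = loci, model = model,
             schedule = schedule,
             config = list(K = K, m = m, R = R, selection = selection,
                           recombination = recombination,
                           selfing = selfing, hardGrowth = hardGrowth,
                           hardReference = hardReference, seed = seed),
             generation = 0L, wRef = 1)
  seedCols <- seq_len(schedule@windowWidth)
  demes0 <- demeIndices0(sim, seedCols)
  eng_set_habitable(ptr, maskFromColumns(sim, seedCols))
  eng_seed_demes(ptr, demes0, as.integer(K))
  sim
}

# 0-based engine deme indices of the given (1-based) columns
demeIndices0 <- function(sim, cols) {
  w <- sim@schedule@landscapeWidth
  as.integer(outer(seq_len(w) - 1L, (cols - 1L) * w, `+`))
}

# full-grid logical mask with the given columns habitable
maskFromColumns <- function(sim, cols) {
  w <- sim@schedule@landscapeWidth
  len <- sim@schedule@landscapeLength
  colMask <- logical(len)
  colMask[cols] <- TRUE
  rep(colMask, each = w)
}

#' Census of every deme
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @return Integer matrix `landscapeWidth x landscapeLength` of diploid
#'   counts.
#' @export
census <- function(sim) {
  matrix(eng_census(sim@ptr), nrow = sim@schedule@landscapeWidth)
}

#' Per-column census
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @return Integer vector of column totals (length `landscapeLength`).
#' @export
columnCensus <- function(sim) {
  as.integer(colSums(census(sim)))
}

#' Mean fitness of the residents of one landscape column
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param col Column index (1-based).
#' @param relative Divide by the burn-in reference fitness (default
#'   `TRUE`).
#' @return Mean fitness, or `NA` if the column is empty.
#' @export
demeMeanFitness <- function(sim, col, relative = TRUE) {
  f <- unlist(lapply(demeIndices0(sim, col),
                     function(d0) eng_deme_fitness(sim@ptr, d0)))
  if (!length(f)) return(NA_real_)
  mean(f) / if (relative) sim@wRef else 1
}

#' Derived-allele frequencies in one or more columns
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param cols Column indices (1-based); residents are pooled.
#' @return Numeric vector of length `nrow(loci)`, in locus-table order.
#' @export
demeFrequencies <- function(sim, cols) {
  eng_freqs(sim@ptr, demeIndices0(sim, cols))
}

#' Extract or inject explicit genotypes
#'
#' `getDemeGenotypes` unpacks the bit-packed state of one deme into an
#' `n x 2 x L` 0/1 array; `setDemeGenotypes` replaces a deme's residents
#' with the given array (used to construct exact test states). Both are
#' intended for small problems.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param col Column index (1-based).
#' @param row Row index (1-based, default 1).
#' @param genotypes Integer array `n x 2 x L`.
#' @return `getDemeGenotypes`: the array; `setDemeGenotypes`: `sim`,
#'   invisibly.
#' @export
getDemeGenotypes <- function(sim, col, row = 1) {
  d0 <- (col - 1L) * sim@schedule@landscapeWidth + (row - 1L)
  eng_get_genotypes(sim@ptr, as.integer(d0))
}

#' @rdname getDemeGenotypes
#' @export
setDemeGenotypes <- function(sim, col, genotypes, row = 1) {
  d0 <- (col - 1L) * sim@schedule@landscapeWidth + (row - 1L)
  eng_set_deme(sim@ptr, as.integer(d0), genotypes)
  invisible(sim)
}

#' Fitness values of the residents of one deme
#'
#' @inheritParams getDemeGenotypes
#' @param relative Divide by the burn-in reference fitness.
#' @return Numeric vector of individual fitness values.
#' @export
demeFitnessValues <- function(sim, col, row = 1, relative = FALSE) {
  d0 <- (col - 1L) * sim@schedule@landscapeWidth + (row - 1L)
  eng_deme_fitness(sim@ptr, as.integer(d0)) / if (relative) sim@wRef else 1
}

#' Deep-copy a simulation
#'
#' Clones the full landscape state (used to branch several scenarios off
#' one shared burn-in) and reseeds the clone's random stream.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param seed Seed of the clone's random stream.
#' @return A new, independent [`RangeSim`][RangeSim-class].
#' @export
cloneSim <- function(sim, seed) {
  out <- sim
  out@ptr <- eng_clone(sim@ptr, seed)
  out@config$seed <- seed
  out
}

#' Advance the simulation by raw generations
#'
#' Applies `n` complete life cycles (migration, then reproduction under
#' logistic regulation with fitness-proportional parentage, then mutation)
#' without touching habitability. Most callers want [simulateRange()] or
#' [runBurnIn()], which also drive the schedule.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param n Number of generations.
#' @param suppressBeneficial Discard mutation events at beneficial loci
#'   (the burn-in convention).
#' @return `sim` with its generation counter advanced (state is updated in
#'   place).
#' @export
runGenerations <- function(sim, n, suppressBeneficial = FALSE) {
  for (i in seq_len(n))
    eng_step(sim@ptr, suppressBeneficial, TRUE, TRUE, TRUE)
  sim@generation <- sim@generation + as.integer(n)
  sim
}

#' Number of clamped fitness factors so far
#'
#' Per-locus fitness factors below the positivity floor (possible only
#' under extreme exponential-DFE draws) are clamped; this returns how many
#' locus factors were affected at initialization.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @return Count of clamped factors.
#' @export
clampedFactorCount <- function(sim) eng_clamp_count(sim@ptr)
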