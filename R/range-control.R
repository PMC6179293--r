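#' Habitable columns at a given generation
#'
#' During burn-in only the seed region (the first `windowWidth` columns) is
#' habitable. In expansion mode the whole landscape opens at the end of the
#' burn-in. In shift mode a window of constant width advances one column
#' every `T` generations — the front column opens and the rear column
#' closes simultaneously — until it reaches the end of the landscape, where
#' it parks (the recovery phase). The window moves at the start of a
#' generation, before migration, so a newly opened column can be colonized
#' in the generation it opens.
#'
#' @param spec A [`ScheduleSpec`][ScheduleSpec-class].
#' @param generation Generation counted from the start of the run
#'   (burn-in included), `>= 0`.
#' @return Logical vector over columns (length `landscapeLength`).
#' @examples
#' sp <- scheduleSpec("shift", T = 5, burnIn = 100, landscapeLength = 20)
#' which(habitabilityAt(sp, 100))  # 1..5
#' which(habitabilityAt(sp, 105))  # 2..6
#' @export
habitabilityAt <- function(spec, generation) {
  stopifnot(is(spec, "ScheduleSpec"), generation >= 0)
  len <- spec@landscapeLength
  width <- spec@windowWidth
  mask <- logical(len)
  if (generation < spec@burnIn || spec@mode == "shift") {
    start <- 0L
    if (generation >= spec@burnIn && spec@mode == "shift") {
      steps <- (generation - spec@burnIn) %/% spec@T
      start <- min(steps, len - width)   # window parks at the far end
    }
    mask[(start + 1):(start + width)] <- TRUE
  } else {
    mask[] <- TRUE
  }
  mask
}

#' Apply a habitability mask to the landscape
#'
#' Residents of any deme newly marked uninhabitable are removed (the
#' trailing edge of a shifting range goes extinct); newly opened demes are
#' empty until migrants arrive.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @param columnMask Logical vector over columns.
#' @return `sim`, invisibly (state updated in place).
#' @export
applyHabitability <- function(sim, columnMask) {
  stopifnot(length(columnMask) == sim@schedule@landscapeLength)
  eng_set_habitable(sim@ptr,
                    rep(columnMask, each = sim@schedule@landscapeWidth))
  invisible(sim)
}

#' Re-reference fitness at the end of the burn-in
#'
#' Sets the reference fitness to the current mean individual fitness over
#' the whole landscape, so that reported relative fitness equals 1 at the
#' end of the burn-in in every scenario (genotypes are untouched). Under
#' hard selection the demographic fitness scaling uses the same reference,
#' fixing the proportionality constant of `K_eff` and `R_eff`.
#'
#' @param sim A [`RangeSim`][RangeSim-class].
#' @return `sim` with `wRef` set.
#' @export
rescaleFitnessReference <- function(sim) {
  w <- eng_mean_fitness_all(sim@ptr)
  if (is.na(w)) stop("cannot rescale fitness: the landscape is extinct")
  # reporting is always relative to w; the demographic scaling under hard
  # selection uses the same reference unless configured absolute
  if (!identical(sim@config$hardReference, "absolute"))
    eng_set_wref(sim@ptr, w)
  sim@wRef <- w
  sim
}

#' Run the burn-in phase
#'
#' Confines the population to the seed region for `burnIn` generations to
#' reach mutation-selection equilibrium. Beneficial mutations are
#' suppressed throughout (otherwise every beneficial locus would fix
#' before the expansion begins). At the end, fitness is re-referenced to 1
#' via [rescaleFitnessReference()].
#'
#' @param sim A freshly initialized [`RangeSim`][RangeSim-class].
#' @return `sim`, advanced to the end of the burn-in.
#' @examples
#' \donttest{
#' sim <- simInit(buildLocusTable(), mutationModel(),
#'                scheduleSpec("shift", T = 5, burnIn = 200), seed = 1)
#' sim <- runBurnIn(sim)
#' }
#' @export
runBurnIn <- function(sim) {
  if (sim@generation != 0L)
    stop("burn-in must start from a freshly initialized simulation")
  applyHabitability(sim, habitabilityAt(sim@schedule, 0))
  sim <- runGenerations(sim, sim@schedule@burnIn, suppressBeneficial = TRUE)
  rescaleFitnessReference(sim)
}
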