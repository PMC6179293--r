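#' @import methods
NULL

#' Mutation model specification
#'
#' Describes the mutational process acting on the selected and neutral loci:
#' the genome-wide rate, the distribution of fitness effects (constant
#' magnitude or exponential), and the dominance scheme (constant `h` or an
#' h-s trade-off in which more deleterious mutations are more recessive).
#' Back-mutation is never allowed: a mutation event landing on an
#' already-derived copy is a silent no-op.
#'
#' @slot U Genome-wide mutation rate per diploid individual per generation,
#'   spread over the selected loci.
#' @slot dfe `"constant"` or `"exponential"`; under the exponential DFE,
#'   per-locus effects are drawn once at initialization with mean magnitude
#'   `meanS` (mirrored between the deleterious and beneficial classes).
#' @slot meanS Magnitude of the selection coefficient (constant model) or
#'   mean magnitude (exponential model).
#' @slot dominance `"constant"` (all deleterious loci share `h`) or
#'   `"hs_tradeoff"` (`h = 1/(1/thetaI - s*thetaR)` per deleterious locus).
#'   Beneficial loci always use `h = 0.5` under the exponential DFE or
#'   trade-off scenarios.
#' @slot h Dominance coefficient of deleterious mutations under the
#'   constant scheme (0.5 additive, 0 fully recessive, 0.3 partial).
#' @slot thetaI Intercept of the h-s trade-off (value of `h` at `s = 0`).
#' @slot thetaR Rate of the h-s trade-off (how fast `h` approaches 0 as
#'   mutations become more deleterious).
#' @slot neutralRate Per-locus, per-haplotype mutation rate of neutral
#'   loci (independent of `U`).
#' @seealso [mutationModel()], [buildLocusTable()]
#' @export
setClass("MutationModel",
  representation(U = "numeric", dfe = "character", meanS = "numeric",
                 dominance = "character", h = "numeric",
                 thetaI = "numeric", thetaR = "numeric",
                 neutralRate = "numeric"),
  prototype(U = 0.1, dfe = "constant", meanS = 0.005,
            dominance = "constant", h = 0.5, thetaI = 0.5, thetaR = 2500,
            neutralRate = 5e-5))

setValidity("MutationModel", function(object) {
  msgs <- character(0)
  if (length(object@U) != 1 || object@U < 0)
    msgs <- c(msgs, "U must be a single nonnegative number")
  if (!object@dfe %in% c("constant", "exponential"))
    msgs <- c(msgs, "dfe must be 'constant' or 'exponential'")
  if (object@meanS <= 0)
    msgs <- c(msgs, "meanS must be positive (sign is carried by the locus class)")
  if (!object@dominance %in% c("constant", "hs_tradeoff"))
    msgs <- c(msgs, "dominance must be 'constant' or 'hs_tradeoff'")
  if (object@h < 0 || object@h > 1)
    msgs <- c(msgs, "h must lie in [0, 1]")
  if (object@thetaI <= 0 || object@thetaI > 1)
    msgs <- c(msgs, "thetaI must lie in (0, 1]")
  if (object@thetaR < 0)
    msgs <- c(msgs, "thetaR must be nonnegative")
  if (object@neutralRate < 0)
    msgs <- c(msgs, "neutralRate must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a mutation model
#'
#' @param U Genome-wide mutation rate per diploid per generation (default
#'   0.1).
#' @param dfe `"constant"` or `"exponential"`.
#' @param meanS (Mean) magnitude of selection coefficients (default 0.005).
#' @param dominance `"constant"` or `"hs_tradeoff"`.
#' @param h Dominance coefficient of deleterious mutations (default 0.5).
#' @param thetaI,thetaR Parameters of the h-s trade-off (defaults 0.5 and
#'   2500).
#' @param neutralRate Per-copy mutation rate of neutral loci (default
#'   5e-5, equal to the per-copy rate implied by `U = 0.1` over 1000
#'   selected loci).
#' @return A [`MutationModel`][MutationModel-class] object.
#' @examples
#' mutationModel()                        # additive, constant effects
#' mutationModel(h = 0)                   # fully recessive
#' mutationModel(dfe = "exponential", dominance = "hs_tradeoff")
#' @export
mutationModel <- function(U = 0.1, dfe = c("constant", "exponential"),
                          meanS = 0.005,
                          dominance = c("constant", "hs_tradeoff"),
                          h = 0.5, thetaI = 0.5, thetaR = 2500,
                          neutralRate = 5e-5) {
  new("MutationModel", U = U, dfe = match.arg(dfe), meanS = meanS,
      dominance = match.arg(dominance), h = h, thetaI = thetaI,
      thetaR = thetaR, neutralRate = neutralRate)
}

setMethod("show", "MutationModel", function(object) {
  cat("MutationModel\n")
  cat("  U (genome-wide, diploid):", object@U, "\n")
  cat("  DFE:", object@dfe, "| mean |s| =", object@meanS, "\n")
  if (object@dominance == "constant")
    cat("  dominance: constant h =", object@h, "\n")
  else
    cat("  dominance: h-s trade-off (thetaI =", object@thetaI,
        ", thetaR =", object@thetaR, ")\n")
  cat("  neutral per-copy rate:", object@neutralRate, "\n")
})

#' Habitability schedule of a run
#'
#' Defines when and where the landscape is habitable: a burn-in phase
#' confined to the seed region, followed by either a range expansion (the
#' whole landscape opens at once) or a range shift (a constant-width window
#' advances one column every `T` generations, closing at the rear as it
#' opens at the front, i.e. moving at speed `v = 1/T`). When the window
#' reaches the end of the landscape it parks there and the run continues
#' (the recovery phase).
#'
#' @slot mode `"expansion"` or `"shift"`.
#' @slot burnIn Burn-in length in generations (default 4000).
#' @slot T Generations between forward steps of the shift window (shift
#'   mode only; `NA` for expansions).
#' @slot windowWidth Width of the habitable window in columns (default 5);
#'   also the width of the seed region in both modes.
#' @slot landscapeLength Number of columns of the landscape (default 300).
#' @slot landscapeWidth Number of rows (1 for 1-D, e.g. 5 for 2-D).
#' @slot totalGenerations Post-burn-in run length (default 5000).
#' @seealso [scheduleSpec()], [habitabilityAt()]
#' @export
setClass("ScheduleSpec",
  representation(mode = "character", burnIn = "integer", T = "integer",
                 windowWidth = "integer", landscapeLength = "integer",
                 landscapeWidth = "integer", totalGenerations = "integer"))

setValidity("ScheduleSpec", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("expansion", "shift"))
    msgs <- c(msgs, "mode must be 'expansion' or 'shift'")
  if (object@burnIn < 0) msgs <- c(msgs, "burnIn must be nonnegative")
  if (object@mode == "shift" && (is.na(object@T) || object@T < 1))
    msgs <- c(msgs, "shift mode requires integer T >= 1")
  if (object@windowWidth < 1) msgs <- c(msgs, "windowWidth must be >= 1")
  if (object@landscapeLength < object@windowWidth)
    msgs <- c(msgs, "landscapeLength must be at least windowWidth")
  if (object@landscapeWidth < 1) msgs <- c(msgs, "landscapeWidth must be >= 1")
  if (object@totalGenerations < 0)
    msgs <- c(msgs, "totalGenerations must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a habitability schedule
#'
#' @param mode `"expansion"` or `"shift"`.
#' @param T Generations per forward step of the shift window; the shift
#'   speed is `v = 1/T`. Ignored for expansions.
#' @param v Alternative to `T`: shift speed in demes per generation
#'   (must be `1/integer`).
#' @param burnIn Burn-in generations (default 4000).
#' @param windowWidth Habitable-window width in columns (default 5).
#' @param landscapeLength Landscape length in columns (default 300).
#' @param landscapeWidth Landscape width in rows (default 1).
#' @param totalGenerations Post-burn-in generations (default 5000).
#' @return A [`ScheduleSpec`][ScheduleSpec-class] object.
#' @examples
#' scheduleSpec("shift", T = 5)          # v = 0.2
#' scheduleSpec("shift", v = 0.05)       # T = 20
#' scheduleSpec("expansion", landscapeLength = 100)
#' @export
scheduleSpec <- function(mode = c("expansion", "shift"), T = NA, v = NULL,
                         burnIn = 4000, windowWidth = 5,
                         landscapeLength = 300, landscapeWidth = 1,
                         totalGenerations = 5000) {
  mode <- match.arg(mode)
  if (!is.null(v)) {
    stopifnot(v > 0, v <= 1)
    T <- round(1 / v)
    # accept conventionally rounded speeds such as 0.066 for 1/15
    if (abs(1 / T - v) > 0.02 * v)
      stop("v must be the reciprocal of an integer number of generations")
  }
  new("ScheduleSpec", mode = mode, burnIn = as.integer(burnIn),
      T = as.integer(T), windowWidth = as.integer(windowWidth),
      landscapeLength = as.integer(landscapeLength),
      landscapeWidth = as.integer(landscapeWidth),
      totalGenerations = as.integer(totalGenerations))
}

#' @describeIn ScheduleSpec-class Shift speed `v = 1/T` (`NA` for
#'   expansions).
#' @param spec A `ScheduleSpec`.
#' @export
shiftSpeed <- function(spec) {
  stopifnot(is(spec, "ScheduleSpec"))
  if (spec@mode == "shift") 1 / spec@T else NA_real_
}

setMethod("show", "ScheduleSpec", function(object) {
  cat("ScheduleSpec:", object@mode, "\n")
  cat("  landscape:", object@landscapeWidth, "x", object@landscapeLength,
      "demes; seed/window width", object@windowWidth, "\n")
  cat("  burn-in:", object@burnIn, "generations; run length",
      object@totalGenerations, "\n")
  if (object@mode == "shift")
    cat("  shift: one column every", object@T, "generations (v =",
        signif(1 / object@T, 3), ")\n")
})

#' Handle on a live individual-based simulation
#'
#' Wraps the external pointer to the compiled simulation state together
#' with the objects that parameterize it. Obtained from [simInit()] (or
#' [runBurnIn()]); advanced with [runGenerations()] / [simulateRange()];
#' inspected with [census()], [demeMeanFitness()], [demeFrequencies()] and
#' friends. The state is mutable: stepping functions advance it in place.
#'
#' @slot ptr External pointer to the engine state.
#' @slot loci Locus table (data frame with columns `locus_id`, `class`,
#'   `s`, `h`).
#' @slot model The [`MutationModel`][MutationModel-class].
#' @slot schedule The [`ScheduleSpec`][ScheduleSpec-class].
#' @slot config Named list of demographic parameters (K, m, R, selection,
#'   recombination, seed).
#' @slot generation Current generation (0 at initialization; burn-in
#'   generations count).
#' @slot wRef Reference fitness set at burn-in end (1 until then).
#' @export
setClass("RangeSim",
  representation(ptr = "externalptr", loci = "data.frame",
                 model = "MutationModel", schedule = "ScheduleSpec",
                 config = "list", generation = "integer", wRef = "numeric"))

setMethod("show", "RangeSim", function(object) {
  cen <- census(object)
  occ <- which(cen > 0)
  cat("RangeSim (", object@config$selection, " selection, ",
      object@config$recombination, " recombination)\n", sep = "")
  cat("  landscape:", object@schedule@landscapeWidth, "x",
      object@schedule@landscapeLength, "| generation",
      object@generation, "\n")
  cat("  loci:", sum(object@loci$class != "neutral"), "selected +",
      sum(object@loci$class == "neutral"), "neutral\n")
  if (length(occ))
    cat("  occupied demes:", length(occ), "| total census:", sum(cen),
        "| columns", min(colOf(object, occ)), "-",
        max(colOf(object, occ)), "\n")
  else cat("  extinct\n")
  cat("  reference fitness:", signif(object@wRef, 6), "\n")
})

# column (1-based) of a deme index within the grid
colOf <- function(sim, demeIdx) {
  ((demeIdx - 1L) %/% sim@schedule@landscapeWidth) + 1L
}
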