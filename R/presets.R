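#' Experiment presets
#'
#' Named parameter sets reproducing the package's headline experiments at
#' reduced scale: each preset bundles one or more run configurations
#' together with the scale factors relative to the full-size study
#' (landscape length, replicate count, recording cadence). Pass
#' `fullScale = TRUE` for the full-size parameters.
#'
#' Available presets:
#' \describe{
#'   \item{`fig1_soft`}{Soft-selection expansion and shifts at
#'     `v = 0.2, 0.05, 0.02`, additive and recessive.}
#'   \item{`fig2_sweep`}{Soft-selection additive shifts over the 8-speed
#'     grid used for the loss-per-deme decomposition.}
#'   \item{`fig3_hard`}{Hard-selection expansion and shifts (extinction
#'     scenarios).}
#'   \item{`fig4_dfe`}{Expansion under partial dominance, exponential DFE
#'     and the h-s trade-off.}
#'   \item{`s9_norecomb`}{No-recombination soft shifts (post-crossing
#'     decline).}
#'   \item{`s4_neutral`}{Shifts and expansion with 1000 neutral loci
#'     (diversity tracking).}
#'   \item{`s5_2d`}{2-D (5-row) soft landscapes.}
#'   \item{`s11_equilibrium`}{Hard-selection slow shifts bracketing the
#'     zero-load speed.}
#' }
#'
#' @param name Preset name.
#' @param fullScale Use full-size landscape/replicates (default `FALSE`:
#'   landscape 100 demes, 3 replicates, records every 20 generations).
#' @return List with `configs` (named list of configuration lists),
#'   `nReps`, and `scale` (human-readable scale note).
#' @examples
#' p <- presetConfigs("fig2_sweep")
#' names(p$configs)
#' @export
presetConfigs <- function(name = c("fig1_soft", "fig2_sweep", "fig3_hard",
                                   "fig4_dfe", "s9_norecomb", "s4_neutral",
                                   "s5_2d", "s11_equilibrium"),
                          fullScale = FALSE) {
  name <- match.arg(name)
  base <- defaultConfig()
  if (!fullScale) {
    base$landscapeLength <- 100
    base$recordEvery <- 20
  }
  nReps <- if (fullScale) 10 else 3
  shift <- function(cfg, T) { cfg$mode <- "shift"; cfg$T <- T; cfg }
  recess <- function(cfg) { cfg$h <- 0; cfg }
  hard <- function(cfg) { cfg$selection <- "hard"; cfg }
  cfgs <- switch(name,
    fig1_soft = {
      e <- base
      list(expansion_additive = e,
           expansion_recessive = recess(e),
           shift_v0.2_additive = shift(e, 5),
           shift_v0.2_recessive = recess(shift(e, 5)),
           shift_v0.05_additive = shift(e, 20),
           shift_v0.02_additive = shift(e, 50))
    },
    fig2_sweep = {
      sp <- c(5, 10, 15, 20, 25, 30, 40, 50)
      out <- lapply(sp, function(T) shift(base, T))
      names(out) <- paste0("shift_T", sp)
      out
    },
    fig3_hard = {
      e <- hard(base)
      list(expansion_additive = e,
           expansion_recessive = recess(e),
           shift_v0.2 = shift(e, 5),
           shift_v0.05 = shift(e, 20),
           shift_v0.02 = shift(e, 50))
    },
    fig4_dfe = {
      partial <- base; partial$h <- 0.3
      expo <- partial; expo$dfe <- "exponential"
      trade <- expo; trade$dominance <- "hs_tradeoff"
      list(expansion_h0.3 = partial,
           expansion_h0.3_expDFE = expo,
           expansion_hsTradeoff_expDFE = trade,
           shift_v0.1_h0.3_expDFE = shift(expo, 10))
    },
    s9_norecomb = {
      nr <- base; nr$recombination <- "none"
      list(shift_v0.2_norecomb = shift(nr, 5),
           shift_v0.2_free = shift(base, 5))
    },
    s4_neutral = {
      neu <- base; neu$nNeutral <- 1000
      list(expansion_neutral = neu,
           shift_v0.2_neutral = shift(neu, 5),
           shift_v0.05_neutral = shift(neu, 20))
    },
    s5_2d = {
      td <- base; td$landscapeWidth <- 5; td$K <- 20
      list(expansion_2d = td, shift_v0.2_2d = shift(td, 5))
    },
    s11_equilibrium = {
      e <- hard(base)
      out <- lapply(c(40, 50, 60, 70, 84), function(T) shift(e, T))
      names(out) <- paste0("shift_T", c(40, 50, 60, 70, 84))
      out
    })
  list(configs = cfgs, nReps = nReps,
       scale = if (fullScale) "full scale (300-deme landscape, 10 replicates)"
               else "reduced scale (100-deme landscape, 3 replicates, records every 20 generations)")
}

#' Run a preset end to end
#'
#' Executes every configuration of a preset with [runReplicates()].
#'
#' @inheritParams presetConfigs
#' @param baseSeed Seed from which all replicate seeds derive.
#' @param nReps Override the preset's replicate count.
#' @return Named list of [runReplicates()] results, with attribute
#'   `"scale"`.
#' @export
reproducePreset <- function(name, baseSeed = 1, nReps = NULL,
                            fullScale = FALSE) {
  p <- presetConfigs(name, fullScale)
  if (is.null(nReps)) nReps <- p$nReps
  out <- lapply(p$configs, runReplicates, nReps = nReps,
                baseSeed = baseSeed)
  attr(out, "scale") <- p$scale
  out
}
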