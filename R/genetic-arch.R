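#' Dominance coefficient under the h-s trade-off
#'
#' Dominance of a deleterious mutation as a function of its selection
#' coefficient, `h = 1 / (1/thetaI - s*thetaR)`: `h` equals `thetaI` for
#' nearly neutral mutations and approaches 0 (complete recessivity) as
#' mutations become strongly deleterious.
#'
#' @param s Selection coefficient, `s <= 0` (deleterious loci only;
#'   beneficial loci keep a constant `h = 0.5`).
#' @param thetaI Intercept: value of `h` at `s = 0`. In `(0, 1]`.
#' @param thetaR Rate at which `h` decays with `|s|`. Nonnegative.
#' @return Dominance coefficient in `(0, thetaI]`.
#' @examples
#' dominanceOf(0)                 # 0.5
#' dominanceOf(-0.005)            # 1/14.5 ~ 0.069
#' dominanceOf(-1, thetaR = 2500) # essentially recessive
#' @export
dominanceOf <- function(s, thetaI = 0.5, thetaR = 2500) {
  stopifnot(thetaI > 0, thetaI <= 1, thetaR >= 0)
  if (any(s > 0))
    stop("dominanceOf applies to deleterious loci only (s <= 0)")
  1 / (1 / thetaI - s * thetaR)
}

#' Build the locus table
#'
#' Assigns class, selection coefficient and dominance coefficient to every
#' locus of the genome: `nDel` deleterious and `nBen` beneficial selected
#' loci, plus optional neutral loci (`s = 0`). Under the constant-effect
#' model every selected locus has `|s| = meanS`; under the exponential DFE,
#' per-locus effects are drawn once here (mean magnitude `meanS`, mirrored
#' between the classes) and stay fixed for the whole run — loci are
#' bi-allelic, so the effect is a property of the locus, not of the
#' mutation event.
#'
#' @param nDel Number of deleterious loci (default 900).
#' @param nBen Number of beneficial loci (default 100).
#' @param nNeutral Number of neutral loci (default 0).
#' @param model A [`MutationModel`][MutationModel-class].
#' @param seed Integer seed for the DFE draws (only used when the DFE is
#'   exponential).
#' @return Data frame with columns `locus_id` (0-based), `class`
#'   (`"deleterious"`, `"beneficial"`, `"neutral"`), `s`, `h`.
#' @examples
#' loci <- buildLocusTable()
#' table(loci$class)
#' range(loci$s)
#' @export
buildLocusTable <- function(nDel = 900, nBen = 100, nNeutral = 0,
                            model = mutationModel(), seed = NULL) {
  if (nDel < 0 || nBen < 0 || nNeutral < 0)
    stop("locus counts must be nonnegative")
  validObject(model)
  n <- nDel + nBen + nNeutral
  if (n == 0) stop("at least one locus is required")
  cls <- rep(c("deleterious", "beneficial", "neutral"),
             c(nDel, nBen, nNeutral))
  if (model@dfe == "constant") {
    s <- rep(c(-model@meanS, model@meanS, 0), c(nDel, nBen, nNeutral))
  } else {
    if (!is.null(seed)) set.seed(seed)
    s <- c(-stats::rexp(nDel, rate = 1 / model@meanS),
           stats::rexp(nBen, rate = 1 / model@meanS),
           rep(0, nNeutral))
  }
  h <- rep(0.5, n)
  if (model@dominance == "constant") {
    h[cls == "deleterious"] <- model@h
    # the constant-h main models (additive/recessive) apply h genome-wide;
    # under the exponential DFE beneficials stay additive (h = 0.5)
    h[cls == "beneficial"] <- if (model@dfe == "constant") model@h else 0.5
  } else {
    h[cls == "deleterious"] <- dominanceOf(s[cls == "deleterious"],
                                           model@thetaI, model@thetaR)
  }
  data.frame(locus_id = seq_len(n) - 1L, class = cls, s = s, h = h)
}

#' Write / read a locus table as TSV
#'
#' @param loci Locus table from [buildLocusTable()].
#' @param path File path.
#' @return `readLocusTable` returns the locus table data frame;
#'   `writeLocusTable` returns `path` invisibly.
#' @export
writeLocusTable <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocusTable
#' @export
readLocusTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# smallest multiplicative factor a locus may contribute; keeps fitness
# positive under extreme exponential-DFE draws
.fitnessFloor <- 1e-6

#' Multiplicative fitness of one individual
#'
#' Fitness is the product over selected loci of 1 (ancestral homozygote),
#' `1 + h*s` (heterozygote) or `1 + s` (derived homozygote); neutral loci
#' contribute factor 1. Per-locus factors are floored at `1e-6` so fitness
#' stays positive even under extreme DFE draws.
#'
#' This is the reference (pure R) implementation used to validate the
#' compiled engine; it operates on one explicit genotype.
#'
#' @param genotype Integer matrix `2 x L` of 0/1 alleles (rows =
#'   haplotypes).
#' @param loci Locus table with `L` rows.
#' @return Relative fitness (positive scalar).
#' @examples
#' loci <- buildLocusTable(2, 1, 0)
#' g <- matrix(0L, 2, 3)
#' individualFitness(g, loci)          # 1
#' g[1, 1] <- 1L
#' individualFitness(g, loci)          # 1 + h*s = 0.9975
#' @export
individualFitness <- function(genotype, loci) {
  stopifnot(is.matrix(genotype), nrow(genotype) == 2,
            ncol(genotype) == nrow(loci), all(genotype %in% c(0L, 1L)))
  sel <- loci$class != "neutral"
  cnt <- genotype[1, sel] + genotype[2, sel]
  f <- ifelse(cnt == 2L, 1 + loci$s[sel],
              ifelse(cnt == 1L, 1 + loci$h[sel] * loci$s[sel], 1))
  prod(pmax(f, .fitnessFloor))
}

#' Draw one gamete from a parental genotype
#'
#' Under free recombination each locus inherits independently from either
#' parental haplotype with probability 1/2; with no recombination one of
#' the two haplotypes is transmitted intact (fair coin).
#'
#' @param genotype Integer matrix `2 x L` (rows = haplotypes).
#' @param regime `"free"` or `"none"`.
#' @return Integer vector of length `L`: the transmitted haplotype.
#' @examples
#' g <- rbind(rep(1L, 4), rep(0L, 4))
#' set.seed(1); makeGamete(g, "free")
#' makeGamete(g, "none")   # one of the two rows, intact
#' @export
makeGamete <- function(genotype, regime = c("free", "none")) {
  regime <- match.arg(regime)
  stopifnot(is.matrix(genotype), nrow(genotype) == 2)
  L <- ncol(genotype)
  if (regime == "free") {
    pick <- stats::runif(L) < 0.5
    ifelse(pick, genotype[1, ], genotype[2, ])
  } else {
    genotype[1 + (stats::runif(1) < 0.5), ]
  }
}

#' Mutate a block of genotypes
#'
#' Applies one generation of mutation to an array of diploid genotypes.
#' Each individual receives a Poisson(`U`) number of mutation events at
#' uniformly chosen (haplotype, selected locus) positions; an event landing
#' on an already-derived copy is a silent no-op (no back-mutation). With
#' `suppressBeneficial = TRUE` (the burn-in convention) events landing on
#' beneficial loci are discarded. Neutral loci mutate independently at
#' `model@neutralRate` per copy.
#'
#' Reference (pure R) implementation mirroring the compiled engine's
#' mutation step.
#'
#' @param block Integer array `n x 2 x L` of 0/1 alleles.
#' @param loci Locus table with `L` rows.
#' @param model A [`MutationModel`][MutationModel-class].
#' @param suppressBeneficial Discard events at beneficial loci (default
#'   `FALSE`).
#' @return The mutated array, with attribute `"events"` = number of drawn
#'   events at selected loci (including no-ops and suppressed draws).
#' @export
mutateBlock <- function(block, loci, model, suppressBeneficial = FALSE) {
  stopifnot(length(dim(block)) == 3, dim(block)[2] == 2,
            dim(block)[3] == nrow(loci))
  validObject(model)
  n <- dim(block)[1]
  selIdx <- which(loci$class != "neutral")
  neuIdx <- which(loci$class == "neutral")
  benSet <- loci$class == "beneficial"
  totalEvents <- 0L
  for (i in seq_len(n)) {
    k <- stats::rpois(1, model@U)
    totalEvents <- totalEvents + k
    if (k > 0 && length(selIdx)) {
      locs <- selIdx[sample.int(length(selIdx), k, replace = TRUE)]
      haps <- sample.int(2, k, replace = TRUE)
      for (j in seq_len(k)) {
        if (suppressBeneficial && benSet[locs[j]]) next
        block[i, haps[j], locs[j]] <- 1L   # no-op if already derived
      }
    }
    if (length(neuIdx) && model@neutralRate > 0) {
      kn <- stats::rpois(1, 2 * length(neuIdx) * model@neutralRate)
      if (kn > 0) {
        locs <- neuIdx[sample.int(length(neuIdx), kn, replace = TRUE)]
        haps <- sample.int(2, kn, replace = TRUE)
        for (j in seq_len(kn)) block[i, haps[j], locs[j]] <- 1L
      }
    }
  }
  attr(block, "events") <- totalEvents
  block
}
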