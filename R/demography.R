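#' Logistic growth expectation
#'
#' Expected next census under the Beverton-Holt style discrete logistic
#' map `N' = N*R / (1 + N*(R-1)/K)`, whose fixed point is `N = K` and whose
#' small-`N` growth factor is `R` (`log R` is the intrinsic growth rate).
#'
#' @param N Current census (nonnegative; may be real-valued).
#' @param R Growth parameter (`R > 1` for net growth; values in `(0, 1]`
#'   arise under hard selection when fitness is low and give decline).
#' @param K Carrying capacity, `K > 0`.
#' @return Expected census next generation (real).
#' @examples
#' logisticExpectation(100, 2, 100)  # 100: fixed point
#' logisticExpectation(50, 2, 100)   # 66.67
#' @export
logisticExpectation <- function(N, R, K) {
  if (any(K <= 0)) stop("carrying capacity K must be positive")
  stopifnot(all(N >= 0), all(R > 0))
  N * R / (1 + N * (R - 1) / K)
}

#' Fitness-dependent growth parameters
#'
#' Under soft selection the demographic parameters are constants; under
#' hard selection both the carrying capacity and the intrinsic growth rate
#' scale with relative mean fitness: `K_eff = K * w` and
#' `log R_eff = w * log R`. The proportionality constant is fixed by
#' `w = 1` at the end of the burn-in (fitness is re-referenced there), so
#' a full-fitness deme behaves identically under both modes.
#'
#' @param wbar Relative mean fitness of the deme (> 0; a deme with
#'   `wbar <= 0` is treated as extinct by the engine).
#' @param mode `"soft"` or `"hard"`.
#' @param R Growth parameter.
#' @param K Carrying capacity.
#' @return Named list with `R` and `K` effective values.
#' @examples
#' effectiveGrowthParams(0.5, "hard", 2, 100)  # K 50, R sqrt(2)
#' effectiveGrowthParams(0.5, "soft", 2, 100)  # unchanged
#' @export
effectiveGrowthParams <- function(wbar, mode = c("soft", "hard"),
                                  R = 2, K = 100) {
  mode <- match.arg(mode)
  stopifnot(wbar > 0)
  if (mode == "soft") list(R = R, K = K)
  else list(R = exp(wbar * log(R)), K = K * wbar)
}

#' Reference implementation of within-deme reproduction
#'
#' Pure R mirror of the engine's reproduction step, for validation on
#' small examples: the offspring number is Poisson with mean
#' [logisticExpectation()] under the mode's effective parameters, each
#' offspring samples two parents independently with replacement with
#' probability proportional to fitness (selfing allowed, monoecious), and
#' each parent contributes one gamete via [makeGamete()].
#'
#' @param block Integer array `n x 2 x L`: the adults' genotypes.
#' @param fitness Numeric vector of the adults' fitness values.
#' @param mode `"soft"` or `"hard"`.
#' @param R,K Demographic parameters.
#' @param wRef Reference fitness dividing absolute fitness under hard
#'   selection.
#' @param regime Recombination regime, `"free"` or `"none"`.
#' @return Offspring array `nOff x 2 x L` with attribute `"parents"`
#'   (`nOff x 2` matrix of parent indices).
#' @export
reproduceDeme <- function(block, fitness, mode = c("soft", "hard"),
                          R = 2, K = 100, wRef = 1,
                          regime = c("free", "none")) {
  mode <- match.arg(mode); regime <- match.arg(regime)
  n <- dim(block)[1]; L <- dim(block)[3]
  stopifnot(n >= 1, length(fitness) == n, all(fitness > 0))
  wbar <- mean(fitness) / wRef
  gp <- effectiveGrowthParams(wbar, mode, R, K)
  nOff <- stats::rpois(1, logisticExpectation(n, gp$R, gp$K))
  off <- array(0L, c(nOff, 2, L))
  parents <- matrix(0L, nOff, 2)
  if (nOff > 0) {
    for (i in seq_len(nOff)) {
      p <- sample.int(n, 2, replace = TRUE, prob = fitness)
      parents[i, ] <- p
      off[i, 1, ] <- makeGamete(block[p[1], , , drop = TRUE], regime)
      off[i, 2, ] <- makeGamete(block[p[2], , , drop = TRUE], regime)
    }
  }
  attr(off, "parents") <- parents
  off
}
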