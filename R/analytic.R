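#' Founders per colonization step
#'
#' Number of effective founders of a newly colonized deme at an expanding
#' front, approximated as half the migrant pool of a single saturated
#' neighbouring deme: `F = K * m / 2`.
#'
#' @param K Deme carrying capacity (diploid individuals).
#' @param m Per-generation emigration probability.
#' @return Real-valued founder number `F`.
#' @examples
#' foundersPerStep(100, 0.1)  # 5
#' @export
foundersPerStep <- function(K, m) {
  stopifnot(is.numeric(K), K > 0, is.numeric(m), m >= 0, m <= 1)
  if (m == 0)
    warning("m = 0 gives F = 0; downstream fixation probabilities are undefined")
  K * m / 2
}

#' Parameters of the analytic front-fitness model
#'
#' Bundles everything the serial-founder-event approximation needs: effect
#' sizes of the two selected locus classes, the fraction of mutations that
#' are deleterious, genome-wide mutation rate, and the demographic
#' quantities determining drift at the front.
#'
#' The initial frequency of a mutation present at the front is `p0 = 1/(2F)`
#' (one copy among the founders' `2F` gene copies), and the model starts at
#' relative front fitness `w0 = 1`.
#'
#' @param sDel Selection coefficient of deleterious mutations (negative).
#' @param sBen Selection coefficient of beneficial mutations (positive).
#' @param phi Fraction of selected loci whose mutations are deleterious.
#' @param U Genome-wide mutation rate per diploid individual per generation.
#' @param K Deme carrying capacity.
#' @param m Migration rate.
#' @return A list of class `"analyticParams"` with elements `sDel`, `sBen`,
#'   `phi`, `U`, `K`, `m`, `F`, `p0`, `w0`.
#' @examples
#' p <- analyticParams()
#' p$F   # 5
#' p$p0  # 0.1
#' @export
analyticParams <- function(sDel = -0.005, sBen = 0.005, phi = 0.9,
                           U = 0.1, K = 100, m = 0.1) {
  stopifnot(sDel < 0, sBen > 0, phi >= 0, phi <= 1, U >= 0, K > 0,
            m > 0, m <= 1)
  Ff <- foundersPerStep(K, m)
  structure(
    list(sDel = sDel, sBen = sBen, phi = phi, U = U, K = K, m = m,
         F = Ff, p0 = 1 / (2 * Ff), w0 = 1),
    class = "analyticParams")
}

#' Diffusion fixation probability after a founder event
#'
#' Probability that a mutation of effect `s`, present at frequency `p0` at
#' the front, fixes through the serial founder process. Selection acts for
#' `T` generations between colonization events, after which drift samples
#' `F` founders; the compound process behaves like a haploid population of
#' `2F` gene copies with compounded selection intensity `s*T`:
#' `p = (1 - exp(-2*F*s*T*p0)) / (1 - exp(-2*F*s*T))`.
#'
#' Continuous at `s = 0` where it equals `p0` (the neutral limit).
#'
#' @param s Selection coefficient (either sign).
#' @param T Generations between consecutive colonization events.
#' @param F Founders per colonization step.
#' @param p0 Initial allele frequency at the front.
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' fixationProb(-0.005, T = 20, F = 5, p0 = 0.1)
#' fixationProb(0, T = 20, F = 5, p0 = 0.1)  # neutral: p0
#' @export
fixationProb <- function(s, T, F, p0) {
  stopifnot(F > 0, T > 0, p0 > 0, p0 <= 1)
  a <- 2 * F * s * T
  # expm1 keeps the ratio accurate for small |a|; the a = 0 limit is p0
  p <- ifelse(abs(a) < 1e-12, p0, expm1(-a * p0) / expm1(-a))
  pmin(pmax(p, 0), 1)
}

# Per-class mutational input and fixation probabilities for one colonization
# step of duration T. Mutation copies of class c arising at the front while
# a deme is being colonized: n_c = K * T * u_c, with u_c the per-haploid-
# genome rate (U/2 split by class).
.stepComponents <- function(T, params) {
  uDel <- params$phi * params$U / 2
  uBen <- (1 - params$phi) * params$U / 2
  list(
    nDel = params$K * T * uDel,
    nBen = params$K * T * uBen,
    pDel = fixationProb(params$sDel, T, params$F, params$p0),
    pBen = fixationProb(params$sBen, T, params$F, params$p0))
}

#' Expected fitness change per colonization step (per deme travelled)
#'
#' The expected log-fitness change accumulated while the front advances one
#' deme, summing over the deleterious and beneficial mutation classes the
#' product of mutational input and fixation probability, weighted by effect:
#' `delta = sum_c n_c * s_c * p(s_c*T, F, p0)` with `n_c = K*T*u_c`.
#'
#' With `effectWeighted = FALSE` the literal unweighted sum
#' `sum_c n_c * p_c` is returned instead (each fixation counted once,
#' regardless of effect); this variant does not reproduce the closed-form
#' critical speed and is kept for comparison only.
#'
#' @param v Shift speed in demes per generation (`T = 1/v`).
#' @param params An [analyticParams()] list.
#' @param effectWeighted Weight fixations by their selection coefficient
#'   (default `TRUE`).
#' @return Expected change in log mean front fitness per deme travelled
#'   (negative = loss).
#' @examples
#' perDemeFitnessChange(0.05, analyticParams())
#' @export
perDemeFitnessChange <- function(v, params = analyticParams(),
                                 effectWeighted = TRUE) {
  stopifnot(v > 0, v <= 1)
  T <- 1 / v
  cc <- .stepComponents(T, params)
  if (effectWeighted)
    cc$nDel * params$sDel * cc$pDel + cc$nBen * params$sBen * cc$pBen
  else
    cc$nDel * cc$pDel + cc$nBen * cc$pBen
}

#' One step of the front-fitness recursion
#'
#' Multiplies current relative front fitness by `(1 + delta)` where `delta`
#' is the expected per-colonization-step change from
#' [perDemeFitnessChange()]. Iterating this recursion gives the analytic
#' trajectory of mean fitness at the front of a shift (or of an expansion,
#' with `T` matched to the realized expansion speed).
#'
#' @param w Current relative mean front fitness (> 0).
#' @param params An [analyticParams()] list.
#' @param T Generations per colonization step.
#' @return Front fitness after one colonization step.
#' @export
frontFitnessStep <- function(w, params = analyticParams(), T) {
  stopifnot(w > 0, T > 0)
  delta <- perDemeFitnessChange(1 / T, params)
  if (abs(delta) >= 1)
    warning("|delta| >= 1: parameters outside the approximation's validity")
  w * (1 + delta)
}

#' Analytic trajectory of mean front fitness
#'
#' Iterates [frontFitnessStep()] over `nSteps` colonization events, starting
#' from `params$w0`.
#'
#' @param params An [analyticParams()] list.
#' @param T Generations per colonization step (for expansions use the
#'   observed mean colonization interval, `T = 3.9` at default parameters).
#' @param nSteps Number of colonization steps (demes travelled).
#' @return Data frame with columns `step`, `generation`, `fitness`.
#' @examples
#' tr <- frontFitnessTrajectory(analyticParams(), T = 3.9, nSteps = 50)
#' tail(tr, 1)
#' @export
frontFitnessTrajectory <- function(params = analyticParams(), T, nSteps) {
  stopifnot(nSteps >= 1)
  delta <- perDemeFitnessChange(1 / T, params)
  w <- params$w0 * cumprod(rep(1 + delta, nSteps))
  data.frame(step = seq_len(nSteps),
             generation = T * seq_len(nSteps),
             fitness = w)
}

#' Closed-form critical shift speed
#'
#' Speed maximising expected fitness loss per deme travelled, from the
#' small-`sT` expansion of the per-deme change:
#' `v* = s * (2F - 1) / (2*phi - 1)`.
#' At the default parameters (`s = 0.005`, `F = 5`, `phi = 0.9`) this is
#' 0.05625 demes per generation.
#'
#' @param s Magnitude of the selection coefficient (positive).
#' @param F Founders per colonization step.
#' @param phi Fraction of mutations that are deleterious; must exceed 0.5.
#' @return Critical speed in demes per generation.
#' @examples
#' criticalSpeedClosedForm(0.005, 5, 0.9)
#' @export
criticalSpeedClosedForm <- function(s, F, phi) {
  stopifnot(s > 0, F > 0)
  if (phi <= 0.5)
    stop("phi must exceed 0.5: with phi <= 0.5 loss per deme has no interior maximum")
  s * (2 * F - 1) / (2 * phi - 1)
}

#' Shift speed at which expected load accumulation vanishes
#'
#' Solves `perDemeFitnessChange(v) = 0` for `v`: below this speed the front
#' gains fitness per deme (beneficial fixations outweigh deleterious ones),
#' above it the front loses fitness. The root is bracketed on `interval`
#' and solved to relative tolerance `tol`.
#'
#' @param params An [analyticParams()] list.
#' @param interval Speed interval to search (demes per generation).
#' @param tol Relative tolerance of the root.
#' @return Zero-load speed in demes per generation.
#' @examples
#' zeroLoadSpeed(analyticParams())  # ~0.021
#' @export
zeroLoadSpeed <- function(params = analyticParams(),
                          interval = c(1e-3, 0.3), tol = 1e-6) {
  f <- function(v) perDemeFitnessChange(v, params)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi))
    stop(sprintf(
      "no sign change of the per-deme fitness change on [%g, %g]; cannot bracket a zero-load speed",
      interval[1], interval[2]))
  stats::uniroot(f, interval, tol = tol * mean(interval))$root
}

#' Numerical critical speed
#'
#' Speed maximising the magnitude of expected fitness loss per deme,
#' found by bracketed scalar optimisation (the closed form
#' [criticalSpeedClosedForm()] is its small-`sT` approximation).
#'
#' @param params An [analyticParams()] list.
#' @param interval Speed interval to search.
#' @return Speed of maximal per-deme loss.
#' @export
criticalSpeedNumeric <- function(params = analyticParams(),
                                 interval = c(1e-3, 0.3)) {
  stats::optimize(function(v) perDemeFitnessChange(v, params),
                  interval, tol = 1e-8)$minimum
}

#' Analytic decomposition of fitness loss over a speed grid
#'
#' Tabulates, for each shift speed, the per-deme and per-generation expected
#' log-fitness change together with its components: mutational input and
#' fixation probability for the deleterious and beneficial classes.
#'
#' @param params An [analyticParams()] list.
#' @param speeds Numeric vector of shift speeds (demes per generation).
#' @return Data frame with columns `v`, `T`, `deltaPerDeme`,
#'   `deltaPerGeneration`, `nDel`, `nBen`, `pDel`, `pBen`.
#' @examples
#' analyticSpeedTable(speeds = c(0.2, 0.05, 0.02))
#' @export
analyticSpeedTable <- function(params = analyticParams(),
                               speeds = c(0.2, 0.1, 0.066, 0.05, 0.04,
                                          0.033, 0.025, 0.02)) {
  stopifnot(all(speeds > 0), all(speeds <= 1))
  rows <- lapply(speeds, function(v) {
    T <- 1 / v
    cc <- .stepComponents(T, params)
    d <- cc$nDel * params$sDel * cc$pDel + cc$nBen * params$sBen * cc$pBen
    data.frame(v = v, T = T, deltaPerDeme = d, deltaPerGeneration = d * v,
               nDel = cc$nDel, nBen = cc$nBen, pDel = cc$pDel, pBen = cc$pBen)
  })
  do.call(rbind, rows)
}

#' Analytic hard-selection front dynamics during a range shift
#'
#' Couples the front-fitness recursion with front census dynamics under
#' hard selection. Between colonization events the front deme grows
#' logistically with fitness-scaled parameters (`K_eff = K * w`,
#' `R_eff = w * R`); every `T = 1/v` generations the new front deme
#' is founded by `F` individuals and expected front fitness declines by one
#' colonization step. Extinction is declared when the front census at a
#' colonization epoch falls below `F`: the population can no longer supply
#' founders at the pace of the moving habitat.
#'
#' The per-step fitness decrement uses mutational input scaled to the
#' founder group (`2F` gene copies) rather than the whole deme, which
#' places the loss rate on the scale realized by individual-based runs;
#' see the methods vignette for the convention choice.
#'
#' @param params An [analyticParams()] list.
#' @param v Shift speed (demes per generation).
#' @param R Growth parameter (`log R` is the intrinsic growth rate).
#' @param maxGenerations Horizon of the recursion.
#' @return A list with `trajectory` (data frame: `generation`, `fitness`,
#'   `frontCensus`) and `extinctionGeneration` (`NA` if no extinction
#'   within the horizon).
#' @examples
#' out <- hardSelectionTrajectory(v = 0.2)
#' out$extinctionGeneration
#' @export
hardSelectionTrajectory <- function(params = analyticParams(), v,
                                    R = 2, maxGenerations = 20000) {
  stopifnot(v > 0, v <= 1, R > 1)
  T <- max(1L, as.integer(round(1 / v)))
  # mutational input scaled to the founder group (2F = K*m copies) rather
  # than the whole deme: this puts the loss rate on the scale observed in
  # individual-based runs, which is what the census recursion needs
  delta <- perDemeFitnessChange(1 / T, params) * (2 * params$F / params$K)
  w <- params$w0
  N <- params$F           # a freshly founded front deme
  gens <- integer(maxGenerations); fits <- numeric(maxGenerations)
  cens <- numeric(maxGenerations)
  ext <- NA_integer_
  g <- 0L
  while (g < maxGenerations) {
    for (i in seq_len(T)) {
      g <- g + 1L
      Keff <- params$K * w
      Reff <- w * R          # growth parameter proportional to fitness
      N <- logisticExpectation(N, Reff, Keff)
      gens[g] <- g; fits[g] <- w; cens[g] <- N
    }
    if (N < params$F) { ext <- g; break }
    # colonization: F founders seed the next front deme, fitness steps down
    N <- params$F
    w <- w * (1 + delta)
    if (w <= 0) { ext <- g; break }
  }
  keep <- seq_len(g)
  list(trajectory = data.frame(generation = gens[keep], fitness = fits[keep],
                               frontCensus = cens[keep]),
       extinctionGeneration = ext)
}
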