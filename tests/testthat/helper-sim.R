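# Shared fixtures and small oracles used across test files.

# tiny locus table: nDel deleterious + nBen beneficial (+ neutral), additive
tinyLoci <- function(nDel = 2, nBen = 1, nNeutral = 0, h = 0.5) {
  buildLocusTable(nDel, nBen, nNeutral, mutationModel(h = h))
}

# random diploid genotype array (n x 2 x L) with derived-allele prob p
randomBlock <- function(n, L, p = 0.1) {
  array(as.integer(stats::runif(n * 2 * L) < p), c(n, 2, L))
}

# independent single-locus Wright-Fisher oracle with one-way mutation and
# genic selection on the heterozygous effect (additive approximation):
# returns final frequencies of `nLoci` independent loci after `gens`
# generations in a population of N diploids
wfMutSelOracle <- function(nLoci, gens, N, u, hs) {
  q <- numeric(nLoci)
  for (g in seq_len(gens)) {
    q <- q + (1 - q) * u                       # one-way mutation
    q <- q * (1 + hs) / (1 + q * hs)           # genic selection
    q <- stats::rbinom(nLoci, 2 * N, q) / (2 * N)
  }
  q
}

# diploid Wright-Fisher fixation oracle: F diploids (2F gene copies),
# additive genotype fitnesses 1, 1+c/2, 1+c with compound coefficient c,
# initial count round(2F*p0); returns the fraction of `reps` replicates
# fixing the allele
wfFixationOracle <- function(reps, F, c, p0) {
  n <- 2 * F
  fixed <- 0L
  for (r in seq_len(reps)) {
    k <- round(n * p0)
    while (k > 0L && k < n) {
      p <- k / n
      w1 <- 1 + c / 2; w2 <- 1 + c
      psel <- (p^2 * w2 + p * (1 - p) * w1) /
        (p^2 * w2 + 2 * p * (1 - p) * w1 + (1 - p)^2)
      k <- stats::rbinom(1, n, psel)
    }
    fixed <- fixed + (k == n)
  }
  fixed / reps
}

# a small burned-in simulation, cached per configuration across the test
# session (burn-ins dominate runtime; states are cloned before use)
.burnInCache <- new.env(parent = emptyenv())
cachedBurnIn <- function(key, builder) {
  if (is.null(.burnInCache[[key]])) .burnInCache[[key]] <- builder()
  .burnInCache[[key]]
}
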