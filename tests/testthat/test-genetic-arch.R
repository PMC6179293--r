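test_that("locus tables follow the configured architecture", {
  loci <- buildLocusTable()
  expect_equal(nrow(loci), 1000)
  expect_equal(sum(loci$class == "deleterious"), 900)
  expect_equal(sum(loci$class == "beneficial"), 100)
  expect_true(all(loci$s[loci$class == "deleterious"] == -0.005))
  expect_true(all(loci$s[loci$class == "beneficial"] == 0.005))
  expect_true(all(loci$h == 0.5))

  neu <- buildLocusTable(0, 0, 1000)
  expect_true(all(neu$s == 0))
  expect_true(all(neu$class == "neutral"))

  expect_error(buildLocusTable(-1, 0, 0), "nonnegative")
  expect_error(buildLocusTable(0, 0, 0), "at least one locus")
  expect_error(mutationModel(meanS = -0.1), "positive")
  expect_error(mutationModel(h = 1.5))
})

test_that("exponential DFE draws have the configured mean and fixed h rules", {
  m <- mutationModel(dfe = "exponential", h = 0.3)
  loci <- buildLocusTable(900, 100, 0, m, seed = 7)
  sDel <- loci$s[loci$class == "deleterious"]
  sBen <- loci$s[loci$class == "beneficial"]
  expect_true(all(sDel < 0) && all(sBen > 0))
  # law of large numbers: mean |s| within 4 standard errors of 0.005
  expect_lt(abs(mean(-sDel) - 0.005), 4 * 0.005 / sqrt(900))
  # beneficial loci stay additive under the exponential DFE
  expect_true(all(loci$h[loci$class == "beneficial"] == 0.5))
  expect_true(all(loci$h[loci$class == "deleterious"] == 0.3))
  # draws are reproducible per seed
  expect_identical(loci, buildLocusTable(900, 100, 0, m, seed = 7))
})

test_that("h-s trade-off dominance follows 1/(1/thetaI - s*thetaR)", {
  expect_equal(dominanceOf(0), 0.5)
  expect_equal(dominanceOf(-0.005), 1 / 14.5)
  expect_lt(dominanceOf(-1), 1e-3)
  expect_error(dominanceOf(0.01), "deleterious")
  # monotonically decreasing in |s|
  s <- -seq(0, 0.1, by = 0.001)
  expect_true(all(diff(dominanceOf(s)) < 0))
  # trade-off locus tables apply it per deleterious locus
  m <- mutationModel(dfe = "exponential", dominance = "hs_tradeoff")
  loci <- buildLocusTable(500, 50, 0, m, seed = 3)
  del <- loci$class == "deleterious"
  expect_equal(loci$h[del], dominanceOf(loci$s[del]))
  expect_true(all(loci$h[del] <= 0.5))
})

test_that("individual fitness is multiplicative over locus factors", {
  loci <- tinyLoci(2, 1)
  g <- matrix(0L, 2, 3)
  expect_equal(individualFitness(g, loci), 1)
  g[1, 1] <- 1L                       # het deleterious
  expect_equal(individualFitness(g, loci), 0.9975)
  g2 <- matrix(0L, 2, 3); g2[, 3] <- 1L   # hom beneficial
  expect_equal(individualFitness(g2, loci), 1.005)
  # neutral loci contribute nothing
  lociN <- buildLocusTable(1, 0, 2)
  gN <- matrix(c(0L, 0L, 1L, 1L, 1L, 1L), 2, 3)
  expect_equal(individualFitness(gN, lociN), 1)
  # random genotypes: product over explicit per-locus factors
  set.seed(9)
  lociR <- buildLocusTable(30, 10, 0, mutationModel(h = 0.3))
  for (rep in 1:5) {
    g <- matrix(as.integer(runif(80) < 0.3), 2, 40)
    cnt <- colSums(g)
    fac <- ifelse(cnt == 2, 1 + lociR$s,
                  ifelse(cnt == 1, 1 + lociR$h * lociR$s, 1))
    expect_equal(individualFitness(g, lociR), prod(fac))
  }
})

test_that("gametes follow the recombination regime", {
  g <- rbind(rep(1L, 40), rep(0L, 40))
  # without recombination the transmitted haplotype is intact
  for (i in 1:10) {
    gam <- makeGamete(g, "none")
    expect_true(all(gam == 1L) || all(gam == 0L))
  }
  # homozygous parent transmits its haplotype under both regimes
  hom <- rbind(rep(1L, 20), rep(1L, 20))
  expect_equal(makeGamete(hom, "free"), rep(1L, 20))
  expect_equal(makeGamete(hom, "none"), rep(1L, 20))
  # free recombination transmits each locus with probability 1/2
  set.seed(11)
  tot <- replicate(400, sum(makeGamete(g, "free")))
  frac <- mean(tot) / 40
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / (400 * 40)))
})

test_that("mutation is Poisson-distributed, unidirectional and suppressible", {
  loci <- buildLocusTable(9, 1, 0, mutationModel(U = 0.5))
  model <- mutationModel(U = 0.5)
  set.seed(21)
  block <- array(0L, c(2000, 2, 10))
  out <- mutateBlock(block, loci, model)
  ev <- attr(out, "events")
  # ~1000 events expected; 4 sigma band
  expect_lt(abs(ev - 1000), 4 * sqrt(1000))
  # U = 0: nothing happens
  out0 <- mutateBlock(block, loci, mutationModel(U = 0))
  expect_equal(sum(out0), 0)
  # no back-mutation: an all-derived block is left untouched
  full <- array(1L, c(50, 2, 10))
  outF <- mutateBlock(full, loci, model)
  expect_true(all(outF == 1L))
  # beneficial suppression leaves beneficial loci ancestral
  set.seed(22)
  outS <- mutateBlock(array(0L, c(2000, 2, 10)), loci, model,
                      suppressBeneficial = TRUE)
  expect_equal(sum(outS[, , loci$class == "beneficial"]), 0)
  expect_gt(sum(outS[, , loci$class == "deleterious"]), 0)
})

test_that("locus tables round-trip through TSV", {
  loci <- buildLocusTable(10, 5, 3, mutationModel(dfe = "exponential"),
                          seed = 1)
  path <- tempfile(fileext = ".tsv")
  writeLocusTable(loci, path)
  back <- readLocusTable(path)
  expect_equal(back$s, loci$s, tolerance = 1e-12)
  expect_equal(back$class, loci$class)
  expect_equal(back$locus_id, loci$locus_id)
})

test_that("engine fitness agrees with the R reference implementation", {
  for (h in c(0.5, 0)) {
    loci <- buildLocusTable(40, 10, 14, mutationModel(h = h))
    sched <- scheduleSpec("expansion", burnIn = 10, landscapeLength = 6,
                          windowWidth = 2, totalGenerations = 10)
    sim <- simInit(loci, mutationModel(h = h), sched, K = 20, seed = 5)
    set.seed(33)
    blk <- randomBlock(15, nrow(loci), p = 0.2)
    setDemeGenotypes(sim, 1, blk)
    engFit <- demeFitnessValues(sim, 1)
    refFit <- vapply(seq_len(15), function(i)
      individualFitness(blk[i, , , drop = TRUE] * 1L, loci), numeric(1))
    expect_equal(engFit, refFit, tolerance = 1e-12)
    # genotype extraction inverts injection
    expect_identical(getDemeGenotypes(sim, 1), blk)
  }
})
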