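test_that("logistic map has its fixed point and limits", {
  expect_equal(logisticExpectation(100, 2, 100), 100)
  expect_equal(logisticExpectation(50, 2, 100), 100 / 1.5)
  expect_equal(logisticExpectation(0.01, 2, 100), 0.02, tolerance = 1e-3)
  expect_error(logisticExpectation(10, 2, 0), "positive")
})

test_that("growth parameters scale with fitness only under hard selection", {
  expect_equal(effectiveGrowthParams(0.3, "soft"), list(R = 2, K = 100))
  expect_equal(effectiveGrowthParams(1, "hard"), list(R = 2, K = 100))
  hard <- effectiveGrowthParams(0.5, "hard", R = 2, K = 100)
  expect_equal(hard$K, 50)
  expect_equal(hard$R, sqrt(2))
  expect_error(effectiveGrowthParams(0, "hard"))
})

test_that("reproduction samples parents proportionally to fitness", {
  set.seed(17)
  blk <- array(0L, c(2, 2, 4))
  blk[1, , ] <- 1L   # individual 1 carries derived alleles everywhere
  counts <- c(0, 0)
  for (rep in 1:300) {
    off <- reproduceDeme(blk, fitness = c(1, 0.5), R = 2, K = 50)
    par <- attr(off, "parents")
    counts <- counts + tabulate(par, 2)
  }
  frac1 <- counts[1] / sum(counts)
  se <- sqrt(2 / 3 * 1 / 3 / sum(counts))
  expect_lt(abs(frac1 - 2 / 3), 4 * se)
  # a single parent selfs every offspring
  off1 <- reproduceDeme(blk[1, , , drop = FALSE], fitness = 1, K = 10)
  if (dim(off1)[1] > 0)
    expect_true(all(attr(off1, "parents") == 1))
  # offspring count is Poisson around the logistic expectation
  set.seed(18)
  n <- replicate(400, dim(reproduceDeme(blk, fitness = c(1, 1),
                                        R = 2, K = 100))[1])
  lam <- logisticExpectation(2, 2, 100)
  expect_lt(abs(mean(n) - lam), 4 * sqrt(lam / 400))
})

test_that("migration conserves the census and splits evenly between sides", {
  loci <- tinyLoci(2, 1)
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 3,
                        windowWidth = 3, totalGenerations = 5)
  sim <- simInit(loci, mutationModel(U = 0), sched, K = 400, m = 0.3,
                 seed = 61)
  before <- sum(census(sim))
  # migration-only steps: the census is conserved exactly
  for (i in 1:5) shiftload:::eng_step(sim@ptr, FALSE, TRUE, FALSE, FALSE)
  expect_equal(sum(census(sim)), before)
  # one migration-only step from the middle deme spreads ~m/2 per side
  sim2 <- simInit(loci, mutationModel(U = 0), sched, K = 1000, m = 0.1,
                  seed = 62)
  # empty the outer demes so arrivals are attributable
  applyHabitability(sim2, c(FALSE, TRUE, FALSE))
  applyHabitability(sim2, c(TRUE, TRUE, TRUE))
  shiftload:::eng_step(sim2@ptr, FALSE, TRUE, FALSE, FALSE)
  cen <- columnCensus(sim2)
  expect_equal(sum(cen), 1000)
  for (side in cen[c(1, 3)])
    expect_lt(abs(side - 50), 4 * sqrt(1000 * 0.05 * 0.95))
  # m = 0: nothing moves
  sim3 <- simInit(loci, mutationModel(U = 0), sched, K = 100, m = 0,
                  seed = 63)
  shiftload:::eng_step(sim3@ptr, FALSE, TRUE, FALSE, FALSE)
  expect_equal(columnCensus(sim3), c(100L, 100L, 100L))
})

test_that("a closed neutral deme fluctuates around carrying capacity", {
  loci <- tinyLoci(2, 1)
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 1,
                        windowWidth = 1, totalGenerations = 5)
  sim <- simInit(loci, mutationModel(U = 0), sched, K = 100, m = 0,
                 seed = 71)
  cen <- replicate(300, shiftload:::eng_step(sim@ptr, FALSE, TRUE, TRUE, TRUE))
  expect_gt(min(cen), 50)
  expect_lt(abs(mean(cen) - 100), 5)
})

test_that("global extinction is a terminal reported state, not an error", {
  loci <- tinyLoci(2, 1)
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 2,
                        windowWidth = 2, totalGenerations = 5)
  sim <- simInit(loci, mutationModel(U = 0), sched, K = 50, seed = 81)
  applyHabitability(sim, c(FALSE, FALSE))   # cull everything
  tot <- shiftload:::eng_step(sim@ptr, FALSE, TRUE, TRUE, TRUE)
  expect_equal(tot, 0)
  expect_null(frontAndCore(sim))
})

test_that("a stationary hard-selection deme with moderate load persists", {
  # fitness frozen via U = 0 after injecting a uniform deleterious load:
  # every individual homozygous at 60 deleterious loci -> w ~ 0.74
  loci <- buildLocusTable(100, 0, 0, mutationModel(U = 0))
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 1,
                        windowWidth = 1, totalGenerations = 5)
  sim <- simInit(loci, mutationModel(U = 0), sched, K = 100, m = 0,
                 selection = "hard", seed = 91)
  blk <- array(0L, c(100, 2, 100))
  blk[, , 1:60] <- 1L
  setDemeGenotypes(sim, 1, blk)
  w <- demeFitnessValues(sim, 1)[1]
  expect_equal(w, 0.995^60, tolerance = 1e-10)
  for (i in 1:300) tot <- shiftload:::eng_step(sim@ptr, FALSE, FALSE, TRUE, FALSE)
  expect_gt(tot, 0)                      # still alive
  expect_gt(sum(census(sim)), 0.995^60 * 100 * 0.5)  # near K_eff
})

test_that("neutral heterozygosity decays like (1 - 1/(2N)) per generation", {
  loci <- buildLocusTable(1, 1, 500, mutationModel(U = 0, neutralRate = 0))
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 1,
                        windowWidth = 1, totalGenerations = 5)
  K <- 100; gens <- 150
  rates <- replicate(3, {
    sim <- simInit(loci, mutationModel(U = 0, neutralRate = 0), sched,
                   K = K, m = 0, seed = sample.int(1e6, 1))
    set.seed(101)
    blk <- randomBlock(K, nrow(loci), p = 0.5)
    setDemeGenotypes(sim, 1, blk)
    het <- numeric(gens)
    for (g in seq_len(gens)) {
      shiftload:::eng_step(sim@ptr, FALSE, FALSE, TRUE, FALSE)
      het[g] <- heterozygosity(sim, 1)
    }
    unname(coef(lm(log(het) ~ seq_len(gens)))[2])
  })
  expected <- log(1 - 1 / (2 * K))
  expect_lt(abs(mean(rates) - expected) / abs(expected), 0.25)
})
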