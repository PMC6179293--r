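test_that("front and core demes are identified with the census threshold", {
  loci <- tinyLoci(2, 1)
  shiftSched <- scheduleSpec("shift", T = 5, burnIn = 5,
                             landscapeLength = 20, totalGenerations = 10)
  sim <- simInit(loci, mutationModel(U = 0), shiftSched, K = 50, seed = 141)
  # seed region occupied: front = forward-most, core = rear-most occupied
  fc <- frontAndCore(sim)
  expect_equal(fc$front, 5)
  expect_equal(fc$core, 1)
  # a trickle of migrants ahead of the front does not move it ...
  applyHabitability(sim, c(rep(TRUE, 7), rep(FALSE, 13)))
  shiftload:::eng_seed_demes(sim@ptr, 5L, 3L)    # deme 6: 3 individuals
  expect_equal(frontAndCore(sim)$front, 5)
  # ... but a census above the threshold does
  shiftload:::eng_seed_demes(sim@ptr, 6L, 12L)   # deme 7: 12 individuals
  expect_equal(frontAndCore(sim)$front, 7)

  # expansions anchor the core at the seed region's forward edge
  expSched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 20,
                           totalGenerations = 10)
  sim2 <- simInit(loci, mutationModel(U = 0), expSched, K = 50, seed = 142)
  expect_equal(frontAndCore(sim2)$core, 5)
  # single occupied deme: front = core
  sim3 <- simInit(loci, mutationModel(U = 0),
                  scheduleSpec("shift", T = 5, burnIn = 5,
                               landscapeLength = 20, windowWidth = 1,
                               totalGenerations = 10), K = 50, seed = 143)
  fc3 <- frontAndCore(sim3)
  expect_equal(fc3$front, fc3$core)
})

test_that("fixation counts and heterozygosity match constructed states", {
  loci <- buildLocusTable(3, 2, 1000)
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 4,
                        windowWidth = 1, totalGenerations = 5)
  sim <- simInit(loci, mutationModel(), sched, K = 10, seed = 151)
  n <- 10
  blk <- array(0L, c(n, 2, nrow(loci)))
  blk[, , 1] <- 1L            # deleterious locus 1 fixed
  blk[, , 5] <- 1L            # beneficial locus 5 fixed
  blk[1:5, 1, 4] <- 1L        # beneficial locus 4 segregating
  blk[1:2, , 6] <- 1L         # neutral locus: p = 0.2
  setDemeGenotypes(sim, 1, blk)
  fx <- fixedCounts(sim, 1)
  expect_equal(unname(fx), c(1L, 1L))
  expect_equal(heterozygosity(sim, 1), 2 * 0.2 * 0.8 / 1000)
  # all-ancestral deme
  setDemeGenotypes(sim, 1, array(0L, c(n, 2, nrow(loci))))
  expect_equal(unname(fixedCounts(sim, 1)), c(0L, 0L))
  expect_equal(heterozygosity(sim, 1), 0)
  # p = 0.5 at every neutral locus gives the maximum 0.5
  blk2 <- array(0L, c(n, 2, nrow(loci)))
  blk2[, 1, 6:1005] <- 1L
  setDemeGenotypes(sim, 1, blk2)
  expect_equal(heterozygosity(sim, 1), 0.5)
  # heterozygosity requires neutral loci
  simNoNeu <- simInit(tinyLoci(2, 1), mutationModel(), sched, K = 10,
                      seed = 152)
  expect_error(heterozygosity(simNoNeu, 1), "neutral")
})

test_that("realized speed is the least-squares slope of the front index", {
  expect_equal(realizedSpeed(c(1, 1, 2, 2, 3), 1:5), 0.5, tolerance = 1e-9)
  front <- rep(1:10, each = 5)           # one deme per 5 generations
  expect_equal(realizedSpeed(front, seq_along(front)), 0.2,
               tolerance = 0.01)
  stalled <- realizedSpeed(rep(4, 20), 1:20)
  expect_equal(as.numeric(stalled), 0)
  expect_true(attr(stalled, "stalled"))
  # noisy synthetic series with known slope
  set.seed(161)
  gen <- 1:400
  noisy <- floor(0.25 * gen + rnorm(400, sd = 1))
  expect_lt(abs(realizedSpeed(noisy, gen) - 0.25), 0.01)
})

test_that("identical configurations and seeds give bit-identical runs", {
  cfg <- loadConfig(overrides = list(
    mode = "shift", T = 2, burnIn = 60, landscapeLength = 15,
    totalGenerations = 60, nDel = 45, nBen = 5, recordEvery = 10,
    K = 30, seed = 77))
  r1 <- runSimulation(cfg)
  r2 <- runSimulation(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$trace, r2$trace)
  cfg$seed <- 78
  r3 <- runSimulation(cfg)
  expect_false(identical(r1$trace, r3$trace))
})

test_that("replicate aggregation reports means with two standard errors", {
  cfg <- loadConfig(overrides = list(
    mode = "shift", T = 5, burnIn = 40, landscapeLength = 14,
    totalGenerations = 40, nDel = 18, nBen = 2, recordEvery = 10,
    K = 40))
  out <- runReplicates(cfg, nReps = 3, baseSeed = 5)
  expect_length(out$replicates, 3)
  agg <- out$aggregate
  expect_true(all(c("mean_meanFrontFitness", "se2_meanFrontFitness",
                    "n") %in% names(agg)))
  expect_true(all(agg$n <= 3))
  # direct recomputation of one cell
  g <- agg$generation[1]
  vals <- vapply(out$replicates, function(r)
    r$records$meanFrontFitness[r$records$generation == g], numeric(1))
  expect_equal(agg$mean_meanFrontFitness[1], mean(vals))
  expect_equal(agg$se2_meanFrontFitness[1], 2 * sd(vals) / sqrt(3))
  # single replicate: SE undefined
  one <- runReplicates(cfg, nReps = 1, baseSeed = 9)
  expect_true(all(is.na(one$aggregate$se2_meanFrontFitness)))
})

test_that("burned-in state can be cloned and branched deterministically", {
  loci <- buildLocusTable(45, 5, 0)
  sched <- scheduleSpec("shift", T = 3, burnIn = 100, landscapeLength = 15,
                        totalGenerations = 30, windowWidth = 3)
  base <- simInit(loci, mutationModel(), sched, K = 30, seed = 171)
  base <- runBurnIn(base)
  cenBefore <- census(base)
  a <- runPhase(cloneSim(base, seed = 1), generations = 30)
  b <- runPhase(cloneSim(base, seed = 1), generations = 30)
  c3 <- runPhase(cloneSim(base, seed = 2), generations = 30)
  expect_identical(a$trace, b$trace)
  expect_false(identical(a$trace, c3$trace))
  # cloning does not disturb the parent state
  expect_identical(census(base), cenBefore)
})

test_that("front identification is robust across census thresholds", {
  loci <- tinyLoci(2, 1)
  sched <- scheduleSpec("expansion", burnIn = 5, landscapeLength = 20,
                        totalGenerations = 10)
  sim <- simInit(loci, mutationModel(U = 0), sched, K = 100, seed = 181)
  # construct a front profile: saturated demes 1-5, 40 in deme 6, 4 in deme 7
  applyHabitability(sim, rep(TRUE, 20))
  shiftload:::eng_seed_demes(sim@ptr, 5L, 40L)
  shiftload:::eng_seed_demes(sim@ptr, 6L, 4L)
  expect_equal(frontAndCore(sim, threshold = 1)$front, 7)
  expect_equal(frontAndCore(sim, threshold = 10)$front, 6)
  expect_equal(frontAndCore(sim, threshold = 50)$front, 5)
  # all three agree within the width of the front itself
  expect_lte(frontAndCore(sim, threshold = 1)$front -
               frontAndCore(sim, threshold = 50)$front, 2)
})
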