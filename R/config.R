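#' Default run configuration
#'
#' All parameters of a run with their main-text defaults: deme capacity
#' `K = 100`, migration `m = 0.1`, growth `R = 2`, genome-wide mutation
#' rate `U = 0.1` over 900 deleterious + 100 beneficial loci of effect
#' magnitude 0.005, additive dominance, free recombination, soft
#' selection, 1-D landscape of 300 demes, burn-in 4000 generations and a
#' 5000-generation scheduled phase.
#'
#' @return Named list of configuration keys.
#' @export
defaultConfig <- function() {
  list(
    K = 100, m = 0.1, R = 2,
    U = 0.1, meanS = 0.005, dfe = "constant",
    dominance = "constant", h = 0.5, thetaI = 0.5, thetaR = 2500,
    nDel = 900, nBen = 100, nNeutral = 0, neutralRate = 5e-5,
    recombination = "free", selection = "soft", selfing = FALSE,
    hardGrowth = "linear", hardReference = "absolute",
    mode = "expansion", T = NA, burnIn = 4000, windowWidth = 5,
    landscapeLength = 300, landscapeWidth = 1, totalGenerations = 5000,
    recordEvery = 100, seed = 1)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file of configuration keys (all optional; defaults from
#' [defaultConfig()] fill the gaps), applies inline overrides on top, and
#' validates. Unknown keys and out-of-range values are rejected with the
#' offending key named. A key `v` may be given instead of `T` for shift
#' runs.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults only.
#' @param overrides Named list applied after the file.
#' @return Validated configuration list.
#' @examples
#' cfg <- loadConfig(overrides = list(mode = "shift", T = 5))
#' cfg$T
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  fromFile <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(fromFile, overrides)) {
    if (length(src) == 0) next
    if (is.null(names(src)) || any(names(src) == ""))
      stop("configuration entries must be named")
    for (k in names(src)) {
      if (k == "v") {
        v <- src[[k]]
        if (!is.numeric(v) || v <= 0 || v > 1)
          stop("config key 'v' must lie in (0, 1]")
        cfg$T <- round(1 / v)
        # speeds are conventionally quoted rounded (e.g. 0.066 for 1/15)
        if (abs(1 / cfg$T - v) > 0.02 * v)
          stop("config key 'v' must be the reciprocal of an integer")
        next
      }
      if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
      cfg[[k]] <- src[[k]]
    }
  }
  validateConfig(cfg)
}

validateConfig <- function(cfg) {
  chk <- function(ok, key, msg)
    if (!ok) stop("invalid configuration key '", key, "': ", msg)
  chk(is.numeric(cfg$K) && cfg$K > 0, "K", "must be positive")
  chk(is.numeric(cfg$m) && cfg$m >= 0 && cfg$m <= 1, "m", "must be in [0, 1]")
  chk(is.numeric(cfg$R) && cfg$R > 1, "R", "must exceed 1")
  chk(is.numeric(cfg$U) && cfg$U >= 0, "U", "must be nonnegative")
  chk(is.numeric(cfg$meanS) && cfg$meanS > 0, "meanS", "must be positive")
  chk(cfg$dfe %in% c("constant", "exponential"), "dfe",
      "must be 'constant' or 'exponential'")
  chk(cfg$dominance %in% c("constant", "hs_tradeoff"), "dominance",
      "must be 'constant' or 'hs_tradeoff'")
  chk(is.numeric(cfg$h) && cfg$h >= 0 && cfg$h <= 1, "h",
      "must be in [0, 1]")
  chk(cfg$nDel >= 0 && cfg$nBen >= 0 && cfg$nNeutral >= 0, "nDel/nBen/nNeutral",
      "locus counts must be nonnegative")
  chk(cfg$nDel + cfg$nBen > 0, "nDel/nBen", "at least one selected locus")
  chk(is.numeric(cfg$neutralRate) && cfg$neutralRate >= 0, "neutralRate",
      "must be nonnegative")
  chk(cfg$recombination %in% c("free", "none"), "recombination",
      "must be 'free' or 'none'")
  chk(cfg$selection %in% c("soft", "hard"), "selection",
      "must be 'soft' or 'hard'")
  chk(is.logical(cfg$selfing) && length(cfg$selfing) == 1, "selfing",
      "must be TRUE or FALSE")
  chk(cfg$hardGrowth %in% c("linear", "log"), "hardGrowth",
      "must be 'linear' or 'log'")
  chk(cfg$hardReference %in% c("absolute", "relative"), "hardReference",
      "must be 'absolute' or 'relative'")
  chk(cfg$mode %in% c("expansion", "shift"), "mode",
      "must be 'expansion' or 'shift'")
  if (cfg$mode == "shift")
    chk(is.numeric(cfg$T) && !is.na(cfg$T) && cfg$T >= 1 &&
          cfg$T == round(cfg$T), "T",
        "shift mode needs an integer T >= 1")
  chk(cfg$burnIn >= 0, "burnIn", "must be nonnegative")
  chk(cfg$windowWidth >= 1, "windowWidth", "must be >= 1")
  chk(cfg$landscapeLength >= cfg$windowWidth, "landscapeLength",
      "must be at least windowWidth")
  chk(cfg$landscapeWidth >= 1, "landscapeWidth", "must be >= 1")
  chk(cfg$totalGenerations >= 0, "totalGenerations", "must be nonnegative")
  chk(cfg$recordEvery >= 1, "recordEvery", "must be >= 1")
  cfg
}

# materialize the component objects of a config
configObjects <- function(cfg) {
  model <- mutationModel(U = cfg$U, dfe = cfg$dfe, meanS = cfg$meanS,
                         dominance = cfg$dominance, h = cfg$h,
                         thetaI = cfg$thetaI, thetaR = cfg$thetaR,
                         neutralRate = cfg$neutralRate)
  loci <- buildLocusTable(cfg$nDel, cfg$nBen, cfg$nNeutral, model,
                          seed = cfg$seed)
  schedule <- scheduleSpec(cfg$mode, T = cfg$T, burnIn = cfg$burnIn,
                           windowWidth = cfg$windowWidth,
                           landscapeLength = cfg$landscapeLength,
                           landscapeWidth = cfg$landscapeWidth,
                           totalGenerations = cfg$totalGenerations)
  list(model = model, loci = loci, schedule = schedule)
}

#' Run one configured simulation
#'
#' End-to-end run of a validated configuration (burn-in plus scheduled
#' phase). Optionally writes the cadenced records, the per-generation
#' trace and a metadata sidecar as tab-separated files.
#'
#' @param config Configuration list from [loadConfig()].
#' @param outPrefix If non-`NULL`, files `<prefix>_records.tsv`,
#'   `<prefix>_trace.tsv` and `<prefix>_meta.tsv` are written.
#' @return A `"shiftloadRun"` list (see [runPhase()]).
#' @export
runSimulation <- function(config = defaultConfig(), outPrefix = NULL) {
  cfg <- validateConfig(config)
  obj <- configObjects(cfg)
  run <- simulateRange(obj$loci, obj$model, obj$schedule,
                       K = cfg$K, m = cfg$m, R = cfg$R,
                       selection = cfg$selection,
                       recombination = cfg$recombination,
                       selfing = cfg$selfing, seed = cfg$seed,
                       recordEvery = cfg$recordEvery,
                       hardGrowth = cfg$hardGrowth,
                       hardReference = cfg$hardReference)
  if (!is.null(outPrefix)) {
    writeTsv <- function(df, suffix) {
      path <- paste0(outPrefix, "_", suffix, ".tsv")
      con <- file(path, "w")
      writeLines(paste0("# shiftload ", suffix, "; seed=", cfg$seed,
                        "; mode=", cfg$mode, "; selection=", cfg$selection),
                 con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    writeTsv(run$records, "records")
    writeTsv(run$trace, "trace")
    meta <- data.frame(key = names(cfg),
                       value = vapply(cfg, function(x)
                         paste(format(x), collapse = ","), character(1)))
    writeTsv(meta, "meta")
  }
  run
}

#' Fit front-fitness slopes of one run
#'
#' Linear-fit slopes of mean relative front fitness against generation
#' (loss per unit time) and against front column index (loss per deme
#' travelled), over post-burn-in generations `window[1]` to `window[2]`
#' and only while the front is still moving (for shifts, before the
#' window parks at the end of the landscape).
#'
#' @param run A `"shiftloadRun"` list.
#' @param window Post-burn-in generation window of the fit (default
#'   `c(100, 2000)`, skipping the initial transient and the late phase
#'   where beneficial loci saturate).
#' @return Named list: `perGeneration`, `perDeme` (slopes), `nPoints`.
#' @export
fitnessSlopes <- function(run, window = c(100, 2000)) {
  tr <- run$trace
  burnIn <- run$sim@schedule@burnIn
  len <- run$sim@schedule@landscapeLength
  t <- tr$generation - burnIn
  keep <- t >= window[1] & t <= window[2] & tr$frontIndex < len
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) < 10 || max(tr$frontIndex) - min(tr$frontIndex) < 2)
    return(list(perGeneration = NA_real_, perDeme = NA_real_,
                nPoints = nrow(tr)))
  list(
    perGeneration = unname(stats::coef(
      stats::lm(meanFrontFitness ~ generation, tr))[2]),
    perDeme = unname(stats::coef(
      stats::lm(meanFrontFitness ~ frontIndex, tr))[2]),
    nPoints = nrow(tr))
}

#' Sweep shift speeds from a shared burn-in
#'
#' For each replicate, one burn-in is run and its end state cloned across
#' all requested shift speeds, so speed comparisons are paired. For each
#' speed the front-fitness slopes per generation and per deme are fitted
#' over `window` (see [fitnessSlopes()]).
#'
#' @param config Base configuration (its `mode` is forced to `"shift"`).
#' @param speeds Shift speeds, each the reciprocal of an integer.
#' @param nReps Replicates per speed.
#' @param baseSeed Seed from which burn-in and phase seeds derive.
#' @param window Fit window in post-burn-in generations.
#' @return Data frame: one row per speed with mean and 2SE of both slopes
#'   plus mean final front fitness.
#' @export
sweepSpeeds <- function(config = defaultConfig(),
                        speeds = c(0.2, 0.1, 0.066, 0.05, 0.04, 0.033,
                                   0.025, 0.02),
                        nReps = 3, baseSeed = 1, window = c(100, 2000)) {
  cfg <- validateConfig(config)
  cfg$mode <- "shift"
  seeds <- replicateSeeds(baseSeed, nReps)
  perDeme <- matrix(NA_real_, nReps, length(speeds))
  perGen <- matrix(NA_real_, nReps, length(speeds))
  finalFit <- matrix(NA_real_, nReps, length(speeds))
  for (r in seq_len(nReps)) {
    cfgR <- cfg; cfgR$seed <- seeds[r]
    cfgR$T <- max(round(1 / max(speeds)), 1)
    obj <- configObjects(cfgR)
    base <- simInit(obj$loci, obj$model, obj$schedule, K = cfgR$K,
                    m = cfgR$m, R = cfgR$R, selection = cfgR$selection,
                    recombination = cfgR$recombination,
                    selfing = cfgR$selfing, seed = seeds[r],
                    hardGrowth = cfgR$hardGrowth,
                    hardReference = cfgR$hardReference)
    base <- runBurnIn(base)
    for (j in seq_along(speeds)) {
      T <- round(1 / speeds[j])
      if (abs(1 / T - speeds[j]) > 0.02 * speeds[j])
        stop("speed ", speeds[j], " is not the reciprocal of an integer")
      sim <- cloneSim(base, seed = seeds[r] + 7919L * j)
      sim@schedule@T <- as.integer(T)
      sim@schedule@mode <- "shift"
      run <- runPhase(sim, generations = min(cfgR$totalGenerations,
                                             window[2]),
                      recordEvery = cfgR$recordEvery)
      sl <- fitnessSlopes(run, window)
      perDeme[r, j] <- sl$perDeme
      perGen[r, j] <- sl$perGeneration
      n <- nrow(run$trace)
      if (n > 0) finalFit[r, j] <- run$trace$meanFrontFitness[n]
    }
  }
  se2 <- function(x) if (sum(!is.na(x)) > 1)
    2 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else NA_real_
  data.frame(
    v = speeds, T = round(1 / speeds),
    slopePerDeme = colMeans(perDeme, na.rm = TRUE),
    se2PerDeme = apply(perDeme, 2, se2),
    slopePerGeneration = colMeans(perGen, na.rm = TRUE),
    se2PerGeneration = apply(perGen, 2, se2),
    finalFrontFitness = colMeans(finalFit, na.rm = TRUE))
}
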