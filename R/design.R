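#' Design configuration for the two-phase experiment
#'
#' Builds and validates the configuration of the simulated experiment: a
#' training phase (spatial memory task only) and a test phase in which an
#' additional-singleton search task is embedded in the memory maintenance
#' period. Defaults reproduce the study design: 10 blocks of 80 training
#' trials; 10 blocks of 92 test trials; 8 location bins at 45 deg spacing
#' with +/- 22.5 deg angular jitter; a color-singleton distractor present
#' on 74% of test trials, placed at the high-probability location (HPL) on
#' 65% of distractor-present trials and at each of the seven
#' low-probability locations (LPL) on 5%; and 13% no-memory trials in the
#' test phase.
#'
#' @param nBlocksTrain,trialsPerBlockTrain training-phase block structure.
#' @param nBlocksTest,trialsPerBlockTest test-phase block structure.
#' @param nLocations number of location bins on the circle.
#' @param jitterHalfRange half-range of the uniform angular jitter (deg).
#' @param pDistractorPresent probability a test trial contains a distractor.
#' @param pHplGivenPresent P(distractor at HPL | present).
#' @param pEachLplGivenPresent P(distractor at one given LPL | present);
#'   must satisfy `pHplGivenPresent + 7 * pEachLplGivenPresent == 1`.
#' @param hplBin the high-probability bin, 0..nLocations-1.
#' @param pNoMemory fraction of test trials without a memory cue.
#' @param seed integer seed used by [generateDesign()].
#' @return a `DesignConfig` list.
#' @examples
#' cfg <- designConfig(seed = 1)
#' cfg$locationCenters
#' @export
designConfig <- function(nBlocksTrain = 10L, trialsPerBlockTrain = 80L,
                         nBlocksTest = 10L, trialsPerBlockTest = 92L,
                         nLocations = 8L, jitterHalfRange = 22.5,
                         pDistractorPresent = 0.74,
                         pHplGivenPresent = 0.65,
                         pEachLplGivenPresent = 0.05,
                         hplBin = 0L, pNoMemory = 0.13, seed = 1L) {
  p <- c(pDistractorPresent, pHplGivenPresent, pEachLplGivenPresent,
         pNoMemory)
  if (any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(pHplGivenPresent + (nLocations - 1) * pEachLplGivenPresent - 1) >
      1e-12)
    stop("conditional distractor-location probabilities must sum to 1 ",
         "(pHplGivenPresent + ", nLocations - 1,
         " * pEachLplGivenPresent)", call. = FALSE)
  if (!hplBin %in% 0:(nLocations - 1))
    stop("hplBin must be in 0..", nLocations - 1, call. = FALSE)
  cfg <- list(
    nBlocksTrain = as.integer(nBlocksTrain),
    trialsPerBlockTrain = as.integer(trialsPerBlockTrain),
    nBlocksTest = as.integer(nBlocksTest),
    trialsPerBlockTest = as.integer(trialsPerBlockTest),
    nLocations = as.integer(nLocations),
    locationCenters = seq(0, 360 - 360 / nLocations,
                          by = 360 / nLocations),
    jitterHalfRange = jitterHalfRange,
    pDistractorPresent = pDistractorPresent,
    pHplGivenPresent = pHplGivenPresent,
    pEachLplGivenPresent = pEachLplGivenPresent,
    hplBin = as.integer(hplBin),
    pNoMemory = pNoMemory,
    seed = as.integer(seed)
  )
  structure(cfg, class = "DesignConfig")
}

#' Generate the trial-level experimental design
#'
#' Samples one simulated session: every trial draws its memory-cue bin
#' uniformly from the location bins (except no-memory test trials), adds
#' uniform angular jitter on `[-jitterHalfRange, +jitterHalfRange)`, and -
#' in the test phase - independently samples distractor presence,
#' distractor location (HPL-biased), and a target location uniform over
#' the bins excluding the distractor's. Conditions are sampled i.i.d. per
#' trial, so realized proportions fluctuate binomially around the
#' configured probabilities. Deterministic given `cfg$seed`.
#'
#' @param cfg a [designConfig()] object.
#' @param phases which phases to generate (`"training"`, `"test"` or both).
#' @return a `data.frame` (TrialTable) with columns `phase`, `block`,
#'   `trial`, `cue_bin` (0-based, `NA` on no-memory trials), `cue_angle`
#'   (deg), `no_memory`, `distractor_present`, `distractor_bin` (`NA` when
#'   absent), `target_bin`, and empty behavioral columns (`rt`, `correct`,
#'   `recall_deviation`) to be filled by [generateBehavior()]. The config
#'   is attached as attribute `"design_config"`.
#' @examples
#' tt <- generateDesign(designConfig(seed = 2))
#' mean(tt$distractor_present[tt$phase == "test"])
#' @export
generateDesign <- function(cfg, phases = c("training", "test")) {
  stopifnot(inherits(cfg, "DesignConfig"))
  phases <- match.arg(phases, several.ok = TRUE)
  set.seed(cfg$seed)
  nb <- cfg$nLocations
  onePhase <- function(phase) {
    nBlocks <- if (phase == "training") cfg$nBlocksTrain else cfg$nBlocksTest
    perBlock <- if (phase == "training") cfg$trialsPerBlockTrain
                else cfg$trialsPerBlockTest
    n <- nBlocks * perBlock
    if (n == 0) return(NULL)
    noMem <- if (phase == "test") stats::runif(n) < cfg$pNoMemory
             else rep(FALSE, n)
    cueBin <- sample.int(nb, n, replace = TRUE) - 1L
    cueBin[noMem] <- NA_integer_
    jitter <- stats::runif(n, -cfg$jitterHalfRange, cfg$jitterHalfRange)
    cueAngle <- (cfg$locationCenters[cueBin + 1L] + jitter) %% 360
    if (phase == "test") {
      present <- stats::runif(n) < cfg$pDistractorPresent
      # conditional location: HPL with pHplGivenPresent, else uniform LPL
      atHpl <- stats::runif(n) < cfg$pHplGivenPresent
      lpls <- setdiff(0:(nb - 1L), cfg$hplBin)
      dBin <- ifelse(atHpl, cfg$hplBin,
                     lpls[sample.int(nb - 1L, n, replace = TRUE)])
      dBinAll <- dBin
      dBin[!present] <- NA_integer_
      # target uniform over the bins excluding the distractor's when present
      off <- sample.int(nb - 1L, n, replace = TRUE)     # 1..nb-1
      tBin <- ifelse(present, (dBinAll + off) %% nb,
                     sample.int(nb, n, replace = TRUE) - 1L)
    } else {
      present <- rep(FALSE, n)
      dBin <- rep(NA_integer_, n)
      tBin <- rep(NA_integer_, n)
    }
    data.frame(
      phase = phase,
      block = rep(seq_len(nBlocks), each = perBlock),
      trial = rep(seq_len(perBlock), times = nBlocks),
      cue_bin = cueBin, cue_angle = cueAngle, no_memory = noMem,
      distractor_present = present, distractor_bin = as.integer(dBin),
      target_bin = as.integer(tBin),
      rt = NA_real_, correct = NA, recall_deviation = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(phases, onePhase))
  rownames(out) <- NULL
  attr(out, "design_config") <- cfg
  out
}

#' Behavioral effect configuration
#'
#' Per-condition reaction-time deltas (ms) and accuracy offsets used by
#' [generateBehavior()]. Defaults emulate the qualitative structure of
#' learned distractor suppression: search is faster and more accurate when
#' the distractor occupies the HPL, slower when the target does, faster on
#' distractor-location repetitions, and graded with distance from the HPL.
#'
#' @param baseRt baseline mean RT (ms) for distractor-absent search.
#' @param distractorAbsentDelta RT delta when no distractor is shown.
#' @param hplBenefit RT delta when the distractor is at the HPL (negative
#'   = suppression benefit).
#' @param targetHplCost RT delta when the target falls on the HPL.
#' @param distDeltas length-4 RT deltas for distractor at distance 1..4
#'   from the HPL (applied to LPL-distractor trials).
#' @param repBenefit RT delta when the distractor location repeats the
#'   previous trial's distractor location.
#' @param noiseSd trial-to-trial Gaussian RT noise SD (ms).
#' @param accBase baseline probability correct.
#' @param accHplBenefit accuracy increment for distractor-at-HPL trials.
#' @param accDistDeltas length-4 accuracy increments for distance 1..4.
#' @param accRepBenefit accuracy increment on repetition trials.
#' @param recallSdTrain,recallSdTest wrapped-normal SD (deg) of memory
#'   recall deviations per phase.
#' @return a `BehaviorEffects` list.
#' @export
behaviorEffects <- function(baseRt = 1000, distractorAbsentDelta = -80,
                            hplBenefit = -50, targetHplCost = 60,
                            distDeltas = c(-40, 0, -8, 0),
                            repBenefit = -40, noiseSd = 150,
                            accBase = 0.90, accHplBenefit = 0.03,
                            accDistDeltas = c(0.04, 0, 0.005, 0),
                            accRepBenefit = 0.02,
                            recallSdTrain = 7, recallSdTest = 12) {
  stopifnot(length(distDeltas) == 4, length(accDistDeltas) == 4)
  structure(as.list(environment()), class = "BehaviorEffects")
}

#' Simulate behavioral outcomes on a trial table
#'
#' Fills `rt`, `correct` and `recall_deviation` for a design generated by
#' [generateDesign()]. RT is the sum of a baseline, additive condition
#' deltas (distractor at HPL, target at HPL, distance-from-HPL deltas on
#' LPL-distractor trials, distractor-location repetition) and Gaussian
#' noise; negative draws are resampled (the resample count is attached as
#' attribute `"n_rt_resampled"`). Accuracy is Bernoulli per condition.
#' Recall deviation is a wrapped-normal sample with a phase-specific SD
#' (no-memory trials get `NA`). Repetitions are evaluated against the
#' immediately preceding trial within the same block.
#'
#' @param trials TrialTable from [generateDesign()].
#' @param effects a [behaviorEffects()] configuration.
#' @param seed integer seed (defaults to the design seed + 1).
#' @return the trial table with behavioral columns filled, plus a logical
#'   `dist_repeat` column.
#' @export
generateBehavior <- function(trials, effects = behaviorEffects(),
                             seed = NULL) {
  stopifnot(inherits(effects, "BehaviorEffects"))
  cfg <- attr(trials, "design_config")
  if (is.null(seed)) seed <- if (!is.null(cfg)) cfg$seed + 1L else 1L
  hpl <- if (!is.null(cfg)) cfg$hplBin else 0L
  nb <- if (!is.null(cfg)) cfg$nLocations else 8L
  set.seed(seed)
  n <- nrow(trials)
  isTest <- trials$phase == "test"

  # distractor-location repetition within block
  prevBin <- c(NA_integer_, trials$distractor_bin[-n])
  newBlock <- c(TRUE, trials$block[-1] != trials$block[-n] |
                      trials$phase[-1] != trials$phase[-n])
  rep_ <- !newBlock & !is.na(prevBin) & !is.na(trials$distractor_bin) &
    prevBin == trials$distractor_bin
  trials$dist_repeat <- rep_ & isTest

  dAtHpl <- isTest & trials$distractor_present &
    trials$distractor_bin == hpl
  dAtHpl[is.na(dAtHpl)] <- FALSE
  tAtHpl <- isTest & trials$target_bin == hpl
  tAtHpl[is.na(tAtHpl)] <- FALSE
  dist <- binDistance(trials$distractor_bin, hpl, nb)

  mu <- rep(NA_real_, n)
  mu[isTest] <- effects$baseRt
  mu[isTest & !trials$distractor_present] <-
    effects$baseRt + effects$distractorAbsentDelta
  mu[dAtHpl] <- mu[dAtHpl] + effects$hplBenefit
  mu[tAtHpl] <- mu[tAtHpl] + effects$targetHplCost
  lplIdx <- which(isTest & trials$distractor_present & !dAtHpl)
  mu[lplIdx] <- mu[lplIdx] + effects$distDeltas[dist[lplIdx]]
  mu[trials$dist_repeat] <- mu[trials$dist_repeat] + effects$repBenefit

  rt <- mu + stats::rnorm(n, 0, effects$noiseSd)
  nResampled <- 0L
  bad <- which(!is.na(rt) & rt < 0)
  while (length(bad)) {
    nResampled <- nResampled + length(bad)
    rt[bad] <- mu[bad] + stats::rnorm(length(bad), 0, effects$noiseSd)
    bad <- bad[!is.na(rt[bad]) & rt[bad] < 0]
  }
  trials$rt <- rt

  pAcc <- rep(NA_real_, n)
  pAcc[isTest] <- effects$accBase
  pAcc[dAtHpl] <- pAcc[dAtHpl] + effects$accHplBenefit
  pAcc[lplIdx] <- pAcc[lplIdx] + effects$accDistDeltas[dist[lplIdx]]
  pAcc[trials$dist_repeat] <- pAcc[trials$dist_repeat] +
    effects$accRepBenefit
  pAcc <- pmin(pmax(pAcc, 0), 1)
  trials$correct <- ifelse(isTest, stats::runif(n) < pAcc, NA)

  sdRec <- ifelse(trials$phase == "training",
                  effects$recallSdTrain, effects$recallSdTest)
  dev <- stats::rnorm(n, 0, sdRec)
  dev <- angularDiff(dev %% 360, 0)
  dev[trials$no_memory] <- NA_real_
  trials$recall_deviation <- dev

  attr(trials, "n_rt_resampled") <- nResampled
  attr(trials, "behavior_effects") <- effects
  trials
}
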