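#' Partition trials into independent sets with per-bin equating
#'
#' Within-session mode randomly assigns the usable trials (known cue bin)
#' to `nSets` disjoint sets, first discarding trials so that every
#' location bin contributes the same count: each bin is randomly
#' subsampled to `floor(min_count / nSets) * nSets` trials, which are then
#' split equally over the sets. Cross-session mode equates and splits the
#' training-phase (localizer) trials into two training sets and assigns
#' the entire test phase to the test set.
#'
#' @param trials TrialTable (needs `cue_bin`; cross mode also `phase`).
#' @param mode `"within"` or `"cross"`.
#' @param nSets number of sets in within mode.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return a `PartitionPlan` data.frame aligned with `trials`: columns
#'   `set` (integer; in cross mode the test phase gets `nSets`, i.e. 3)
#'   and `bin`; discarded or unusable trials have `NA` set. Attribute
#'   `"test_set"` names the held-out set id.
#' @export
partitionEquate <- function(trials, mode = c("within", "cross"),
                            nSets = 3L, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- nrow(trials)
  setv <- rep(NA_integer_, n)
  usable <- !is.na(trials$cue_bin)
  if ("no_memory" %in% names(trials)) usable <- usable & !trials$no_memory

  assignSets <- function(idx, bins, ns, offset = 0L) {
    counts <- table(bins)
    minCount <- min(counts)
    keepPer <- floor(minCount / ns) * ns
    if (keepPer < ns)
      stop("bin ", names(counts)[which.min(counts)], " has too few ",
           "usable trials (", minCount, ") for ", ns, " sets",
           call. = FALSE)
    for (b in unique(bins)) {
      bi <- idx[bins == b]
      keep <- sample(bi, keepPer)
      setv[keep] <<- offset + rep(seq_len(ns), each = keepPer / ns)[
        sample.int(keepPer)]
    }
    invisible(NULL)
  }

  if (mode == "within") {
    idx <- which(usable)
    assignSets(idx, trials$cue_bin[idx], nSets)
    testSet <- nSets
  } else {
    if (!"phase" %in% names(trials))
      stop("cross-session partitioning needs a 'phase' column",
           call. = FALSE)
    tri <- which(usable & trials$phase == "training")
    assignSets(tri, trials$cue_bin[tri], 2L)
    tei <- which(usable & trials$phase == "test")
    setv[tei] <- 3L
    testSet <- 3L
  }
  plan <- data.frame(set = setv, bin = trials$cue_bin)
  plan$bin[is.na(plan$set)] <- NA_integer_
  attr(plan, "test_set") <- testSet
  attr(plan, "mode") <- mode
  plan
}

#' Iterated partition-train-invert-recenter IEM analysis
#'
#' The full encoding loop: for each iteration, randomly re-partition the
#' trials ([partitionEquate()]), compute evoked or total power per
#' (set x bin) observation group, smooth, optionally reduce features by
#' principal components (fitted on the training observations only), train
#' the weight matrix on the training sets against the basis-predicted
#' responses at the bin centers, invert the model on the held-out set, and
#' re-center the estimated channel responses on each observation's cue
#' bin. CTFs are averaged across iterations. In cross-session mode the
#' weights are estimated exclusively from training-phase (localizer)
#' epochs and tested on the entire test phase, with training and test time
#' samples strictly aligned.
#'
#' @param analytic an [AnalyticEpochs-class] holding every candidate
#'   trial (both phases for cross mode).
#' @param kind `"evoked"` or `"total"` power.
#' @param mode partitioning mode, see [partitionEquate()].
#' @param nIter number of random partitions averaged (default 100).
#' @param seed master seed; each iteration derives its own.
#' @param hplBin high-probability bin for the distance grouping.
#' @param basis a [BasisSet-class].
#' @param smoothWindow sliding-average window in samples (0 = none).
#' @param pcaK number of principal components (`NULL` = no reduction).
#' @param window restrict the analyzed time axis to this window (s).
#' @return a `CTF` list (see [recenterCTF()]) with iteration-averaged
#'   `byLocation`, `byDistance`, `grand`, plus `nIter` and `kind`.
#' @export
runIEMIterations <- function(analytic, kind = c("evoked", "total"),
                             mode = c("within", "cross"), nIter = 100L,
                             seed = 1L, hplBin = 0L, basis = makeBasis(),
                             smoothWindow = 8L, pcaK = NULL,
                             window = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  stopifnot(is(analytic, "AnalyticEpochs"))
  trials <- trialInfo(analytic)
  binCenters <- basis@centers

  acc <- NULL
  times <- NULL
  for (it in seq_len(nIter)) {
    plan <- partitionEquate(trials, mode = mode,
                            seed = deriveSeed(seed, it))
    testSet <- attr(plan, "test_set")
    pow <- if (kind == "evoked") evokedPower(analytic, plan)
           else totalPower(analytic, plan)
    if (smoothWindow > 1) pow <- smoothPower(pow, smoothWindow)
    if (!is.null(window)) {
      widx <- which(pow@times >= window[1] & pow@times <= window[2])
      pow <- initialize(pow, power = pow@power[, , widx, drop = FALSE],
                        times = pow@times[widx])
    }
    isTest <- pow@obs$set == testSet
    sub <- function(pb, sel)
      initialize(pb, power = pb@power[sel, , , drop = FALSE],
                 obs = pb@obs[sel, , drop = FALSE])
    trainPow <- sub(pow, !isTest)
    testPow <- sub(pow, isTest)
    if (!is.null(pcaK)) {
      red <- pcaReduce(trainPow, testPow, pcaK)
      trainPow <- red$train; testPow <- red$test
    }
    C1 <- predictedResponses(binCenters[trainPow@obs$bin + 1L], basis)
    w <- trainWeights(trainPow, C1)
    resp <- invertChannels(w, testPow)
    ctf <- recenterCTF(resp, hplBin = hplBin)
    if (is.null(acc)) {
      acc <- list(byLocation = ctf$byLocation,
                  byDistance = ctf$byDistance, grand = ctf$grand)
      times <- ctf$times
      offsets <- ctf$offsets
    } else {
      acc$byLocation <- acc$byLocation + ctf$byLocation
      if (!is.null(acc$byDistance))
        acc$byDistance <- acc$byDistance + ctf$byDistance
      acc$grand <- acc$grand + ctf$grand
    }
  }
  structure(list(byLocation = acc$byLocation / nIter,
                 byDistance = if (!is.null(acc$byDistance))
                   acc$byDistance / nIter,
                 grand = acc$grand / nIter,
                 offsets = offsets, times = times, nIter = nIter,
                 kind = kind, mode = mode, hplBin = hplBin),
            class = "CTF")
}
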