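#' @name accessors
#' @title Accessors for pingCTF containers
#' @description Slot accessors for [EpochArray-class], [AnalyticEpochs-class]
#'   and [PowerBlock-class]: raw signal arrays, time axes, sampling rate,
#'   trial and electrode tables, and counts.
#' @param object an object of one of the pingCTF classes.
NULL

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("electrodeInfo", function(object) standardGeneric("electrodeInfo"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nElectrodes", function(object) standardGeneric("nElectrodes"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
setMethod("epochData", "EpochArray", function(object) object@signals)
#' @rdname accessors
setMethod("epochData", "AnalyticEpochs", function(object) object@signals)
#' @rdname accessors
setMethod("epochData", "PowerBlock", function(object) object@power)
#' @rdname accessors
setMethod("epochTimes", "EpochArray", function(object) object@times)
#' @rdname accessors
setMethod("epochTimes", "AnalyticEpochs", function(object) object@times)
#' @rdname accessors
setMethod("epochTimes", "PowerBlock", function(object) object@times)
#' @rdname accessors
setMethod("samplingRate", "EpochArray", function(object) object@sfreq)
#' @rdname accessors
setMethod("samplingRate", "AnalyticEpochs", function(object) object@sfreq)
#' @rdname accessors
setMethod("trialInfo", "EpochArray", function(object) object@trials)
#' @rdname accessors
setMethod("trialInfo", "AnalyticEpochs", function(object) object@trials)
#' @rdname accessors
setMethod("electrodeInfo", "EpochArray", function(object) object@electrodes)
#' @rdname accessors
setMethod("nTrials", "EpochArray", function(object) dim(object@signals)[1])
#' @rdname accessors
setMethod("nTrials", "AnalyticEpochs",
          function(object) dim(object@signals)[1])
#' @rdname accessors
setMethod("nElectrodes", "EpochArray",
          function(object) dim(object@signals)[2])
#' @rdname accessors
setMethod("groundTruth", "EpochArray", function(object) object@truth)

#' Subset an EpochArray by trials
#'
#' `x[i]` keeps trials `i` (logical or integer), subsetting the signal
#' array, the trial table and any per-trial ground-truth entries.
#'
#' @param x an [EpochArray-class].
#' @param i trial index (integer or logical).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EpochArray", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nTrials(x))[i]
  truth <- x@truth
  for (nm in names(truth)) {
    tr <- truth[[nm]]
    if (is.array(tr) && length(dim(tr)) == 2 && nrow(tr) == nTrials(x)) {
      truth[[nm]] <- tr[idx, , drop = FALSE]
    } else if (is.vector(tr) && length(tr) == nTrials(x)) {
      truth[[nm]] <- tr[idx]
    } else if (is.array(tr) && length(dim(tr)) == 3 &&
               dim(tr)[1] == nTrials(x)) {
      truth[[nm]] <- tr[idx, , , drop = FALSE]
    }
  }
  new("EpochArray",
      signals = x@signals[idx, , , drop = FALSE],
      times = x@times, sfreq = x@sfreq,
      trials = x@trials[idx, , drop = FALSE],
      electrodes = x@electrodes, lock = x@lock, truth = truth)
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@signals)
  cat(sprintf(
    "EpochArray: %d trials x %d electrodes x %d samples (%.0f Hz)\n",
    d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  lock: %s; time %.3f .. %.3f s\n", object@lock,
              min(object@times), max(object@times)))
  if (length(object@truth))
    cat("  ground truth:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "AnalyticEpochs", function(object) {
  d <- dim(object@signals)
  cat(sprintf(
    "AnalyticEpochs: %d trials x %d electrodes x %d samples (%.0f Hz)\n",
    d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  band: %g-%g Hz (Butterworth order %d, zero-phase)\n",
              object@band[1], object@band[2], object@filterOrder))
})

setMethod("show", "PowerBlock", function(object) {
  d <- dim(object@power)
  cat(sprintf("PowerBlock (%s): %d observations x %d features x %d samples\n",
              object@kind, d[1], d[2], d[3]))
})

setMethod("show", "BasisSet", function(object) {
  cat(sprintf(
    "BasisSet: %d spatial channels, sin(theta/2)^%g profile, centers %s\n",
    object@k, object@power,
    paste0(object@centers, collapse = ", ")))
})
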