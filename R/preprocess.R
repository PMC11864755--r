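#' Detect and repair muscle artifacts by high-band z-scoring
#'
#' Screens epochs for electromyographic contamination: the signals are
#' band-passed 110-140 Hz (zero-phase Butterworth), the band envelope is
#' z-scored per electrode against its across-epochs distribution, and each
#' epoch receives a score equal to the maximum, within the window of
#' interest, of the electrode-summed z trace. Epochs whose score exceeds
#' the data-driven threshold `median + c * MAD` of all epoch scores are
#' flagged (the scaled median absolute deviation estimates the
#' within-subject score spread without being inflated by the artifacts
#' themselves). Rather than dropping flagged epochs outright, the electrodes
#' contributing most to the accumulated z within the artifact period are
#' interpolated one at a time (inverse-distance weighting over the nearest
#' neighbors, see [interpolateElectrode()]), re-testing after each; an
#' epoch is dropped only if it still exceeds the threshold after
#' `maxInterp` interpolations.
#'
#' @param epochs an [EpochArray-class].
#' @param window window of interest in seconds (default the whole epoch).
#' @param c threshold multiplier on the robust spread of epoch scores
#'   (default 4).
#' @param band detection band in Hz.
#' @param order Butterworth order for the detection filter.
#' @param maxInterp maximum electrodes interpolated per epoch (default 5).
#' @return a list with `epochs` (repaired, dropped epochs removed),
#'   `report` (an `ArtifactReport`: `scores`, `threshold`, `flagged`,
#'   `interpolated` data.frame of epoch/electrode pairs, `dropped`,
#'   `kept`), invisibly usable for truth-mask comparisons.
#' @export
detectMuscleArtifacts <- function(epochs, window = NULL, c = 4,
                                  band = c(110, 140), order = 4,
                                  maxInterp = 5L) {
  stopifnot(is(epochs, "EpochArray"))
  nyq <- samplingRate(epochs) / 2
  if (band[2] >= nyq)
    stop("detection band must lie below the Nyquist frequency (", nyq,
         " Hz)", call. = FALSE)
  times <- epochTimes(epochs)
  if (is.null(window)) window <- range(times)
  widx <- which(times >= window[1] & times <= window[2])
  n <- nTrials(epochs); m <- nElectrodes(epochs)

  bf <- signal::butter(order, band / nyq, type = "pass")
  envOf <- function(arr) {
    hf <- applyTimewise(arr, function(x) filtfiltMat(bf$b, bf$a, x))
    abs(hf)
  }
  env <- envOf(epochs@signals)
  mu <- apply(env, 2, mean); sdv <- apply(env, 2, stats::sd)
  zOf <- function(envArr) {
    sweep(sweep(envArr, 2, mu, "-"), 2, sdv, "/")
  }
  z <- zOf(env)

  epochScore <- function(zi) {                 # zi: electrodes x samples
    max(colSums(zi[, widx, drop = FALSE]))
  }
  scores <- vapply(seq_len(n), function(i) epochScore(z[i, , ]), 0)
  threshold <- stats::median(scores) + c * stats::mad(scores)
  flagged <- which(scores > threshold)

  interpolated <- data.frame(epoch = integer(), electrode = integer())
  dropped <- integer()
  arr <- epochs@signals
  pos <- as.matrix(epochs@electrodes[, c("x", "y", "z")])
  for (i in flagged) {
    zi <- z[i, , ]
    done <- integer()
    for (iter in seq_len(maxInterp)) {
      sumz <- colSums(zi[, widx, drop = FALSE])
      if (max(sumz) <= threshold) break
      # artifact period: window samples where the summed z is above
      # threshold (at least the peak sample)
      art <- widx[sumz > threshold]
      if (!length(art)) art <- widx[which.max(sumz)]
      contrib <- rowSums(zi[, art, drop = FALSE])
      contrib[done] <- -Inf
      worst <- which.max(contrib)
      arr[i, worst, ] <- interpolateSignal(arr[i, , ], worst, pos,
                                           exclude = done)
      done <- c(done, worst)
      interpolated <- rbind(interpolated,
                            data.frame(epoch = i, electrode = worst))
      envI <- envOf(arr[i, , , drop = FALSE])
      zi <- zOf(envI)[1, , ]
    }
    sumz <- colSums(zi[, widx, drop = FALSE])
    if (max(sumz) > threshold) dropped <- c(dropped, i)
  }
  kept <- setdiff(seq_len(n), dropped)
  cleaned <- initialize(epochs, signals = arr)
  cleaned <- cleaned[kept]
  report <- structure(
    list(scores = scores, threshold = threshold, flagged = flagged,
         interpolated = interpolated, dropped = dropped, kept = kept,
         reason = ifelse(seq_len(n) %in% dropped, "muscle", "ok")),
    class = "ArtifactReport")
  list(epochs = cleaned, report = report)
}

#' @export
print.ArtifactReport <- function(x, ...) {
  cat(sprintf(
    "ArtifactReport: %d epochs; %d flagged, %d interpolations, %d dropped (threshold %.1f)\n",
    length(x$scores), length(x$flagged), nrow(x$interpolated),
    length(x$dropped), x$threshold))
  invisible(x)
}

## Inverse-distance-weighted reconstruction of one electrode's trace from
## its nearest `nNeighbors` non-excluded electrodes. sig: electrodes x
## samples matrix for one epoch.
interpolateSignal <- function(sig, electrode, pos, nNeighbors = 4L,
                              exclude = integer()) {
  dists <- sqrt(colSums((t(pos) - pos[electrode, ])^2))
  cand <- setdiff(order(dists), c(electrode, exclude))
  cand <- cand[seq_len(min(nNeighbors, length(cand)))]
  if (length(cand) < 3L) {
    warning("fewer than 3 usable neighbors; electrode left untouched")
    return(sig[electrode, ])
  }
  w <- 1 / dists[cand]
  w <- w / sum(w)
  colSums(sig[cand, , drop = FALSE] * w)
}

#' Interpolate one electrode across epochs
#'
#' Replaces an electrode's signal with the inverse-distance-weighted mean
#' of its nearest 4 non-excluded neighbors (3-D layout coordinates), in
#' every epoch (or a subset). Idempotent: interpolating an already
#' interpolated electrode reproduces the same signal.
#'
#' @param epochs an [EpochArray-class].
#' @param electrode electrode index to replace.
#' @param positions electrode x/y/z matrix; defaults to the epochs'
#'   electrode table.
#' @param trials which epochs to touch (default all).
#' @param exclude electrode indices that may not serve as neighbors
#'   (e.g. other flagged electrodes).
#' @return the epochs with the electrode replaced.
#' @export
interpolateElectrode <- function(epochs, electrode, positions = NULL,
                                 trials = NULL, exclude = integer()) {
  stopifnot(is(epochs, "EpochArray"))
  if (is.null(positions))
    positions <- as.matrix(epochs@electrodes[, c("x", "y", "z")])
  if (is.null(trials)) trials <- seq_len(nTrials(epochs))
  arr <- epochs@signals
  for (i in trials)
    arr[i, electrode, ] <- interpolateSignal(arr[i, , ], electrode,
                                             positions, exclude = exclude)
  initialize(epochs, signals = arr)
}

#' Reject epochs with eye movements
#'
#' Flags epochs using the gaze trace when available - any radial gaze
#' excursion beyond `gazeThreshold` visual degrees inside the rejection
#' window - and otherwise falls back to a step detector on the HEOG
#' trace: a sliding window (200 ms, stepped by 10 ms) flags an epoch when
#' the absolute difference between the mean of its second and first half
#' exceeds `heogThreshold` microvolts. The default rejection window
#' follows the epochs' locking event: -100..500 ms for cue-locked and
#' -200..300 ms for placeholder-locked epochs.
#'
#' @param epochs an [EpochArray-class] (used for the time axis and lock).
#' @param gaze trials x samples matrix of radial gaze deviation from
#'   fixation, in visual degrees (or `NULL`).
#' @param heog trials x samples HEOG matrix in microvolts (or `NULL`).
#' @param gazeThreshold gaze rejection threshold in degrees.
#' @param window rejection window in seconds (default from the lock).
#' @param heogWindow,heogStep,heogThreshold step-detector parameters
#'   (seconds, seconds, microvolts).
#' @return logical keep mask (TRUE = epoch retained).
#' @export
rejectEye <- function(epochs, gaze = NULL, heog = NULL,
                      gazeThreshold = 1.2, window = NULL,
                      heogWindow = 0.2, heogStep = 0.01,
                      heogThreshold = 15) {
  stopifnot(is(epochs, "EpochArray"))
  if (is.null(gaze) && is.null(heog)) {
    tr <- groundTruth(epochs)
    gaze <- tr$gaze; heog <- tr$heog
  }
  if (is.null(gaze) && is.null(heog))
    stop("need a gaze trace or an HEOG trace", call. = FALSE)
  times <- epochTimes(epochs)
  if (is.null(window))
    window <- if (epochs@lock == "cue") c(-0.1, 0.5) else c(-0.2, 0.3)
  widx <- which(times >= window[1] & times <= window[2])
  if (!is.null(gaze)) {
    bad <- apply(abs(gaze[, widx, drop = FALSE]), 1, max) > gazeThreshold
    return(!bad)
  }
  sf <- samplingRate(epochs)
  wlen <- round(heogWindow * sf)
  half <- floor(wlen / 2)
  stepn <- max(1L, round(heogStep * sf))
  starts <- seq(widx[1], max(widx[1], widx[length(widx)] - wlen + 1L),
                by = stepn)
  bad <- rep(FALSE, nrow(heog))
  for (s in starts) {
    i1 <- s:(s + half - 1L)
    i2 <- (s + half):(min(s + wlen - 1L, ncol(heog)))
    stat <- abs(rowMeans(heog[, i2, drop = FALSE]) -
                  rowMeans(heog[, i1, drop = FALSE]))
    bad <- bad | stat > heogThreshold
  }
  !bad
}
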