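#' Standard 64-electrode 10-10 layout
#'
#' Loads the BioSemi 64-channel 10-10 montage coordinates shipped with the
#' package (head-frame x/y/z in meters). Used only to define interpolation
#' neighborhoods and to give forward-model topographies a spatial
#' organization; no lead-field modeling is implied.
#'
#' @param n optionally subsample to `n` electrodes (evenly over the list).
#' @return data.frame with columns `name`, `x`, `y`, `z`.
#' @export
standardLayout <- function(n = 64L) {
  path <- system.file("extdata", "biosemi64_layout.tsv",
                      package = "pingCTF", mustWork = TRUE)
  lay <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (n < nrow(lay)) {
    idx <- unique(round(seq(1, nrow(lay), length.out = n)))
    lay <- lay[idx, , drop = FALSE]
    rownames(lay) <- NULL
  }
  lay
}

#' Forward model mapping spatial channels to electrodes
#'
#' Defines how `k` location-tuned spatial channels project to the
#' electrode array, plus the oscillatory and noise parameters of the
#' generator. The mixing matrix gives each channel a smooth, lateralized
#' scalp topography: electrode azimuth (from the layout's x/y position) is
#' compared to the channel's preferred angle through a von-Mises-shaped
#' profile, with a small random perturbation so the matrix has full column
#' rank. The exact spatial profile of real alpha topographies is unknown;
#' this is a modeling choice, and the inverse model never sees it.
#'
#' @param nElectrodes number of electrodes (layout subsampled evenly).
#' @param k number of spatial channels.
#' @param alphaFreq carrier frequency of the tuned oscillation (Hz).
#' @param evokedAmp amplitude (a.u.) of the phase-locked component
#'   following the locking event.
#' @param inducedAmp amplitude of the non-phase-locked (random-phase)
#'   sustained component.
#' @param pingAmp amplitude of the phase-locked revival evoked by the
#'   placeholder ("ping") display.
#' @param gradient length-5 multipliers applied to the ping-evoked tuning
#'   amplitude by the cue's bin distance (0..4) from the HPL; all ones =
#'   no planted gradient.
#' @param noisePink,noiseWhite SDs of the 1/f and white noise added per
#'   electrode (a.u.). Defaults calibrated once so that single-subject CTF
#'   recovery succeeds at roughly 300 trials.
#' @param mixingKappa concentration of the topography profile.
#' @param layout electrode table from [standardLayout()].
#' @param seed seed for the mixing perturbation.
#' @return a `ForwardModel` list; element `mixing` is electrodes x k.
#' @export
forwardModel <- function(nElectrodes = 64L, k = 8L, alphaFreq = 10,
                         evokedAmp = 1, inducedAmp = 1, pingAmp = 1,
                         gradient = rep(1, 5),
                         noisePink = 1.5, noiseWhite = 0.5,
                         mixingKappa = 2, layout = NULL, seed = 99L) {
  if (is.null(layout)) layout <- standardLayout(nElectrodes)
  stopifnot(length(gradient) == 5, all(gradient >= 0))
  centers <- seq(0, 360 - 360 / k, by = 360 / k) * pi / 180
  az <- atan2(layout$y, layout$x)
  set.seed(seed)
  mixing <- sapply(centers, function(c0)
    exp(mixingKappa * (cos(az - c0) - 1)))
  mixing <- mixing + matrix(stats::rnorm(length(mixing), 0, 0.05),
                            nrow(mixing))
  mixing <- pmax(mixing, 0)
  if (qr(mixing)$rank < k)
    stop("mixing matrix is rank deficient; increase electrodes or jitter",
         call. = FALSE)
  structure(list(mixing = mixing, k = as.integer(k),
                 alphaFreq = alphaFreq, evokedAmp = evokedAmp,
                 inducedAmp = inducedAmp, pingAmp = pingAmp,
                 gradient = gradient, noisePink = noisePink,
                 noiseWhite = noiseWhite, layout = layout, seed = seed),
            class = "ForwardModel")
}

#' Epoch timing definition
#'
#' Event-locked epoch extents in seconds. Defaults follow the analysis
#' windows of the design: cue-locked epochs span -0.75..1.6 s with a
#' window of interest of -0.25..1.1 s; placeholder-locked epochs span
#' -0.75..1.0 s with a window of interest of -0.25..0.5 s. Epochs are
#' deliberately longer than the window of interest so that filter edge
#' effects fall outside it.
#'
#' @param lock `"cue"` or `"placeholder"`.
#' @param sfreq sampling rate (Hz).
#' @param tmin,tmax epoch extent (s); defaults depend on `lock`.
#' @param windowOfInterest analysis window (s).
#' @param pingOnset for cue-locked epochs, when the placeholder appears
#'   (s); for placeholder-locked epochs the ping is at 0.
#' @return an `EpochTiming` list.
#' @export
epochTiming <- function(lock = c("placeholder", "cue"), sfreq = 512,
                        tmin = NULL, tmax = NULL,
                        windowOfInterest = NULL, pingOnset = 1.2) {
  lock <- match.arg(lock)
  if (lock == "cue") {
    if (is.null(tmin)) tmin <- -0.75
    if (is.null(tmax)) tmax <- 1.6
    if (is.null(windowOfInterest)) windowOfInterest <- c(-0.25, 1.1)
  } else {
    if (is.null(tmin)) tmin <- -0.75
    if (is.null(tmax)) tmax <- 1.0
    if (is.null(windowOfInterest)) windowOfInterest <- c(-0.25, 0.5)
    pingOnset <- 0
  }
  structure(list(lock = lock, sfreq = sfreq, tmin = tmin, tmax = tmax,
                 windowOfInterest = windowOfInterest,
                 pingOnset = pingOnset),
            class = "EpochTiming")
}

## Envelope of the phase-locked ("evoked"/ping) component: Gaussian bump.
evokedEnvelope <- function(times, onset, peakDelay = 0.15, width = 0.07) {
  env <- exp(-0.5 * ((times - onset - peakDelay) / width)^2)
  env[times < onset] <- env[times < onset] *
    exp(-((onset - times[times < onset]) / 0.01)^2)  # hard pre-onset cutoff
  env
}

## Envelope of the sustained non-phase-locked component: smooth step.
inducedEnvelope <- function(times, onset, rise = 0.1) {
  stats::plogis((times - onset - rise / 2) / (rise / 8))
}

#' Generate multichannel epochs from the forward model
#'
#' Builds synthetic event-locked epochs with location-tuned alpha
#' oscillations. Per trial, the channel activation vector is the basis
#' response evaluated at the trial's cue angle; the electrode pattern is
#' `mixing %*% activation`. Two tuned components ride on an alpha carrier:
#' a phase-locked (evoked) component with a fixed phase across trials, and
#' a non-phase-locked (induced) component whose carrier phase is drawn
#' uniformly per trial - only the former survives complex trial averaging.
#' For placeholder-locked epochs the phase-locked revival amplitude is
#' additionally scaled by `fwd$gradient[distance(cue_bin, hpl_bin) + 1]`,
#' the planted distance gradient. Pink (1/f) plus white noise is added per
#' electrode. No-memory trials (no cue) receive noise only. Ground truth
#' (activation matrix, per-trial gradient multiplier, envelopes) is stored
#' in the returned object.
#'
#' @param trials TrialTable (test- or training-phase rows).
#' @param fwd a [forwardModel()].
#' @param timing an [epochTiming()].
#' @param seed integer seed.
#' @param basis optional [BasisSet-class]; default `makeBasis(fwd$k)`.
#' @return an [EpochArray-class] with ground truth in `groundTruth()`.
#' @export
generateEpochs <- function(trials, fwd, timing = epochTiming(), seed = 1L) {
  stopifnot(inherits(fwd, "ForwardModel"),
            inherits(timing, "EpochTiming"))
  cfg <- attr(trials, "design_config")
  hpl <- if (!is.null(cfg)) cfg$hplBin else 0L
  nb <- if (!is.null(cfg)) cfg$nLocations else 8L
  basis <- makeBasis(fwd$k)
  n <- nrow(trials)
  m <- nrow(fwd$mixing)
  times <- seq(timing$tmin, timing$tmax, by = 1 / timing$sfreq)
  nt <- length(times)
  set.seed(seed)

  # channel activations at the true (jittered) cue angle; zero without cue
  act <- matrix(0, n, fwd$k)
  hasCue <- !is.na(trials$cue_bin)
  if (any(hasCue))
    act[hasCue, ] <- t(predictedResponses(trials$cue_angle[hasCue], basis))
  pattern <- act %*% t(fwd$mixing)                     # n x m

  gradMult <- rep(1, n)
  if (timing$lock == "placeholder" || timing$pingOnset <= timing$tmax) {
    d <- binDistance(ifelse(hasCue, trials$cue_bin, 0L), hpl, nb)
    gradMult <- fwd$gradient[d + 1L]
    gradMult[!hasCue] <- 1
  }

  carrier <- 2 * pi * fwd$alphaFreq * times
  envEv <- if (timing$lock == "cue")
    evokedEnvelope(times, 0) else evokedEnvelope(times, timing$pingOnset)
  envPing <- if (timing$lock == "cue" && timing$pingOnset <= timing$tmax)
    evokedEnvelope(times, timing$pingOnset) else NULL
  envInd <- inducedEnvelope(times, 0)

  # per-trial tuned time courses (n x nt)
  evAmp <- if (timing$lock == "placeholder") fwd$pingAmp * gradMult
           else rep(fwd$evokedAmp, n)
  tc <- outer(evAmp, rep(1, nt)) *
    matrix(envEv * cos(carrier), n, nt, byrow = TRUE)
  if (!is.null(envPing)) {
    tc <- tc + outer(fwd$pingAmp * gradMult, rep(1, nt)) *
      matrix(envPing * cos(carrier), n, nt, byrow = TRUE)
  }
  phi <- stats::runif(n, 0, 2 * pi)
  tc <- tc + fwd$inducedAmp *
    cos(outer(phi, carrier, "+")) *
    matrix(envInd, n, nt, byrow = TRUE)

  arr <- array(0, c(n, m, nt))
  for (e in seq_len(m)) arr[, e, ] <- pattern[, e] * tc

  if (fwd$noisePink > 0) {
    pn <- pinkNoise(nt, n * m)
    arr <- arr + fwd$noisePink *
      aperm(array(pn, c(nt, n, m)), c(2, 3, 1))
  }
  if (fwd$noiseWhite > 0)
    arr <- arr + array(stats::rnorm(n * m * nt, 0, fwd$noiseWhite),
                       c(n, m, nt))

  new("EpochArray", signals = arr, times = times, sfreq = timing$sfreq,
      trials = trials, electrodes = fwd$layout, lock = timing$lock,
      truth = list(activations = act, grad_mult = gradMult,
                   envelope_evoked = envEv, envelope_induced = envInd,
                   pattern = pattern, hpl_bin = hpl,
                   tuned_timecourse = NULL))
}

#' Inject artifacts into clean epochs
#'
#' Adds controlled artifacts and auxiliary eye traces to an
#' [EpochArray-class] for testing the rejection procedures: high-frequency
#' (125 Hz) muscle bursts on chosen trials and electrodes, step-like HEOG
#' deflections, and gaze excursions on a simulated radial gaze trace.
#' Clean trials get near-fixation gaze jitter and baseline HEOG noise.
#' Truth masks of contaminated trials are stored in `groundTruth()`.
#'
#' @param epochs an [EpochArray-class].
#' @param burstTrials fraction (if < 1) or count of trials receiving a
#'   muscle burst.
#' @param burstElectrodes how many electrodes each burst contaminates.
#' @param burstAmp burst amplitude (same units as the signals); 0 disables.
#' @param burstFreq burst carrier frequency (Hz), inside the 110-140 Hz
#'   detection band.
#' @param burstDuration burst length (s).
#' @param eyeTrials fraction or count of trials receiving an eye artifact.
#' @param gazeAmp radial gaze excursion amplitude (visual degrees).
#' @param heogStep HEOG step amplitude (microvolts).
#' @param eyeOnset onset of the eye artifact (s).
#' @param seed integer seed.
#' @return the epochs with artifacts added; `groundTruth()` gains
#'   `burst_mask`, `eye_mask` (logical per trial), `gaze` and `heog`
#'   (trials x samples matrices).
#' @export
injectArtifacts <- function(epochs, burstTrials = 0.1,
                            burstElectrodes = 1L, burstAmp = 40,
                            burstFreq = 125, burstDuration = 0.15,
                            eyeTrials = 0.1, gazeAmp = 2.0,
                            heogStep = 30, eyeOnset = 0.1, seed = 7L) {
  stopifnot(is(epochs, "EpochArray"))
  set.seed(seed)
  n <- nTrials(epochs); m <- nElectrodes(epochs)
  times <- epochTimes(epochs)
  nt <- length(times)
  toCount <- function(x) if (x < 1) round(x * n) else as.integer(x)

  arr <- epochs@signals
  burstMask <- rep(FALSE, n)
  nb <- toCount(burstTrials)
  if (nb > 0 && burstAmp > 0) {
    bt <- sample.int(n, nb)
    burstMask[bt] <- TRUE
    t0 <- 0.05                       # inside the window of interest
    bidx <- which(times >= t0 & times < t0 + burstDuration)
    burst <- burstAmp * sin(2 * pi * burstFreq * times[bidx]) *
      sin(pi * seq_along(bidx) / length(bidx))^2     # tapered
    for (i in bt) {
      els <- sample.int(m, min(burstElectrodes, m))
      for (e in els) arr[i, e, bidx] <- arr[i, e, bidx] + burst
    }
  }

  gaze <- matrix(abs(stats::rnorm(n * nt, 0, 0.15)), n, nt)
  heog <- matrix(stats::rnorm(n * nt, 0, 2), n, nt)
  eyeMask <- rep(FALSE, n)
  ne <- toCount(eyeTrials)
  if (ne > 0) {
    et <- sample.int(n, ne)
    eyeMask[et] <- TRUE
    eidx <- which(times >= eyeOnset & times < eyeOnset + 0.25)
    gaze[et, eidx] <- gaze[et, eidx] + gazeAmp
    heog[et, times >= eyeOnset] <- heog[et, times >= eyeOnset] + heogStep
  }

  truth <- epochs@truth
  truth$burst_mask <- burstMask
  truth$eye_mask <- eyeMask
  truth$gaze <- gaze
  truth$heog <- heog
  initialize(epochs, signals = arr, truth = truth)
}
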