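#' @import methods
NULL

#' EpochArray: event-locked multichannel epochs
#'
#' Container for segmented multichannel EEG-like data: a numeric array of
#' dimension trials x electrodes x time samples, an event-locked time axis
#' in seconds, the sampling rate, a per-trial design table, electrode
#' metadata (names and 3-D positions used for interpolation
#' neighborhoods), and an optional ground-truth list filled in by the
#' synthetic generator (planted channel activations, artifact masks).
#'
#' @slot signals numeric array, trials x electrodes x samples (microvolts).
#' @slot times numeric, time axis in seconds relative to the locking event.
#' @slot sfreq sampling rate in Hz.
#' @slot trials data.frame with one row per trial (design labels).
#' @slot electrodes data.frame with columns `name`, `x`, `y`, `z`.
#' @slot lock character, the event the epochs are locked to
#'   (`"cue"` or `"placeholder"`).
#' @slot truth list of generator ground truth (may be empty).
#' @export
setClass("EpochArray",
  representation(
    signals = "array", times = "numeric", sfreq = "numeric",
    trials = "data.frame", electrodes = "data.frame",
    lock = "character", truth = "list"
  ),
  prototype(lock = "cue", truth = list())
)

setValidity("EpochArray", function(object) {
  d <- dim(object@signals)
  msg <- character()
  if (length(d) != 3) msg <- c(msg, "signals must be a 3-D array")
  if (length(d) == 3) {
    if (d[3] != length(object@times))
      msg <- c(msg, "length(times) must equal dim(signals)[3]")
    if (nrow(object@trials) > 0 && d[1] != nrow(object@trials))
      msg <- c(msg, "nrow(trials) must equal dim(signals)[1]")
    if (nrow(object@electrodes) > 0 && d[2] != nrow(object@electrodes))
      msg <- c(msg, "nrow(electrodes) must equal dim(signals)[2]")
  }
  if (length(object@sfreq) != 1 || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' AnalyticEpochs: complex band-limited analytic signals
#'
#' Same layout as [EpochArray-class] but holding the complex analytic
#' signal obtained by zero-phase band-pass filtering followed by the
#' Hilbert transform. The band edges and filter order are recorded.
#'
#' @slot signals complex array, trials x electrodes x samples.
#' @slot band numeric length-2, band edges in Hz.
#' @slot filterOrder Butterworth order used for the band-pass.
#' @slot times,sfreq,trials,lock as in [EpochArray-class].
#' @export
setClass("AnalyticEpochs",
  representation(
    signals = "array", times = "numeric", sfreq = "numeric",
    trials = "data.frame", band = "numeric", filterOrder = "numeric",
    lock = "character"
  )
)

setValidity("AnalyticEpochs", function(object) {
  msg <- character()
  if (!is.complex(object@signals)) msg <- c(msg, "signals must be complex")
  if (length(dim(object@signals)) != 3)
    msg <- c(msg, "signals must be a 3-D array")
  if (length(object@band) != 2 || object@band[1] <= 0 ||
      object@band[2] <= object@band[1])
    msg <- c(msg, "band must satisfy 0 < lo < hi")
  if (any(!is.finite(Mod(object@signals))))
    msg <- c(msg, "analytic magnitudes must be finite")
  if (length(msg)) msg else TRUE
})

#' BasisSet: circular spatial channel basis
#'
#' Half-sinusoid basis for `k` spatial channels: the base profile
#' `sin(theta / 2)^7` on an integer degree grid, circularly shifted so that
#' channel `j` peaks (at exactly 1) at its center angle. The response at
#' angular distance `d` from a channel's center is `cos(d / 2)^7`.
#'
#' @slot k number of channels.
#' @slot angles the angle grid in degrees (0..359).
#' @slot R k x length(angles) response matrix, values in [0, 1].
#' @slot centers channel peak angles in degrees.
#' @slot power exponent of the half-sinusoid.
#' @export
setClass("BasisSet",
  representation(k = "integer", angles = "numeric", R = "matrix",
                 centers = "numeric", power = "numeric")
)

setValidity("BasisSet", function(object) {
  msg <- character()
  if (nrow(object@R) != object@k) msg <- c(msg, "R must have k rows")
  if (ncol(object@R) != length(object@angles))
    msg <- c(msg, "R must have one column per angle")
  if (any(object@R < -1e-12) || any(object@R > 1 + 1e-12))
    msg <- c(msg, "responses must lie in [0, 1]")
  peaks <- apply(object@R, 1, max)
  if (any(abs(peaks - 1) > 1e-9))
    msg <- c(msg, "each channel must peak at exactly 1")
  if (length(msg)) msg else TRUE
})

#' PowerBlock: grouped power observations
#'
#' Alpha-band power aggregated per observation group (partition set x
#' location bin), kept per feature (electrode or principal component) and
#' per time sample: an observations x features x samples array, with an
#' observation table recording each group's set and cue bin, and the power
#' kind (`"evoked"`: squared magnitude of the across-trial mean analytic
#' signal; `"total"`: across-trial mean of per-trial squared magnitudes).
#'
#' @slot power numeric array, observations x features x samples; >= 0
#'   unless the features have been rotated into principal components.
#' @slot obs data.frame with columns `set` and `bin` (and optionally more).
#' @slot times time axis in seconds.
#' @slot kind `"evoked"` or `"total"`.
#' @slot reduced `TRUE` after [pcaReduce()] (component features may be
#'   negative).
#' @export
setClass("PowerBlock",
  representation(power = "array", obs = "data.frame", times = "numeric",
                 kind = "character", reduced = "logical"),
  prototype(reduced = FALSE)
)

setValidity("PowerBlock", function(object) {
  msg <- character()
  if (length(dim(object@power)) != 3)
    msg <- c(msg, "power must be a 3-D array")
  else {
    if (dim(object@power)[1] != nrow(object@obs))
      msg <- c(msg, "nrow(obs) must equal dim(power)[1]")
    if (dim(object@power)[3] != length(object@times))
      msg <- c(msg, "length(times) must equal dim(power)[3]")
  }
  if (!object@kind %in% c("evoked", "total"))
    msg <- c(msg, "kind must be 'evoked' or 'total'")
  if (!isTRUE(object@reduced) && any(object@power < -1e-12))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})
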