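#' Alpha-band analytic signal
#'
#' Band-pass filters every trial and electrode with a zero-phase
#' (forward-backward) Butterworth filter and applies the Hilbert transform
#' to obtain the complex analytic signal. Zero-phase filtering is used so
#' that time-resolved tuning latencies are not phase-shifted; epochs
#' should extend beyond the window of interest so edge effects fall
#' outside it. Deterministic.
#'
#' @param epochs an [EpochArray-class].
#' @param lo,hi band edges in Hz (default 8-13).
#' @param order Butterworth order (default 5).
#' @return an [AnalyticEpochs-class].
#' @export
bandpassHilbert <- function(epochs, lo = 8, hi = 13, order = 5) {
  stopifnot(is(epochs, "EpochArray"))
  nyq <- samplingRate(epochs) / 2
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq)
    stop("upper band edge (", hi, " Hz) must be below the Nyquist ",
         "frequency (", nyq, " Hz)", call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  # reflection padding must cover the filter's ring-down so that the
  # circular FFT convolution cannot wrap band-limited content across the
  # epoch; size it from the slowest pole's decay to 1e-4
  rho <- max(Mod(polyroot(rev(bf$a))))
  ringPad <- ceiling(log(1e-4) / log(rho))
  ana <- applyTimewise(epochs@signals, function(m)
    zeroPhaseAnalyticMat(bf$b, bf$a, m, minPad = ringPad))
  new("AnalyticEpochs", signals = ana, times = epochs@times,
      sfreq = epochs@sfreq, trials = epochs@trials,
      band = c(lo, hi), filterOrder = order, lock = epochs@lock)
}

## Shared grouped-power engine. groups: data.frame(set, bin) per trial
## (NA set = trial unused). Returns PowerBlock.
groupedPower <- function(analytic, groups, kind) {
  stopifnot(is(analytic, "AnalyticEpochs"))
  if (!all(c("set", "bin") %in% names(groups)))
    stop("groups needs 'set' and 'bin' columns", call. = FALSE)
  use <- which(!is.na(groups$set) & !is.na(groups$bin))
  if (!length(use)) stop("no usable trials in any group", call. = FALSE)
  g <- interaction(groups$set[use], groups$bin[use], drop = FALSE,
                   lex.order = TRUE)
  lev <- levels(droplevels(g))
  full <- expand.grid(bin = sort(unique(groups$bin[use])),
                      set = sort(unique(groups$set[use])))
  wanted <- paste(full$set, full$bin, sep = ".")
  missing <- setdiff(wanted, lev)
  if (length(missing))
    stop("empty observation group(s): ", paste(missing, collapse = ", "),
         " (set.bin)", call. = FALSE)
  d <- dim(analytic@signals)
  flat <- matrix(analytic@signals[use, , , drop = FALSE],
                 nrow = length(use))
  cnt <- as.vector(table(g))
  if (kind == "evoked") {
    re <- rowsum(Re(flat), g) / cnt
    im <- rowsum(Im(flat), g) / cnt
    pow <- re^2 + im^2
  } else {
    pow <- rowsum(Re(flat)^2 + Im(flat)^2, g) / cnt
  }
  ng <- nrow(pow)
  arr <- array(pow, c(ng, d[2], d[3]))
  parts <- do.call(rbind, strsplit(rownames(pow), ".", fixed = TRUE))
  obs <- data.frame(set = type.convert(parts[, 1], as.is = TRUE),
                    bin = as.integer(parts[, 2]),
                    n_trials = cnt)
  new("PowerBlock", power = arr, obs = obs, times = analytic@times,
      kind = kind)
}

#' Evoked (phase-locked) power per observation group
#'
#' For each group (partition set x cue bin), averages the complex analytic
#' signal across the group's trials and squares the magnitude of the
#' average. Only activity with a consistent phase across trials survives
#' the complex averaging, so this isolates the phase-locked component.
#'
#' @param analytic an [AnalyticEpochs-class].
#' @param groups data.frame with per-trial `set` and `bin` columns (`NA`
#'   set = trial excluded); see [partitionEquate()].
#' @return a [PowerBlock-class] with `kind = "evoked"`.
#' @export
evokedPower <- function(analytic, groups)
  groupedPower(analytic, groups, "evoked")

#' Total power per observation group
#'
#' Squares the analytic magnitude per trial first, then averages power
#' across each group's trials, capturing all band-limited activity
#' regardless of its phase relation to the locking event. Total power is
#' always at least the evoked power of the same group.
#'
#' @inheritParams evokedPower
#' @return a [PowerBlock-class] with `kind = "total"`.
#' @export
totalPower <- function(analytic, groups)
  groupedPower(analytic, groups, "total")

#' Sliding-window smoothing of power time series
#'
#' Moving average along the time axis (default window 8 samples = 15.62 ms
#' at 512 Hz, step 1). The output time axis is window-centered: sample `i`
#' of the output is stamped with the midpoint of input samples
#' `i .. i + window - 1`.
#'
#' @param power a [PowerBlock-class].
#' @param window window length in samples.
#' @param step step between output samples.
#' @return a smoothed [PowerBlock-class] (time axis shortened by
#'   `window - 1` samples before stepping).
#' @export
smoothPower <- function(power, window = 8L, step = 1L) {
  stopifnot(is(power, "PowerBlock"))
  nt <- dim(power@power)[3]
  if (window > nt) stop("window exceeds series length", call. = FALSE)
  cs <- aperm(apply(power@power, c(1, 2), cumsum), c(2, 3, 1)) # obs x f x t
  zero <- array(0, c(dim(cs)[1], dim(cs)[2], 1))
  cs0 <- array(c(zero, cs), dim(cs) + c(0, 0, 1))
  starts <- seq(1L, nt - window + 1L, by = step)
  sm <- (cs0[, , starts + window, drop = FALSE] -
           cs0[, , starts, drop = FALSE]) / window
  tOut <- (power@times[starts] + power@times[starts + window - 1L]) / 2
  initialize(power, power = sm, times = tOut)
}

#' Dimensionality reduction by principal components
#'
#' Fits an (uncentered) principal component rotation on the training
#' observations - pooled over time samples - and applies the same rotation
#' to both blocks. The rotation is orthogonal and is not centered, so the
#' no-intercept encoding GLM is preserved exactly: with `k` equal to the
#' feature count the transform is invertible and IEM results are
#' unchanged.
#'
#' @param train,test [PowerBlock-class] objects sharing a feature axis.
#' @param k number of components to keep (default 16).
#' @return list with elements `train` and `test` (reduced PowerBlocks)
#'   and `rotation` (features x k).
#' @export
pcaReduce <- function(train, test, k = 16L) {
  stopifnot(is(train, "PowerBlock"), is(test, "PowerBlock"))
  m <- dim(train@power)[2]
  if (k > m) stop("k exceeds the number of features", call. = FALSE)
  X <- matrix(aperm(train@power, c(1, 3, 2)), ncol = m)  # (obs*t) x m
  sv <- svd(X, nu = 0, nv = m)
  if (k > sum(sv$d > sv$d[1] * 1e-10))
    stop("k exceeds the rank of the training data", call. = FALSE)
  rot <- sv$v[, seq_len(k), drop = FALSE]
  project <- function(pb) {
    d <- dim(pb@power)
    Y <- matrix(aperm(pb@power, c(1, 3, 2)), ncol = m) %*% rot
    red <- aperm(array(Y, c(d[1], d[3], k)), c(1, 3, 2))
    initialize(pb, power = red, reduced = TRUE)
  }
  list(train = project(train), test = project(test), rotation = rot)
}
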