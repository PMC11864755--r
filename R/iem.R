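#' Construct the circular spatial-channel basis
#'
#' Builds `k` location-tuned channels on a 1-degree angle grid. The base
#' profile is the half sinusoid raised to the seventh power,
#' `R(theta) = sin(theta / 2)^7`, circularly shifted so that channel `j`
#' peaks (at exactly 1) at its center angle `(j - 1) * 360 / k`. The
#' response at angular distance `d` from a channel's center is
#' `cos(d / 2)^7`: 1 at the center, ~0.5745 at 45 deg, ~0.0884 at 90 deg,
#' ~0.0012 at 135 deg, and exactly 0 at 180 deg.
#'
#' @param k number of channels; must divide 360.
#' @param power exponent of the half sinusoid.
#' @return a [BasisSet-class].
#' @examples
#' b <- makeBasis()
#' b@R[1, c(1, 46, 91)]   # responses of channel 1 at 0, 45, 90 deg
#' @export
makeBasis <- function(k = 8L, power = 7) {
  if (360 %% k != 0) stop("k must divide 360", call. = FALSE)
  angles <- 0:359
  centers <- seq(0, 360 - 360 / k, by = 360 / k)
  R <- t(vapply(centers, function(c0) {
    d <- angularDiff(angles, c0)
    cos(d * pi / 360)^power          # cos(d/2) with d in degrees
  }, numeric(length(angles))))
  new("BasisSet", k = as.integer(k), angles = as.numeric(angles), R = R,
      centers = centers, power = power)
}

#' Predicted channel responses for a set of cue angles
#'
#' Evaluates the basis at arbitrary angles (continuous, not grid lookup):
#' column `j` of the result is each channel's response to angle `j`.
#'
#' @param angles cue angles in degrees, `[0, 360)`.
#' @param basis a [BasisSet-class].
#' @return `k x length(angles)` matrix `C1`.
#' @export
predictedResponses <- function(angles, basis = makeBasis()) {
  stopifnot(is(basis, "BasisSet"), all(angles >= 0 & angles < 360))
  vapply(angles, function(a) {
    d <- angularDiff(a, basis@centers)
    cos(d * pi / 360)^basis@power
  }, numeric(basis@k))
}

#' Estimate the channel-to-feature weight matrix
#'
#' Fits the encoding GLM `B1 = W C1` per time sample by least squares,
#' where `B1` is features x observations power and `C1` the predicted
#' channel responses of the training observations. All samples are solved
#' in one batched computation against the common pseudoinverse of `C1`.
#'
#' @param B1 a [PowerBlock-class] of training observations.
#' @param C1 `k x n1` predicted responses (see [predictedResponses()]).
#' @return an `iemWeights` list: `W` (features x k x samples), `times`.
#' @export
trainWeights <- function(B1, C1) {
  stopifnot(is(B1, "PowerBlock"))
  k <- nrow(C1)
  n1 <- ncol(C1)
  if (dim(B1@power)[1] != n1)
    stop("C1 must have one column per training observation", call. = FALSE)
  if (qr(C1)$rank < k)
    stop("C1 is rank deficient: the training design does not span all ",
         "channels", call. = FALSE)
  m <- dim(B1@power)[2]; nt <- dim(B1@power)[3]
  # W_t = B1_t C1' (C1 C1')^{-1}; batch over samples
  P <- t(solve(C1 %*% t(C1), C1))                    # n1 x k
  bm <- matrix(aperm(B1@power, c(2, 3, 1)), m * nt, n1)
  W <- array(bm %*% P, c(m, nt, k))
  structure(list(W = aperm(W, c(1, 3, 2)), times = B1@times, k = k),
            class = "iemWeights")
}

#' Invert the encoding model on test data
#'
#' Transforms observed test power `B2` into estimated channel responses
#' `C2` by solving `W_hat C2 = B2` per time sample (least squares).
#'
#' @param weights `iemWeights` from [trainWeights()].
#' @param B2 a [PowerBlock-class] of test observations (same features and
#'   time axis as the training block).
#' @return a `ChannelResponses` list: `C2` (observations x k x samples),
#'   `obs`, `times`.
#' @export
invertChannels <- function(weights, B2) {
  stopifnot(inherits(weights, "iemWeights"), is(B2, "PowerBlock"))
  W <- weights$W
  m <- dim(W)[1]; k <- dim(W)[2]; nt <- dim(W)[3]
  if (dim(B2@power)[2] != m || dim(B2@power)[3] != nt)
    stop("test power must match the training features and time axis",
         call. = FALSE)
  n2 <- dim(B2@power)[1]
  C2 <- array(NA_real_, c(n2, k, nt))
  for (t in seq_len(nt)) {
    Wt <- W[, , t, drop = TRUE]
    if (!is.matrix(Wt)) Wt <- matrix(Wt, m, k)
    G <- crossprod(Wt)
    if (rcond(G) < 1e-12)
      stop("estimated weight matrix is rank deficient at sample ", t,
           call. = FALSE)
    Bt <- matrix(B2@power[, , t], n2, m)
    C2[, , t] <- t(solve(G, crossprod(Wt, t(Bt))))
  }
  structure(list(C2 = C2, obs = B2@obs, times = B2@times, k = k),
            class = "ChannelResponses")
}

#' Re-center channel responses into channel tuning functions
#'
#' Circularly shifts each observation's estimated channel response vector
#' so that the channel matching the observation's cue bin sits at offset
#' 0, yielding channel tuning functions (CTFs) on a common center. The
#' offset axis is ordered 0, 45, 90, 135, 180, -135, -90, -45 degrees.
#' Three groupings are returned: per-location CTFs (one per physical cue
#' bin), distance-to-HPL CTFs (bins grouped by circular distance 0..4 from
#' the high-probability location), and the grand average across bins.
#'
#' @param responses `ChannelResponses` from [invertChannels()], or an
#'   observations x k x samples array.
#' @param bins 0-based cue bin per observation (taken from the
#'   observation table when `responses` carries one).
#' @param hplBin the high-probability bin (for the distance grouping);
#'   `NULL` skips that grouping.
#' @return a `CTF` list: `recentered` (observations x offsets x samples),
#'   `offsets`, `byLocation` (bins x offsets x samples), `byDistance`
#'   (5 x offsets x samples or NULL), `grand` (offsets x samples),
#'   `times`, `bins`.
#' @export
recenterCTF <- function(responses, bins = NULL, hplBin = NULL) {
  if (inherits(responses, "ChannelResponses")) {
    arr <- responses$C2
    times <- responses$times
    if (is.null(bins) && !is.null(responses$obs$bin))
      bins <- responses$obs$bin
  } else {
    arr <- responses
    times <- seq_len(dim(arr)[3])
  }
  k <- dim(arr)[2]
  if (is.null(bins) || anyNA(bins) || any(!bins %in% 0:(k - 1)))
    stop("each observation needs a known cue bin in 0..", k - 1,
         call. = FALSE)
  n <- dim(arr)[1]; nt <- dim(arr)[3]
  rec <- array(NA_real_, dim(arr))
  for (i in seq_len(n)) {
    shift <- (seq_len(k) - 1L + bins[i]) %% k + 1L   # channel at bin -> 0
    rec[i, , ] <- arr[i, shift, ]
  }
  offsets <- ((seq_len(k) - 1L) * (360 / k))
  offsets <- ifelse(offsets > 180, offsets - 360, offsets)

  byLoc <- array(NA_real_, c(k, k, nt))
  for (b in 0:(k - 1)) {
    idx <- which(bins == b)
    if (length(idx))
      byLoc[b + 1L, , ] <- colMeans(rec[idx, , , drop = FALSE], dims = 1)
  }
  byDist <- NULL
  if (!is.null(hplBin)) {
    d <- binDistance(0:(k - 1), hplBin, k)
    byDist <- array(NA_real_, c(max(d) + 1L, k, nt))
    for (dd in 0:max(d)) {
      idx <- which(bins %in% (which(d == dd) - 1L))
      if (length(idx))
        byDist[dd + 1L, , ] <- colMeans(rec[idx, , , drop = FALSE],
                                        dims = 1)
    }
  }
  grand <- colMeans(rec, dims = 1)
  structure(list(recentered = rec, offsets = offsets, byLocation = byLoc,
                 byDistance = byDist, grand = grand, times = times,
                 bins = bins),
            class = "CTF")
}
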