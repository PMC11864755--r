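#' Circular distance between location bins
#'
#' Distance between two of `n` equally spaced circular location bins,
#' counted in bin steps, i.e. `min(|a - b|, n - |a - b|)`. With the default
#' eight bins the result lies in 0..4; distance 4 is the single diametrically
#' opposite bin.
#'
#' @param a,b integer bin indices (0-based, in `0:(n - 1)`); recycled.
#' @param n number of bins on the circle.
#' @return integer vector of bin distances.
#' @examples
#' binDistance(0, 7)      # 1
#' binDistance(1, 5)      # 4
#' @export
binDistance <- function(a, b, n = 8L) {
  d <- abs(a - b) %% n
  as.integer(pmin(d, n - d))
}

#' Signed angular difference wrapped to (-180, 180]
#' @param a,b angles in degrees.
#' @return signed difference `a - b` in degrees, wrapped.
#' @export
angularDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## Derive a child seed from a master seed and a counter; stays below 2^31.
deriveSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %%
               2147483647)
}

#' Pink (1/f) noise
#'
#' Generates noise whose amplitude spectrum falls off as `1/f^(alpha/2)`
#' (power as `1/f^alpha`), by shaping a flat random-phase spectrum and
#' inverse transforming. Each column of the returned matrix is an
#' independent realization, scaled to unit standard deviation.
#'
#' @param n number of time samples.
#' @param m number of independent series (columns).
#' @param alpha spectral exponent of the power spectrum (1 = classic pink).
#' @return `n` x `m` numeric matrix, each column ~ zero mean, unit SD.
#' @export
pinkNoise <- function(n, m = 1L, alpha = 1) {
  nFull <- n
  n <- stats::nextn(n, c(2, 3, 5))   # stationary: truncate after synthesis
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  ph <- matrix(stats::runif(nf * m, 0, 2 * pi), nf, m)
  half <- amp * exp(1i * ph)              # recycles amp down columns
  spec <- matrix(0 + 0i, n, m)
  spec[2:(nf + 1), ] <- half
  idx <- n - seq_len(nf - (n %% 2 == 0)) + 1L
  spec[idx, ] <- Conj(half[seq_along(idx), ])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  x <- x[seq_len(nFull), , drop = FALSE]
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  x
}

## Causal IIR filtering of every column of a time x series matrix, with
## initial conditions equivalent to the input having been constant at its
## first sample since forever (the steady-state / "zi" convention). The
## numerator runs as a convolution and the denominator as a recursive
## filter, both in compiled code.
iirFilterMat <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  n <- nrow(x); m <- ncol(x)
  gain <- sum(b) / sum(a)
  if (nb > 1) {
    xa <- rbind(matrix(x[1, ], nb - 1L, m, byrow = TRUE), x)
    u <- stats::filter(xa, b, method = "convolution", sides = 1)
    u <- u[nb - 1L + seq_len(n), , drop = FALSE]
  } else {
    u <- b * x
  }
  if (na > 1) {
    init <- matrix(gain * x[1, ], na - 1L, m, byrow = TRUE)
    y <- stats::filter(u, -a[-1], method = "recursive", init = init)
  } else {
    y <- u
  }
  matrix(as.numeric(y), n, m)
}

## Zero-phase (forward-backward) filtering of each column, with odd
## reflection padding at both ends; together with the steady-state initial
## conditions of iirFilterMat this matches the usual filtfilt contract.
filtfiltMat <- function(b, a, x) {
  n <- nrow(x)
  npad <- min(3L * (max(length(a), length(b)) - 1L) * 2L, n - 1L)
  top <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[npad + 1L - seq_len(npad) + 1L, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], npad, ncol(x), byrow = TRUE) -
    x[n - seq_len(npad), , drop = FALSE]
  xe <- rbind(top, x, bot)
  y <- iirFilterMat(b, a, xe)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- iirFilterMat(b, a, y)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[npad + seq_len(n), , drop = FALSE]
}

## Complex frequency response H(e^{i w}) of a digital filter b/a at the N
## FFT bin frequencies.
freqResponse <- function(b, a, N) {
  v <- exp(-1i * 2 * pi * (0:(N - 1)) / N)     # z^-1 at each bin
  horner <- function(cf) {
    out <- rep(0 + 0i, N)
    for (cc in rev(cf)) out <- out * v + cc
    out
  }
  horner(b) / horner(a)
}

## Half-spectrum (analytic-signal) mask of length N.
hilbertMask <- function(N) {
  h <- numeric(N)
  if (N %% 2 == 0) {
    h[c(1, N / 2 + 1)] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((N + 1) / 2)] <- 2
  }
  h
}

## Fused zero-phase band-pass + analytic signal for every column of a
## time x series matrix: odd-reflection padding to a fast FFT length,
## multiplication by |H|^2 (forward-backward Butterworth magnitude
## response, zero phase) times the analytic-signal mask, inverse FFT,
## crop. minPad should cover the filter's ring-down so that circular
## wrap-around stays inside the padding.
zeroPhaseAnalyticMat <- function(b, a, x, minPad = 256L) {
  n <- nrow(x)
  N <- stats::nextn(n + 2L * min(minPad, n - 1L), c(2, 3, 5))
  npadL <- (N - n) %/% 2L
  npadR <- N - n - npadL
  refl <- function(idx, anchor) {
    2 * matrix(x[anchor, ], length(idx), ncol(x), byrow = TRUE) -
      x[idx, , drop = FALSE]
  }
  top <- refl(pmin(n, 1L + rev(seq_len(npadL))), 1L)
  bot <- refl(pmax(1L, n - seq_len(npadR)), n)
  xe <- rbind(top, x, bot)
  g <- Mod(freqResponse(b, a, N))^2 * hilbertMask(N)
  out <- stats::mvfft(stats::mvfft(xe) * g, inverse = TRUE) / N
  out[npadL + seq_len(n), , drop = FALSE]
}

## Analytic signal per column via the FFT half-spectrum method
## (positive frequencies doubled, negative zeroed).
analyticMat <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

## Apply a function mapping a (time x series) matrix to another such matrix
## over an epochs array (trials x electrodes x samples); returns an array of
## the same trial/electrode layout, possibly complex.
applyTimewise <- function(arr, fun) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])
  out <- fun(m)
  aperm(array(out, c(d[3], d[1], d[2])), c(2, 3, 1))
}
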