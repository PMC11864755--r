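## Linear-fit weights for response vs folded distance 0..4:
## slope = -cov(d, y) / var(d) with d = 0:4, sign-flipped so that a CTF
## peaked at offset 0 yields a positive value.
slopeWeights <- function() -( (0:4) - 2 ) / 10

#' Fold a re-centered CTF over its symmetric offsets
#'
#' Averages the +/-45, +/-90 and +/-135 degree offsets of an 8-channel
#' re-centered CTF, yielding 5 points at bin distances 0..4 from the
#' cued location (distance 4 = the single 180 degree channel).
#'
#' @param x length-8 vector, 8 x T matrix, or array with the offset axis
#'   identified by `offsets`.
#' @param offsets offset labels in degrees, default the [recenterCTF()]
#'   convention `0, 45, 90, 135, 180, -135, -90, -45`.
#' @return 5-vector or 5 x T matrix of folded responses.
#' @export
foldCTF <- function(x, offsets = c(0, 45, 90, 135, 180, -135, -90, -45)) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  fold <- function(d) {
    idx <- which(abs(offsets) == d)
    colMeans(x[idx, , drop = FALSE])
  }
  out <- rbind(fold(0), fold(45), fold(90), fold(135), fold(180))
  rownames(out) <- paste0("dist", 0:4)
  if (ncol(out) == 1) out[, 1] else out
}

#' CTF slope: scalar spatial selectivity
#'
#' Folds the re-centered CTF ([foldCTF()]) and fits a least-squares line
#' of response against distance (0..4), reporting minus the fitted
#' coefficient so that positive slopes indicate spatial selectivity
#' (tuning peaked at the cued location) and negative slopes indicate
#' suppression. The estimator is linear in the CTF:
#' `slope(a * ctf + b) = a * slope(ctf)`.
#'
#' @param ctf a `CTF` object (uses its grand-average profile), or an
#'   offsets-vector / offsets x T matrix / first-axis-grouped array.
#' @param profile for `CTF` objects: `"grand"`, `"byLocation"`, or
#'   `"byDistance"` (the latter two return one slope series per group).
#' @return numeric scalar, length-T vector, or groups x T matrix.
#' @examples
#' ideal <- c(1, 0.5745, 0.0884, 0.0012, 0)
#' sum(slopeFromFolded(ideal))   # ~0.2573
#' @export
ctfSlope <- function(ctf, profile = c("grand", "byLocation",
                                      "byDistance")) {
  if (inherits(ctf, "CTF")) {
    profile <- match.arg(profile)
    if (profile == "grand")
      return(slopeFromFolded(foldCTF(ctf$grand, ctf$offsets)))
    arr <- ctf[[profile]]
    out <- t(vapply(seq_len(dim(arr)[1]), function(g)
      slopeFromFolded(foldCTF(arr[g, , , drop = TRUE], ctf$offsets)),
      numeric(dim(arr)[3])))
    rownames(out) <- if (profile == "byDistance")
      paste0("dist", seq_len(nrow(out)) - 1L)
    return(out)
  }
  slopeFromFolded(foldCTF(ctf))
}

#' @rdname ctfSlope
#' @param folded 5-point folded profile (vector or 5 x T matrix) at
#'   distances 0..4.
#' @export
slopeFromFolded <- function(folded) {
  w <- slopeWeights()
  if (is.null(dim(folded))) sum(w * folded) else colSums(w * folded)
}

#' Cluster-based one-sample sign-flip permutation test
#'
#' Nonparametric inference on a subjects x time matrix (e.g. CTF slopes):
#' a one-sample t statistic is computed per time sample; contiguous runs
#' of samples whose |t| exceeds the cluster-forming threshold form
#' clusters, scored by their summed t (cluster mass). The null
#' distribution is built by randomly flipping the sign of each subject's
#' entire time series and retaining the largest absolute cluster mass of
#' each permutation; an observed cluster is significant when its mass
#' exceeds the `1 - alpha` quantile of that distribution. The p-value
#' uses the add-one correction `(1 + #{perm >= obs}) / (1 + nPerm)` and
#' so never reaches zero.
#'
#' @param values subjects x time matrix.
#' @param nPerm number of sign-flip permutations (default 1024).
#' @param alpha cluster significance level.
#' @param threshold cluster-forming threshold on |t|; default the
#'   two-tailed t critical value at `alpha` with `n - 1` df.
#' @param seed integer seed for the sign flips.
#' @return a `ClusterResult` list: `t` (time series), `clusters`
#'   (data.frame with `start`, `end`, `mass`, `p`, `sign`), `permDist`,
#'   `sigMask` (logical per sample at `alpha`), `threshold`.
#' @export
clusterPermTest <- function(values, nPerm = 1024L, alpha = 0.05,
                            threshold = NULL, seed = 1L) {
  stopifnot(is.matrix(values), nrow(values) >= 2)
  if (nPerm < 100) warning("fewer than 100 permutations: p-values crude")
  n <- nrow(values); nt <- ncol(values)
  if (is.null(threshold))
    threshold <- stats::qt(1 - alpha / 2, df = n - 1)

  tOf <- function(M) {                         # rows = datasets
    mu <- colMeans(M)
    s <- sqrt(pmax(colSums(M^2) - n * mu^2, 0) / (n - 1))
    tv <- mu * sqrt(n) / s                     # +/-Inf when variance is 0
    tv[mu == 0 & s == 0] <- 0
    tv
  }
  clustersOf <- function(tv) {
    out <- NULL
    for (sgn in c(1, -1)) {
      r <- rle(sgn * tv > threshold)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      if (length(keep))
        out <- rbind(out, data.frame(
          start = starts[keep], end = ends[keep],
          mass = vapply(keep, function(j)
            sum(tv[starts[j]:ends[j]]), 0),
          sign = sgn))
    }
    out
  }

  tObs <- tOf(values)
  obs <- clustersOf(tObs)

  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  ssq <- colSums(values^2)
  M <- (signs %*% values) / n                  # per-perm means
  permDist <- vapply(seq_len(nPerm), function(p) {
    s <- sqrt(pmax(ssq - n * M[p, ]^2, 0) / (n - 1))
    tv <- M[p, ] * sqrt(n) / s
    tv[M[p, ] == 0 & s == 0] <- 0
    cl <- clustersOf(tv)
    if (is.null(cl)) 0 else max(abs(cl$mass))
  }, 0)

  sigMask <- rep(FALSE, nt)
  if (!is.null(obs)) {
    obs$p <- vapply(obs$mass, function(m)
      (1 + sum(permDist >= abs(m))) / (1 + nPerm), 0)
    for (j in seq_len(nrow(obs)))
      if (obs$p[j] <= alpha) sigMask[obs$start[j]:obs$end[j]] <- TRUE
  } else {
    obs <- data.frame(start = integer(), end = integer(),
                      mass = numeric(), sign = numeric(), p = numeric())
  }
  structure(list(t = tObs, clusters = obs, permDist = permDist,
                 sigMask = sigMask, threshold = threshold,
                 alpha = alpha, nPerm = nPerm),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d cluster(s), threshold |t| > %.2f, %d permutations\n",
              nrow(x$clusters), x$threshold, x$nPerm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Distance-gradient regression around the high-probability location
#'
#' Tests whether spatial selectivity changes systematically with the
#' cue's bin distance (0..4) from the high-probability distractor
#' location: per subject and time sample, a least-squares line is fitted
#' to the five distance-grouped CTF slopes, and the per-subject
#' regression coefficients are submitted to the cluster-based sign-flip
#' permutation test. A negative coefficient means selectivity decreases
#' with distance from the HPL (tuning most pronounced at the
#' to-be-suppressed location).
#'
#' @param slopes subjects x time x 5 array of distance-grouped CTF
#'   slopes (distances 0..4).
#' @param ... passed to [clusterPermTest()].
#' @return a `GradientResult` list: `coef` (subjects x time), `cluster`
#'   (a `ClusterResult`).
#' @export
distanceGradient <- function(slopes, ...) {
  stopifnot(length(dim(slopes)) == 3, dim(slopes)[3] == 5)
  if (anyNA(slopes)) stop("all five distance levels must be present",
                          call. = FALSE)
  w <- ((0:4) - 2) / 10                         # d-regression weights
  co <- apply(slopes, c(1, 2), function(y) sum(w * y))
  cl <- clusterPermTest(co, ...)
  structure(list(coef = co, cluster = cl), class = "GradientResult")
}
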