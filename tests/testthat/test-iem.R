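test_that("basis responses follow cos(d/2)^7 at key angular distances", {
  b <- makeBasis()
  # channel 1 peaks at 0 deg
  expect_equal(b@R[1, 1], 1)
  expect_equal(b@R[1, 46], cos(45 * pi / 360)^7, tolerance = 1e-12)
  expect_equal(b@R[1, 46], 0.5745, tolerance = 1e-3)
  expect_equal(b@R[1, 91], 0.0884, tolerance = 1e-3)
  expect_lt(abs(b@R[1, 136] - 0.0012), 1e-3)
  expect_equal(b@R[1, 181], 0, tolerance = 1e-9)
  # rows are circular shifts of one another
  expect_equal(b@R[3, ], b@R[1, ((0:359 - 90) %% 360) + 1],
               tolerance = 1e-12)
  expect_error(makeBasis(k = 7), "divide")
})

test_that("predicted responses evaluate the basis at arbitrary angles", {
  b <- makeBasis()
  C <- predictedResponses(c(45, 45, 22.5), b)
  expect_equal(C[2, 1], 1)                      # cue at channel 2 center
  expect_identical(C[, 1], C[, 2])              # identical angles
  # midway cue: two adjacent channels equal at cos(11.25 deg)^7
  expect_equal(C[1, 3], C[2, 3], tolerance = 1e-12)
  expect_equal(C[1, 3], cos(11.25 * pi / 180)^7, tolerance = 1e-12)
  expect_equal(C[1, 3], 0.873, tolerance = 1e-3)
})

test_that("weight training recovers a planted weight matrix exactly", {
  set.seed(11)
  b <- makeBasis()
  m <- 12; nt <- 4
  Wtrue <- matrix(rnorm(m * 8), m, 8)
  C1 <- predictedResponses(rep(seq(0, 315, by = 45), 2), b)
  arr <- array(NA_real_, c(16, m, nt))
  for (t in seq_len(nt)) arr[, , t] <- t(Wtrue %*% C1)
  B1 <- toyPower(abs(arr), obs = data.frame(set = rep(1:2, each = 8),
                                            bin = rep(0:7, 2)))
  # use the signed array via the reduced flag (components may be negative)
  B1 <- initialize(B1, power = arr, reduced = TRUE)
  w <- trainWeights(B1, C1)
  for (t in seq_len(nt))
    expect_lt(max(abs(w$W[, , t] - Wtrue)), 1e-8)

  # zero data give zero weights
  B0 <- initialize(B1, power = array(0, dim(arr)))
  expect_true(all(trainWeights(B0, C1)$W == 0))

  # rank-deficient design errors
  C1bad <- predictedResponses(rep(0, 16), b)
  expect_error(trainWeights(B1, C1bad), "rank")
})

test_that("weight estimates are unbiased under additive noise", {
  set.seed(21)
  b <- makeBasis()
  m <- 6
  Wtrue <- matrix(rnorm(m * 8), m, 8)
  C1 <- predictedResponses(rep(seq(0, 315, by = 45), 3), b)
  nRep <- 400
  errs <- matrix(NA_real_, nRep, m * 8)
  for (r in seq_len(nRep)) {
    B <- t(Wtrue %*% C1) + matrix(rnorm(24 * m, 0, 0.5), 24, m)
    pb <- new("PowerBlock", power = array(B, c(24, m, 1)),
              obs = data.frame(set = rep(1:3, each = 8),
                               bin = rep(0:7, 3)),
              times = 0, kind = "total", reduced = TRUE)
    errs[r, ] <- as.vector(trainWeights(pb, C1)$W[, , 1] - Wtrue)
  }
  meanErr <- colMeans(errs)
  seErr <- apply(errs, 2, sd) / sqrt(nRep)
  expect_true(all(abs(meanErr) < 3.5 * seErr + 1e-12))
})

test_that("model inversion recovers planted channel responses", {
  set.seed(31)
  Wtrue <- matrix(runif(10 * 8), 10, 8)
  C1 <- predictedResponses(rep(seq(0, 315, by = 45), 2))
  B1 <- new("PowerBlock",
            power = array(t(Wtrue %*% C1), c(16, 10, 2)),
            obs = data.frame(set = rep(1:2, each = 8), bin = rep(0:7, 2)),
            times = 1:2, kind = "total")
  w <- trainWeights(B1, C1)
  cvec <- c(0.3, 0.7, 0, 0, 0, 0, 0, 0)
  B2 <- new("PowerBlock",
            power = array(rep(Wtrue %*% cvec, times = 2), c(1, 10, 2)),
            obs = data.frame(set = 3, bin = 0),
            times = 1:2, kind = "total")
  r <- invertChannels(w, B2)
  expect_lt(max(abs(r$C2[1, , 1] - cvec)), 1e-8)

  # zero observation -> zero response
  B2z <- initialize(B2, power = array(0, c(1, 10, 2)))
  expect_true(all(invertChannels(w, B2z)$C2 == 0))

  # mismatched feature axis errors
  B2bad <- initialize(B2, power = array(1, c(1, 4, 2)))
  expect_error(invertChannels(w, B2bad), "match")
})

test_that("noiseless round trip recovers the basis-predicted responses", {
  b <- makeBasis()
  mix <- forwardModel(nElectrodes = 16, noisePink = 0,
                      noiseWhite = 0)$mixing
  angles <- seq(0, 315, by = 45)
  C1 <- predictedResponses(rep(angles, 2), b)
  B1 <- new("PowerBlock", power = array(t(mix %*% C1), c(16, 16, 1)),
            obs = data.frame(set = rep(1:2, each = 8), bin = rep(0:7, 2)),
            times = 0, kind = "total")
  Cheld <- predictedResponses(angles, b)
  B2 <- new("PowerBlock", power = array(t(mix %*% Cheld), c(8, 16, 1)),
            obs = data.frame(set = 3, bin = 0:7),
            times = 0, kind = "total")
  r <- invertChannels(trainWeights(B1, C1), B2)
  expect_lt(max(abs(r$C2[, , 1] - t(Cheld))), 1e-6)
})

test_that("re-centering aligns the cued channel at offset zero", {
  # indicator response at the cue channel
  resp <- array(0, c(1, 8, 2)); resp[1, 3, ] <- 1
  ctf <- recenterCTF(resp, bins = 2L, hplBin = 0L)
  expect_equal(ctf$recentered[1, , 1], c(1, rep(0, 7)))
  expect_equal(ctf$offsets, c(0, 45, 90, 135, 180, -135, -90, -45))

  # planted basis-shaped peak re-centers to the ideal profile for any bin
  b <- makeBasis()
  for (bin in c(0L, 3L, 7L)) {
    resp <- array(b@R[, bin * 45 + 1], c(1, 8, 1))
    ctf <- recenterCTF(resp, bins = bin)
    expect_equal(ctf$recentered[1, 1, 1], 1, tolerance = 1e-12)
    expect_equal(foldCTF(ctf$recentered[1, , 1]), idealFolded(),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(recenterCTF(resp, bins = 9L), "bin")
})

test_that("distance grouping uses circular bin distance to the HPL", {
  k <- 8
  resp <- array(rep(1:8, each = 8), c(8, k, 1))  # obs value = bin + 1
  ctf <- recenterCTF(resp, bins = 0:7, hplBin = 2L)
  # dist 1 group = bins 1 and 3 -> mean response value (2 + 4) / 2 = 3
  expect_equal(ctf$byDistance[2, 1, 1], 3)
  # dist 4 group = single bin (2 + 4) %% 8 = 6 -> value 7
  expect_equal(ctf$byDistance[5, 1, 1], 7)
})

test_that("re-centering is rotationally equivariant", {
  set.seed(41)
  mix <- forwardModel(nElectrodes = 16, noisePink = 0,
                      noiseWhite = 0)$mixing
  b <- makeBasis()
  runFor <- function(rot) {
    angles <- (seq(0, 315, by = 45) + rot * 45) %% 360
    bins <- ((0:7) + rot) %% 8
    C1 <- predictedResponses(rep(angles, 2), b)
    B1 <- new("PowerBlock", power = array(t(mix %*% C1), c(16, 16, 1)),
              obs = data.frame(set = rep(1:2, each = 8),
                               bin = rep(bins, 2)),
              times = 0, kind = "total")
    B2 <- new("PowerBlock",
              power = array(t(mix %*% predictedResponses(angles, b)),
                            c(8, 16, 1)),
              obs = data.frame(set = 3, bin = bins),
              times = 0, kind = "total")
    Ctr <- predictedResponses(
      b@centers[B1@obs$bin + 1L], b)
    recenterCTF(invertChannels(trainWeights(B1, Ctr), B2))$grand
  }
  expect_equal(runFor(0), runFor(1), tolerance = 1e-9)
})
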