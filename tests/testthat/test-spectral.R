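test_that("a passband sinusoid's analytic envelope recovers its amplitude", {
  ep <- sinusoidEpochs(10, amp = 3)
  an <- bandpassHilbert(ep)
  env <- Mod(epochData(an)[1, 1, ])
  mid <- epochTimes(an) >= -0.25 & epochTimes(an) <= 0.5
  # mean gain in the window of interest within 1%, pointwise ripple < 4%
  expect_lt(abs(mean(env[mid]) / 3 - 1), 0.01)
  expect_lt(max(abs(env[mid] / 3 - 1)), 0.04)
})

test_that("stop-band content is suppressed and zero maps to zero", {
  an30 <- bandpassHilbert(sinusoidEpochs(30, amp = 3))
  mid <- epochTimes(an30) >= -0.25 & epochTimes(an30) <= 0.5
  expect_lt(max(Mod(epochData(an30)[1, 1, mid])), 0.05 * 3)

  z <- bandpassHilbert(toyEpochs(array(0, c(1, 1, 900))))
  expect_true(all(Mod(epochData(z)) == 0))
})

test_that("the band-pass + Hilbert operator is linear and deterministic", {
  set.seed(12)
  a1 <- array(rnorm(2 * 2 * 900), c(2, 2, 900))
  a2 <- array(rnorm(2 * 2 * 900), c(2, 2, 900))
  f <- function(a) epochData(bandpassHilbert(toyEpochs(a)))
  expect_equal(f(a1 + a2), f(a1) + f(a2), tolerance = 1e-9)
  expect_identical(f(a1), f(a1))
})

test_that("band edges are validated against Nyquist", {
  ep <- toyEpochs(array(0, c(1, 1, 600)), sfreq = 100)
  expect_error(bandpassHilbert(ep, 8, 60), "Nyquist")
  expect_error(bandpassHilbert(ep, 0, 13), "lo")
})

test_that("the FFT spectral path agrees with time-domain filtfilt", {
  # two independent implementations of the zero-phase Butterworth:
  # the production FFT route vs the causal forward-backward recursion
  set.seed(13)
  sf <- 512
  x <- matrix(rnorm(900 * 4), 900, 4)
  bf <- signal::butter(5, c(8, 13) / (sf / 2), "pass")
  fft_route <- Re(pingCTF:::zeroPhaseAnalyticMat(bf$b, bf$a, x,
                                                 minPad = 256))
  td_route <- pingCTF:::filtfiltMat(bf$b, bf$a, x)
  inner <- 250:650
  expect_lt(max(abs(fft_route[inner, ] - td_route[inner, ])),
            0.05)
  expect_gt(stats::cor(as.vector(fft_route[inner, ]),
                       as.vector(td_route[inner, ])), 0.98)
  # and the recursion itself matches signal::filtfilt away from edges
  y3 <- signal::filtfilt(bf, x[, 1])
  expect_gt(stats::cor(td_route[inner, 1], y3[inner]), 0.98)
})

test_that("evoked power cancels random phase; total power does not", {
  # two trials with analytic values z and -z: evoked 0, total |z|^2
  z <- complex(modulus = 2, argument = 0.7)
  arr <- array(c(z, -z), c(2, 1, 1))
  an <- toyAnalytic(arr)
  groups <- data.frame(set = c(1, 1), bin = c(0, 0))
  expect_equal(as.vector(epochData(evokedPower(an, groups))), 0)
  expect_equal(as.vector(epochData(totalPower(an, groups))), 4)

  # magnitudes 1 and 3 with equal phase: total (1 + 9) / 2 = 5
  arr2 <- array(complex(modulus = c(1, 3), argument = 0), c(2, 1, 1))
  expect_equal(as.vector(epochData(totalPower(toyAnalytic(arr2),
                                              groups))), 5)

  # a one-trial group: evoked equals total
  arr3 <- array(complex(modulus = 2.5, argument = 1.1), c(1, 1, 3))
  g1 <- data.frame(set = 1, bin = 0)
  expect_equal(epochData(evokedPower(toyAnalytic(arr3), g1)),
               epochData(totalPower(toyAnalytic(arr3), g1)))
})

test_that("random-phase trials: total tends to A^2 while evoked vanishes", {
  set.seed(14)
  n <- 1000; A <- 1.5
  arr <- array(complex(modulus = A, argument = runif(n, 0, 2 * pi)),
               c(n, 1, 1))
  an <- toyAnalytic(arr)
  g <- data.frame(set = rep(1, n), bin = rep(0, n))
  tot <- as.vector(epochData(totalPower(an, g)))
  ev <- as.vector(epochData(evokedPower(an, g)))
  expect_equal(tot, A^2, tolerance = 1e-9)
  expect_lt(ev, 3 * A^2 / n * 3)     # mean resultant ~ O(1/sqrt(n))
})

test_that("total power dominates evoked power on any grouping", {
  set.seed(15)
  arr <- array(complex(real = rnorm(40 * 3 * 10),
                       imaginary = rnorm(40 * 3 * 10)), c(40, 3, 10))
  an <- toyAnalytic(arr)
  g <- data.frame(set = rep(1:2, 20), bin = rep(0:3, each = 10))
  ev <- epochData(evokedPower(an, g))
  tot <- epochData(totalPower(an, g))
  expect_true(all(tot - ev >= -1e-9 * tot))
})

test_that("empty observation groups raise an error naming the group", {
  arr <- array(complex(modulus = 1, argument = 0), c(4, 1, 1))
  an <- toyAnalytic(arr, trials = data.frame(cue_bin = c(0, 0, 1, 1)))
  g <- data.frame(set = c(1, 1, 2, 2), bin = c(0, 0, 1, 1))
  expect_error(evokedPower(an, g), "2.0")
})

test_that("sliding-window smoothing behaves like a moving average", {
  # constant series unchanged
  cst <- toyPower(array(2.5, c(1, 1, 40)))
  sm <- smoothPower(cst, window = 8)
  expect_true(all(epochData(sm) == 2.5))
  expect_equal(dim(epochData(sm))[3], 33)

  # unit impulse spreads into 8 samples of 1/8
  imp <- array(0, c(1, 1, 30)); imp[1, 1, 15] <- 1
  smi <- as.vector(epochData(smoothPower(toyPower(imp), window = 8)))
  expect_equal(sum(smi > 0), 8)
  expect_equal(max(smi), 1 / 8)
  expect_equal(sum(smi), 1)

  # global mean preserved up to edges, time axis window-centered
  set.seed(16)
  p <- toyPower(array(runif(50), c(1, 1, 50)),
                times = NULL)
  smp <- smoothPower(p, window = 5)
  expect_equal(mean(epochData(smp)),
               mean(vapply(1:46, function(i)
                 mean(epochData(p)[1, 1, i:(i + 4)]), 0)))
  expect_equal(smp@times[1], mean(p@times[1:5]))
  expect_error(smoothPower(p, window = 100), "window")
})

test_that("PCA reduction preserves low-rank structure and the GLM", {
  set.seed(17)
  # rank-2 data: k = 2 reconstructs exactly
  U <- matrix(rnorm(10 * 2), 10, 2)
  V <- matrix(rnorm(2 * 6), 2, 6)
  X <- U %*% V                               # 10 obs x 6 features
  pb <- toyPower(array(X, c(10, 6, 1)),
                 obs = data.frame(set = 1, bin = 0:9), reduced = TRUE)
  red <- pcaReduce(pb, pb, k = 2)
  back <- epochData(red$train)[, , 1] %*% t(red$rotation)
  expect_equal(back, X, tolerance = 1e-9)
  expect_error(pcaReduce(pb, pb, k = 5), "rank")

  # loadings are orthonormal
  expect_equal(crossprod(red$rotation), diag(2), tolerance = 1e-12)

  # with k = feature count the IEM is unchanged
  b <- makeBasis()
  mix <- forwardModel(nElectrodes = 12, noisePink = 0,
                      noiseWhite = 0)$mixing
  C1 <- predictedResponses(rep(seq(0, 315, by = 45), 2), b)
  noise <- matrix(abs(rnorm(16 * 12, 0, 0.01)), 16, 12)  # full rank
  B1 <- new("PowerBlock", power = array(t(mix %*% C1) + noise,
                                        c(16, 12, 1)),
            obs = data.frame(set = rep(1:2, each = 8), bin = rep(0:7, 2)),
            times = 0, kind = "total")
  B2 <- new("PowerBlock",
            power = array(t(mix %*% predictedResponses(
              seq(0, 315, by = 45), b)), c(8, 12, 1)),
            obs = data.frame(set = 3, bin = 0:7), times = 0,
            kind = "total")
  direct <- invertChannels(trainWeights(B1, C1), B2)$C2
  redf <- pcaReduce(B1, B2, k = 12)
  viaPca <- invertChannels(trainWeights(redf$train, C1), redf$test)$C2
  expect_equal(viaPca, direct, tolerance = 1e-8)
})
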