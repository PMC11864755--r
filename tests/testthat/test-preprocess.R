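# epochs of pink+white background noise for artifact testing
noiseEpochs <- function(n = 60, m = 16, sfreq = 512, dur = 0.8,
                        seed = 1) {
  set.seed(seed)
  nt <- round(dur * sfreq)
  arr <- array(rnorm(n * m * nt, 0, 1), c(n, m, nt)) +
    aperm(array(pinkNoise(nt, n * m), c(nt, n, m)), c(2, 3, 1))
  toyEpochs(arr, sfreq = sfreq, t0 = -0.2)
}

test_that("artifact injection is inert at zero amplitude and marks truth", {
  ep <- noiseEpochs(n = 20)
  same <- injectArtifacts(ep, burstTrials = 0.5, burstAmp = 0,
                          eyeTrials = 0, seed = 2)
  expect_identical(same@signals, ep@signals)

  inj <- injectArtifacts(ep, burstTrials = 0.1, burstAmp = 40,
                         eyeTrials = 0.2, seed = 2)
  expect_equal(sum(groundTruth(inj)$burst_mask), 2)
  expect_equal(sum(groundTruth(inj)$eye_mask), 4)
  expect_false(identical(inj@signals, ep@signals))
})

test_that("muscle screening flags bursts, repairs single electrodes, and drops broad ones", {
  ep <- noiseEpochs(n = 60, m = 16)
  # 6 epochs with a one-electrode burst: flagged but repairable
  inj <- injectArtifacts(ep, burstTrials = 6L, burstElectrodes = 1L,
                         burstAmp = 40, eyeTrials = 0, seed = 3)
  res <- detectMuscleArtifacts(inj, window = c(-0.1, 0.5))
  truth <- which(groundTruth(inj)$burst_mask)
  expect_setequal(res$report$flagged, truth)
  expect_length(res$report$dropped, 0)
  expect_equal(nTrials(res$epochs), 60)
  expect_true(all(res$report$interpolated$epoch %in% truth))

  # clean data: nothing dropped
  clean <- detectMuscleArtifacts(ep, window = c(-0.1, 0.5))
  expect_length(clean$report$dropped, 0)

  # bursts across 8 electrodes at once cannot be repaired with 5
  broad <- injectArtifacts(ep, burstTrials = 6L, burstElectrodes = 8L,
                           burstAmp = 40, eyeTrials = 0, seed = 4)
  resB <- detectMuscleArtifacts(broad, window = c(-0.1, 0.5))
  truthB <- which(groundTruth(broad)$burst_mask)
  expect_setequal(resB$report$dropped, truthB)
  expect_equal(nTrials(resB$epochs), 60 - length(truthB))
})

test_that("screening hits injected bursts with few false positives", {
  ep <- noiseEpochs(n = 100, m = 16, seed = 5)
  inj <- injectArtifacts(ep, burstTrials = 10L, burstElectrodes = 2L,
                         burstAmp = 40, eyeTrials = 0, seed = 6)
  res <- detectMuscleArtifacts(inj, window = c(-0.1, 0.5))
  truth <- groundTruth(inj)$burst_mask
  sens <- mean(which(truth) %in% res$report$flagged)
  fpr <- mean(setdiff(1:100, which(truth)) %in% res$report$flagged)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("band edges above Nyquist are rejected", {
  ep <- noiseEpochs(n = 4, sfreq = 256)
  expect_error(detectMuscleArtifacts(ep), "Nyquist")
})

test_that("electrode interpolation satisfies its contract", {
  # an electrode identical to all neighbors is unchanged
  m <- 8; nt <- 100
  base <- matrix(rnorm(nt), 1, nt)
  arr <- array(rep(base, each = m), c(1, m, nt))
  ep <- toyEpochs(arr, sfreq = 100)
  out <- interpolateElectrode(ep, 3)
  expect_equal(out@signals[1, 3, ], arr[1, 3, ], tolerance = 1e-12)

  # a burst riding on the neighbors' signal is removed
  arr2 <- arr
  arr2[1, 3, 40:60] <- arr2[1, 3, 40:60] + 50
  ep2 <- toyEpochs(arr2, sfreq = 100)
  out2 <- interpolateElectrode(ep2, 3)
  expect_gt(cor(out2@signals[1, 3, ], arr[1, 3, ]), 0.99)
  expect_lt(max(abs(out2@signals[1, 3, 40:60] - arr[1, 3, 40:60])), 1)

  # idempotent
  out3 <- interpolateElectrode(out2, 3)
  expect_equal(out3@signals, out2@signals, tolerance = 1e-12)
})

test_that("gaze-based eye rejection applies the 1.2 degree rule", {
  ep <- noiseEpochs(n = 3, m = 4, dur = 0.8)   # t0 = -0.2 s
  nt <- length(epochTimes(ep))
  gaze <- matrix(0.2, 3, nt)
  tidx <- which(abs(epochTimes(ep) - 0.2) < 0.01)
  gaze[1, tidx] <- 1.3          # excursion inside the window -> reject
  gaze[2, ] <- 1.1              # below threshold everywhere -> keep
  gaze[3, epochTimes(ep) > 0.4] <- 5  # outside placeholder window -> keep
  keep <- rejectEye(ep, gaze = gaze, window = c(-0.2, 0.3))
  expect_equal(keep, c(FALSE, TRUE, TRUE))
})

test_that("HEOG step detection uses the sliding half-window contrast", {
  ep <- noiseEpochs(n = 3, m = 4, dur = 0.8)
  nt <- length(epochTimes(ep))
  heog <- matrix(0, 3, nt)
  heog[1, epochTimes(ep) >= 0.1] <- 20    # 20 uV step -> reject
  heog[2, epochTimes(ep) >= 0.1] <- 10    # 10 uV step -> keep
  keep <- rejectEye(ep, heog = heog, window = c(-0.2, 0.3))
  expect_equal(keep, c(FALSE, TRUE, TRUE))
  expect_error(rejectEye(ep), "gaze")
})

test_that("injected eye artifacts are caught via the stored aux traces", {
  ep <- noiseEpochs(n = 40, m = 8)
  inj <- injectArtifacts(ep, burstTrials = 0, burstAmp = 0,
                         eyeTrials = 8L, gazeAmp = 2, heogStep = 20,
                         eyeOnset = 0.1, seed = 8)
  keepGaze <- rejectEye(inj, gaze = groundTruth(inj)$gaze,
                        window = c(-0.2, 0.3))
  expect_setequal(which(!keepGaze), which(groundTruth(inj)$eye_mask))
  keepHeog <- rejectEye(inj, heog = groundTruth(inj)$heog,
                        window = c(-0.2, 0.3))
  expect_setequal(which(!keepHeog), which(groundTruth(inj)$eye_mask))
})
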