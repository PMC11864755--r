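# Shared fixture builders; all fixtures are generated in code.

# Minimal electrode table: points on a circle (z = 0) plus apex.
toyLayout <- function(m) {
  ang <- seq(0, 2 * pi, length.out = m + 1)[seq_len(m)]
  data.frame(name = paste0("E", seq_len(m)),
             x = cos(ang), y = sin(ang), z = 0)
}

# EpochArray holding an arbitrary trials x electrodes x samples array.
toyEpochs <- function(arr, sfreq = 512, t0 = -0.75, lock = "placeholder",
                      trials = NULL) {
  nt <- dim(arr)[3]
  times <- t0 + (seq_len(nt) - 1) / sfreq
  if (is.null(trials))
    trials <- data.frame(cue_bin = rep(0L, dim(arr)[1]))
  new("EpochArray", signals = arr, times = times, sfreq = sfreq,
      trials = trials, electrodes = toyLayout(dim(arr)[2]), lock = lock)
}

# Epochs of pure sinusoids (same on every trial/electrode).
sinusoidEpochs <- function(freq, amp = 1, nTrial = 1, m = 1, sfreq = 512,
                           t0 = -0.75, t1 = 1.0, phase = 0) {
  times <- seq(t0, t1, by = 1 / sfreq)
  x <- amp * cos(2 * pi * freq * times + phase)
  arr <- array(rep(x, each = nTrial * m), c(nTrial, m, length(times)))
  toyEpochs(arr, sfreq = sfreq, t0 = t0)
}

# PowerBlock straight from an array.
toyPower <- function(arr, obs = NULL, kind = "total", times = NULL,
                     reduced = FALSE) {
  if (is.null(obs))
    obs <- data.frame(set = rep(1L, dim(arr)[1]),
                      bin = seq_len(dim(arr)[1]) - 1L)
  if (is.null(times)) times <- seq_len(dim(arr)[3])
  new("PowerBlock", power = arr, obs = obs, times = times, kind = kind,
      reduced = reduced)
}

# AnalyticEpochs from a complex array.
toyAnalytic <- function(arr, sfreq = 512, trials = NULL) {
  nt <- dim(arr)[3]
  if (is.null(trials))
    trials <- data.frame(cue_bin = rep(0L, dim(arr)[1]))
  new("AnalyticEpochs", signals = arr,
      times = (seq_len(nt) - 1) / sfreq, sfreq = sfreq, trials = trials,
      band = c(8, 13), filterOrder = 5, lock = "placeholder")
}

# Ideal folded CTF profile of the sin^7 basis at distances 0..4.
idealFolded <- function() cos(c(0, 45, 90, 135, 180) * pi / 360)^7
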