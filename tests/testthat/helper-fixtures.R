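# engineered count tensors with exactly controlled trial-averaged rates:
# counts for each bin are spread as evenly as possible over trials, so the
# trial-averaged rate equals `rate` exactly (rate * binSize * nTrials must be
# a whole number)

# default baseline: 25 bins with rates mean 4 Hz, sd 1 Hz (sample sd, n-1)
baselineRates4 <- function() c(rep(3, 12), rep(5, 12), 4)

makeCountTensor <- function(postRates, baselineRates = baselineRates4(),
                            nTrials = 10, binSize = 0.2, nUnits = 1) {
  rates <- c(baselineRates, postRates)
  nb <- length(rates)
  w <- c(length(baselineRates), length(postRates)) * binSize
  arr <- array(0L, dim = c(nUnits, nTrials, nb),
               dimnames = list(sprintf("u%02d", seq_len(nUnits)),
                               seq_len(nTrials), NULL))
  for (b in seq_len(nb)) {
    total <- rates[b] * binSize * nTrials
    stopifnot(abs(total - round(total)) < 1e-9)
    total <- round(total)
    per <- rep(total %/% nTrials, nTrials)
    extra <- total %% nTrials
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    for (u in seq_len(nUnits)) arr[u, , b] <- as.integer(per)
  }
  new("CountTensor", counts = arr, binSize = binSize, window = w,
      binStarts = seq(-w[1], w[2] - binSize, by = binSize))
}

# hand-built two-trial toy session with one unit
toySession <- function() {
  SpikeSession("toy", "u1",
               data.frame(unit_id = "u1", trial_id = c(1L, 1L, 2L),
                          t_s = c(-0.5, 0.1, 1.3)),
               data.frame(trial_id = 1:2, stimulus = c("LS", "HS"),
                          withdrawal_latency_s = c(1.2, NA),
                          laser_mW = c(150, 250)))
}

# a small strongly separable two-class session
separableSession <- function(seed = 1, nUnits = 5, nTrials = 15,
                             amplitude = 10) {
  cfg <- generatorConfig(nUnits = nUnits, nTrialsPerClass = nTrials,
                         baselineMeanLog = log(2), baselineSdLog = 0,
                         amplitudes = c(NS = 0, LS = 0, HS = amplitude),
                         fractionResponsive = 1)
  simulateSession(cfg, c("NS", "HS"), seed = seed)
}
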