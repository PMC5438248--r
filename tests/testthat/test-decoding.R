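test_that("feature dimensionality grows from C to 50C", {
  s <- simulateSession(generatorConfig(nUnits = 7, nTrialsPerClass = 6),
                       c("NS", "HS"), seed = 2)
  fs <- buildCumulativeFeatures(s, 0.1, 5.0)
  expect_equal(length(binStarts(fs)), 50L)
  expect_equal(ncol(featureMatrix(fs, 1)), 7L)
  expect_equal(ncol(featureMatrix(fs, 50)), 350L)
  expect_equal(nUnits(fs), 7L)
})

test_that("a single early spike accumulates into every later bin", {
  tr <- data.frame(trial_id = 1:2, stimulus = c("NS", "HS"),
                   withdrawal_latency_s = NA_real_, laser_mW = c(50, 250))
  s <- SpikeSession("one", "u1",
                    data.frame(unit_id = "u1", trial_id = 1L, t_s = 0.05), tr)
  fs <- buildCumulativeFeatures(s, 0.1, 5.0)
  expect_equal(unname(fs@cum[1, 1, ]), rep(1, 50))  # cumulative count
  expect_equal(unname(fs@cum[2, 1, ]), rep(0, 50))
})

test_that("cumulative features match manual binning", {
  tr <- data.frame(trial_id = 1:2, stimulus = c("NS", "HS"),
                   withdrawal_latency_s = NA_real_, laser_mW = c(50, 250))
  s <- SpikeSession("man", c("u1", "u2"),
                    data.frame(unit_id = c("u1", "u1", "u2", "u1"),
                               trial_id = c(1L, 1L, 1L, 2L),
                               t_s = c(0.05, 0.25, 0.11, 0.31)), tr)
  fs <- buildCumulativeFeatures(s, 0.1, 0.5)
  # trial 1, u1: spikes in bins 1 and 3 -> cumulative 1,1,2,2,2
  expect_equal(unname(fs@cum[1, 1, ]), c(1, 1, 2, 2, 2))
  expect_equal(unname(fs@cum[1, 2, ]), c(0, 1, 1, 1, 1))
  expect_equal(unname(fs@cum[2, 1, ]), c(0, 0, 0, 1, 1))
  # feature matrix at bin 3 concatenates per-bin counts of bins 1..3
  m <- featureMatrix(fs, 3)
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(unname(m[1, ]), c(1, 0, 0, 1, 1, 0))
})

test_that("decoder inputs are validated", {
  s3 <- simulateSession(generatorConfig(nUnits = 2, nTrialsPerClass = 6),
                        c("NS", "LS", "HS"), seed = 4)
  expect_error(buildCumulativeFeatures(s3), "exactly 2 stimulus classes")
  s1 <- simulateSession(generatorConfig(nUnits = 2, nTrialsPerClass = 6),
                        "HS", seed = 4)
  expect_error(buildCumulativeFeatures(s1), "exactly 2 stimulus classes")
  s <- simulateSession(generatorConfig(nUnits = 2, nTrialsPerClass = 3),
                       c("NS", "HS"), seed = 4)
  fs <- buildCumulativeFeatures(s, 0.1, 1.0)
  expect_error(evaluateDecoder(fs, folds = 5), "at least as many trials")
  expect_error(permutationChance(fs, nPermutations = 0), "nPermutations")
})

test_that("uninformative features decode at chance at every bin", {
  cfg <- generatorConfig(nUnits = 4, nTrialsPerClass = 12,
                         amplitudes = c(NS = 0, LS = 0, HS = 0))
  s <- simulateSession(cfg, c("NS", "HS"), seed = 40)
  fs <- buildCumulativeFeatures(s, 0.1, 1.0)
  r <- evaluateDecoder(fs, folds = 4, mcRepeats = 5, seed = 41)
  expect_true(all(accuracy(r) > 0.2 & accuracy(r) < 0.8))
  expect_lt(abs(mean(accuracy(r)) - 0.5), 0.12)
})

test_that("well-separated classes are decoded nearly perfectly by late bins", {
  s <- separableSession(seed = 50, nUnits = 5, nTrials = 15)
  fs <- buildCumulativeFeatures(s, 0.1, 2.0)
  r <- evaluateDecoder(fs, folds = 5, mcRepeats = 2, seed = 51)
  expect_gte(max(accuracy(r)), 0.9)
  expect_true(all(accuracySEM(r) >= 0))
  expect_true(all(accuracy(r) >= 0 & accuracy(r) <= 1))
})

test_that("decoding is invariant to unit ordering", {
  s <- separableSession(seed = 60, nUnits = 4, nTrials = 10, amplitude = 6)
  sp <- spikes(s)
  s2 <- SpikeSession(sessionId(s), rev(unitIds(s)), sp, trials(s))
  fs1 <- buildCumulativeFeatures(s, 0.1, 1.0)
  fs2 <- buildCumulativeFeatures(s2, 0.1, 1.0)
  r1 <- evaluateDecoder(fs1, mcRepeats = 2, seed = 61)
  r2 <- evaluateDecoder(fs2, mcRepeats = 2, seed = 61)
  expect_equal(accuracy(r1), accuracy(r2), tolerance = 1e-12)
})

test_that("balanced-label permutation chance sits near 50%", {
  s <- separableSession(seed = 70, nUnits = 4, nTrials = 10, amplitude = 8)
  fs <- buildCumulativeFeatures(s, 0.1, 1.0)
  ch <- permutationChance(fs, nPermutations = 30, folds = 5, seed = 71)
  per <- attr(ch, "per_permutation")
  se <- sd(per) / sqrt(length(per))
  expect_lt(abs(mean(ch) - 0.5), max(3 * se, 0.05))
})

test_that("chance level does not depend on the evoked amplitude", {
  mk <- function(a, seed) {
    cfg <- generatorConfig(nUnits = 4, nTrialsPerClass = 10,
                           baselineMeanLog = log(2), baselineSdLog = 0,
                           amplitudes = c(NS = 0, LS = 0, HS = a),
                           fractionResponsive = 1)
    buildCumulativeFeatures(simulateSession(cfg, c("NS", "HS"), seed = seed),
                            0.1, 1.0)
  }
  ch0 <- permutationChance(mk(0, 80), nPermutations = 25, seed = 81)
  chBig <- permutationChance(mk(10, 80), nPermutations = 25, seed = 81)
  expect_lt(abs(mean(ch0) - mean(chBig)), 0.08)
})

test_that("session aggregation applies the minimum-population filter", {
  mkRes <- function(id, C, acc) new("DecodingResult", sessionId = id,
    accuracyMean = acc, accuracySem = rep(0, length(acc)),
    binStarts = seq(0, by = 0.1, length.out = length(acc)),
    nUnits = as.integer(C), classCounts = c(a = 10L, b = 10L),
    mcRepeats = 1L)
  r1 <- mkRes("s1", 7, c(0.5, 0.8, 0.9))
  r2 <- mkRes("s2", 5, c(0.5, 0.6, 0.7))
  r3 <- mkRes("s3", 4, c(0.9, 0.9, 0.9))   # too few units
  agg <- aggregateSessions(list(r1, r2, r3), minUnits = 5)
  expect_equal(agg$n_sessions, 2L)
  expect_equal(agg$excluded_sessions, "s3")
  expect_equal(agg$mean_max_accuracy, mean(c(0.9, 0.7)))
  expect_equal(agg$mean_curve, c(0.5, 0.7, 0.8))
  # identical sessions -> SEM 0
  aggSame <- aggregateSessions(list(r1, r1), minUnits = 5)
  expect_equal(aggSame$sem_max_accuracy, 0)
  expect_error(aggregateSessions(list(r3), minUnits = 5),
               "minimum-units filter")
})
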