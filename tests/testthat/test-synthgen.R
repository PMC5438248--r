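test_that("generated sessions have the stated trial structure", {
  cfg <- generatorConfig(nUnits = 6, nTrialsPerClass = 35)
  s <- simulateSession(cfg, "HS", seed = 1)
  expect_equal(nTrials(s), 35L)
  expect_equal(attr(s, "mean_iti_s"), 60)
  sMix <- simulateSession(generatorConfig(nUnits = 6, nTrialsPerClass = 30),
                          c("LS", "HS"), seed = 2)
  expect_equal(as.integer(table(trials(sMix)$stimulus)[c("LS", "HS")]),
               c(30L, 30L))
  expect_equal(unname(sort(unique(trials(sMix)$laser_mW))), c(150, 250))
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- generatorConfig(nUnits = 4, nTrialsPerClass = 8)
  s1 <- simulateSession(cfg, c("LS", "HS"), seed = 123)
  s2 <- simulateSession(cfg, c("LS", "HS"), seed = 123)
  expect_identical(spikes(s1), spikes(s2))
  expect_identical(trials(s1), trials(s2))
})

test_that("spike counts are Poisson: mean approximately equals variance", {
  cfg <- generatorConfig(nUnits = 1, nTrialsPerClass = 400,
                         baselineMeanLog = log(3), baselineSdLog = 0,
                         amplitudes = c(NS = 0, LS = 0, HS = 0), gainSd = 0)
  s <- simulateSession(cfg, "HS", seed = 5)
  cn <- counts(binCounts(s, 1.0))  # 1 s bins
  perTrial <- cn[1, , 3]
  expect_gt(var(perTrial) / mean(perTrial), 0.8)
  expect_lt(var(perTrial) / mean(perTrial), 1.2)
  expect_equal(mean(perTrial), 3, tolerance = 0.12)
})

test_that("larger evoked amplitudes give larger post-stimulus counts", {
  cfg <- generatorConfig(nUnits = 5, nTrialsPerClass = 40,
                         amplitudes = c(NS = 0, LS = 4, HS = 9),
                         fractionResponsive = 1)
  s <- simulateSession(cfg, c("NS", "LS", "HS"), seed = 6)
  ct <- binCounts(s, 0.2)
  post <- 26:50
  tot <- apply(counts(ct)[, , post], 2, sum)
  byClass <- tapply(tot, trials(s)$stimulus, mean)
  expect_lt(byClass[["NS"]], byClass[["LS"]])
  expect_lt(byClass[["LS"]], byClass[["HS"]])
})

test_that("pre-CFA cohorts show steeper generated tuning than post-CFA", {
  slopeFor <- function(regime, seed) {
    cfg <- generatorConfig(nUnits = 7, nTrialsPerClass = 20, regime = regime,
                           fractionResponsive = 1)
    pairs <- do.call(rbind, lapply(1:4, function(i) {
      s <- simulateSession(cfg, c("LS", "HS"), seed = seed + i)
      extractPeakPairs(
        zscorePSTH(binCounts(subsetTrials(s, "LS"), 0.2)),
        zscorePSTH(binCounts(subsetTrials(s, "HS"), 0.2)))
    }))
    slopeEstimate(fitTuningSlope(pairs))
  }
  expect_gt(slopeFor("pre_cfa", 900), slopeFor("post_cfa", 900))
})

test_that("withdrawal latencies order HS < LS and NS rarely withdraws", {
  cfg <- generatorConfig(nUnits = 1, nTrialsPerClass = 300,
                         amplitudes = c(NS = 0, LS = 0, HS = 0))
  s <- simulateSession(cfg, c("NS", "LS", "HS"), seed = 7)
  w <- withdrawalSummary(s)
  expect_lt(w$latency_mean_s[w$stimulus == "HS"],
            w$latency_mean_s[w$stimulus == "LS"])
  expect_lt(w$withdrawal_fraction[w$stimulus == "NS"], 0.05)
  expect_equal(w$withdrawal_fraction[w$stimulus == "LS"], 1)
  lat <- trials(s)$withdrawal_latency_s
  expect_true(all(is.na(lat) | (lat >= 0 & lat < 5)))
})

test_that("tuning cohorts are exact in the noiseless limit", {
  coh <- simulateTuningCohort(20, 2, noiseSd = 0, seed = 8)
  expect_equal(coh$hs_peak, 2 * coh$ls_peak)
  f <- fitTuningSlope(coh)
  expect_equal(slopeEstimate(f), 2, tolerance = 1e-10)
})

test_that("noise calibration hits the requested population R-squared", {
  r2 <- vapply(1:40, function(i) {
    coh <- simulateTuningCohort(200, 1.31, rSquared = 0.6,
                                seed = childSeed(3, i))
    cor(coh$ls_peak, coh$hs_peak)^2
  }, numeric(1))
  expect_equal(mean(r2), 0.6, tolerance = 0.03)
})

test_that("CPA cohorts conserve occupancy and respect the effect size", {
  cpa <- simulateCPACohort(50, effectS = 0, noiseSd = 20, seed = 9)
  tot <- tapply(cpa$baseline_s, cpa$animal_id, sum)
  expect_true(all(abs(tot - 600) < 1e-9))
  tot2 <- tapply(cpa$test_s, cpa$animal_id, sum)
  expect_true(all(abs(tot2 - 600) < 1e-9))
  sc <- cpaScore(filterCPABaseline(cpa)$kept)
  expect_lt(abs(mean(sc$cpa_score_s)), 15)

  # deterministic limit: effect recovered exactly on included animals
  cpaDet <- simulateCPACohort(40, effectS = 100, noiseSd = 0, seed = 10)
  scDet <- cpaScore(filterCPABaseline(cpaDet)$kept)
  expect_true(all(abs(scDet$cpa_score_s - 100) < 1e-9))
  expect_error(simulateCPACohort(5, effectS = 700), "phase duration")
})

test_that("the default baseline bias excludes roughly a fifth of animals", {
  cpa <- simulateCPACohort(600, effectS = 100, seed = 11)
  flt <- filterCPABaseline(cpa)
  fracExcluded <- length(unique(flt$excluded$animal_id)) / 600
  expect_gt(fracExcluded, 0.12)
  expect_lt(fracExcluded, 0.28)
})
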