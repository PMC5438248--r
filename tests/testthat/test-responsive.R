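test_that("Z_SEM is zero for identical trials and follows FR_SEM / sd(FR_b)", {
  # identical counts on every trial -> FR_SEM = 0 in every bin
  ctConst <- makeCountTensor(postRates = c(10, rep(0, 24)),
                             baselineRates = c(rep(0, 12), rep(10, 12), 5))
  zsem <- computeZSEM(ctConst)
  expect_equal(unname(zsem[1, ]), rep(0, 50))

  # generic counts: Z_SEM must equal SE(per-trial rate) / baseline sd
  s <- simulateSession(generatorConfig(nUnits = 3, nTrialsPerClass = 12),
                       c("LS", "HS"), seed = 21)
  ct <- binCounts(s, 0.2)
  p <- zscorePSTH(ct)
  zsem <- computeZSEM(ct, p)
  rates <- counts(ct) / 0.2
  u <- 2; b <- 30
  expect_equal(zsem[u, b],
               sd(rates[u, , b]) / sqrt(dim(rates)[2]) / p@baselineSd[u],
               ignore_attr = TRUE)
})

test_that("doubling trials at fixed variance shrinks Z_SEM by sqrt(2)", {
  ct1 <- makeCountTensor(postRates = rep(c(3, 5), length.out = 25))
  cn <- counts(ct1)
  ct2 <- new("CountTensor",
             counts = array(cn[, c(seq_len(10), seq_len(10)), ],
                            dim = c(1, 20, 50), dimnames = NULL),
             binSize = 0.2, window = c(5, 5), binStarts = binStarts(ct1))
  z1 <- computeZSEM(ct1)
  z2 <- computeZSEM(ct2)
  # duplicated trials: same per-trial sd (up to the n-1 denominator), n doubled
  sdRatio <- sd(rep(cn[1, , 26], 2)) / sd(cn[1, , 26])
  expect_equal(unname(z2[1, 26] / z1[1, 26]), sdRatio / sqrt(2))
})

test_that("the two-part criterion is applied as stated", {
  # all post bins at the baseline mean -> z = 0 everywhere -> non-responsive
  r0 <- classifyResponsive(makeCountTensor(postRates = rep(4, 25)))
  expect_false(r0$is_responsive)
  expect_equal(r0$n_bins_c1, 0L)

  # two strong bins (z = 3, small Z_SEM) -> responsive
  r2 <- classifyResponsive(makeCountTensor(postRates = c(7, 7, rep(4, 23))))
  expect_true(r2$is_responsive)
  expect_equal(r2$bins_c1[[1]], c(1L, 2L))
  expect_true(all(r2$bins_c2[[1]] %in% c(1L, 2L)))

  # a single strong bin (z = 5) is not enough: the rule needs two bins
  r1 <- classifyResponsive(makeCountTensor(postRates = c(9, rep(4, 24))))
  expect_false(r1$is_responsive)
  expect_equal(r1$n_bins_c1, 1L)
})

test_that("criterion 1 uses |z|: strong suppression also counts", {
  # two post bins at 0 Hz -> z = -4, |z| >= 2.33, but criterion 2 is
  # one-sided positive so the unit is not classified responsive
  r <- classifyResponsive(makeCountTensor(postRates = c(0, 0, rep(4, 23))))
  expect_equal(r$n_bins_c1, 2L)
  expect_equal(r$n_bins_c2, 0L)
  expect_false(r$is_responsive)
})

test_that("classification is monotone in a uniform post-stimulus increment", {
  ct <- makeCountTensor(postRates = c(7, 7, rep(4, 23)))
  expect_true(classifyResponsive(ct)$is_responsive)
  for (inc in c(1L, 3L)) {
    cn <- counts(ct)
    cn[, , 26:50] <- cn[, , 26:50] + inc   # +5*inc Hz to every trial and bin
    ct2 <- new("CountTensor", counts = cn, binSize = 0.2, window = c(5, 5),
               binStarts = binStarts(ct))
    expect_true(classifyResponsive(ct2)$is_responsive)
  }
})

test_that("degenerate-baseline units are indeterminate, never responsive", {
  tr <- data.frame(trial_id = 1:4, stimulus = "HS",
                   withdrawal_latency_s = NA_real_, laser_mW = 250)
  s <- SpikeSession("d", c("u1", "u2"),
                    data.frame(unit_id = "u2",
                               trial_id = rep(1:4, each = 3),
                               t_s = rep(c(-3.3, -1.0, 0.5), 4)), tr)
  r <- suppressWarnings(classifyResponsive(binCounts(s, 0.2)))
  expect_true(r$indeterminate[r$unit_id == "u1"])
  expect_false(r$is_responsive[r$unit_id == "u1"])
})

test_that("null-generator false-positive rate stays well below 5%", {
  cfg <- generatorConfig(nUnits = 10, nTrialsPerClass = 35,
                         amplitudes = c(NS = 0, LS = 0, HS = 0))
  res <- do.call(rbind, lapply(1:30, function(i) {
    s <- simulateSession(cfg, "HS", seed = 7000 + i)
    suppressWarnings(classifyResponsive(binCounts(s, 0.2)))
  }))
  ok <- !res$indeterminate
  expect_gte(sum(ok), 290)
  expect_lt(mean(res$is_responsive[ok]), 0.05)
})

test_that("strong evoked responses are detected in nearly all flagged units", {
  cfg <- generatorConfig(nUnits = 7, nTrialsPerClass = 35,
                         baselineMeanLog = log(2), baselineSdLog = 0,
                         amplitudes = c(NS = 0, LS = 0, HS = 10),
                         fractionResponsive = 1)
  hits <- unlist(lapply(1:5, function(i) {
    s <- simulateSession(cfg, "HS", seed = 880 + i)
    classifyResponsive(binCounts(s, 0.2))$is_responsive
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("intensity-coding units are a flagged subset of responsive units", {
  cfg <- generatorConfig(nUnits = 6, nTrialsPerClass = 35,
                         baselineMeanLog = log(2.5), baselineSdLog = 0.2,
                         amplitudes = c(NS = 0, LS = 4, HS = 8),
                         unitGainSd = 0, fractionResponsive = 1)
  s <- simulateSession(cfg, c("LS", "HS"), seed = 31)
  resp <- classifyResponsive(binCounts(s, 0.2))
  respUnits <- resp$unit_id[resp$is_responsive]
  ic <- identifyIntensityCoding(respUnits, s, s)
  expect_true(all(ic$unit_id %in% respUnits))
  # HS amplitude is twice LS: most responsive units must be flagged
  expect_gte(mean(ic$hs_gt_ls), 0.8)
  expect_true(all(ic$mean_hs[ic$hs_gt_ls] > ic$mean_ls[ic$hs_gt_ls]))
})
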