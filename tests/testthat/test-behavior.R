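mkCpa <- function(baselines, tests = NULL) {
  n <- length(baselines)
  if (is.null(tests)) tests <- baselines
  ids <- sprintf("a%02d", seq_len(n))
  rbind(
    data.frame(animal_id = ids, group = "g", chamber = "paired",
               paired_stimulus = "LS", baseline_s = baselines,
               test_s = tests),
    data.frame(animal_id = ids, group = "g", chamber = "unpaired",
               paired_stimulus = "NS", baseline_s = 600 - baselines,
               test_s = 600 - tests))
}

test_that("baseline exclusion applies the 100/500 s band to both chambers", {
  cpa <- mkCpa(c(300, 501, 99, 450, 120))
  flt <- filterCPABaseline(cpa)
  keptIds <- unique(flt$kept$animal_id)
  expect_setequal(keptIds, c("a01", "a04", "a05"))
  # a02 spends 501 s (and its other chamber 99 s): both bounds violated
  expect_true(all(c("a02", "a03") %in% flt$excluded$animal_id))
  expect_true(all(nchar(flt$excluded$reason) > 0))
})

test_that("baseline filtering is an idempotent partition", {
  cpa <- simulateCPACohort(80, seed = 14)
  flt <- filterCPABaseline(cpa)
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(cpa))
  expect_length(intersect(unique(flt$kept$animal_id),
                          unique(flt$excluded$animal_id)), 0)
  again <- filterCPABaseline(flt$kept)
  expect_equal(nrow(again$excluded), 0L)
  expect_equal(again$kept[, names(flt$kept)], flt$kept)
})

test_that("a record missing a chamber is rejected", {
  cpa <- mkCpa(300)[1, , drop = FALSE]
  expect_error(filterCPABaseline(cpa), "exactly 2 chambers")
})

test_that("the CPA score is baseline minus test time in the paired chamber", {
  cpa <- mkCpa(c(300, 250), tests = c(200, 250))
  sc <- cpaScore(cpa, "paired")
  expect_equal(sc$cpa_score_s, c(100, 0))
  expect_error(cpaScore(cpa, "middle"), "unknown chamber")
  # two-chamber antisymmetry under occupancy conservation
  scU <- cpaScore(cpa, "unpaired")
  expect_equal(sc$cpa_score_s + scU$cpa_score_s, c(0, 0))
})

test_that("a CFA-like cohort scores higher aversion than a saline-like one", {
  sal <- simulateCPACohort(30, effectS = 40, noiseSd = 40, group = "saline",
                           seed = 15)
  cfa <- simulateCPACohort(30, effectS = 140, noiseSd = 40, group = "CFA",
                           seed = 16)
  sSal <- cpaScore(filterCPABaseline(sal)$kept)
  sCfa <- cpaScore(filterCPABaseline(cfa)$kept)
  expect_gt(mean(sCfa$cpa_score_s), mean(sSal$cpa_score_s))
  tt <- t.test(sCfa$cpa_score_s, sSal$cpa_score_s)
  expect_lt(tt$p.value, 0.05)
})

test_that("monotone von Frey sequences clamp at the filament-set boundary", {
  expect_equal(as.numeric(updownThreshold(rep("X", 4))), 0.45)
  expect_equal(as.numeric(updownThreshold(rep("O", 6))), 15.10)
})

test_that("the up-down estimate matches a brute-force likelihood oracle", {
  fil <- vonFreyFilaments()
  delta <- mean(diff(log10(fil)))
  bruteMu <- function(responses) {
    # exhaustive grid search over candidate 50% points
    i <- match(2.55, fil); path <- integer(length(responses))
    for (k in seq_along(responses)) {
      path[k] <- i
      i <- max(1L, min(length(fil),
                       if (responses[k] == "X") i - 1L else i + 1L))
    }
    x <- log10(fil[path]); r <- responses == "X"
    grid <- seq(log10(fil[1]) - 2 * delta, log10(fil[8]) + 2 * delta,
                length.out = 20001)
    ll <- vapply(grid, function(mu) {
      p <- pnorm((x - mu) / delta)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      sum(ifelse(r, log(p), log(1 - p)))
    }, numeric(1))
    grid[which.max(ll)]
  }
  for (pattern in list(c("O", "X", "O", "X", "O", "X"),
                       c("X", "O", "X", "O", "O", "X"),
                       c("O", "O", "X", "X", "X", "O"))) {
    est <- updownThreshold(pattern)
    oracle <- min(max(10^bruteMu(pattern), fil[1]), fil[8])
    expect_equal(as.numeric(est), oracle, tolerance = 1e-3)
  }
})

test_that("converting a no-response to a response never raises the threshold", {
  pats <- expand.grid(rep(list(c("X", "O")), 6), stringsAsFactors = FALSE)
  for (row in seq_len(nrow(pats))) {
    pat <- unlist(pats[row, ])
    th <- as.numeric(updownThreshold(pat))
    for (j in which(pat == "O")) {
      flipped <- pat; flipped[j] <- "X"
      expect_lte(as.numeric(updownThreshold(flipped)), th + 1e-9)
    }
  }
})

test_that("simulated staircases recover the underlying threshold region", {
  for (trueTh in c(1.0, 3.5, 8.0)) {
    sq <- simulateVonFreySequence(trueTh, seed = 17)
    est <- as.numeric(updownThreshold(sq))
    expect_gt(est, trueTh / 3)
    expect_lt(est, trueTh * 3)
  }
})

test_that("an inconsistent filament path is rejected", {
  sq <- simulateVonFreySequence(3.5, seed = 18)
  sq$filament_g[2] <- 15.10
  expect_error(updownThreshold(sq), "transition rule")
})

test_that("withdrawal summaries report SEM 0 for constant latencies", {
  tr <- data.frame(trial_id = 1:4, stimulus = "LS",
                   withdrawal_latency_s = rep(1.5, 4), laser_mW = 150)
  expect_message(w <- withdrawalSummary(tr), "omitted")
  expect_equal(w$latency_sem_s[w$stimulus == "LS"], 0)
  expect_equal(w$latency_mean_s[w$stimulus == "LS"], 1.5)
})

test_that("withdrawal velocity is height over time to height", {
  expect_equal(withdrawalVelocity(c(0.1, 0.2), c(0.05, 0.05)), c(2, 4))
  expect_error(withdrawalVelocity(0.1, 0), "timeToHeightS")
})
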