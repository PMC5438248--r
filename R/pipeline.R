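## run one pipeline stage, aborting with the stage name on failure
runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' End-to-end run over a set of mixed LS/HS sessions: low-rate unit
#' filtering, per-class PSTHs, responsive-unit classification,
#' intensity-coding detection, LS-vs-HS cumulative decoding with permutation
#' chance, tuning-curve fitting across units, and behavioral (CPA, von Frey,
#' withdrawal) scoring. Sessions are either simulated from
#' \code{generator} or read from \code{inputPaths} (a list with elements
#' \code{spikes}, \code{trials} and optionally \code{behavior}).
#'
#' All outputs are written under \code{outDir}: per-unit z curves
#' (\code{psth_<class>.csv}), \code{responsiveness.csv},
#' \code{intensity_coding.csv}, \code{decoding_curve.csv},
#' \code{tuning_pairs.csv}, \code{cpa_scores.csv} and a machine-readable
#' \code{summary.json} recording the seeds, package version and headline
#' numbers. With a fixed \code{config$rngSeed} the run is bit-reproducible;
#' every randomized stage uses a child seed derived from the root seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @param generator a \code{\link{generatorConfig}} used when no input paths
#'   are given.
#' @param inputPaths optional list of CSV paths (\code{spikes},
#'   \code{trials}, \code{behavior}).
#' @param nSessions number of sessions to simulate.
#' @param nCpaAnimals simulated CPA cohort size.
#' @return invisibly, the summary list written to \code{summary.json}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        generator = generatorConfig(), inputPaths = NULL,
                        nSessions = 3L, nCpaAnimals = 16L) {
  if (!inherits(config, "nocicode_config"))
    stop("config must come from pipelineConfig()", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rngSeed

  sessions <- runStage("acquire", {
    if (is.null(inputPaths)) {
      lapply(seq_len(nSessions), function(i)
        simulateSession(generator, c("LS", "HS"), seed = childSeed(seed, i),
                        sessionId = sprintf("sim-%02d", i)))
    } else {
      list(readSpikeSession(inputPaths$spikes, inputPaths$trials))
    }
  })

  sessions <- runStage("filter_low_rate_units",
                       lapply(sessions, filterLowRateUnits))

  psths <- runStage("psth", {
    out <- lapply(sessions, function(s) {
      lapply(c(LS = "LS", HS = "HS"), function(cl)
        zscorePSTH(binCounts(subsetTrials(s, cl), config$binSizePsth),
                   baselineSdOver = config$baselineSdOver))
    })
    for (cl in c("LS", "HS")) {
      rows <- do.call(rbind, lapply(seq_along(out), function(i) {
        z <- zMatrix(out[[i]][[cl]])
        data.frame(session_id = sessionId(sessions[[i]]),
                   unit_id = rep(rownames(z), ncol(z)),
                   bin_start_s = rep(binStarts(out[[i]][[cl]]),
                                     each = nrow(z)),
                   z = as.vector(z))
      }))
      utils::write.csv(rows, file.path(outDir, paste0("psth_", cl, ".csv")),
                       row.names = FALSE)
    }
    out
  })

  responsive <- runStage("responsive", {
    res <- do.call(rbind, lapply(sessions, function(s) {
      r <- classifyResponsive(binCounts(subsetTrials(s, "HS"),
                                        config$binSizePsth),
                              thresholds = config$zThresholds,
                              baselineSdOver = config$baselineSdOver)
      cbind(session_id = sessionId(s),
            r[, c("unit_id", "is_responsive", "indeterminate",
                  "n_bins_c1", "n_bins_c2")])
    }))
    utils::write.csv(res, file.path(outDir, "responsiveness.csv"),
                     row.names = FALSE)
    res
  })

  intensity <- runStage("intensity_coding", {
    res <- do.call(rbind, lapply(seq_along(sessions), function(i) {
      s <- sessions[[i]]
      resp <- responsive[responsive$session_id == sessionId(s) &
                         responsive$is_responsive, "unit_id"]
      if (!length(resp)) return(NULL)
      cbind(session_id = sessionId(s),
            identifyIntensityCoding(resp, s, s,
                                    binSizeS = config$binSizePsth))
    }))
    if (!is.null(res))
      utils::write.csv(res, file.path(outDir, "intensity_coding.csv"),
                       row.names = FALSE)
    res
  })

  decoding <- runStage("decode", {
    results <- lapply(seq_along(sessions), function(i) {
      fs <- buildCumulativeFeatures(sessions[[i]], config$binSizeDecoding,
                                    config$windowS)
      r <- evaluateDecoder(fs, folds = config$cvFolds,
                           mcRepeats = config$mcRepeats,
                           seed = childSeed(seed, 100 + i),
                           kernel = config$svmKernel,
                           degree = config$svmDegree, coef0 = config$svmCoef0,
                           cost = config$svmCost)
      ch <- permutationChance(fs, nPermutations = config$nPermutations,
                              folds = config$cvFolds,
                              seed = childSeed(seed, 200 + i),
                              kernel = config$svmKernel,
                              degree = config$svmDegree,
                              coef0 = config$svmCoef0, cost = config$svmCost)
      setChance(r, ch, config$nPermutations)
    })
    agg <- aggregateSessions(results, minUnits = config$minUnitsPerSession)
    curve <- data.frame(bin_start_s = binStarts(results[[1]]),
                        accuracy_mean = agg$mean_curve,
                        chance_mean = agg$mean_chance)
    utils::write.csv(curve, file.path(outDir, "decoding_curve.csv"),
                     row.names = FALSE)
    agg
  })

  tuning <- runStage("tuning", {
    pairs <- do.call(rbind, lapply(seq_along(sessions), function(i) {
      p <- extractPeakPairs(psths[[i]]$LS, psths[[i]]$HS)
      if (nrow(p)) cbind(session_id = sessionId(sessions[[i]]), p) else NULL
    }))
    utils::write.csv(pairs, file.path(outDir, "tuning_pairs.csv"),
                     row.names = FALSE)
    if (is.null(pairs) || nrow(pairs) < 3) NULL else fitTuningSlope(pairs)
  })

  behavior <- runStage("behavior", {
    cpa <- if (!is.null(inputPaths$behavior))
      readCPARecords(inputPaths$behavior) else
      simulateCPACohort(nCpaAnimals, seed = childSeed(seed, 300))
    flt <- filterCPABaseline(cpa)
    scores <- cpaScore(flt$kept)
    utils::write.csv(scores, file.path(outDir, "cpa_scores.csv"),
                     row.names = FALSE)
    vf <- simulateVonFreySequence(3.5, seed = childSeed(seed, 301))
    wd <- withdrawalSummary(trials(sessions[[1]]))
    list(cpa_scores = scores, n_excluded = length(unique(flt$excluded$animal_id)),
         vf_threshold_g = as.numeric(updownThreshold(vf)),
         withdrawal = wd)
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("nocicode")),
    rng_seed = seed,
    n_sessions = length(sessions),
    n_units = sum(vapply(sessions, nUnits, integer(1))),
    n_responsive = sum(responsive$is_responsive),
    n_intensity_coding = if (is.null(intensity)) 0L else
      sum(intensity$hs_gt_ls),
    decoding_mean_max_accuracy = decoding$mean_max_accuracy,
    decoding_sem_max_accuracy = decoding$sem_max_accuracy,
    decoding_mean_chance = if (is.null(decoding$mean_chance)) NULL else
      mean(decoding$mean_chance),
    tuning_slope = if (is.null(tuning)) NULL else slopeEstimate(tuning),
    tuning_slope_se = if (is.null(tuning)) NULL else slopeSE(tuning),
    tuning_r_squared = if (is.null(tuning)) NULL else rSquared(tuning),
    cpa_mean_score_s = mean(behavior$cpa_scores$cpa_score_s),
    cpa_n_excluded = behavior$n_excluded,
    vonfrey_threshold_g = behavior$vf_threshold_g)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
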