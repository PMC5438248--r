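#' Construct a SpikeSession
#'
#' @param sessionId session identifier.
#' @param unitIds character vector of unit ids.
#' @param spikes data.frame with columns \code{unit_id}, \code{trial_id},
#'   \code{t_s}.
#' @param trials data.frame with columns \code{trial_id}, \code{stimulus},
#'   \code{withdrawal_latency_s}, \code{laser_mW}.
#' @param window baseline and post-stimulus extent in seconds.
#' @return a validated \linkS4class{SpikeSession}.
#' @export
SpikeSession <- function(sessionId, unitIds, spikes, trials, window = c(5, 5)) {
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$trial_id <- as.integer(spikes$trial_id)
  trials$trial_id <- as.integer(trials$trial_id)
  trials$stimulus <- as.character(trials$stimulus)
  new("SpikeSession", sessionId = as.character(sessionId),
      unitIds = as.character(unitIds), spikes = spikes, trials = trials,
      window = as.numeric(window))
}

#' Analysis pipeline configuration
#'
#' Bundles the constants of the analysis: PSTH and decoding bin sizes, the
#' 5 s analysis window, the two responsiveness z thresholds (2.33 and 1.645),
#' cross-validation geometry, Monte-Carlo and permutation repeat counts, the
#' minimum simultaneously recorded units per decoded session, and the SVM
#' kernel settings.
#'
#' @param binSizePsth PSTH bin width (s); 0.2 gives 25 baseline + 25
#'   post-stimulus bins over a 5 s window.
#' @param binSizeDecoding cumulative decoding bin width (s); 0.1 gives 50
#'   evaluation bins.
#' @param windowS half-window (s): seconds of baseline and of post-stimulus
#'   data analyzed.
#' @param zThresholds length-2: criterion-1 |z| threshold and criterion-2
#'   lower-bound threshold.
#' @param cvFolds cross-validation folds (each fold is the 20\% test split
#'   when \code{cvFolds = 5}).
#' @param mcRepeats Monte-Carlo repeats of the CV with reshuffled folds.
#' @param nPermutations label permutations for the chance level.
#' @param minUnitsPerSession sessions with fewer simultaneously recorded
#'   units are excluded from population decoding.
#' @param baselineSdOver "bins": baseline SD over the pre-stimulus bins of the
#'   trial-averaged rate (default); "trials": SD of per-trial baseline rates.
#' @param svmKernel,svmDegree,svmCoef0,svmCost SVM kernel family and
#'   parameters.
#' @param rngSeed root seed; all randomized stages derive child seeds from it.
#' @return a named list of validated settings.
#' @export
pipelineConfig <- function(binSizePsth = 0.2, binSizeDecoding = 0.1,
                           windowS = 5.0, zThresholds = c(2.33, 1.645),
                           cvFolds = 5L, mcRepeats = 100L,
                           nPermutations = 500L, minUnitsPerSession = 5L,
                           baselineSdOver = c("bins", "trials"),
                           svmKernel = c("polynomial", "linear"),
                           svmDegree = 3, svmCoef0 = 1, svmCost = 1,
                           rngSeed = 1L) {
  baselineSdOver <- match.arg(baselineSdOver)
  svmKernel <- match.arg(svmKernel)
  cfg <- list(binSizePsth = binSizePsth, binSizeDecoding = binSizeDecoding,
              windowS = windowS, zThresholds = zThresholds,
              cvFolds = as.integer(cvFolds), mcRepeats = as.integer(mcRepeats),
              nPermutations = as.integer(nPermutations),
              minUnitsPerSession = as.integer(minUnitsPerSession),
              baselineSdOver = baselineSdOver, svmKernel = svmKernel,
              svmDegree = svmDegree, svmCoef0 = svmCoef0, svmCost = svmCost,
              rngSeed = as.integer(rngSeed))
  with(cfg, {
    if (cvFolds < 2L) stop("cvFolds must be at least 2", call. = FALSE)
    if (mcRepeats < 1L || nPermutations < 1L || minUnitsPerSession < 1L)
      stop("repeat counts and unit minimum must be positive", call. = FALSE)
    if (binSizePsth <= 0 || binSizeDecoding <= 0 || windowS <= 0)
      stop("bin sizes and window must be positive", call. = FALSE)
    for (b in c(binSizePsth, binSizeDecoding)) {
      nb <- windowS / b
      if (abs(nb - round(nb)) > 1e-8)
        stop("bin size must divide the window into an integer number of bins",
             call. = FALSE)
    }
    if (length(zThresholds) != 2L || any(zThresholds <= 0))
      stop("zThresholds must be two positive values", call. = FALSE)
  })
  class(cfg) <- "nocicode_config"
  cfg
}

#' Derive an independent child seed from a root seed
#'
#' Every randomized stage of the pipeline draws its own seed from the root
#' seed and a stage index, so stages are reproducible in isolation.
#'
#' @param seed root integer seed.
#' @param index stage index (any nonnegative integer).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, index) {
  ## Lehmer-style mixing, kept in double precision well below 2^53
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 9973 + 12345) %% 2147483647
  x <- (x * 16807 + 2531011) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

## standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

## run expr with a local RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
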