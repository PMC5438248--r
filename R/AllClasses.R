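STIMULUS_LEVELS <- c("NS", "LS", "HS")

#' Trial-aligned spike data for one recording session
#'
#' A \code{SpikeSession} holds the spike events of a set of simultaneously
#' recorded single units, aligned to stimulus (laser) onset, together with
#' per-trial metadata. Spike times are in seconds relative to onset and must
#' lie within \code{[-window[1], +window[2])}; trials carry a stimulus class
#' (\code{NS}, \code{LS} or \code{HS} -- 50/150/250 mW by convention), an
#' optional withdrawal latency (absent when no withdrawal occurred within the
#' 5 s stimulus) and the nominal laser power.
#'
#' @slot sessionId single session identifier.
#' @slot unitIds character vector of unit identifiers.
#' @slot spikes data.frame with columns \code{unit_id}, \code{trial_id},
#'   \code{t_s} (seconds relative to onset).
#' @slot trials data.frame with columns \code{trial_id}, \code{stimulus},
#'   \code{withdrawal_latency_s} (NA = no withdrawal), \code{laser_mW}.
#' @slot window numeric of length 2: seconds of baseline and post-stimulus
#'   coverage (default 5 and 5).
#'
#' @export
setClass("SpikeSession",
  representation(
    sessionId = "character",
    unitIds = "character",
    spikes = "data.frame",
    trials = "data.frame",
    window = "numeric"
  ),
  prototype(window = c(5, 5))
)

setValidity("SpikeSession", function(object) {
  msg <- character()
  sp <- object@spikes
  tr <- object@trials
  need_sp <- c("unit_id", "trial_id", "t_s")
  need_tr <- c("trial_id", "stimulus", "withdrawal_latency_s", "laser_mW")
  if (!all(need_sp %in% names(sp)))
    msg <- c(msg, paste("spikes must have columns", paste(need_sp, collapse = ", ")))
  if (!all(need_tr %in% names(tr)))
    msg <- c(msg, paste("trials must have columns", paste(need_tr, collapse = ", ")))
  if (length(object@window) != 2L || any(object@window <= 0))
    msg <- c(msg, "window must be two positive durations (baseline, post)")
  if (length(msg)) return(msg)
  if (anyDuplicated(tr$trial_id))
    msg <- c(msg, "duplicated trial_id in trials")
  bad <- which(!sp$trial_id %in% tr$trial_id)
  if (length(bad))
    msg <- c(msg, paste0("spikes reference unknown trial_id (rows ",
                         paste(utils::head(bad, 5), collapse = ", "), ")"))
  bad <- which(!sp$unit_id %in% object@unitIds)
  if (length(bad))
    msg <- c(msg, paste0("spikes reference unknown unit_id (rows ",
                         paste(utils::head(bad, 5), collapse = ", "), ")"))
  bad <- which(sp$t_s < -object@window[1] | sp$t_s >= object@window[2])
  if (length(bad))
    msg <- c(msg, paste0("spike times outside [-", object@window[1], ", ",
                         object@window[2], ") s (rows ",
                         paste(utils::head(bad, 5), collapse = ", "), ")"))
  if (!all(tr$stimulus %in% STIMULUS_LEVELS))
    msg <- c(msg, "stimulus labels must be NS, LS or HS")
  wl <- tr$withdrawal_latency_s
  if (any(!is.na(wl) & (wl < 0 | wl >= 5)))
    msg <- c(msg, "withdrawal_latency_s must be in [0, 5) s or NA")
  if (any(!is.na(tr$laser_mW) & tr$laser_mW <= 0))
    msg <- c(msg, "laser_mW must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-trial spike counts on a trial-aligned bin grid
#'
#' Three-dimensional count array indexed (unit, trial, bin) over half-open
#' bins \code{[t, t + binSize)} covering \code{[-window[1], +window[2])}.
#' A spike at exactly t = 0 falls in the first post-stimulus bin.
#'
#' @slot counts integer array unit x trial x bin.
#' @slot binSize bin width in seconds.
#' @slot window numeric length 2, baseline and post-stimulus extent (s).
#' @slot binStarts left edge of every bin, in seconds relative to onset.
#'
#' @export
setClass("CountTensor",
  representation(
    counts = "array",
    binSize = "numeric",
    window = "numeric",
    binStarts = "numeric"
  )
)

setValidity("CountTensor", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be a 3-d array (unit, trial, bin)")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be nonnegative integers")
  nb <- sum(object@window) / object@binSize
  if (abs(nb - round(nb)) > 1e-8)
    msg <- c(msg, "bin size must divide the window into an integer number of bins")
  else if (dim(object@counts)[3] != round(nb))
    msg <- c(msg, "third dimension must equal (baseline + post) / binSize")
  if (length(object@binStarts) != dim(object@counts)[3])
    msg <- c(msg, "binStarts length must match the bin dimension")
  if (length(msg)) msg else TRUE
})

#' Baseline-normalized peristimulus time histograms
#'
#' Per-unit, per-bin trial-averaged firing rates and their z-scored form
#' \code{Z = (FR - mean(FR_b)) / sd(FR_b)}, where the baseline statistics are
#' taken over the pre-stimulus bins of the trial-averaged rate. Units whose
#' baseline rate has zero variability cannot be z-scored and are flagged
#' degenerate (their z rows are NA).
#'
#' @slot z unit x bin matrix of z-scored rates.
#' @slot fr unit x bin matrix of trial-averaged firing rate (Hz).
#' @slot frSem unit x bin standard error of the per-trial rate across trials.
#' @slot baselineMean,baselineSd named per-unit baseline statistics (Hz).
#' @slot degenerate logical per unit; TRUE when sd(FR_b) == 0.
#' @slot binSize,binStarts bin geometry, as in \linkS4class{CountTensor}.
#' @slot nBaselineBins number of pre-stimulus bins.
#'
#' @export
setClass("PSTHMatrix",
  representation(
    z = "matrix",
    fr = "matrix",
    frSem = "matrix",
    baselineMean = "numeric",
    baselineSd = "numeric",
    degenerate = "logical",
    binSize = "numeric",
    binStarts = "numeric",
    nBaselineBins = "integer"
  )
)

setValidity("PSTHMatrix", function(object) {
  msg <- character()
  ok <- !object@degenerate
  if (any(!is.finite(object@z[ok, , drop = FALSE])))
    msg <- c(msg, "z must be finite for units with non-degenerate baseline")
  if (any(ok)) {
    zb <- object@z[ok, seq_len(object@nBaselineBins), drop = FALSE]
    if (max(abs(rowMeans(zb))) > 1e-6)
      msg <- c(msg, "baseline bins of z must average to 0")
  }
  if (length(msg)) msg else TRUE
})

#' Cumulative-window population decoding result
#'
#' Per evaluation bin: mean and SEM (over Monte-Carlo cross-validation
#' repeats) of the decoding accuracy, and optionally the label-permutation
#' chance curve.
#'
#' @slot sessionId originating session.
#' @slot accuracyMean,accuracySem per-bin accuracy statistics in [0, 1].
#' @slot chanceMean per-bin mean shuffled-label accuracy (length 0 if not
#'   computed).
#' @slot binStarts left edges (s) of the evaluation bins.
#' @slot nUnits number of simultaneously recorded units C.
#' @slot classCounts named trial counts of the two decoded classes.
#' @slot mcRepeats,nPermutations repeat counts actually used.
#'
#' @export
setClass("DecodingResult",
  representation(
    sessionId = "character",
    accuracyMean = "numeric",
    accuracySem = "numeric",
    chanceMean = "numeric",
    binStarts = "numeric",
    nUnits = "integer",
    classCounts = "integer",
    mcRepeats = "integer",
    nPermutations = "integer"
  ),
  prototype(chanceMean = numeric(0), nPermutations = 0L)
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  acc <- c(object@accuracyMean, object@chanceMean)
  if (any(acc < 0 | acc > 1)) msg <- c(msg, "accuracies must lie in [0, 1]")
  if (any(object@accuracySem < 0)) msg <- c(msg, "SEM must be nonnegative")
  if (length(object@accuracySem) != length(object@accuracyMean))
    msg <- c(msg, "accuracyMean and accuracySem must have equal length")
  if (length(msg)) msg else TRUE
})

#' Robust intensity tuning-curve fit
#'
#' Slope/intercept of the robust (IRLS, bisquare) regression of per-neuron
#' peak z-scored HS responses on peak LS responses. A slope above 1 means
#' responses grow with stimulus intensity; a flatter slope means degraded
#' intensity discrimination.
#'
#' @slot slope,slopeSe,intercept,interceptSe coefficient estimates and
#'   standard errors.
#' @slot rSquared squared correlation between fitted and observed HS peaks.
#' @slot n number of neurons in the fit.
#'
#' @export
setClass("TuningFit",
  representation(
    slope = "numeric",
    slopeSe = "numeric",
    intercept = "numeric",
    interceptSe = "numeric",
    rSquared = "numeric",
    n = "integer"
  )
)

setValidity("TuningFit", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "a tuning fit needs at least 3 neurons")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn SpikeSession-class session identifier
#' @param x object
#' @export
setMethod("sessionId", "SpikeSession", function(x) x@sessionId)

#' @describeIn SpikeSession-class unit identifiers
#' @export
setMethod("unitIds", "SpikeSession", function(x) x@unitIds)

#' @describeIn SpikeSession-class spike event table
#' @export
setMethod("spikes", "SpikeSession", function(x) x@spikes)

#' @describeIn SpikeSession-class trial metadata table
#' @export
setMethod("trials", "SpikeSession", function(x) x@trials)

#' @describeIn SpikeSession-class number of units
#' @export
setMethod("nUnits", "SpikeSession", function(x) length(x@unitIds))

#' @describeIn SpikeSession-class number of trials
#' @export
setMethod("nTrials", "SpikeSession", function(x) nrow(x@trials))

#' @describeIn CountTensor-class the count array
#' @param x object
#' @export
setMethod("counts", "CountTensor", function(x) x@counts)

#' @describeIn CountTensor-class bin width (s)
#' @export
setMethod("binSize", "CountTensor", function(x) x@binSize)

#' @describeIn CountTensor-class bin left edges (s)
#' @export
setMethod("binStarts", "CountTensor", function(x) x@binStarts)

#' @describeIn PSTHMatrix-class z-scored PSTH matrix
#' @param x object
#' @export
setMethod("zMatrix", "PSTHMatrix", function(x) x@z)

#' @describeIn PSTHMatrix-class trial-averaged firing rate (Hz)
#' @export
setMethod("firingRate", "PSTHMatrix", function(x) x@fr)

#' @describeIn PSTHMatrix-class per-unit baseline mean/sd (Hz)
#' @export
setMethod("baselineStats", "PSTHMatrix", function(x)
  data.frame(unit_id = names(x@baselineMean),
             baseline_mean_hz = unname(x@baselineMean),
             baseline_sd_hz = unname(x@baselineSd),
             degenerate = unname(x@degenerate)))

#' @describeIn PSTHMatrix-class units with zero baseline variability
#' @export
setMethod("degenerateUnits", "PSTHMatrix", function(x)
  names(x@degenerate)[x@degenerate])

#' @describeIn PSTHMatrix-class bin width (s)
#' @export
setMethod("binSize", "PSTHMatrix", function(x) x@binSize)

#' @describeIn PSTHMatrix-class bin left edges (s)
#' @export
setMethod("binStarts", "PSTHMatrix", function(x) x@binStarts)

#' @describeIn DecodingResult-class per-bin mean accuracy
#' @param x object
#' @export
setMethod("accuracy", "DecodingResult", function(x) x@accuracyMean)

#' @describeIn DecodingResult-class originating session id
#' @export
setMethod("sessionId", "DecodingResult", function(x) x@sessionId)

#' @describeIn DecodingResult-class per-bin accuracy SEM
#' @export
setMethod("accuracySEM", "DecodingResult", function(x) x@accuracySem)

#' @describeIn DecodingResult-class per-bin permutation chance curve
#' @export
setMethod("chanceLevel", "DecodingResult", function(x) x@chanceMean)

#' @describeIn DecodingResult-class maximum of the cumulative accuracy curve
#' @export
setMethod("maxAccuracy", "DecodingResult", function(x) max(x@accuracyMean))

#' @describeIn DecodingResult-class bin left edges (s)
#' @export
setMethod("binStarts", "DecodingResult", function(x) x@binStarts)

#' @describeIn DecodingResult-class number of units C
#' @export
setMethod("nUnits", "DecodingResult", function(x) x@nUnits)

#' @describeIn TuningFit-class fitted slope
#' @param x object
#' @export
setMethod("slopeEstimate", "TuningFit", function(x) x@slope)

#' @describeIn TuningFit-class slope standard error
#' @export
setMethod("slopeSE", "TuningFit", function(x) x@slopeSe)

#' @describeIn TuningFit-class fitted intercept
#' @export
setMethod("interceptEstimate", "TuningFit", function(x) x@intercept)

#' @describeIn TuningFit-class squared fitted-vs-observed correlation
#' @export
setMethod("rSquared", "TuningFit", function(x) x@rSquared)

#' @describeIn TuningFit-class number of neurons
#' @export
setMethod("nObs", "TuningFit", function(x) x@n)

## ---- show ------------------------------------------------------------------

setMethod("show", "SpikeSession", function(object) {
  cat("SpikeSession '", object@sessionId, "': ",
      length(object@unitIds), " units, ", nrow(object@trials), " trials, ",
      nrow(object@spikes), " spikes\n", sep = "")
  tab <- table(object@trials$stimulus)
  cat("  stimuli:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  window: [-", object@window[1], ", +", object@window[2], ") s\n",
      sep = "")
})

setMethod("show", "CountTensor", function(object) {
  d <- dim(object@counts)
  cat("CountTensor: ", d[1], " units x ", d[2], " trials x ", d[3],
      " bins of ", object@binSize * 1000, " ms\n", sep = "")
})

setMethod("show", "PSTHMatrix", function(object) {
  cat("PSTHMatrix: ", nrow(object@z), " units x ", ncol(object@z),
      " bins (", object@nBaselineBins, " baseline), bin ",
      object@binSize * 1000, " ms\n", sep = "")
  if (any(object@degenerate))
    cat("  degenerate-baseline units:",
        paste(names(object@degenerate)[object@degenerate], collapse = ", "),
        "\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult '", object@sessionId, "': C = ", object@nUnits,
      " units, trials ", paste(names(object@classCounts),
                               object@classCounts, sep = "=", collapse = " vs "),
      "\n  max accuracy ", round(max(object@accuracyMean), 3), " over ",
      length(object@accuracyMean), " cumulative bins (",
      object@mcRepeats, " MC repeats)\n", sep = "")
  if (length(object@chanceMean))
    cat("  mean permutation chance ", round(mean(object@chanceMean), 3),
        " (", object@nPermutations, " permutations)\n", sep = "")
})

setMethod("show", "TuningFit", function(object) {
  cat(sprintf("TuningFit: slope = %.3f +/- %.3f, intercept = %.3f, R2 = %.4f, n = %d\n",
              object@slope, object@slopeSe, object@intercept,
              object@rSquared, object@n))
})
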