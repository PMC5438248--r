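#' Synthetic-data generator configuration
#'
#' Parameters of the inhomogeneous-Poisson session generator. A unit fires at
#' its baseline rate before stimulus onset; from onset, responsive units add a
#' transient evoked component \code{gain * A_s * k(t)} where \code{A_s} is the
#' stimulus-class amplitude (Hz at kernel peak), \code{k} a normalized
#' rise-and-decay kernel and \code{gain} a per-trial multiplicative
#' (log-normal, mean 1) excitability factor shared by all units of the trial.
#'
#' Two tuning regimes are provided. \code{pre_cfa} uses well-separated LS and
#' HS amplitudes (steep intensity tuning); \code{post_cfa} compresses the LS
#' amplitude toward the HS amplitude, emulating the flattened tuning seen in
#' the chronic inflammatory pain state. Baseline rates and amplitudes are not
#' reported by recording studies in usable units, so defaults are chosen as
#' physiologically plausible and are fully config-exposed.
#'
#' @param nUnits simultaneously recorded units per session.
#' @param nTrialsPerClass trials per stimulus class (35 for single-class
#'   sessions; mixed two-class decoding sessions typically use 30 + 30).
#' @param baselineMeanLog,baselineSdLog log-normal parameters of per-unit
#'   baseline rates (defaults give a median near 2.5 Hz).
#' @param amplitudes named numeric: evoked peak amplitude (Hz) per stimulus
#'   class; \code{NULL} picks the regime default
#'   (pre_cfa: NS 0 / LS 5 / HS 9; post_cfa: NS 0 / LS 7.5 / HS 9).
#' @param regime \code{"pre_cfa"} or \code{"post_cfa"}.
#' @param kernelRiseS,kernelDecayS rise and decay time constants (s) of the
#'   evoked kernel \code{(1 - exp(-t/rise)) * exp(-t/decay)}, peak-normalized.
#' @param gainSd SD of log per-trial gain.
#' @param unitGainSd SD of the log per-unit response-magnitude gain: neurons
#'   differ in how strongly they respond overall, but each neuron's LS and HS
#'   responses share its magnitude, which is what makes per-neuron intensity
#'   tuning (HS peak vs LS peak) a correlated, fittable relation.
#' @param fractionResponsive fraction of units given nonzero amplitude.
#' @param itiS mean inter-trial interval (s), recorded as trial metadata.
#' @param phaseS CPA phase duration (s).
#' @param baselineBiasSd SD (s) of the baseline paired-chamber occupancy
#'   around an even 300/300 split; the default gives roughly one animal in
#'   five falling outside the 100--500 s inclusion band.
#' @return a named list of generator settings.
#' @export
generatorConfig <- function(nUnits = 7L, nTrialsPerClass = 35L,
                            baselineMeanLog = log(2.5), baselineSdLog = 0.4,
                            amplitudes = NULL,
                            regime = c("pre_cfa", "post_cfa"),
                            kernelRiseS = 0.5, kernelDecayS = 1.5,
                            gainSd = 0.2, unitGainSd = 0.6,
                            fractionResponsive = 0.75,
                            itiS = 60, phaseS = 600, baselineBiasSd = 156) {
  regime <- match.arg(regime)
  if (is.null(amplitudes))
    amplitudes <- switch(regime,
      pre_cfa  = c(NS = 0, LS = 5.0, HS = 9.0),
      post_cfa = c(NS = 0, LS = 7.5, HS = 9.0))
  stopifnot(nUnits >= 1, nTrialsPerClass >= 1, all(amplitudes >= 0),
            kernelRiseS > 0, kernelDecayS > 0, gainSd >= 0, unitGainSd >= 0,
            fractionResponsive >= 0, fractionResponsive <= 1)
  if (regime == "pre_cfa" &&
      !(amplitudes["NS"] <= amplitudes["LS"] &&
        amplitudes["LS"] <= amplitudes["HS"]))
    stop("pre_cfa amplitudes must satisfy A_NS <= A_LS <= A_HS", call. = FALSE)
  list(nUnits = as.integer(nUnits),
       nTrialsPerClass = as.integer(nTrialsPerClass),
       baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
       amplitudes = amplitudes, regime = regime,
       kernelRiseS = kernelRiseS, kernelDecayS = kernelDecayS,
       gainSd = gainSd, unitGainSd = unitGainSd,
       fractionResponsive = fractionResponsive,
       itiS = itiS, phaseS = phaseS, baselineBiasSd = baselineBiasSd)
}

## peak-normalized evoked kernel on t >= 0
evokedKernel <- function(t, riseS, decayS) {
  k <- (1 - exp(-t / riseS)) * exp(-t / decayS)
  grid <- seq(0, 10 * decayS, by = 0.001)
  k / max((1 - exp(-grid / riseS)) * exp(-grid / decayS))
}

laserPower <- c(NS = 50, LS = 150, HS = 250)

## withdrawal latency draws per stimulus class; HS withdraws fastest,
## NS withdraws on <5% of trials
drawLatency <- function(stimulus, n) {
  switch(stimulus,
    NS = ifelse(stats::runif(n) < 0.03,
                pmin(2 + stats::rgamma(n, shape = 4, scale = 0.5), 4.99), NA_real_),
    LS = pmin(0.3 + stats::rgamma(n, shape = 4, scale = 0.42), 4.99),
    HS = pmin(0.2 + stats::rgamma(n, shape = 4, scale = 0.15), 4.99))
}

#' Simulate one trial-aligned spike session
#'
#' Spikes are drawn from an inhomogeneous Poisson process: a stationary
#' baseline over the whole \code{[-5, +5)} s window plus, for responsive
#' units from onset, a transient evoked component generated by thinning
#' against the peak rate.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param stimulusSet character vector of stimulus classes; each contributes
#'   \code{nTrialsPerClass} randomly interleaved trials.
#' @param seed integer seed.
#' @param sessionId identifier for the session.
#' @param window baseline/post extent (s).
#' @return a \linkS4class{SpikeSession}; the responsive-unit assignment is in
#'   \code{attr(, "responsive_units")} and the per-unit baseline rates in
#'   \code{attr(, "baseline_rates_hz")}.
#' @export
simulateSession <- function(config = generatorConfig(),
                            stimulusSet = c("LS", "HS"), seed = 1L,
                            sessionId = "synthetic-1", window = c(5, 5)) {
  stopifnot(all(stimulusSet %in% STIMULUS_LEVELS))
  with_seed(seed, {
    nu <- config$nUnits
    units <- sprintf("u%02d", seq_len(nu))
    baseRates <- stats::rlnorm(nu, config$baselineMeanLog, config$baselineSdLog)
    unitGain <- stats::rlnorm(nu, -config$unitGainSd^2 / 2, config$unitGainSd)
    nResp <- round(config$fractionResponsive * nu)
    respUnits <- if (nResp > 0) sort(sample(units, nResp)) else character(0)

    stimuli <- sample(rep(stimulusSet, each = config$nTrialsPerClass))
    nt <- length(stimuli)
    gains <- stats::rlnorm(nt, -config$gainSd^2 / 2, config$gainSd)
    lat <- rep(NA_real_, nt)
    for (s in unique(stimuli)) {
      idx <- which(stimuli == s)
      lat[idx] <- drawLatency(s, length(idx))
    }
    trials <- data.frame(trial_id = seq_len(nt), stimulus = stimuli,
                         withdrawal_latency_s = lat,
                         laser_mW = unname(laserPower[stimuli]))

    totalT <- sum(window)
    spk <- vector("list", nu * nt)
    k <- 0L
    for (u in seq_len(nu)) {
      amps <- if (units[u] %in% respUnits) unitGain[u] * config$amplitudes else
        stats::setNames(rep(0, length(config$amplitudes)),
                        names(config$amplitudes))
      for (tr in seq_len(nt)) {
        nBase <- stats::rpois(1, baseRates[u] * totalT)
        tBase <- if (nBase > 0)
          stats::runif(nBase, -window[1], window[2]) else numeric(0)
        a <- gains[tr] * amps[[stimuli[tr]]]
        tEv <- numeric(0)
        if (a > 0) {  # thinning against the peak rate a (kernel peak = 1)
          nCand <- stats::rpois(1, a * window[2])
          if (nCand > 0) {
            tc <- stats::runif(nCand, 0, window[2])
            keep <- stats::runif(nCand) <
              evokedKernel(tc, config$kernelRiseS, config$kernelDecayS)
            tEv <- tc[keep]
          }
        }
        tt <- c(tBase, tEv)
        if (length(tt)) {
          k <- k + 1L
          spk[[k]] <- data.frame(unit_id = units[u], trial_id = tr, t_s = tt)
        }
      }
    }
    spikeTab <- if (k > 0) do.call(rbind, spk[seq_len(k)]) else
      data.frame(unit_id = character(0), trial_id = integer(0),
                 t_s = numeric(0))
    ses <- SpikeSession(sessionId, units, spikeTab, trials, window)
    attr(ses, "responsive_units") <- respUnits
    attr(ses, "baseline_rates_hz") <- stats::setNames(baseRates, units)
    attr(ses, "mean_iti_s") <- config$itiS
    ses
  })
}

#' Simulate a cohort of (LS peak, HS peak) response pairs
#'
#' Generates per-neuron peak z-scored LS responses from a log-normal
#' distribution and HS responses as \code{slope * ls + Normal(0, noiseSd)}.
#' When \code{noiseSd} is omitted it is calibrated so that the population
#' R-squared of the linear relation equals \code{rSquared}:
#' \code{noiseSd = slope * SD(ls) * sqrt((1 - R2) / R2)} with the theoretical
#' log-normal SD.
#'
#' @param n number of neurons (>= 3).
#' @param slope generating slope (> 0).
#' @param noiseSd SD of the additive HS noise; mutually exclusive with
#'   \code{rSquared}.
#' @param rSquared target population R-squared used to calibrate the noise.
#' @param lsMeanLog,lsSdLog log-normal parameters of the LS peaks.
#' @param seed integer seed.
#' @return data.frame with columns \code{unit_id}, \code{ls_peak},
#'   \code{hs_peak}.
#' @export
simulateTuningCohort <- function(n, slope, noiseSd = NULL, rSquared = NULL,
                                 lsMeanLog = 1, lsSdLog = 0.45, seed = 1L) {
  if (n < 3L) stop("need at least 3 neurons", call. = FALSE)
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (is.null(noiseSd)) {
    if (is.null(rSquared))
      stop("give either noiseSd or rSquared", call. = FALSE)
    stopifnot(rSquared > 0, rSquared < 1)
    sdLs <- sqrt((exp(lsSdLog^2) - 1) * exp(2 * lsMeanLog + lsSdLog^2))
    noiseSd <- slope * sdLs * sqrt((1 - rSquared) / rSquared)
  }
  if (noiseSd < 0) stop("noiseSd must be nonnegative", call. = FALSE)
  with_seed(seed, {
    ls <- stats::rlnorm(n, lsMeanLog, lsSdLog)
    hs <- slope * ls + stats::rnorm(n, 0, noiseSd)
    data.frame(unit_id = sprintf("n%03d", seq_len(n)), ls_peak = ls,
               hs_peak = hs)
  })
}

#' Simulate a conditioned-place-aversion cohort
#'
#' Each animal explores a two-chamber apparatus for 600 s at baseline and
#' 600 s at test; occupancy of the two chambers sums exactly to the phase
#' duration in each phase. Baseline time in the stimulus-paired chamber is
#' Normal(300, \code{baselineBiasSd}); at test it is reduced by
#' \code{effectS} seconds of aversion plus Normal(0, \code{noiseSd}) noise,
#' clamped to \code{[0, phaseS]}.
#'
#' @param nAnimals cohort size.
#' @param effectS mean aversion effect (s) for the paired chamber.
#' @param noiseSd SD (s) of the test-phase noise.
#' @param baselineBiasSd SD (s) of the baseline chamber bias.
#' @param phaseS phase duration (s).
#' @param group cohort label (e.g. "saline", "CFA").
#' @param pairedStimulus stimulus paired with the target chamber.
#' @param seed integer seed.
#' @return wide CPA table: one row per animal and chamber with
#'   \code{baseline_s} and \code{test_s}.
#' @export
simulateCPACohort <- function(nAnimals, effectS = 100, noiseSd = 30,
                              baselineBiasSd = 156, phaseS = 600,
                              group = "cohort", pairedStimulus = "LS",
                              seed = 1L) {
  if (effectS > phaseS)
    stop("aversion effect cannot exceed the phase duration", call. = FALSE)
  with_seed(seed, {
    base <- pmin(pmax(stats::rnorm(nAnimals, phaseS / 2, baselineBiasSd), 0),
                 phaseS)
    test <- pmin(pmax(base - effectS + stats::rnorm(nAnimals, 0, noiseSd), 0),
                 phaseS)
    ids <- sprintf("%s-a%03d", group, seq_len(nAnimals))
    rbind(
      data.frame(animal_id = ids, group = group, chamber = "paired",
                 paired_stimulus = pairedStimulus,
                 baseline_s = base, test_s = test),
      data.frame(animal_id = ids, group = group, chamber = "unpaired",
                 paired_stimulus = "NS",
                 baseline_s = phaseS - base, test_s = phaseS - test))
  })
}

#' Simulate a Dixon up-down von Frey response sequence
#'
#' Walks the up-down staircase against an animal with 50\% withdrawal
#' threshold \code{thresholdG}: the probability of withdrawal at filament
#' force g is \code{pnorm((log10(g) - log10(thresholdG)) / slopeSdLog)}
#' (a deterministic step when \code{slopeSdLog = 0}). Testing starts at
#' \code{startG}, steps down after a withdrawal and up after none, and stops
#' after the first direction change plus four further stimuli (or at a
#' boundary of the filament set under a monotone run).
#'
#' @param thresholdG true 50\% threshold (g).
#' @param filaments ordered filament set (g).
#' @param startG starting filament (g).
#' @param slopeSdLog SD of the log10 psychometric function; 0 = deterministic.
#' @param seed integer seed (ignored when deterministic).
#' @return object of class \code{vonfrey_sequence}: list with
#'   \code{filament_g} (sequence tested) and \code{response} ("X" withdrawal,
#'   "O" none), plus the filament set.
#' @export
simulateVonFreySequence <- function(thresholdG, filaments = vonFreyFilaments(),
                                    startG = 2.55, slopeSdLog = 0,
                                    seed = 1L) {
  stopifnot(thresholdG > 0, startG %in% filaments)
  with_seed(seed, {
    i <- match(startG, filaments)
    seqF <- integer(0)
    resp <- character(0)
    nAfterReversal <- NA_integer_
    repeat {
      p <- if (slopeSdLog == 0) as.numeric(filaments[i] >= thresholdG) else
        stats::pnorm((log10(filaments[i]) - log10(thresholdG)) / slopeSdLog)
      r <- if (stats::runif(1) < p) "X" else "O"
      seqF <- c(seqF, i)
      resp <- c(resp, r)
      if (is.na(nAfterReversal) && length(resp) >= 2 &&
          resp[length(resp)] != resp[length(resp) - 1])
        nAfterReversal <- 0L
      if (!is.na(nAfterReversal)) {
        nAfterReversal <- nAfterReversal + 1L
        if (nAfterReversal > 4L) break
      }
      i2 <- if (r == "X") i - 1L else i + 1L
      if (i2 < 1L || i2 > length(filaments)) break  # boundary: clamp case
      i <- i2
    }
    structure(list(filament_g = filaments[seqF], response = resp,
                   filaments = filaments), class = "vonfrey_sequence")
  })
}
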