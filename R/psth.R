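#' Bin spikes into trial-aligned counts
#'
#' Counts spikes per unit, trial and half-open bin \code{[t, t + binSize)}
#' over the full \code{[-window[1], +window[2])} range. A spike at exactly
#' t = 0 lands in the first post-stimulus bin.
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param binSizeS bin width in seconds (default 200 ms).
#' @return a \linkS4class{CountTensor}.
#' @export
binCounts <- function(session, binSizeS = 0.2) {
  w <- session@window
  nb <- sum(w) / binSizeS
  if (abs(nb - round(nb)) > 1e-8)
    stop("bin size ", binSizeS,
         " s does not divide the window into an integer number of bins",
         call. = FALSE)
  nb <- as.integer(round(nb))
  if (nTrials(session) == 0L) stop("session has no trials", call. = FALSE)
  units <- unitIds(session)
  nu <- length(units)
  nt <- nTrials(session)
  sp <- spikes(session)
  arr <- array(0L, dim = c(nu, nt, nb),
               dimnames = list(units, trials(session)$trial_id, NULL))
  if (nrow(sp)) {
    ui <- match(sp$unit_id, units)
    ti <- match(sp$trial_id, trials(session)$trial_id)
    bi <- pmin(floor((sp$t_s + w[1]) / binSizeS) + 1L, nb)
    lin <- ui + (ti - 1L) * nu + (bi - 1L) * nu * nt
    cnt <- tabulate(lin, nbins = nu * nt * nb)
    arr[] <- as.integer(cnt)
  }
  new("CountTensor", counts = arr, binSize = binSizeS, window = w,
      binStarts = seq(-w[1], w[2] - binSizeS, by = binSizeS))
}

#' Baseline z-scored peristimulus time histograms
#'
#' Converts per-trial counts to trial-averaged firing rates FR per bin and
#' z-scores them against the pre-stimulus baseline:
#' \deqn{Z = (FR - \mathrm{mean}(FR_b)) / \mathrm{sd}(FR_b)}
#' where \eqn{FR_b} are the baseline values of FR. With the default 5 s
#' window at 200 ms this uses 25 baseline and 25 post-stimulus bins. By
#' construction the baseline bins of z then have sample mean 0 and sample
#' SD 1. The alternative reading of the baseline SD -- across per-trial
#' baseline rates rather than across baseline bins of the trial average --
#' is available via \code{baselineSdOver = "trials"}.
#'
#' Units whose baseline shows no variability at all cannot be z-scored; they
#' are flagged degenerate, their z rows set to NA, and a warning is emitted
#' so downstream classification can exclude them.
#'
#' @param ct a \linkS4class{CountTensor}.
#' @param baselineSdOver "bins" (default) or "trials"; see Details.
#' @return a \linkS4class{PSTHMatrix}.
#' @export
zscorePSTH <- function(ct, baselineSdOver = c("bins", "trials")) {
  baselineSdOver <- match.arg(baselineSdOver)
  cn <- counts(ct)
  nu <- dim(cn)[1]; nt <- dim(cn)[2]; nb <- dim(cn)[3]
  nb0 <- as.integer(round(ct@window[1] / ct@binSize))
  if (nb0 < 2L) stop("need at least 2 baseline bins", call. = FALSE)
  rates <- cn / ct@binSize                      # unit x trial x bin, Hz
  fr <- apply(rates, c(1, 3), mean)             # unit x bin
  frSem <- if (nt >= 2L)
    apply(rates, c(1, 3), stats::sd) / sqrt(nt) else
    matrix(NA_real_, nu, nb)
  bmean <- rowMeans(fr[, seq_len(nb0), drop = FALSE])
  bsd <- switch(baselineSdOver,
    bins = apply(fr[, seq_len(nb0), drop = FALSE], 1, stats::sd),
    trials = {
      perTrialBase <- apply(rates[, , seq_len(nb0), drop = FALSE],
                            c(1, 2), mean)
      apply(perTrialBase, 1, stats::sd)
    })
  degen <- !is.finite(bsd) | bsd == 0
  z <- (fr - bmean) / bsd
  z[degen, ] <- NA_real_
  if (any(degen))
    warning("degenerate baseline (zero variability) for unit(s): ",
            paste(rownames(cn)[degen], collapse = ", "),
            "; z undefined, excluded downstream", call. = FALSE)
  un <- rownames(cn)
  dimnames(z) <- dimnames(fr) <- dimnames(frSem) <- list(un, NULL)
  new("PSTHMatrix", z = z, fr = fr, frSem = frSem,
      baselineMean = stats::setNames(bmean, un),
      baselineSd = stats::setNames(unname(bsd), un),
      degenerate = stats::setNames(degen, un),
      binSize = ct@binSize, binStarts = ct@binStarts, nBaselineBins = nb0)
}

#' Drop units with sub-threshold peak firing rates
#'
#' Excludes single units whose maximum trial-averaged per-bin firing rate
#' (200 ms bins over the full window) is below \code{minPeakRateHz}, the
#' standard preprocessing cut for poorly isolated or near-silent units.
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param minPeakRateHz exclusion threshold in Hz (default 1).
#' @param binSizeS bin width used to assess the peak rate.
#' @return the session restricted to retained units.
#' @export
filterLowRateUnits <- function(session, minPeakRateHz = 1.0, binSizeS = 0.2) {
  if (nTrials(session) == 0L) stop("session has no trials", call. = FALSE)
  ct <- binCounts(session, binSizeS)
  fr <- apply(counts(ct) / binSizeS, c(1, 3), mean)
  keep <- unitIds(session)[apply(fr, 1, max) >= minPeakRateHz]
  sp <- spikes(session)
  out <- SpikeSession(sessionId(session), keep,
                      sp[sp$unit_id %in% keep, , drop = FALSE],
                      trials(session), session@window)
  rv <- attr(session, "responsive_units")
  if (!is.null(rv)) attr(out, "responsive_units") <- rv[rv %in% keep]
  br <- attr(session, "baseline_rates_hz")
  if (!is.null(br)) attr(out, "baseline_rates_hz") <- br[names(br) %in% keep]
  out
}
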