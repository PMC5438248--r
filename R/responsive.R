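#' Standard error of the z-scored rate across trials
#'
#' \eqn{Z_{SEM}(bin) = FR_{SEM}(bin) / \mathrm{sd}(FR_b)} where
#' \eqn{FR_{SEM}} is the standard error, across trials, of the per-trial
#' firing rate in that bin. This expresses the trial-to-trial uncertainty of
#' each PSTH bin in baseline-SD units, and provides the lower confidence
#' bound \eqn{Z - Z_{SEM}} used by the second responsiveness criterion.
#'
#' @param ct a \linkS4class{CountTensor} with at least 2 trials.
#' @param psth optional precomputed \linkS4class{PSTHMatrix} for \code{ct}.
#' @return unit x bin matrix of Z_SEM values (NA rows for degenerate units).
#' @export
computeZSEM <- function(ct, psth = zscorePSTH(ct)) {
  if (dim(counts(ct))[2] < 2L)
    stop("Z_SEM needs at least 2 trials", call. = FALSE)
  zsem <- psth@frSem / psth@baselineSd
  zsem[psth@degenerate, ] <- NA_real_
  zsem
}

#' Classify pain-responsive units
#'
#' Applies the two-part threshold rule to the post-stimulus bins of the
#' z-scored PSTH: (1) at least two post-stimulus bins must have
#' \eqn{|Z| \ge 2.33}; (2) evaluated only when (1) passes, at least two
#' post-stimulus bins must have lower bound \eqn{Z - Z_{SEM} > 1.645}. A
#' unit is responsive iff both criteria hold. Units with degenerate
#' (zero-variability) baselines are classified indeterminate and are never
#' responsive.
#'
#' @param ct a \linkS4class{CountTensor}.
#' @param thresholds length 2: the criterion-1 |z| threshold and the
#'   criterion-2 lower-bound threshold.
#' @param baselineSdOver passed to \code{\link{zscorePSTH}}.
#' @return data.frame with one row per unit: \code{unit_id},
#'   \code{is_responsive}, \code{indeterminate}, \code{n_bins_c1},
#'   \code{n_bins_c2}, and list columns \code{bins_c1}, \code{bins_c2} of
#'   passing post-stimulus bin indices (1 = first bin after onset). The
#'   z and Z_SEM matrices ride along as attributes \code{"z"} and
#'   \code{"z_sem"}.
#' @export
classifyResponsive <- function(ct, thresholds = c(2.33, 1.645),
                               baselineSdOver = c("bins", "trials")) {
  psth <- zscorePSTH(ct, baselineSdOver = match.arg(baselineSdOver))
  zsem <- computeZSEM(ct, psth)
  nb0 <- psth@nBaselineBins
  post <- seq(nb0 + 1L, ncol(psth@z))
  un <- rownames(psth@z)
  res <- lapply(seq_along(un), function(u) {
    if (psth@degenerate[u])
      return(data.frame(unit_id = un[u], is_responsive = FALSE,
                        indeterminate = TRUE, n_bins_c1 = NA_integer_,
                        n_bins_c2 = NA_integer_,
                        bins_c1 = I(list(integer(0))),
                        bins_c2 = I(list(integer(0)))))
    z <- psth@z[u, post]
    zs <- zsem[u, post]
    c1 <- which(abs(z) >= thresholds[1])
    pass1 <- length(c1) >= 2L
    c2 <- if (pass1) which(z - zs > thresholds[2]) else integer(0)
    data.frame(unit_id = un[u],
               is_responsive = pass1 && length(c2) >= 2L,
               indeterminate = FALSE,
               n_bins_c1 = length(c1), n_bins_c2 = length(c2),
               bins_c1 = I(list(c1)), bins_c2 = I(list(c2)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "z") <- psth@z
  attr(out, "z_sem") <- zsem
  out
}

#' Restrict a session to trials of one stimulus class
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param stimulus stimulus class to keep ("NS", "LS" or "HS").
#' @return the session containing only trials of that class.
#' @export
subsetTrials <- function(session, stimulus) {
  tr <- trials(session)
  keep <- tr$trial_id[tr$stimulus == stimulus]
  sp <- spikes(session)
  SpikeSession(sessionId(session), unitIds(session),
               sp[sp$trial_id %in% keep, , drop = FALSE],
               tr[tr$trial_id %in% keep, , drop = FALSE], session@window)
}

## per-trial peak z-scored post-stimulus rate for every unit:
## per-trial bin rates are z-scored with the unit's (trial-averaged) baseline
## statistics, then the maximum over post-stimulus bins is taken per trial
perTrialPeakZ <- function(session, binSizeS = 0.2) {
  ct <- binCounts(session, binSizeS)
  psth <- zscorePSTH(ct)
  nb0 <- psth@nBaselineBins
  rates <- counts(ct) / binSizeS
  post <- seq(nb0 + 1L, dim(rates)[3])
  zTrial <- sweep(sweep(rates[, , post, drop = FALSE], 1,
                        psth@baselineMean, "-"), 1, psth@baselineSd, "/")
  peaks <- apply(zTrial, c(1, 2), max)   # unit x trial
  peaks[psth@degenerate, ] <- NA_real_
  peaks
}

#' Identify intensity-coding units (HS > LS) among responsive units
#'
#' For each responsive unit recorded under both LS and HS stimulation,
#' compares per-trial response summaries (peak z-scored bin rate in the
#' post-stimulus window) between the two intensities with a paired one-sided
#' Student's t test. Because LS and HS trials are distinct recordings with no
#' natural pairing, trials are paired by rank order of the response summary
#' within each class; unequal trial counts are truncated to the common count.
#'
#' @param responsiveUnits character vector of unit ids already classified
#'   responsive (see \code{\link{classifyResponsive}}).
#' @param lsSession,hsSession \linkS4class{SpikeSession}s (single-class, or
#'   mixed sessions containing LS / HS trials respectively).
#' @param alpha significance level for the HS > LS flag.
#' @param binSizeS PSTH bin width (s).
#' @return data.frame per tested unit: \code{unit_id}, \code{hs_gt_ls},
#'   \code{t}, \code{df}, \code{p}, \code{mean_ls}, \code{mean_hs},
#'   \code{n_pairs}.
#' @export
identifyIntensityCoding <- function(responsiveUnits, lsSession, hsSession,
                                    alpha = 0.05, binSizeS = 0.2) {
  ls <- if ("LS" %in% trials(lsSession)$stimulus &&
            length(unique(trials(lsSession)$stimulus)) > 1L)
    subsetTrials(lsSession, "LS") else lsSession
  hs <- if ("HS" %in% trials(hsSession)$stimulus &&
            length(unique(trials(hsSession)$stimulus)) > 1L)
    subsetTrials(hsSession, "HS") else hsSession
  common <- intersect(responsiveUnits,
                      intersect(unitIds(ls), unitIds(hs)))
  skipped <- setdiff(responsiveUnits, common)
  if (length(skipped))
    message("skipping unit(s) missing a condition: ",
            paste(skipped, collapse = ", "))
  if (!length(common))
    return(data.frame(unit_id = character(0), hs_gt_ls = logical(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      mean_ls = numeric(0), mean_hs = numeric(0),
                      n_pairs = integer(0)))
  pkLs <- perTrialPeakZ(ls, binSizeS)
  pkHs <- perTrialPeakZ(hs, binSizeS)
  out <- lapply(common, function(u) {
    a <- sort(pkLs[u, ])
    b <- sort(pkHs[u, ])
    n <- min(length(a), length(b))
    if (length(a) != length(b))
      message("unit ", u, ": unequal trial counts, truncated to ", n)
    a <- a[seq_len(n)]; b <- b[seq_len(n)]
    if (n < 2L || any(!is.finite(c(a, b))) || stats::sd(b - a) == 0)
      return(data.frame(unit_id = u, hs_gt_ls = FALSE, t = NA_real_,
                        df = NA_real_, p = NA_real_,
                        mean_ls = mean(a), mean_hs = mean(b), n_pairs = n))
    tt <- stats::t.test(b, a, paired = TRUE, alternative = "greater")
    data.frame(unit_id = u, hs_gt_ls = unname(tt$p.value < alpha),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value),
               mean_ls = mean(a), mean_hs = mean(b), n_pairs = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
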