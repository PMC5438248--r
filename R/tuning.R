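#' Extract per-neuron (LS peak, HS peak) response pairs
#'
#' The peak response of a neuron under a stimulus class is the maximum of its
#' z-scored PSTH over the post-stimulus bins. Only neurons present in both
#' conditions are paired, and -- following the definition of the tuning-fit
#' population -- only pairs with a larger HS than LS peak are retained.
#'
#' @param psthLs,psthHs \linkS4class{PSTHMatrix} objects for the LS and HS
#'   conditions.
#' @param requireHsGreater keep only pairs with \code{hs_peak > ls_peak}
#'   (default TRUE, the fit population rule).
#' @return data.frame with columns \code{unit_id}, \code{ls_peak},
#'   \code{hs_peak}.
#' @export
extractPeakPairs <- function(psthLs, psthHs, requireHsGreater = TRUE) {
  common <- intersect(rownames(psthLs@z), rownames(psthHs@z))
  skipped <- setdiff(union(rownames(psthLs@z), rownames(psthHs@z)), common)
  if (length(skipped))
    message("unit(s) missing one condition, skipped: ",
            paste(skipped, collapse = ", "))
  postL <- seq(psthLs@nBaselineBins + 1L, ncol(psthLs@z))
  postH <- seq(psthHs@nBaselineBins + 1L, ncol(psthHs@z))
  ok <- common[!psthLs@degenerate[common] & !psthHs@degenerate[common]]
  ls <- apply(psthLs@z[ok, postL, drop = FALSE], 1, max)
  hs <- apply(psthHs@z[ok, postH, drop = FALSE], 1, max)
  out <- data.frame(unit_id = ok, ls_peak = unname(ls), hs_peak = unname(hs))
  if (requireHsGreater) out <- out[out$hs_peak > out$ls_peak, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Robust intensity tuning-curve fit
#'
#' Fits \code{hs_peak ~ ls_peak} by iteratively reweighted least squares with
#' Tukey bisquare weights (tuning constant 4.685, the conventional 95\%
#' Gaussian-efficiency value). A slope above 1 indicates that responses grow
#' with stimulus intensity; flattening of the slope indicates degraded
#' intensity discrimination. R-squared is reported as the squared correlation
#' between fitted and observed HS peaks (the robust fit has no unique
#' variance decomposition). An exactly collinear dataset (zero residuals)
#' makes the robust scale estimate degenerate, so that case is returned from
#' the ordinary least-squares fit the IRLS would converge to.
#'
#' @param pairs data.frame with columns \code{ls_peak}, \code{hs_peak}
#'   (see \code{\link{extractPeakPairs}}).
#' @param tuningConstant bisquare tuning constant.
#' @param maxIter IRLS iteration cap.
#' @return a \linkS4class{TuningFit}.
#' @export
fitTuningSlope <- function(pairs, tuningConstant = 4.685, maxIter = 100L) {
  n <- nrow(pairs)
  if (n < 3L) stop("tuning fit needs at least 3 pairs", call. = FALSE)
  x <- pairs$ls_peak
  y <- pairs$hs_peak
  if (stats::sd(x) == 0)
    stop("singular design: all ls_peak values identical", call. = FALSE)
  ols <- stats::lm(y ~ x)
  if (max(abs(stats::residuals(ols))) <
      1e-10 * max(abs(y) + abs(x))) {
    cf <- suppressWarnings(summary(ols))$coefficients
    return(new("TuningFit", slope = cf[2, 1], slopeSe = cf[2, 2],
               intercept = cf[1, 1], interceptSe = cf[1, 2],
               rSquared = 1, n = as.integer(n)))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = tuningConstant,
                   maxit = maxIter)
  cf <- summary(fit)$coefficients
  r2 <- stats::cor(stats::fitted(fit), y)^2
  new("TuningFit", slope = cf[2, 1], slopeSe = cf[2, 2],
      intercept = cf[1, 1], interceptSe = cf[1, 2],
      rSquared = r2, n = as.integer(n))
}

#' Compare the slopes of two regression lines
#'
#' Student's t test for the difference of two independently estimated
#' regression slopes:
#' \deqn{t = (b_1 - b_2) / \sqrt{SE_1^2 + SE_2^2}, \quad df = n_1 + n_2 - 4}
#' with a two-sided p value.
#'
#' @param fitA,fitB \linkS4class{TuningFit} objects.
#' @return list with \code{t_statistic}, \code{df}, \code{p_value}.
#' @export
compareSlopes <- function(fitA, fitB) {
  seCombined <- sqrt(slopeSE(fitA)^2 + slopeSE(fitB)^2)
  d <- slopeEstimate(fitA) - slopeEstimate(fitB)
  t <- if (seCombined == 0 && d == 0) 0 else d / seCombined
  df <- nObs(fitA) + nObs(fitB) - 4
  p <- max(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
  list(t_statistic = t, df = df, p_value = p)
}
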