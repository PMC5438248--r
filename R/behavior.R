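#' The standard von Frey filament set
#'
#' Logarithmically incremented filament forces (grams) used for the Dixon
#' up-down estimation of the 50\% mechanical withdrawal threshold.
#'
#' @return numeric vector of filament forces in grams.
#' @export
vonFreyFilaments <- function() c(0.45, 0.75, 1.20, 2.55, 4.40, 6.10, 10.50,
                                 15.10)

#' Exclude animals with biased baseline chamber preference
#'
#' Animals spending more than \code{hi} s or less than \code{lo} s of the
#' preconditioning (baseline) phase in either main chamber are excluded from
#' the CPA analysis: a strong innate preference leaves no room to measure
#' conditioned avoidance.
#'
#' @param records wide CPA table (one row per animal and chamber; see
#'   \code{\link{readCPARecords}}).
#' @param lo,hi inclusion band for baseline chamber time (s).
#' @return list with elements \code{kept} and \code{excluded} (the latter
#'   with a \code{reason} column); the two partition the input animals.
#' @export
filterCPABaseline <- function(records, lo = 100, hi = 500) {
  byAnimal <- split(records, records$animal_id)
  bad <- vapply(byAnimal, function(r) {
    if (nrow(r) != 2L)
      stop("animal ", r$animal_id[1], " must have exactly 2 chambers",
           call. = FALSE)
    any(r$baseline_s < lo | r$baseline_s > hi)
  }, logical(1))
  keptIds <- names(byAnimal)[!bad]
  exIds <- names(byAnimal)[bad]
  kept <- records[records$animal_id %in% keptIds, , drop = FALSE]
  excluded <- records[records$animal_id %in% exIds, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(excluded$baseline_s < lo,
                              paste0("baseline < ", lo, " s"),
                       ifelse(excluded$baseline_s > hi,
                              paste0("baseline > ", hi, " s"),
                              "other chamber out of band"))
  } else excluded$reason <- character(0)
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Conditioned-place-aversion score
#'
#' \code{score = baseline_s - test_s} for the chamber paired with the more
#' noxious stimulus: positive values mean the animal avoided that chamber
#' after conditioning.
#'
#' @param records wide CPA table.
#' @param chamber target chamber label (default "paired").
#' @return data.frame with one row per animal: \code{animal_id},
#'   \code{group}, \code{paired_stimulus}, \code{cpa_score_s}.
#' @export
cpaScore <- function(records, chamber = "paired") {
  r <- records[records$chamber == chamber, , drop = FALSE]
  if (!nrow(r))
    stop("unknown chamber '", chamber, "'; available: ",
         paste(unique(records$chamber), collapse = ", "), call. = FALSE)
  data.frame(animal_id = r$animal_id, group = r$group,
             paired_stimulus = r$paired_stimulus,
             cpa_score_s = r$baseline_s - r$test_s)
}

## mean log10 step of the filament set
logStep <- function(filaments) mean(diff(log10(filaments)))

## negative log-likelihood of a normal psychometric function with mean mu and
## SD delta (the mean log-step), given tested log-forces x and responses r
updownNegLogLik <- function(mu, x, r, delta) {
  p <- stats::pnorm((x - mu) / delta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(ifelse(r, log(p), log(1 - p)))
}

#' Dixon up-down 50\% withdrawal threshold
#'
#' Estimates the 50\% mechanical withdrawal threshold from an up-down
#' response sequence: testing steps down one filament after a withdrawal (X)
#' and up one after none (O). The estimate is the maximum-likelihood 50\%
#' point of a normal psychometric function on the log10 force axis whose SD
#' is fixed at the mean log-step of the filament set -- the model underlying
#' the classical up-down tables. Equivalently the estimate can be written
#' \code{10^(Xf + kappa * delta)} with Xf the log10 force of the final
#' filament, delta the mean log-step and kappa the pattern-dependent factor
#' returned in \code{attr(, "kappa")}. Monotone sequences (withdrawal down to
#' the weakest filament, or none up to the stiffest) are clamped to the set
#' boundary.
#'
#' @param x a \code{vonfrey_sequence} (see
#'   \code{\link{simulateVonFreySequence}}) or a character vector of
#'   responses \code{"X"}/\code{"O"}.
#' @param filaments ordered filament set (g); used when \code{x} is a bare
#'   response vector.
#' @param startG starting filament (g); likewise.
#' @return the 50\% threshold in grams, with attributes \code{kappa} and
#'   \code{filament_g} (the filament path).
#' @export
updownThreshold <- function(x, filaments = vonFreyFilaments(),
                            startG = 2.55) {
  if (inherits(x, "vonfrey_sequence")) {
    responses <- x$response
    filaments <- x$filaments
    startG <- x$filament_g[1]
    given <- x$filament_g
  } else {
    responses <- x
    given <- NULL
  }
  if (!length(responses) || !all(responses %in% c("X", "O")))
    stop("responses must be a nonempty sequence of 'X'/'O'", call. = FALSE)
  if (!startG %in% filaments)
    stop("starting filament not in the filament set", call. = FALSE)
  ## reconstruct the staircase path implied by the responses
  n <- length(filaments)
  i <- match(startG, filaments)
  path <- integer(length(responses))
  for (k in seq_along(responses)) {
    path[k] <- i
    i <- max(1L, min(n, if (responses[k] == "X") i - 1L else i + 1L))
  }
  if (!is.null(given) && !isTRUE(all.equal(filaments[path], given)))
    stop("filament sequence violates the up-down transition rule",
         call. = FALSE)
  if (all(responses == "X")) {
    out <- filaments[1]
    attr(out, "kappa") <- NA_real_
  } else if (all(responses == "O")) {
    out <- filaments[n]
    attr(out, "kappa") <- NA_real_
  } else {
    delta <- logStep(filaments)
    xlog <- log10(filaments[path])
    lo <- log10(filaments[1]) - 2 * delta
    hi <- log10(filaments[n]) + 2 * delta
    mu <- stats::optimize(updownNegLogLik, c(lo, hi), x = xlog,
                          r = responses == "X", delta = delta,
                          tol = 1e-9)$minimum
    out <- min(max(10^mu, filaments[1]), filaments[n])
    attr(out, "kappa") <- (log10(out) - xlog[length(xlog)]) / delta
  }
  attr(out, "filament_g") <- filaments[path]
  out
}

#' Withdrawal latency and velocity summaries
#'
#' Per stimulus class: mean and SEM of the withdrawal latency over trials
#' with a withdrawal, and the fraction of trials with any withdrawal (NS
#' should elicit one on fewer than 5\% of trials). Classes without trials
#' are omitted with a note.
#'
#' @param x trial metadata table (columns \code{stimulus},
#'   \code{withdrawal_latency_s}) or a \linkS4class{SpikeSession}.
#' @return data.frame per class: \code{stimulus}, \code{n_trials},
#'   \code{withdrawal_fraction}, \code{latency_mean_s}, \code{latency_sem_s}.
#' @export
withdrawalSummary <- function(x) {
  tr <- if (is(x, "SpikeSession")) trials(x) else x
  out <- lapply(STIMULUS_LEVELS, function(s) {
    rows <- tr[tr$stimulus == s, , drop = FALSE]
    if (!nrow(rows)) {
      message("no trials for class ", s, "; omitted")
      return(NULL)
    }
    lat <- rows$withdrawal_latency_s
    withd <- lat[!is.na(lat)]
    data.frame(stimulus = s, n_trials = nrow(rows),
               withdrawal_fraction = length(withd) / nrow(rows),
               latency_mean_s = if (length(withd)) mean(withd) else NA_real_,
               latency_sem_s = if (length(withd) > 1) sem(withd) else
                 if (length(withd) == 1) 0 else NA_real_)
  })
  do.call(rbind, out)
}

#' Paw-withdrawal velocity
#'
#' Velocity of the withdrawal movement: the height reached by the paw divided
#' by the time taken to reach that height.
#'
#' @param heightM peak paw height per event (m).
#' @param timeToHeightS time to reach the peak (s).
#' @return velocity in m/s, elementwise.
#' @export
withdrawalVelocity <- function(heightM, timeToHeightS) {
  stopifnot(all(timeToHeightS > 0))
  heightM / timeToHeightS
}
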