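#' Cumulative spike-count feature set for population decoding
#'
#' For each trial and evaluation bin b, the decoder sees the per-unit spike
#' counts of all 100 ms bins from stimulus onset up to b, concatenated: the
#' input dimensionality grows from C (one bin, C units) to 50C (all bins of a
#' 5 s horizon). Emulates online decoding in which evidence accumulates over
#' the trial.
#'
#' @slot cum cumulative counts, trial x unit x bin.
#' @slot labels two-level factor of trial stimulus classes.
#' @slot binStarts left edges (s) of the evaluation bins.
#' @slot sessionId originating session.
#' @export
setClass("FeatureSet",
  representation(cum = "array", labels = "factor", binStarts = "numeric",
                 sessionId = "character"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (nlevels(object@labels) != 2L)
    msg <- c(msg, "decoding is binary: labels must have exactly 2 levels")
  if (length(object@labels) != dim(object@cum)[1])
    msg <- c(msg, "one label per trial required")
  if (dim(object@cum)[3] > 1L &&
      any(apply(object@cum, c(1, 2), diff) < 0))
    msg <- c(msg, "cumulative counts must be nondecreasing in bin index")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureSet", function(object) {
  d <- dim(object@cum)
  cat("FeatureSet '", object@sessionId, "': ", d[1], " trials x C = ", d[2],
      " units x ", d[3], " cumulative bins (dimension ", d[2], " to ",
      d[2] * d[3], ")\n  classes: ",
      paste(levels(object@labels), table(object@labels), sep = "=",
            collapse = " vs "), "\n", sep = "")
})

#' @describeIn FeatureSet-class number of units C
#' @param x object
#' @export
setMethod("nUnits", "FeatureSet", function(x) dim(x@cum)[2])

#' @describeIn FeatureSet-class number of trials
#' @export
setMethod("nTrials", "FeatureSet", function(x) dim(x@cum)[1])

#' @describeIn FeatureSet-class evaluation-bin left edges (s)
#' @export
setMethod("binStarts", "FeatureSet", function(x) x@binStarts)

#' Trial-feature matrix at one evaluation bin
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param b evaluation bin index.
#' @return trial x (b * C) matrix: for bins 1..b the per-unit counts,
#'   concatenated bin by bin.
#' @export
featureMatrix <- function(fs, b) {
  stopifnot(b >= 1, b <= dim(fs@cum)[3])
  d <- dim(fs@cum)
  full <- featureMatrixFull(fs)
  full[, seq_len(b * d[2]), drop = FALSE]
}

## trial x (B*C) matrix of per-bin (not cumulative) counts, bin-major columns
featureMatrixFull <- function(fs) {
  d <- dim(fs@cum)
  percol <- fs@cum
  if (d[3] > 1L)
    percol[, , 2:d[3]] <- fs@cum[, , 2:d[3], drop = FALSE] -
      fs@cum[, , 1:(d[3] - 1L), drop = FALSE]
  m <- matrix(percol, nrow = d[1])
  colnames(m) <- paste0("b", rep(seq_len(d[3]), each = d[2]), "_u",
                        rep(seq_len(d[2]), d[3]))
  m
}

#' Build cumulative-window decoding features
#'
#' Bins post-stimulus spikes into \code{binSizeS} windows from onset to
#' \code{horizonS} and accumulates them, per unit, across bins.
#'
#' @param session a \linkS4class{SpikeSession} whose trials carry exactly two
#'   stimulus classes.
#' @param binSizeS accumulation window (default 100 ms).
#' @param horizonS decoding horizon (default 5 s, i.e. 50 bins).
#' @return a \linkS4class{FeatureSet}.
#' @export
buildCumulativeFeatures <- function(session, binSizeS = 0.1, horizonS = 5.0) {
  cls <- unique(trials(session)$stimulus)
  if (length(cls) != 2L)
    stop("binary decoder: session must contain exactly 2 stimulus classes, ",
         "found ", length(cls), call. = FALSE)
  if (nUnits(session) < 1L || nTrials(session) < 2L)
    stop("need at least 1 unit and 2 trials", call. = FALSE)
  if (horizonS > session@window[2])
    stop("horizon exceeds the recorded post-stimulus window", call. = FALSE)
  ct <- binCounts(session, binSizeS)
  post <- which(ct@binStarts >= -1e-9 &
                ct@binStarts < horizonS - 1e-9 + binSizeS / 2)
  post <- post[seq_len(round(horizonS / binSizeS))]
  cn <- counts(ct)[, , post, drop = FALSE]
  cum <- if (length(post) > 1L)
    aperm(apply(cn, c(1, 2), cumsum), c(3, 2, 1)) else  # -> trial x unit x bin
    array(aperm(cn, c(2, 1, 3)), dim = dim(cn)[c(2, 1, 3)])
  new("FeatureSet", cum = cum,
      labels = factor(trials(session)$stimulus, levels = sort(cls)),
      binStarts = ct@binStarts[post], sessionId = sessionId(session))
}

## train a maximum-margin classifier on scaled training features and return
## predicted labels for the test rows; degenerate designs fall back to the
## majority training label
svmPredict <- function(xtr, ytr, xte, kernel, degree, coef0, cost) {
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, stats::sd)
  ok <- is.finite(sdev) & sdev > 0
  majority <- levels(ytr)[which.max(tabulate(as.integer(ytr), nlevels(ytr)))]
  if (!any(ok) || length(unique(ytr)) < 2L)
    return(factor(rep(majority, nrow(xte)), levels = levels(ytr)))
  xtr <- sweep(sweep(xtr[, ok, drop = FALSE], 2, mu[ok]), 2, sdev[ok], "/")
  xte <- sweep(sweep(xte[, ok, drop = FALSE], 2, mu[ok]), 2, sdev[ok], "/")
  fit <- e1071::svm(xtr, ytr, scale = FALSE, kernel = kernel,
                    degree = degree, coef0 = coef0, cost = cost,
                    gamma = 1 / ncol(xtr))
  stats::predict(fit, xte)
}

## stratified fold assignment: within each class, shuffled round-robin
stratifiedFolds <- function(labels, folds) {
  f <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

## one full cross-validation pass: per-bin pooled accuracy
cvPass <- function(fs, labels, folds, kernel, degree, coef0, cost) {
  full <- featureMatrixFull(fs)
  C <- dim(fs@cum)[2]
  nb <- dim(fs@cum)[3]
  fold <- stratifiedFolds(labels, folds)
  correct <- integer(nb)
  total <- 0L
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (!length(te)) next
    total <- total + length(te)
    for (b in seq_len(nb)) {
      cols <- seq_len(b * C)
      pred <- svmPredict(full[tr, cols, drop = FALSE], labels[tr],
                         full[te, cols, drop = FALSE],
                         kernel, degree, coef0, cost)
      correct[b] <- correct[b] + sum(pred == labels[te])
    }
  }
  correct / total
}

#' Cross-validated cumulative decoding accuracy
#'
#' At each evaluation bin, trains a maximum-margin (SVM) classifier with a
#' polynomial kernel on the cumulative spike-count features of the training
#' folds and scores the held-out fold; with \code{folds = 5} each fold is a
#' 20\% test split. The whole cross-validation is repeated
#' \code{mcRepeats} times with freshly shuffled stratified fold assignments
#' (Monte-Carlo cross-validation); the per-bin mean and SEM over repeats are
#' reported. Feature standardization is fit on the training folds only.
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param folds cross-validation folds.
#' @param mcRepeats Monte-Carlo repeats.
#' @param seed integer seed for fold shuffling.
#' @param kernel \code{"polynomial"} (default, degree \code{degree}) or
#'   \code{"linear"}.
#' @param degree,coef0,cost kernel degree, additive coefficient and soft
#'   margin cost.
#' @return a \linkS4class{DecodingResult} (chance curve unset).
#' @export
evaluateDecoder <- function(fs, folds = 5L, mcRepeats = 100L, seed = 1L,
                            kernel = c("polynomial", "linear"), degree = 3,
                            coef0 = 1, cost = 1) {
  kernel <- match.arg(kernel)
  if (mcRepeats < 1L) stop("mcRepeats must be >= 1", call. = FALSE)
  cc <- table(fs@labels)
  if (any(cc < folds))
    stop("each class needs at least as many trials as folds", call. = FALSE)
  acc <- with_seed(seed, {
    vapply(seq_len(mcRepeats), function(i)
      cvPass(fs, fs@labels, folds, kernel, degree, coef0, cost),
      numeric(dim(fs@cum)[3]))
  })
  acc <- matrix(acc, nrow = dim(fs@cum)[3])   # bin x repeat
  accSem <- if (mcRepeats > 1L) apply(acc, 1, sem) else rep(0, nrow(acc))
  new("DecodingResult", sessionId = fs@sessionId,
      accuracyMean = rowMeans(acc), accuracySem = accSem,
      binStarts = fs@binStarts, nUnits = dim(fs@cum)[2],
      classCounts = stats::setNames(as.integer(cc), names(cc)),
      mcRepeats = as.integer(mcRepeats))
}

#' Label-permutation chance level
#'
#' Randomly permutes the trial labels and re-runs the full cross-validated
#' decoding; repeated \code{nPermutations} times, the mean accuracy per bin
#' is the empirical chance level of the decoder. With balanced classes it is
#' close to 50\%; class imbalance pushes it modestly above.
#'
#' @inheritParams evaluateDecoder
#' @param nPermutations number of label permutations.
#' @return numeric chance accuracy per evaluation bin, with the per-
#'   permutation bin-mean accuracies in \code{attr(, "per_permutation")}.
#' @export
permutationChance <- function(fs, nPermutations = 500L, folds = 5L, seed = 1L,
                              kernel = c("polynomial", "linear"), degree = 3,
                              coef0 = 1, cost = 1) {
  kernel <- match.arg(kernel)
  if (nPermutations < 1L) stop("nPermutations must be >= 1", call. = FALSE)
  nb <- dim(fs@cum)[3]
  acc <- with_seed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      perm <- sample(fs@labels)
      cvPass(fs, perm, folds, kernel, degree, coef0, cost)
    }, numeric(nb))
  })
  acc <- matrix(acc, nrow = nb)
  out <- rowMeans(acc)
  attr(out, "per_permutation") <- colMeans(acc)
  out
}

#' Attach a chance curve to a decoding result
#'
#' @param result a \linkS4class{DecodingResult}.
#' @param chance per-bin chance curve from \code{\link{permutationChance}}.
#' @param nPermutations permutations used to compute it.
#' @return the updated \linkS4class{DecodingResult}.
#' @export
setChance <- function(result, chance, nPermutations) {
  result@chanceMean <- as.numeric(chance)
  result@nPermutations <- as.integer(nPermutations)
  validObject(result)
  result
}

#' Aggregate decoding results across recording sessions
#'
#' Applies the minimum-population filter (only sessions with at least
#' \code{minUnits} simultaneously recorded units enter the population
#' analysis) and summarizes the per-session maximum cumulative accuracies
#' and the mean per-bin curves.
#'
#' @param results list of \linkS4class{DecodingResult}s.
#' @param minUnits minimum simultaneously recorded units per session.
#' @return list with \code{n_sessions}, \code{per_session_max},
#'   \code{mean_max_accuracy}, \code{sem_max_accuracy}, \code{mean_curve},
#'   \code{mean_chance} (NULL when no session has a chance curve), and
#'   \code{excluded_sessions}.
#' @export
aggregateSessions <- function(results, minUnits = 5L) {
  if (!length(results)) stop("no session results supplied", call. = FALSE)
  keep <- vapply(results, function(r) r@nUnits >= minUnits, logical(1))
  if (!any(keep))
    stop("all sessions excluded by the minimum-units filter (C >= ",
         minUnits, ")", call. = FALSE)
  dropped <- vapply(results[!keep], sessionId, character(1))
  res <- results[keep]
  maxima <- vapply(res, maxAccuracy, numeric(1))
  curves <- vapply(res, accuracy, numeric(length(res[[1]]@accuracyMean)))
  curves <- matrix(curves, ncol = length(res))
  chances <- Filter(length, lapply(res, chanceLevel))
  list(n_sessions = length(res),
       per_session_max = stats::setNames(maxima,
                                         vapply(res, sessionId, character(1))),
       mean_max_accuracy = mean(maxima),
       sem_max_accuracy = if (length(maxima) > 1) sem(maxima) else 0,
       mean_curve = rowMeans(curves),
       mean_chance = if (length(chances))
         rowMeans(matrix(unlist(chances), ncol = length(chances))) else NULL,
       excluded_sessions = dropped)
}
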