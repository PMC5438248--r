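#' Read a trial-aligned spike session from CSV
#'
#' Expects two plain CSV files. \code{spikes.csv} has columns
#' \code{session_id,unit_id,trial_id,t_s}; \code{trials.csv} has
#' \code{session_id,trial_id,stimulus,withdrawal_latency_s,laser_mW}.
#' Rows violating the session invariants (unknown trial or unit references,
#' spike times outside the window, illegal stimulus labels) are reported with
#' their line numbers before the read fails.
#'
#' @param path path to the spikes CSV.
#' @param trialPath path to the trials CSV.
#' @param sessionId optional session to extract when the files hold several;
#'   defaults to the single session present.
#' @param window baseline/post extent in seconds.
#' @return a validated \linkS4class{SpikeSession}.
#' @export
readSpikeSession <- function(path, trialPath, sessionId = NULL,
                             window = c(5, 5)) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr <- utils::read.csv(trialPath, stringsAsFactors = FALSE)
  needSp <- c("session_id", "unit_id", "trial_id", "t_s")
  needTr <- c("session_id", "trial_id", "stimulus", "withdrawal_latency_s",
              "laser_mW")
  missSp <- setdiff(needSp, names(sp))
  missTr <- setdiff(needTr, names(tr))
  if (length(missSp))
    stop("spikes file ", path, " is missing column(s): ",
         paste(missSp, collapse = ", "), call. = FALSE)
  if (length(missTr))
    stop("trials file ", trialPath, " is missing column(s): ",
         paste(missTr, collapse = ", "), call. = FALSE)
  if (is.null(sessionId)) {
    ids <- unique(c(sp$session_id, tr$session_id))
    if (length(ids) != 1L)
      stop("files contain sessions ", paste(ids, collapse = ", "),
           "; pass sessionId to pick one", call. = FALSE)
    sessionId <- ids
  }
  spLine <- which(sp$session_id == sessionId)  # CSV line = row + 1 (header)
  trRows <- tr[tr$session_id == sessionId, , drop = FALSE]
  spRows <- sp[spLine, , drop = FALSE]

  bad <- spLine[!spRows$trial_id %in% trRows$trial_id]
  if (length(bad))
    stop("spikes reference unknown trial_id at ", path, " line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  bad <- spLine[spRows$t_s < -window[1] | spRows$t_s >= window[2]]
  if (length(bad))
    stop("spike time outside [-", window[1], ", ", window[2], ") s at ",
         path, " line(s) ", paste(utils::head(bad + 1L, 10), collapse = ", "),
         call. = FALSE)
  badTr <- which(tr$session_id == sessionId &
                 !tr$stimulus %in% STIMULUS_LEVELS)
  if (length(badTr))
    stop("illegal stimulus label at ", trialPath, " line(s) ",
         paste(utils::head(badTr + 1L, 10), collapse = ", "), call. = FALSE)

  SpikeSession(sessionId = sessionId,
               unitIds = sort(unique(spRows$unit_id)),
               spikes = spRows[, c("unit_id", "trial_id", "t_s")],
               trials = trRows[, c("trial_id", "stimulus",
                                   "withdrawal_latency_s", "laser_mW")],
               window = window)
}

#' Write a spike session to the CSV interchange format
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param path output path for spikes.csv.
#' @param trialPath output path for trials.csv.
#' @return invisibly, the two paths.
#' @export
writeSpikeSession <- function(session, path, trialPath) {
  sp <- cbind(session_id = sessionId(session), spikes(session))
  tr <- cbind(session_id = sessionId(session), trials(session))
  utils::write.csv(sp, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(tr, trialPath, row.names = FALSE, quote = FALSE)
  invisible(c(path, trialPath))
}

#' Read conditioned-place-aversion records from CSV
#'
#' The long behavior format has columns
#' \code{animal_id,group,phase,chamber,seconds,paired_stimulus} with one row
#' per animal, phase (\code{baseline} or \code{test}) and chamber. The
#' returned wide table has one row per animal and chamber with
#' \code{baseline_s} and \code{test_s} columns.
#'
#' @param path path to behavior.csv.
#' @return data.frame with columns \code{animal_id}, \code{group},
#'   \code{chamber}, \code{paired_stimulus}, \code{baseline_s}, \code{test_s}.
#' @export
readCPARecords <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "phase", "chamber", "seconds",
            "paired_stimulus")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("behavior file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(b$phase %in% c("baseline", "test")))
    stop("phase must be 'baseline' or 'test'", call. = FALSE)
  key <- c("animal_id", "group", "chamber", "paired_stimulus")
  base <- b[b$phase == "baseline", c(key, "seconds")]
  test <- b[b$phase == "test", c(key, "seconds")]
  names(base)[5] <- "baseline_s"
  names(test)[5] <- "test_s"
  out <- merge(base, test, by = key, all = TRUE)
  out <- out[order(out$animal_id, out$chamber), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write conditioned-place-aversion records to the long CSV format
#'
#' @param records wide CPA table as returned by \code{\link{readCPARecords}}
#'   or \code{\link{simulateCPACohort}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCPARecords <- function(records, path) {
  long <- rbind(
    data.frame(animal_id = records$animal_id, group = records$group,
               phase = "baseline", chamber = records$chamber,
               seconds = records$baseline_s,
               paired_stimulus = records$paired_stimulus),
    data.frame(animal_id = records$animal_id, group = records$group,
               phase = "test", chamber = records$chamber,
               seconds = records$test_s,
               paired_stimulus = records$paired_stimulus))
  long <- long[order(long$animal_id, long$phase, long$chamber), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
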