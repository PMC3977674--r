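#' Read a fixation table from CSV
#'
#' Expected header:
#' \code{participant,group,trial,stimulus,fix_index,x_px,y_px,duration_ms}
#' with 0-based pixel coordinates (origin top-left, y downward) and
#' 1-based fixation indices that increase strictly within each
#' participant x trial. Malformed input produces an error naming the
#' offending column or row.
#'
#' @param path CSV path.
#' @return data.frame of typed fixation records (row order preserved).
#' @export
readFixations <- function(path) {
  need <- c("participant", "group", "trial", "stimulus", "fix_index",
            "x_px", "y_px", "duration_ms")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("fixation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("fixation table '", path, "' is empty")
    tab <- tab[, need]
    for (cc in c("trial", "fix_index")) tab[[cc]] <- integer(0)
    for (cc in c("x_px", "y_px", "duration_ms")) tab[[cc]] <- numeric(0)
    return(tab)
  }
  tab <- tab[, need]
  for (cc in c("fix_index", "trial", "x_px", "y_px", "duration_ms")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s at row %d ('%s')", cc, bad[1L],
                   tab[[cc]][bad[1L]]), call. = FALSE)
    }
    tab[[cc]] <- if (cc %in% c("fix_index", "trial")) as.integer(v) else v
  }
  if (any(tab$duration_ms <= 0)) {
    bad <- which(tab$duration_ms <= 0)[1L]
    stop("non-positive duration at row ", bad, call. = FALSE)
  }
  key <- paste(tab$participant, tab$trial, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    fi <- tab$fix_index[idx]
    if (any(diff(fi) <= 0)) {
      bad <- idx[which(diff(fi) <= 0)[1L] + 1L]
      stop("fix_index not strictly increasing at row ", bad, call. = FALSE)
    }
  }
  tab
}

#' Preprocess fixation records
#'
#' Applies the standard cleaning: the first fixation of every trial is
#' discarded, fixations outside the stimulus frame are removed (dropped,
#' not clamped: an off-frame fixation cannot overlap any ROI), and trials
#' left with zero fixations are flagged and excluded from per-trial
#' statistics.
#'
#' @param records fixation data.frame from \code{\link{readFixations}}.
#' @param geometry a \code{\link{viewingGeometry}} (frame size).
#' @return the retained records, with attributes \code{nFirstDiscarded},
#'   \code{nOutOfFrame} and \code{flaggedTrials} (data.frame of
#'   participant/trial emptied by preprocessing).
#' @export
preprocessFixations <- function(records, geometry = viewingGeometry()) {
  if (nrow(records) == 0L) {
    out <- records
    attr(out, "nFirstDiscarded") <- 0L
    attr(out, "nOutOfFrame") <- 0L
    attr(out, "flaggedTrials") <- data.frame(participant = character(0),
                                             trial = integer(0))
    return(out)
  }
  key <- paste(records$participant, records$trial, sep = "\r")
  first <- records$fix_index == 1L
  nFirst <- sum(first)
  out <- records[!first, , drop = FALSE]
  fp <- geometry@framePx
  inframe <- out$x_px >= 0 & out$x_px <= fp - 1 &
             out$y_px >= 0 & out$y_px <= fp - 1
  nOut <- sum(!inframe)
  out <- out[inframe, , drop = FALSE]
  keyOut <- paste(out$participant, out$trial, sep = "\r")
  emptied <- setdiff(unique(key), unique(keyOut))
  flagged <- if (length(emptied) > 0L) {
    parts <- strsplit(emptied, "\r", fixed = TRUE)
    data.frame(participant = vapply(parts, `[`, "", 1L),
               trial = as.integer(vapply(parts, `[`, "", 2L)))
  } else {
    data.frame(participant = character(0), trial = integer(0))
  }
  attr(out, "nFirstDiscarded") <- nFirst
  attr(out, "nOutOfFrame") <- nOut
  attr(out, "flaggedTrials") <- flagged
  out
}

#' Per-participant mean saccade amplitude (degrees of visual angle)
#'
#' A saccade amplitude is the Euclidean pixel distance between consecutive
#' retained fixations within a trial (saccades never span trial
#' boundaries), converted to degrees with the linear px-per-degree factor
#' of the viewing geometry. Each participant's value is the mean over all
#' their saccades; participants with no saccades are excluded with a
#' warning.
#'
#' @param records preprocessed fixation records.
#' @param geometry a \code{\link{viewingGeometry}}.
#' @return data.frame \code{participant, group, mean_amplitude_deg,
#'   n_saccades}.
#' @examples
#' g <- viewingGeometry()  # 44.44 px/deg: 44.44 px steps are 1 deg
#' @export
saccadeAmplitudes <- function(records, geometry = viewingGeometry()) {
  ppd <- pxPerDeg(geometry)
  res <- list()
  for (p in unique(records$participant)) {
    sub <- records[records$participant == p, , drop = FALSE]
    amps <- numeric(0)
    for (tr in unique(sub$trial)) {
      tsub <- sub[sub$trial == tr, , drop = FALSE]
      tsub <- tsub[order(tsub$fix_index), , drop = FALSE]
      if (nrow(tsub) < 2L) next
      d <- sqrt(diff(tsub$x_px)^2 + diff(tsub$y_px)^2) / ppd
      amps <- c(amps, d)
    }
    if (length(amps) == 0L) {
      warning("participant ", p, " has no saccades; excluded")
      next
    }
    res[[length(res) + 1L]] <- data.frame(
      participant = p, group = sub$group[1L],
      mean_amplitude_deg = mean(amps), n_saccades = length(amps))
  }
  if (length(res) == 0L) {
    return(data.frame(participant = character(0), group = character(0),
                      mean_amplitude_deg = numeric(0),
                      n_saccades = integer(0)))
  }
  do.call(rbind, res)
}

#' Per-participant mean dwell time (ms)
#'
#' Arithmetic mean of the retained fixation durations per participant.
#'
#' @param records preprocessed fixation records.
#' @return data.frame \code{participant, group, mean_dwell_ms,
#'   n_fixations}.
#' @export
dwellTimes <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(participant = character(0), group = character(0),
                      mean_dwell_ms = numeric(0), n_fixations = integer(0)))
  }
  agg <- lapply(split(records, records$participant), function(sub) {
    data.frame(participant = sub$participant[1L], group = sub$group[1L],
               mean_dwell_ms = mean(sub$duration_ms),
               n_fixations = nrow(sub))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Write per-participant scanpath metrics as CSV
#'
#' Joins amplitude and dwell tables into
#' \code{participant,group,mean_amplitude_deg,mean_dwell_ms,n_saccades}.
#'
#' @param amplitudes output of \code{\link{saccadeAmplitudes}}.
#' @param dwells output of \code{\link{dwellTimes}}.
#' @param path output CSV path.
#' @export
writeMetricsCSV <- function(amplitudes, dwells, path) {
  m <- merge(amplitudes, dwells[, c("participant", "mean_dwell_ms")],
             by = "participant", all.x = TRUE)
  m <- m[, c("participant", "group", "mean_amplitude_deg", "mean_dwell_ms",
             "n_saccades")]
  utils::write.csv(m[order(m$participant), ], path, row.names = FALSE)
  invisible(path)
}
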