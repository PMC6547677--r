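#' Interbeat-interval series
#'
#' Lightweight container for one participant's ordered interbeat intervals
#' (IBIs, milliseconds). Times are task-relative seconds: the first beat
#' terminates at \code{t0_s + ibis_ms[1]/1000}, and cumulative time is
#' strictly increasing because all intervals are positive.
#'
#' @param ibis_ms numeric vector of positive interbeat intervals (ms).
#' @param t0_s task-relative time (seconds) at which the series starts
#'   (negative values place the start inside the baseline recording).
#' @param flags optional logical vector of per-interval artifact flags.
#' @param provenance \code{"raw"} or \code{"corrected"}.
#' @return Object of class \code{"beat_series"}.
#' @export
beat_series <- function(ibis_ms, t0_s = 0,
                        flags = rep(FALSE, length(ibis_ms)),
                        provenance = c("raw", "corrected")) {
  provenance <- match.arg(provenance)
  ibis_ms <- as.numeric(ibis_ms)
  if (!length(ibis_ms)) stop("empty IBI series", call. = FALSE)
  if (any(!is.finite(ibis_ms)) || any(ibis_ms <= 0))
    stop("all IBIs must be positive and finite", call. = FALSE)
  stopifnot(length(flags) == length(ibis_ms))
  structure(list(ibis_ms = ibis_ms, t0_s = t0_s,
                 flags = as.logical(flags), provenance = provenance),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %.1f s from t0 = %.1f s (%s",
              length(x$ibis_ms), sum(x$ibis_ms) / 1000, x$t0_s,
              x$provenance))
  nf <- sum(x$flags)
  if (nf) cat(sprintf(", %d flagged", nf))
  cat(")\n")
  invisible(x)
}

#' Beat end-times of a series
#'
#' @param beats a [beat_series()].
#' @return Numeric vector of task-relative times (s) at which each interval
#'   terminates.
#' @export
beat_times <- function(beats) {
  beats$t0_s + cumsum(beats$ibis_ms) / 1000
}

#' Write / read the two-column IBI text format
#'
#' Plain-text interchange format: a comment header carrying the series
#' start time, then one row per beat with the beat index and the interval
#' in milliseconds.
#'
#' @param beats a [beat_series()].
#' @param path file path.
#' @return \code{write_ibi} returns \code{path} invisibly; \code{read_ibi}
#'   returns a [beat_series()].
#' @export
write_ibi <- function(beats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t0_s: %.6f", beats$t0_s), con)
  writeLines(sprintf("# provenance: %s", beats$provenance), con)
  utils::write.table(
    data.frame(beat = seq_along(beats$ibis_ms), ibi_ms = beats$ibis_ms),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ibi
#' @export
read_ibi <- function(path) {
  hdr <- readLines(path, n = 2L)
  t0 <- as.numeric(sub("^# t0_s:\\s*", "", hdr[1]))
  prov <- sub("^# provenance:\\s*", "", hdr[2])
  if (!prov %in% c("raw", "corrected")) prov <- "raw"
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  beat_series(tab$ibi_ms, t0_s = t0, provenance = prov)
}

#' Flag improbably short interbeat intervals
#'
#' Implements the ratio rule for spotting spuriously placed beats: interval
#' \eqn{k} is flagged when it is at most \code{ratio_threshold} times the
#' size of the *subsequent* interval (\code{ibis[k] <= 0.6 * ibis[k+1]} at
#' the default threshold). A spurious extra beat splits one true interval
#' into two short ones, so the rule catches the dominant scoring error in
#' ECG-derived IBI series. The last interval has no successor and is never
#' flagged. Flagging compares intervals to intervals, so it is invariant to
#' rescaling the whole series.
#'
#' @param beats a [beat_series()].
#' @param ratio_threshold unitless ratio; default 0.6.
#' @return The series with updated \code{flags}; flagged positions and
#'   their end-times are attached as attributes \code{"flag_index"} and
#'   \code{"flag_times"}.
#' @export
flag_improbable_ibis <- function(beats, ratio_threshold = 0.6) {
  ib <- beats$ibis_ms
  n <- length(ib)
  if (!n) stop("empty IBI series", call. = FALSE)
  flags <- c(ib[-n] <= ratio_threshold * ib[-1], FALSE)
  beats$flags <- flags
  attr(beats, "flag_index") <- which(flags)
  attr(beats, "flag_times") <- beat_times(beats)[flags]
  beats
}

#' Correct flagged intervals
#'
#' Three correction strategies for intervals flagged by
#' [flag_improbable_ibis()]:
#' \describe{
#'   \item{merge_adjacent}{A flagged interval is summed with a neighbour
#'     when the sum falls within 20\% of the local median interval. The
#'     successor is tried first; if its sum does not match, the predecessor
#'     is tried, because the ratio rule flags the trailing half of a split
#'     beat (short relative to the next normal beat), whose true
#'     counterpart is the interval before it. Merging conserves cumulative
#'     duration exactly.}
#'   \item{interpolate}{Flagged intervals are replaced by the mean of their
#'     unflagged neighbours.}
#'   \item{drop}{Flagged intervals are removed.}
#' }
#' The local median is computed over up to five intervals on either side,
#' excluding flagged intervals and the merge candidates themselves.
#'
#' @param beats a flagged [beat_series()].
#' @param strategy one of \code{"merge_adjacent"}, \code{"interpolate"},
#'   \code{"drop"}.
#' @param tol relative tolerance around the local median for a merge
#'   (default 0.2).
#' @return Corrected [beat_series()] with \code{provenance = "corrected"};
#'   attribute \code{"n_corrected"} counts altered intervals.
#' @export
correct_flagged <- function(beats,
                            strategy = c("merge_adjacent", "interpolate",
                                         "drop"),
                            tol = 0.2) {
  strategy <- tryCatch(match.arg(strategy),
                       error = function(e)
                         stop("unknown correction strategy", call. = FALSE))
  ib <- beats$ibis_ms
  flags <- beats$flags
  if (!any(flags)) {
    out <- beats
    out$provenance <- "corrected"
    attr(out, "n_corrected") <- 0L
    return(out)
  }
  n_corrected <- 0L
  if (strategy == "merge_adjacent") {
    alive <- rep(TRUE, length(ib))
    k_set <- which(flags)
    for (k in k_set) {
      if (!alive[k] || !flags[k]) next
      cands <- c(k + 1L, k - 1L)
      cands <- cands[cands >= 1L & cands <= length(ib)]
      cands <- cands[alive[cands]]
      merged <- FALSE
      for (j in cands) {
        med <- local_median(ib, flags, alive, exclude = c(k, j))
        if (!is.finite(med)) next
        s <- ib[k] + ib[j]
        if (abs(s - med) <= tol * med) {
          lo <- min(k, j)
          ib[lo] <- s
          alive[max(k, j)] <- FALSE
          flags[lo] <- FALSE
          merged <- TRUE
          n_corrected <- n_corrected + 1L
          break
        }
      }
      if (!merged) flags[k] <- FALSE  # unresolved; leave interval in place
    }
    ib <- ib[alive]
    flags <- flags[alive]
  } else if (strategy == "interpolate") {
    k_set <- which(flags)
    good <- which(!flags)
    for (k in k_set) {
      nb <- c(max(good[good < k]), min(good[good > k]))
      nb <- nb[is.finite(nb)]
      if (length(nb)) {
        ib[k] <- mean(ib[nb])
        n_corrected <- n_corrected + 1L
      }
    }
    flags[] <- FALSE
  } else { # drop
    n_corrected <- sum(flags)
    ib <- ib[!flags]
    flags <- rep(FALSE, length(ib))
  }
  out <- beat_series(ib, t0_s = beats$t0_s, flags = flags,
                     provenance = "corrected")
  attr(out, "n_corrected") <- n_corrected
  out
}

local_median <- function(ib, flags, alive, exclude, halfwidth = 5L) {
  k <- exclude[1]
  win <- seq(max(1L, k - halfwidth), min(length(ib), k + halfwidth))
  win <- setdiff(win, exclude)
  win <- win[alive[win] & !flags[win]]
  if (!length(win)) return(NA_real_)
  median(ib[win])
}

#' Quality-control report for a set of beat series
#'
#' Applies [flag_improbable_ibis()] and, optionally, [correct_flagged()] to
#' each series and tabulates the outcome.
#'
#' @param series named list of [beat_series()] objects (names are
#'   participant ids).
#' @param ratio_threshold flag threshold passed through.
#' @param strategy correction strategy, or \code{"none"} to only flag.
#' @return List with \code{series} (corrected or flagged series) and
#'   \code{report} (data frame: participant, n_beats, n_flags, n_corrected,
#'   strategy, flag_times as comma-separated seconds).
#' @export
qc_beat_series <- function(series, ratio_threshold = 0.6,
                           strategy = "merge_adjacent") {
  stopifnot(is.list(series))
  out <- vector("list", length(series))
  names(out) <- names(series)
  rep_rows <- vector("list", length(series))
  for (i in seq_along(series)) {
    fl <- flag_improbable_ibis(series[[i]], ratio_threshold)
    n_flags <- sum(fl$flags)
    ft <- attr(fl, "flag_times")
    if (identical(strategy, "none")) {
      out[[i]] <- fl
      ncor <- 0L
    } else {
      out[[i]] <- correct_flagged(fl, strategy)
      ncor <- attr(out[[i]], "n_corrected")
    }
    rep_rows[[i]] <- data.frame(
      participant_id = names(series)[i] %||% as.character(i),
      n_beats = length(series[[i]]$ibis_ms),
      n_flags = n_flags, n_corrected = ncor, strategy = strategy,
      flag_times = paste(sprintf("%.2f", ft), collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(series = out, report = do.call(rbind, rep_rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
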