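#' Segment a beat series into overlapping analysis epochs
#'
#' Cuts the task window into \code{epoch_s}-second effective epochs, each
#' carried inside a window padded by \code{pad_s} seconds on either side
#' (54-s inputs for 30-s epochs at the defaults, because the index stage
#' truncates the first and final 12 s of each filtered segment). Adjacent
#' segments therefore overlap by \code{2 * pad_s} while their effective
#' windows tile the task exactly. An interval belongs to a segment when its
#' terminating beat time falls inside the half-open window.
#'
#' The margins for the first and last epoch normally come from the
#' baseline and recovery recordings. When the recording does not cover a
#' padded window, the segment errors by default (naming the epoch); with
#' \code{allow_degraded = TRUE} the missing margin is synthesised by
#' reflecting the available intervals at the recording edge and the
#' segment is marked degraded.
#'
#' @param beats a [beat_series()].
#' @param task_window numeric length-2, task-relative \code{[start, end)}
#'   in seconds; length must be divisible by \code{epoch_s}.
#' @param epoch_s effective epoch length (s).
#' @param pad_s padding on each side of the effective window (s).
#' @param dyad_id,participant_id optional identifiers stored on each
#'   segment.
#' @param allow_degraded reflect-pad segments with missing margins instead
#'   of erroring.
#' @return List of class \code{"epoch_segments"}; each element is a list
#'   with \code{epoch_index} (0-based), \code{window} (padded),
#'   \code{effective_window}, \code{ibis_ms}, \code{times_s} (beat end
#'   times) and \code{degraded}.
#' @export
segment_epochs <- function(beats, task_window = c(0, 300), epoch_s = 30,
                           pad_s = 12, dyad_id = NA, participant_id = NA,
                           allow_degraded = FALSE) {
  len <- diff(task_window)
  if (len <= 0 || abs(len / epoch_s - round(len / epoch_s)) > 1e-9)
    stop("task window length must be a positive multiple of epoch_s",
         call. = FALSE)
  n_epochs <- as.integer(round(len / epoch_s))
  times <- beat_times(beats)
  rec_start <- beats$t0_s
  rec_end <- times[length(times)]
  segs <- vector("list", n_epochs)
  for (k in seq_len(n_epochs) - 1L) {
    w0 <- task_window[1] + k * epoch_s - pad_s
    w1 <- task_window[1] + (k + 1) * epoch_s + pad_s
    degraded <- FALSE
    sel <- times >= w0 & times < w1
    seg_t <- times[sel]
    seg_ib <- beats$ibis_ms[sel]
    if (rec_start > w0 + 1e-9 || rec_end < w1 - 1e-9) {
      if (!allow_degraded)
        stop(sprintf(
          "recording does not cover the padded window [%.1f, %.1f) of epoch %d",
          w0, w1, k), call. = FALSE)
      degraded <- TRUE
      refl <- reflect_pad(seg_t, seg_ib, w0, w1)
      seg_t <- refl$times
      seg_ib <- refl$ibis
    }
    segs[[k + 1L]] <- list(
      dyad_id = dyad_id, participant_id = participant_id,
      epoch_index = k, window = c(w0, w1),
      effective_window = c(w0 + pad_s, w1 - pad_s),
      ibis_ms = seg_ib, times_s = seg_t, degraded = degraded)
  }
  class(segs) <- "epoch_segments"
  segs
}

## mirror the observed beats at whichever window edge lacks coverage
reflect_pad <- function(times, ibis, w0, w1) {
  if (!length(times)) return(list(times = times, ibis = ibis))
  lo <- min(times); hi <- max(times)
  if (lo > w0 + 1e-9) {
    m <- times <= lo + (lo - w0)
    add_t <- 2 * lo - times[m]
    keep <- add_t >= w0 & add_t < lo
    times <- c(add_t[keep], times)
    ibis <- c(ibis[m][keep], ibis)
  }
  if (hi < w1 - 1e-9) {
    m <- times >= hi - (w1 - hi)
    add_t <- 2 * hi - times[m]
    keep <- add_t > hi & add_t < w1
    times <- c(times, add_t[keep])
    ibis <- c(ibis, ibis[m][keep])
  }
  o <- order(times)
  list(times = times[o], ibis = ibis[o])
}

#' @export
print.epoch_segments <- function(x, ...) {
  cat(sprintf("<epoch_segments> %d segments", length(x)))
  if (length(x)) {
    w <- x[[1]]$window
    cat(sprintf(", %g-s windows (effective %g s)",
                diff(w), diff(x[[1]]$effective_window)))
    nd <- sum(vapply(x, function(s) s$degraded, logical(1)))
    if (nd) cat(sprintf(", %d degraded", nd))
  }
  cat("\n")
  invisible(x)
}
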