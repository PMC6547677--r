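#' Cardiac Sympathetic Index of a segment
#'
#' Builds the Lorenz (Poincare) plot of successive interbeat intervals
#' \eqn{(IBI_n, IBI_{n+1})}, rotates it 45 degrees onto the identity axis,
#' and returns the ratio of the longitudinal to the transverse spread:
#' \eqn{CSI = L/T} with \eqn{L = 4\,SD[(IBI_{n+1}+IBI_n)/\sqrt2]} and
#' \eqn{T = 4\,SD[(IBI_{n+1}-IBI_n)/\sqrt2]}. The ratio is invariant to
#' additive shifts and multiplicative rescaling of the intervals. For a
#' stationary series with lag-1 autocorrelation \eqn{\rho} the ratio tends
#' to \eqn{\sqrt{(1+\rho)/(1-\rho)}}.
#'
#' @param segment an element of [segment_epochs()] output, or any list with
#'   an \code{ibis_ms} component.
#' @param min_beats minimum number of intervals required.
#' @return Unitless positive ratio, or \code{NA} (with a \code{"reason"}
#'   attribute) when the segment has too few beats.
#' @export
compute_csi <- function(segment, min_beats = 20) {
  ib <- segment$ibis_ms
  n <- length(ib)
  if (n < min_beats) {
    return(structure(NA_real_, reason = sprintf("only %d beats", n)))
  }
  x <- ib[-n]; y <- ib[-1]
  long_sd <- sd((y + x) / sqrt(2))
  trans_sd <- sd((y - x) / sqrt(2))
  if (trans_sd <= 1e-12 * max(long_sd, 1))
    stop("degenerate Lorenz-plot geometry: successive intervals are collinear",
         call. = FALSE)
  (4 * long_sd) / (4 * trans_sd)
}

#' Log respiratory sinus arrhythmia of a segment
#'
#' Derives the respiratory component of the heart-period signal and
#' returns the natural log of its band-limited variance. The interbeat
#' intervals are interpolated against their beat end-times into a
#' continuous heart-period signal, resampled at \code{fs_hz}, band-passed
#' inside the adult respiration band, and the first and final
#' \code{trunc_s} seconds of the *filtered* signal are discarded (removing
#' filter edge transients and reducing a 54-s input to its effective 30-s
#' epoch). The band-pass is a zero-phase Butterworth filter (order
#' \code{order}, applied forward and backward), so epoch alignment is not
#' distorted by filter lag; the band-pass removes the mean, making the
#' index invariant to constant IBI shifts.
#'
#' For a sinusoidal modulation of amplitude \eqn{A} ms inside the band the
#' index equals \eqn{\log(A^2/2)} up to filter tolerance.
#'
#' @param segment an element of [segment_epochs()] output (must carry
#'   \code{times_s} and \code{window}).
#' @param band_hz numeric length-2 pass band in Hz.
#' @param fs_hz resampling rate in Hz.
#' @param trunc_s seconds truncated from each end of the filtered signal.
#' @param min_beats minimum number of intervals required.
#' @param interp \code{"spline"} (piecewise-cubic, default) or
#'   \code{"linear"} heart-period interpolation.
#' @param order Butterworth order (per direction).
#' @param floor_log values below this are reported missing (numerically
#'   degenerate, e.g. a constant series whose band-limited variance is 0).
#' @return log(ms^2), or \code{NA} with a \code{"reason"} attribute.
#' @export
compute_log_rsa <- function(segment, band_hz = c(0.12, 0.40), fs_hz = 10,
                            trunc_s = 12, min_beats = 20,
                            interp = c("spline", "linear"), order = 3,
                            floor_log = -20) {
  interp <- match.arg(interp)
  ib <- segment$ibis_ms
  tt <- segment$times_s
  if (length(ib) < min_beats)
    return(structure(NA_real_,
                     reason = sprintf("only %d beats", length(ib))))
  w <- segment$window
  grid <- seq(w[1], w[2] - 1 / fs_hz, by = 1 / fs_hz)
  hp <- if (interp == "spline") {
    spline(tt, ib, xout = grid, method = "natural")$y
  } else {
    stats::approx(tt, ib, xout = grid, rule = 2)$y
  }
  hp <- hp - mean(hp)
  bf <- signal::butter(order, band_hz * 2 / fs_hz, type = "pass")
  flt <- signal::filtfilt(bf, hp)
  keep <- grid >= w[1] + trunc_s & grid < w[2] - trunc_s
  v <- var(flt[keep])
  if (!is.finite(v) || v <= 0 || log(v) < floor_log)
    return(structure(NA_real_, reason = "band-limited variance degenerate"))
  log(v)
}

#' Per-epoch autonomic index panel
#'
#' Applies [compute_csi()] and [compute_log_rsa()] to every segment of one
#' or more participants.
#'
#' @param segments an \code{"epoch_segments"} object or a list of them.
#' @param ... passed to the index functions (band, sampling rate,
#'   truncation, minimum beats).
#' @param min_beats minimum beats per segment; under it both indices are
#'   missing.
#' @return Data frame: \code{dyad_id}, \code{participant_id},
#'   \code{epoch_index}, \code{csi}, \code{log_rsa}, \code{n_beats_used},
#'   \code{degraded}.
#' @export
compute_indices <- function(segments, ..., min_beats = 20) {
  if (inherits(segments, "epoch_segments")) segments <- list(segments)
  rows <- lapply(segments, function(segs) {
    do.call(rbind, lapply(segs, function(s) {
      csi <- tryCatch(compute_csi(s, min_beats = min_beats),
                      error = function(e) NA_real_)
      lr <- compute_log_rsa(s, min_beats = min_beats, ...)
      data.frame(dyad_id = s$dyad_id, participant_id = s$participant_id,
                 epoch_index = s$epoch_index,
                 csi = as.numeric(csi), log_rsa = as.numeric(lr),
                 n_beats_used = length(s$ibis_ms), degraded = s$degraded)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
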