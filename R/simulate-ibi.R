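#' Generate raw interbeat-interval series for simulated dyads
#'
#' Emits one [beat_series()] per participant spanning a stationary
#' 5-minute baseline (task-relative time \eqn{[-baseline_s, 0)}), the task
#' window, and a short recovery margin. The heart period is modulated
#' sinusoidally at the respiratory frequency; within each task epoch the
#' modulation amplitude is set so that the band-limited log variance of the
#' heart-period signal (the logRSA index) tracks the participant's
#' epoch-level parasympathetic reactivity trajectory from the panel:
#' \eqn{A_{p,e} = \sqrt{2\exp(\log(A_0^2/2) + y_{p,e})}} where \eqn{A_0}
#' is the baseline amplitude and \eqn{y_{p,e}} the reactivity value.
#'
#' Beats are laid down sequentially: the interval terminating at time
#' \eqn{t} has length \code{base_ibi_ms + A(t) sin(2 pi f t)} (plus
#' optional white jitter), evaluated at the interval's start.
#'
#' @param config a [sim_config()].
#' @param panel optional \code{"epoch_panel"} whose per-epoch reactivity
#'   supplies the target logRSA trajectory; when \code{NULL} the amplitude
#'   is constant at \code{rsa_amp_ms}.
#' @param dyads optional integer vector restricting generation to a subset
#'   of dyads.
#' @param seed integer seed; defaults to \code{config$seed + 2}.
#' @return Named list of [beat_series()] keyed by participant id, with the
#'   participant metadata table attached as attribute
#'   \code{"participants"}.
#' @export
generate_dyad_ibi <- function(config, panel = NULL, dyads = NULL,
                              seed = config$seed + 2L) {
  validate_sim_config(config)
  set.seed(seed)
  task_len <- config$epochs_per_task * config$epoch_s
  if (is.null(panel)) {
    des <- dyad_design(config)
    meta <- do.call(rbind, lapply(seq_len(config$n_dyads), function(d)
      data.frame(dyad_id = d, participant_id = (d - 1L) * 2L + 1:2,
                 sex = des$sex[d], talk = des$talk[d], coop = des$coop[d])))
  } else {
    meta <- participant_meta(panel)
  }
  if (!is.null(dyads)) meta <- meta[meta$dyad_id %in% dyads, ]
  base_amp <- config$rsa_amp_ms
  log_rsa0 <- log(base_amp^2 / 2)
  out <- vector("list", nrow(meta))
  names(out) <- as.character(meta$participant_id)
  for (i in seq_len(nrow(meta))) {
    pid <- meta$participant_id[i]
    if (!is.null(panel)) {
      own <- panel[panel$participant_id == pid, ]
      own <- own[order(own$epoch), ]
      amp_epoch <- sqrt(2 * exp(log_rsa0 + own$react))
    } else {
      amp_epoch <- rep(base_amp, config$epochs_per_task)
    }
    # amplitude must stay below half the base IBI to keep intervals positive
    amp_epoch <- pmin(amp_epoch, 0.49 * config$base_ibi_ms)
    out[[i]] <- simulate_ibi_track(
      base_ms = config$base_ibi_ms, freq_hz = config$rsa_freq_hz,
      base_amp = base_amp, amp_epoch = amp_epoch,
      epoch_s = config$epoch_s, t_start = -config$baseline_s,
      t_end = task_len + 15, noise_ms = config$ibi_noise_ms)
  }
  attr(out, "participants") <- meta
  out
}

simulate_ibi_track <- function(base_ms, freq_hz, base_amp, amp_epoch,
                               epoch_s, t_start, t_end, noise_ms = 0) {
  n_guess <- ceiling((t_end - t_start) / (base_ms / 1000)) + 16L
  ibis <- numeric(n_guess)
  tt <- t_start
  k <- 0L
  task_len <- length(amp_epoch) * epoch_s
  while (tt < t_end) {
    if (tt >= 0 && tt < task_len) {
      amp <- amp_epoch[floor(tt / epoch_s) + 1L]
    } else {
      amp <- base_amp
    }
    ib <- base_ms + amp * sin(2 * pi * freq_hz * tt)
    if (noise_ms > 0) ib <- ib + rnorm(1, 0, noise_ms)
    ib <- max(ib, 0.2 * base_ms)
    k <- k + 1L
    if (k > length(ibis)) ibis <- c(ibis, numeric(n_guess))
    ibis[k] <- ib
    tt <- tt + ib / 1000
  }
  beat_series(ibis[seq_len(k)], t0_s = t_start, provenance = "raw")
}

#' Inject missed-R-wave artifacts into a beat series
#'
#' Emulates the dominant ECG scoring error: a spuriously placed R wave
#' splits one true interval into two short intervals that sum exactly to
#' the original. Each interval is independently selected for splitting
#' with probability \code{rate}; the split fraction is uniform on
#' [0.4, 0.6] ("near half"), so each fragment is well below 0.6 of the
#' adjacent normal intervals and triggers the ratio flagger downstream.
#'
#' @param beats a [beat_series()].
#' @param rate per-interval split probability in [0, 0.5).
#' @param seed integer seed.
#' @return A new [beat_series()] with ground truth attached as attribute
#'   \code{"splits"}: a data frame with the original interval index, its
#'   value and the two fragments.
#' @export
inject_artifacts <- function(beats, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5)
    stop("rate must lie in [0, 0.5)", call. = FALSE)
  set.seed(seed)
  ib <- beats$ibis_ms
  hit <- which(runif(length(ib)) < rate)
  if (!length(hit)) {
    out <- beats
    attr(out, "splits") <- data.frame(index = integer(), original = numeric(),
                                      first = numeric(), second = numeric())
    return(out)
  }
  frac <- runif(length(hit), 0.4, 0.6)
  pieces <- vector("list", length(ib))
  for (k in seq_along(ib)) pieces[[k]] <- ib[k]
  for (j in seq_along(hit)) {
    k <- hit[j]
    pieces[[k]] <- c(ib[k] * frac[j], ib[k] * (1 - frac[j]))
  }
  out <- beat_series(unlist(pieces), t0_s = beats$t0_s, provenance = "raw")
  attr(out, "splits") <- data.frame(index = hit, original = ib[hit],
                                    first = ib[hit] * frac,
                                    second = ib[hit] * (1 - frac))
  out
}
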