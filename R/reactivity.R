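#' Residualized-change reactivity scores
#'
#' Converts per-epoch autonomic indices into reactivity relative to the
#' resting baseline using residualized change: per branch, the epoch index
#' is regressed on the participant's baseline summary in a single pooled
#' regression across all participant-epochs, and the residual is the
#' reactivity score. Residualized change examines change beyond baseline
#' levels while absorbing the regression-to-the-mean component that simple
#' change scores carry; the residuals are exactly orthogonal to baseline
#' and have mean zero across the fitting sample.
#'
#' Residualization is pooled across all participants (not per condition):
#' per-condition residualization would absorb the very condition effects
#' the synchrony model is built to estimate.
#'
#' When the baseline has zero variance across the sample the regression is
#' undefined; the function falls back to simple change scores
#' (\code{value - baseline}) with a warning.
#'
#' @param task data frame of task epochs: \code{participant_id},
#'   \code{epoch} (or \code{epoch_index}), \code{value}, and optionally
#'   \code{dyad_id}.
#' @param baseline data frame with \code{participant_id} and
#'   \code{baseline} (the participant's mean index over baseline epochs,
#'   computed with the same segmentation as the task epochs).
#' @return Data frame of class \code{"reactivity_panel"} with the task
#'   columns plus \code{baseline} and \code{reactivity}; the pooled fit is
#'   attached as attribute \code{"fit"} (list: intercept, slope, method).
#' @export
residualized_change <- function(task, baseline) {
  if (!"epoch" %in% names(task) && "epoch_index" %in% names(task))
    task$epoch <- task$epoch_index
  stopifnot(all(c("participant_id", "value") %in% names(task)),
            all(c("participant_id", "baseline") %in% names(baseline)))
  task$baseline <- baseline$baseline[
    match(task$participant_id, baseline$participant_id)]
  if (any(is.na(task$baseline)))
    stop("every participant needs a baseline summary", call. = FALSE)
  ok <- !is.na(task$value)
  if (sd(task$baseline[ok]) < 1e-12) {
    warning("baseline has zero variance; falling back to simple change scores")
    task$reactivity <- task$value - task$baseline
    fit <- list(intercept = 0, slope = 1, method = "simple_change")
  } else {
    m <- lm(value ~ baseline, data = task[ok, ])
    task$reactivity <- NA_real_
    task$reactivity[ok] <- resid(m)
    fit <- list(intercept = unname(coef(m)[1]), slope = unname(coef(m)[2]),
                method = "residualized_change")
  }
  attr(task, "fit") <- fit
  class(task) <- c("reactivity_panel", "data.frame")
  task
}

#' Baseline-by-condition confound check
#'
#' Tests whether baseline autonomic levels differ between experimental
#' conditions (a confound for reactivity analyses, since conditions are
#' assigned before the task but baseline is recorded first and should be
#' independent of them). Fits baseline ~ talk * coop with a dyad-level
#' random intercept (participants are nested in dyads) and reports the
#' condition contrasts with between-within degrees of freedom.
#'
#' @param baseline data frame: \code{participant_id}, \code{dyad_id},
#'   \code{baseline}, \code{talk}, \code{coop} (+1/-1 codes).
#' @return Data frame with one row per condition term: estimate, SE, df,
#'   t, p.
#' @export
baseline_condition_check <- function(baseline) {
  stopifnot(all(c("participant_id", "dyad_id", "baseline", "talk", "coop")
                %in% names(baseline)))
  if (sd(baseline$baseline) < 1e-12) {
    return(data.frame(term = c("talk", "coop", "talk:coop"),
                      estimate = 0, se = NA_real_, df = NA_real_,
                      t_value = 0, p_value = 1))
  }
  fit <- nlme::lme(baseline ~ talk * coop, random = ~ 1 | dyad_id,
                   data = baseline, method = "REML",
                   control = nlme::lmeControl(opt = "optim"))
  tt <- summary(fit)$tTable
  out <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                    se = tt[, "Std.Error"], df = tt[, "DF"],
                    t_value = tt[, "t-value"], p_value = tt[, "p-value"],
                    row.names = NULL)
  out[out$term != "(Intercept)", ]
}
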