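#' Generate an epoch-level dyadic reactivity panel with known ground truth
#'
#' Simulates the long-format panel that the synchrony model consumes: for
#' every dyad, both directed partner observations (each member serves once
#' as the outcome series), ten epochs each, with dyad-specific concurrent
#' coupling, lag-1 autoregression, +1/-1 coded condition effects and AR(1)
#' epoch-level residuals.
#'
#' Each participant contributes two epoch series: an exogenous *actor*
#' series (their measured reactivity as it enters the partner's equation as
#' the concurrent "synchrony" predictor; standard normal white noise) and an
#' *outcome* series generated from the structural equation documented in
#' [sim_config()]. Separating the two roles makes the fitted conditional
#' model identical to the generative truth, so maximum-likelihood estimates
#' are consistent and confidence intervals attain nominal coverage; in real
#' recordings a single measured series plays both roles and the model is an
#' approximation (see the methods vignette). The first epoch of each
#' outcome series is drawn independent of the random effects and residual
#' chain, so that the model conditional on the first (lag-only) epoch is
#' exactly correctly specified.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return A data frame of class \code{"epoch_panel"} with one row per
#'   directed observation and epoch: \code{dyad_id}, \code{participant_id}
#'   (owner of the outcome series), \code{partner_id}, \code{sex},
#'   \code{talk}, \code{coop} (+1/-1 codes), \code{epoch} (1-based),
#'   \code{react} (outcome reactivity), \code{react_lag} (own lag-1 value,
#'   \code{NA} at the first epoch) and \code{partner_react} (partner's
#'   concurrent actor value). Ground truth is attached as attributes:
#'   \code{"truth"} (generator parameters plus per-dyad true slopes) and
#'   \code{"participants"} (metadata table).
#' @export
generate_epoch_panel <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  des <- dyad_design(config)
  Tt <- config$epochs_per_task
  ce <- config$cond_effects
  se <- config$sync_cond_effects
  n <- config$n_dyads

  u_sync <- rnorm(n, 0, config$sigma_sync)
  u_dyad <- rnorm(n, 0, config$sd_dyad_intercept)

  rows <- vector("list", 2L * n)
  for (d in seq_len(n)) {
    talk <- des$talk[d]; coop <- des$coop[d]
    slope_d <- config$beta_sync + u_sync[d] +
      se[["talk"]] * talk + se[["coop"]] * coop +
      se[["talk_coop"]] * talk * coop
    mu_d <- config$b0 + u_dyad[d] +
      ce[["talk"]] * talk + ce[["coop"]] * coop +
      ce[["talk_coop"]] * talk * coop
    for (m in 1:2) {
      pid <- (d - 1L) * 2L + m
      partner <- (d - 1L) * 2L + (3L - m)
      b_p <- rnorm(1, 0, config$sd_participant_intercept)
      x <- rnorm(Tt)                       # partner's actor series
      eps <- numeric(Tt)
      if (Tt >= 2) {
        eps[2] <- rnorm(1, 0, config$sigma_resid)
        if (Tt >= 3) {
          innov_sd <- config$sigma_resid * sqrt(1 - config$phi_ar1^2)
          for (t in 3:Tt)
            eps[t] <- config$phi_ar1 * eps[t - 1] + rnorm(1, 0, innov_sd)
        }
      }
      y <- numeric(Tt)
      # first epoch independent of random effects and the residual chain
      y[1] <- config$b0 + ce[["talk"]] * talk + ce[["coop"]] * coop +
        ce[["talk_coop"]] * talk * coop + rnorm(1, 0, config$sigma_resid)
      mu <- mu_d + b_p
      for (t in 2:Tt)
        y[t] <- mu + config$rho_lag * y[t - 1] + slope_d * x[t] + eps[t]
      rows[[(d - 1L) * 2L + m]] <- data.frame(
        dyad_id = d, participant_id = pid, partner_id = partner,
        sex = des$sex[d], talk = talk, coop = coop,
        epoch = seq_len(Tt),
        react = y, react_lag = c(NA_real_, y[-Tt]), partner_react = x,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  attr(panel, "truth") <- list(
    beta_sync = config$beta_sync, sigma_sync = config$sigma_sync,
    rho_lag = config$rho_lag, phi_ar1 = config$phi_ar1,
    b0 = config$b0, cond_effects = ce,
    dyad_slopes = data.frame(dyad_id = seq_len(n),
                             true_slope = config$beta_sync + u_sync,
                             talk = des$talk, coop = des$coop))
  attr(panel, "participants") <- participant_meta(panel)
  class(panel) <- c("epoch_panel", "data.frame")
  panel
}

participant_meta <- function(panel) {
  mt <- unique(panel[, c("dyad_id", "participant_id", "partner_id",
                         "sex", "talk", "coop")])
  rownames(mt) <- NULL
  mt
}

#' Assemble a directed synchrony panel from per-participant reactivity
#'
#' Builds the long-format panel for [fit_synchrony_model()] from measured
#' (or simulated) per-epoch reactivity scores: each participant serves once
#' as the outcome series, with their own lag-1 value and the partner's
#' concurrent reactivity as predictors. This is the entry point for real
#' recordings, where a single measured series plays both the outcome and
#' predictor roles.
#'
#' @param reactivity data frame with columns \code{dyad_id},
#'   \code{participant_id}, \code{epoch}, \code{reactivity} and the
#'   condition metadata columns \code{talk}, \code{coop} (and optionally
#'   \code{sex}).
#' @return An \code{"epoch_panel"} data frame (see
#'   [generate_epoch_panel()]); \code{partner_react} is the partner's
#'   measured reactivity.
#' @export
build_synchrony_panel <- function(reactivity) {
  need <- c("dyad_id", "participant_id", "epoch", "reactivity",
            "talk", "coop")
  miss <- setdiff(need, names(reactivity))
  if (length(miss))
    stop("reactivity panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"sex" %in% names(reactivity)) reactivity$sex <- "U"
  reactivity <- reactivity[order(reactivity$dyad_id,
                                 reactivity$participant_id,
                                 reactivity$epoch), ]
  out <- lapply(split(reactivity, reactivity$dyad_id), function(dd) {
    pids <- unique(dd$participant_id)
    if (length(pids) != 2L)
      stop("dyad ", dd$dyad_id[1], " does not have exactly two participants",
           call. = FALSE)
    both <- lapply(pids, function(p) dd[dd$participant_id == p, ])
    do.call(rbind, lapply(1:2, function(m) {
      self <- both[[m]]; other <- both[[3 - m]]
      other_val <- other$reactivity[match(self$epoch, other$epoch)]
      data.frame(dyad_id = self$dyad_id, participant_id = self$participant_id,
                 partner_id = other$participant_id[1], sex = self$sex,
                 talk = self$talk, coop = self$coop, epoch = self$epoch,
                 react = self$reactivity,
                 react_lag = c(NA_real_, self$reactivity[-nrow(self)]),
                 partner_react = other_val, stringsAsFactors = FALSE)
    }))
  })
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  attr(panel, "participants") <- participant_meta(panel)
  class(panel) <- c("epoch_panel", "data.frame")
  panel
}

## Per-participant series view used by pseudo-dyad re-pairing: each
## participant's outcome series (their rows) and actor series (the
## partner_react values stored on the partner's rows).
panel_series <- function(panel) {
  meta <- participant_meta(panel)
  series <- lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$participant_id[i]
    own <- panel[panel$participant_id == p, ]
    own <- own[order(own$epoch), ]
    on_partner <- panel[panel$partner_id == p, ]
    on_partner <- on_partner[order(on_partner$epoch), ]
    list(outcome = own$react, actor = on_partner$partner_react,
         epoch = own$epoch)
  })
  names(series) <- meta$participant_id
  list(meta = meta, series = series)
}

#' Generate affiliation outcomes tied to synchrony and reactivity truth
#'
#' Produces the per-participant affiliation table: three continuous
#' self-report outcomes (perceived similarity and friendship interest on
#' 1-7 scales, negative affect on a 1-5 scale) generated as linear
#' functions of the dyad's true coupling slope, the participant's mean
#' reactivity, the +1/-1 condition codes and any interactions named in
#' \code{config$outcome_effects}, with residuals correlated across outcomes
#' within participant.
#'
#' @param panel an \code{"epoch_panel"} from [generate_epoch_panel()] (must
#'   carry the ground-truth attribute).
#' @param config the [sim_config()] used to generate the panel.
#' @param seed integer seed; defaults to \code{config$seed + 1}.
#' @return Data frame of class \code{"affiliation_table"}: one row per
#'   participant with \code{dyad_id}, \code{participant_id}, \code{sex},
#'   \code{talk}, \code{coop}, \code{sync} (dyad-level slope, attached to
#'   both members), \code{react} (participant mean reactivity) and the
#'   three outcome columns.
#' @export
generate_affiliation_outcomes <- function(panel, config,
                                          seed = config$seed + 1L) {
  truth <- attr(panel, "truth")
  if (is.null(truth))
    stop("panel does not carry ground truth; use generate_epoch_panel()",
         call. = FALSE)
  check_outcome_effects(config$outcome_effects)
  set.seed(seed)
  meta <- participant_meta(panel)
  react <- tapply(panel$react, panel$participant_id, mean)
  meta$react <- as.numeric(react[as.character(meta$participant_id)])
  meta$sync <- truth$dyad_slopes$true_slope[
    match(meta$dyad_id, truth$dyad_slopes$dyad_id)]

  outs <- affil_outcomes()
  D <- diag(config$outcome_sd[outs])
  Sigma <- D %*% config$resid_corr[outs, outs] %*% D
  E <- MASS::mvrnorm(nrow(meta), mu = rep(0, 3), Sigma = Sigma)
  colnames(E) <- outs

  base <- list(talk = meta$talk, coop = meta$coop,
               react = meta$react, sync = meta$sync)
  for (o in outs) {
    val <- rep(config$outcome_intercepts[[o]], nrow(meta))
    co <- config$outcome_effects[[o]]
    if (length(co)) {
      for (term in names(co)) {
        parts <- strsplit(term, ":", fixed = TRUE)[[1]]
        v <- Reduce(`*`, base[parts])
        val <- val + co[[term]] * v
      }
    }
    meta[[o]] <- val + E[, o]
  }
  rownames(meta) <- NULL
  class(meta) <- c("affiliation_table", "data.frame")
  meta
}
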