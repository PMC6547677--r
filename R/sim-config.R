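#' Simulation configuration for synthetic dyads
#'
#' Collects every parameter of the synthetic-data generator in one validated
#' object. The defaults reproduce the study conditions the downstream models
#' were designed around: 67 same-sex stranger dyads in a 2 (talking) x 2
#' (cooperation) between-dyad design, a 5-minute baseline followed by a
#' 5-minute task split into ten 30-second epochs, respiratory heart-period
#' modulation inside the adult respiration band, and epoch-level reactivity
#' dynamics with a dyad-specific concurrent coupling slope, a lag-1
#' autoregressive term, and AR(1) epoch-level residuals.
#'
#' Epoch-level dynamics: for each directed partner pair within a dyad the
#' outcome series follows
#' \deqn{y_t = b_0 + u_d + u_p + c'\,\mathrm{cond} + \rho_{lag} y_{t-1} +
#'   (\beta_{sync} + s_d)\, x_t + \varepsilon_t,}
#' where \eqn{x_t} is the partner's concurrent reactivity, \eqn{s_d \sim
#' N(0, \sigma_{sync}^2)} is the dyad's coupling deviation and
#' \eqn{\varepsilon_t} is AR(1) with autocorrelation \code{phi_ar1} and
#' stationary standard deviation \code{sigma_resid}.
#'
#' @param n_dyads number of dyads (two participants each).
#' @param epochs_per_task number of effective 30-s epochs in the task window.
#' @param epoch_s effective epoch length in seconds.
#' @param baseline_s length of the resting baseline recording in seconds.
#' @param base_ibi_ms mean interbeat interval in milliseconds.
#' @param rsa_freq_hz respiratory modulation frequency; must lie within the
#'   0.12--0.40 Hz respiration band used by the band-pass filter.
#' @param rsa_amp_ms baseline amplitude of the respiratory IBI modulation in
#'   milliseconds; must satisfy \code{base_ibi_ms > 2 * rsa_amp_ms}.
#' @param b0 fixed intercept of the epoch-level outcome equation.
#' @param beta_sync mean concurrent coupling ("synchrony") slope.
#' @param sigma_sync standard deviation of dyad-specific coupling slopes.
#' @param rho_lag coefficient on the outcome's own lag-1 value.
#' @param phi_ar1 AR(1) autocorrelation of epoch-level residuals, |phi| < 1.
#' @param cond_effects named numeric vector \code{c(talk=, coop=, talk_coop=)}
#'   of reactivity shifts for the +1/-1 coded conditions.
#' @param sync_cond_effects named numeric vector \code{c(talk=, coop=,
#'   talk_coop=)} of condition moderation of the coupling slope (default all
#'   zero: synchrony is unmoderated by condition).
#' @param sd_dyad_intercept,sd_participant_intercept standard deviations of
#'   the dyad- and participant-level random intercepts.
#' @param sigma_resid stationary standard deviation of epoch-level residuals.
#' @param cell_weights relative number of dyads allocated to the four cells
#'   (talking-cooperative, talking-competitive, no-talking-cooperative,
#'   no-talking-competitive); defaults to the 16:16:15:20 allocation of the
#'   emulated study.
#' @param prop_female proportion of dyads labelled female (pairs are
#'   same-sex; the label only matters for pseudo-dyad re-pairing strata).
#' @param outcome_effects named list (one element per affiliation outcome:
#'   \code{similarity}, \code{friendship}, \code{negative_affect}) of named
#'   coefficient vectors over the terms \code{talk}, \code{coop},
#'   \code{react}, \code{sync} and their \code{":"}-separated products.
#' @param outcome_intercepts,outcome_sd named numeric vectors of scale
#'   intercepts and residual standard deviations for the three outcomes.
#' @param resid_corr 3x3 symmetric positive-definite correlation matrix of
#'   the within-participant residuals across the three outcomes.
#' @param ibi_noise_ms standard deviation of white beat-to-beat IBI jitter
#'   added by the raw-signal generator (default 0: purely respiratory
#'   modulation).
#' @param seed default random seed carried by the configuration; generator
#'   functions also accept an explicit \code{seed} argument.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @seealso [generate_epoch_panel()], [generate_dyad_ibi()],
#'   [generate_affiliation_outcomes()]
#' @export
sim_config <- function(n_dyads = 67,
                       epochs_per_task = 10,
                       epoch_s = 30,
                       baseline_s = 300,
                       base_ibi_ms = 800,
                       rsa_freq_hz = 0.25,
                       rsa_amp_ms = 40,
                       b0 = 0.017,
                       beta_sync = 0.061,
                       sigma_sync = sqrt(0.032),
                       rho_lag = -0.263,
                       phi_ar1 = 0.461,
                       cond_effects = c(talk = 0.201, coop = 0.138,
                                        talk_coop = 0.035),
                       sync_cond_effects = c(talk = 0, coop = 0,
                                             talk_coop = 0),
                       sd_dyad_intercept = sqrt(0.075),
                       sd_participant_intercept = sqrt(0.199),
                       sigma_resid = sqrt(0.648),
                       cell_weights = c(16, 16, 15, 20),
                       prop_female = 0.7,
                       outcome_effects = default_outcome_effects(),
                       outcome_intercepts = c(similarity = 4.41,
                                              friendship = 4.81,
                                              negative_affect = 1.28),
                       outcome_sd = c(similarity = 0.97,
                                      friendship = 1.08,
                                      negative_affect = 0.46),
                       resid_corr = default_resid_corr(),
                       ibi_noise_ms = 0,
                       seed = 1L) {
  cfg <- list(
    n_dyads = as.integer(n_dyads), epochs_per_task = as.integer(epochs_per_task),
    epoch_s = epoch_s, baseline_s = baseline_s,
    base_ibi_ms = base_ibi_ms, rsa_freq_hz = rsa_freq_hz,
    rsa_amp_ms = rsa_amp_ms, b0 = b0,
    beta_sync = beta_sync, sigma_sync = sigma_sync, rho_lag = rho_lag,
    phi_ar1 = phi_ar1, cond_effects = cond_effects,
    sync_cond_effects = sync_cond_effects,
    sd_dyad_intercept = sd_dyad_intercept,
    sd_participant_intercept = sd_participant_intercept,
    sigma_resid = sigma_resid, cell_weights = cell_weights,
    prop_female = prop_female, outcome_effects = outcome_effects,
    outcome_intercepts = outcome_intercepts, outcome_sd = outcome_sd,
    resid_corr = resid_corr, ibi_noise_ms = ibi_noise_ms,
    seed = as.integer(seed))
  if (is.matrix(cfg$resid_corr) && is.null(dimnames(cfg$resid_corr)))
    dimnames(cfg$resid_corr) <- list(affil_outcomes(), affil_outcomes())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d dyads, %d x %g-s epochs, %g-s baseline\n",
              x$n_dyads, x$epochs_per_task, x$epoch_s, x$baseline_s))
  cat(sprintf("  IBI %g ms, RSA %g ms @ %g Hz\n",
              x$base_ibi_ms, x$rsa_amp_ms, x$rsa_freq_hz))
  cat(sprintf("  beta_sync %.3f (SD %.3f), rho_lag %.3f, phi %.3f\n",
              x$beta_sync, x$sigma_sync, x$rho_lag, x$phi_ar1))
  cat(sprintf("  cond effects: talk %.3f, coop %.3f, talk:coop %.3f\n",
              x$cond_effects[["talk"]], x$cond_effects[["coop"]],
              x$cond_effects[["talk_coop"]]))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_dyads >= 1)
  if (cfg$epochs_per_task < 2)
    stop("epochs_per_task must be >= 2", call. = FALSE)
  if (abs(cfg$phi_ar1) >= 1)
    stop("phi_ar1 must lie strictly inside (-1, 1)", call. = FALSE)
  if (cfg$sigma_sync < 0)
    stop("sigma_sync must be non-negative", call. = FALSE)
  if (cfg$rsa_freq_hz < 0.12 || cfg$rsa_freq_hz > 0.40)
    stop("rsa_freq_hz must lie within the 0.12-0.40 Hz respiration band",
         call. = FALSE)
  if (cfg$base_ibi_ms <= 2 * cfg$rsa_amp_ms)
    stop("base_ibi_ms must exceed twice rsa_amp_ms", call. = FALSE)
  for (nm in c("talk", "coop", "talk_coop")) {
    if (!nm %in% names(cfg$cond_effects))
      stop("cond_effects must name talk, coop and talk_coop", call. = FALSE)
  }
  rc <- cfg$resid_corr
  if (!is.matrix(rc) || nrow(rc) != 3L || ncol(rc) != 3L ||
      max(abs(rc - t(rc))) > 1e-10)
    stop("resid_corr must be a symmetric 3x3 matrix", call. = FALSE)
  ev <- eigen(rc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("resid_corr must be positive-definite", call. = FALSE)
  check_outcome_effects(cfg$outcome_effects)
  invisible(cfg)
}

#' Default affiliation coefficient map
#'
#' Moderate condition-by-reactivity-by-synchrony structure emulating the
#' kind of effects the affiliation models are built to detect: a direct
#' synchrony effect on perceived similarity, reactivity effects on
#' friendship interest, and opposing three-way interactions of the talking
#' and cooperation conditions with reactivity and synchrony on friendship.
#'
#' @return Named list of named coefficient vectors.
#' @export
default_outcome_effects <- function() {
  list(
    similarity = c(sync = 2.0, react = 0.48, "talk:react" = 0.46),
    friendship = c(react = 0.69, "talk:react" = 0.60, "coop:react" = -0.72,
                   "talk:react:sync" = 4.2, "coop:react:sync" = -4.3),
    negative_affect = c())
}

#' Default cross-outcome residual correlation matrix
#'
#' Similarity and friendship interest correlate positively; negative affect
#' correlates weakly and negatively with both.
#'
#' @return 3x3 correlation matrix.
#' @export
default_resid_corr <- function() {
  m <- matrix(c(1, 0.55, -0.20,
                0.55, 1, -0.25,
                -0.20, -0.25, 1), 3, 3,
              dimnames = list(affil_outcomes(), affil_outcomes()))
  m
}

affil_outcomes <- function() c("similarity", "friendship", "negative_affect")

outcome_term_basis <- function() c("talk", "coop", "react", "sync")

check_outcome_effects <- function(effects) {
  if (!is.list(effects))
    stop("outcome_effects must be a named list", call. = FALSE)
  unknown_outcomes <- setdiff(names(effects), affil_outcomes())
  if (length(unknown_outcomes))
    stop("unknown outcome(s) in outcome_effects: ",
         paste(unknown_outcomes, collapse = ", "), call. = FALSE)
  basis <- outcome_term_basis()
  for (o in names(effects)) {
    co <- effects[[o]]
    if (!length(co)) next
    parts <- strsplit(names(co), ":", fixed = TRUE)
    bad <- vapply(parts, function(p) {
      any(!p %in% basis) || anyDuplicated(p) > 0
    }, logical(1))
    if (any(bad))
      stop("outcome_effects for '", o, "' references unknown term(s): ",
           paste(names(co)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(effects)
}

## Allocate dyads to the 2x2 cells by largest remainder on cell_weights,
## and assign sex labels (same-sex pairs).
dyad_design <- function(cfg) {
  w <- cfg$cell_weights / sum(cfg$cell_weights)
  n <- cfg$n_dyads
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- w * n - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  cells <- data.frame(talk = c(1, 1, -1, -1), coop = c(1, -1, 1, -1))
  idx <- rep(seq_len(4), base)
  n_f <- round(cfg$prop_female * n)
  data.frame(dyad_id = seq_len(n),
             talk = cells$talk[idx], coop = cells$coop[idx],
             sex = rep(c("F", "M"), c(n_f, n - n_f))[seq_len(n)],
             stringsAsFactors = FALSE)
}
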