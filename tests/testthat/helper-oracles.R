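# shared fixtures and independent oracles

# per-dyad ordinary-least-squares synchrony slope: pools a dyad's two
# directed series and regresses outcome on own lag + partner concurrent
per_dyad_ols <- function(panel) {
  dat <- panel[!is.na(panel$react_lag), ]
  vapply(split(dat, dat$dyad_id), function(dd) {
    unname(coef(lm(react ~ react_lag + partner_react, data = dd))["partner_react"])
  }, numeric(1))
}

# sequential beat layout for a sinusoidally modulated heart period
mk_sine_beats <- function(freq_hz, amp_ms = 40, base_ms = 800,
                          t0 = -15, t1 = 315) {
  tt <- t0
  ibis <- numeric(0)
  while (tt < t1) {
    ib <- base_ms + amp_ms * sin(2 * pi * freq_hz * tt)
    ibis <- c(ibis, ib)
    tt <- tt + ib / 1000
  }
  beat_series(ibis, t0_s = t0)
}

# AR(1) interbeat series with known lag-1 correlation
mk_ar1_beats <- function(n, rho, base_ms = 800, sd_ms = 50, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, sqrt(1 - rho^2))
  beat_series(base_ms + sd_ms * x)
}

quiet_fit <- function(...) suppressWarnings(fit_synchrony_model(...))

# fraction of the original intervals present intact in the corrected
# series: an interval is restored when its two cumulative-time boundaries
# appear as *adjacent* boundaries of the corrected series
restored_fraction <- function(original, corrected, tol = 1e-6) {
  cb <- c(0, cumsum(original$ibis_ms))
  cf <- c(0, cumsum(corrected$ibis_ms))
  intact <- vapply(seq_along(original$ibis_ms), function(k) {
    i <- which(abs(cf - cb[k]) < tol)
    length(i) == 1 && i < length(cf) && abs(cf[i + 1] - cb[k + 1]) < tol
  }, logical(1))
  mean(intact)
}

# small panel config used across model tests
test_config <- function(n_dyads = 67, ...) {
  sim_config(n_dyads = n_dyads, beta_sync = 0.30, sigma_sync = 0.20,
             rho_lag = -0.25, phi_ar1 = 0.50, ...)
}
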