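test_that("degenerate noiseless panel collapses to the intercept", {
  cfg <- sim_config(n_dyads = 4, b0 = 5, beta_sync = 0, sigma_sync = 0,
                    rho_lag = 0, phi_ar1 = 0, sigma_resid = 0,
                    sd_dyad_intercept = 0, sd_participant_intercept = 0,
                    cond_effects = c(talk = 0, coop = 0, talk_coop = 0))
  p <- generate_epoch_panel(cfg)
  expect_true(all(p$react == 5))
})

test_that("panel shape and lag bookkeeping match the design", {
  cfg <- test_config(seed = 1)
  p <- generate_epoch_panel(cfg)
  expect_equal(nrow(p), 67 * 2 * 10)
  # 10 epochs leave 9 usable lagged rows per directed series
  usable <- tapply(!is.na(p$react_lag), p$participant_id, sum)
  expect_true(all(usable == 9))
  expect_true(all(p$talk %in% c(-1, 1)) && all(p$coop %in% c(-1, 1)))
  # lag column is the outcome series shifted by one epoch
  one <- p[p$participant_id == 5, ]
  expect_equal(one$react_lag[-1], one$react[-nrow(one)])
})

test_that("seed-fixed generation is byte-identical and seeds differ", {
  cfg <- test_config(seed = 11)
  expect_identical(generate_epoch_panel(cfg), generate_epoch_panel(cfg))
  p2 <- generate_epoch_panel(cfg, seed = 12)
  expect_false(identical(p2$react, generate_epoch_panel(cfg)$react))
})

test_that("noiseless per-dyad regression recovers true slopes exactly", {
  cfg <- sim_config(n_dyads = 10, beta_sync = 0.3, sigma_sync = 0.2,
                    rho_lag = -0.25, phi_ar1 = 0, sigma_resid = 0,
                    sd_dyad_intercept = 0, sd_participant_intercept = 0,
                    seed = 3)
  p <- generate_epoch_panel(cfg)
  est <- per_dyad_ols(p)
  truth <- attr(p, "truth")$dyad_slopes$true_slope
  expect_equal(unname(est), truth, tolerance = 1e-10)
})

test_that("mean dyad slope and slope variance match generator targets", {
  cfg <- test_config(seed = 1)
  p <- generate_epoch_panel(cfg)
  est <- per_dyad_ols(p)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.30), 3 * se)
  big <- sim_config(n_dyads = 2000, sigma_sync = 0.2, seed = 4)
  slopes <- attr(generate_epoch_panel(big), "truth")$dyad_slopes$true_slope
  expect_lt(abs(var(slopes) - 0.04), 0.1 * 0.04)
})

test_that("epoch-level residuals carry the configured AR(1) autocorrelation", {
  cfg <- sim_config(n_dyads = 1, epochs_per_task = 10000, b0 = 0,
                    beta_sync = 0.3, sigma_sync = 0, rho_lag = -0.25,
                    phi_ar1 = 0.5, sd_dyad_intercept = 0,
                    sd_participant_intercept = 0,
                    cond_effects = c(talk = 0, coop = 0, talk_coop = 0),
                    seed = 5)
  p <- generate_epoch_panel(cfg)
  one <- p[p$participant_id == 1 & !is.na(p$react_lag), ]
  e <- one$react - cfg$rho_lag * one$react_lag -
    0.3 * one$partner_react
  r1 <- cor(e[-1], e[-length(e)])
  expect_lt(abs(r1 - 0.5), 0.05)
})

test_that("artifact injection is exact bookkeeping", {
  cfg <- sim_config(n_dyads = 1)
  beats <- beat_series(rep(800, 300))
  expect_identical(inject_artifacts(beats, 0, seed = 7)$ibis_ms,
                   beats$ibis_ms)
  inj <- inject_artifacts(beats, 0.05, seed = 7)
  sp <- attr(inj, "splits")
  expect_gt(nrow(sp), 5)
  expect_lt(nrow(sp), 30)
  expect_equal(sp$first + sp$second, sp$original)
  # near-half splits leave both fragments below 0.6 of adjacent beats
  expect_true(all(sp$first < 0.6 * 800) && all(sp$second < 0.6 * 800))
  expect_equal(sum(inj$ibis_ms), sum(beats$ibis_ms))
})

test_that("raw IBI generation spans baseline and task and tracks amplitude", {
  cfg <- sim_config(n_dyads = 2, seed = 8)
  series <- generate_dyad_ibi(cfg)
  expect_length(series, 4)
  b <- series[[1]]
  tt <- beat_times(b)
  expect_lt(b$t0_s, -299)
  expect_gt(max(tt), 300)
  # zero amplitude produces a constant series
  cfg0 <- sim_config(n_dyads = 1, rsa_amp_ms = 0, rsa_freq_hz = 0.25,
                     base_ibi_ms = 1)
  expect_error(sim_config(n_dyads = 1, rsa_amp_ms = 0, base_ibi_ms = 0),
               "twice")
  flat <- generate_dyad_ibi(sim_config(n_dyads = 1, rsa_amp_ms = 1e-9))
  expect_lt(diff(range(flat[[1]]$ibis_ms)), 1e-6)
  # same config, different seeds: distinct series, same time span
  s1 <- generate_dyad_ibi(cfg, seed = 1)[[1]]
  s2 <- generate_dyad_ibi(sim_config(n_dyads = 2, ibi_noise_ms = 2, seed = 8),
                          seed = 2)[[1]]
  expect_equal(beat_times(s1)[length(s1$ibis_ms)],
               beat_times(s2)[length(s2$ibis_ms)], tolerance = 2)
})

test_that("affiliation generator recovers planted coefficients by OLS", {
  # all-zero effects: recovered coefficients near zero
  cfg <- sim_config(n_dyads = 200, seed = 21,
                    outcome_effects = list(similarity = c(),
                                           friendship = c(),
                                           negative_affect = c()))
  p <- generate_epoch_panel(cfg)
  a <- generate_affiliation_outcomes(p, cfg)
  m <- summary(lm(similarity ~ talk * coop * react * sync, data = a))
  co <- m$coefficients[-1, ]
  expect_true(all(abs(co[, "Estimate"]) < 3 * co[, "Std. Error"]))

  # planted 3-way on friendship at n = 500 dyads
  eff <- list(similarity = c(), negative_affect = c(),
              friendship = c("talk:react:sync" = 4.2))
  cfg2 <- sim_config(n_dyads = 500, outcome_effects = eff, seed = 22)
  p2 <- generate_epoch_panel(cfg2)
  a2 <- generate_affiliation_outcomes(p2, cfg2)
  m2 <- summary(lm(friendship ~ talk * react * sync, data = a2))
  row <- m2$coefficients["talk:react:sync", ]
  expect_lt(abs(row["Estimate"] - 4.2), 3 * row["Std. Error"])
})

test_that("identity residual correlation yields uncorrelated outcomes", {
  cfg <- sim_config(n_dyads = 300, resid_corr = diag(3), seed = 23,
                    outcome_effects = list(similarity = c(),
                                           friendship = c(),
                                           negative_affect = c()))
  p <- generate_epoch_panel(cfg)
  a <- generate_affiliation_outcomes(p, cfg)
  cors <- cor(a[, c("similarity", "friendship", "negative_affect")])
  expect_true(all(abs(cors[upper.tri(cors)]) < 3 / sqrt(nrow(a))))
})
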