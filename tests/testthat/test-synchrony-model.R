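test_that("t-to-r conversion reproduces every printed triple", {
  # (t, df, r) triples quoted in the emulated study's results tables
  # columns: t, df, printed r, printed decimal places
  triples <- rbind(
    # sympathetic synchrony model
    c(0.268, 1067, 0.008, 3), c(-9.771, 1067, -0.287, 3),
    c(1.597, 1067, 0.049, 3), c(3.218, 63, 0.376, 3),
    c(2.207, 63, 0.268, 3), c(-1.308, 1067, -0.040, 3),
    c(0.380, 1067, 0.012, 3), c(0.567, 63, 0.071, 3),
    c(0.938, 1067, 0.029, 3),
    # parasympathetic synchrony model
    c(0.156, 1067, 0.005, 3), c(-8.510, 1067, -0.252, 3),
    c(2.613, 1067, 0.08, 2), c(2.664, 63, 0.318, 3),
    c(-0.969, 63, -0.121, 3), c(-0.321, 1067, -0.010, 3),
    c(0.025, 1067, 0.001, 3), c(-1.470, 63, -0.182, 3),
    c(1.349, 1067, 0.041, 3),
    # affiliation models (spot rows)
    c(2.000, 288, 0.117, 3), c(2.716, 288, 0.158, 3),
    c(3.650, 288, 0.210, 3), c(2.823, 288, 0.164, 3),
    c(-2.876, 288, -0.167, 3), c(-3.317, 288, -0.192, 3),
    c(41.976, 288, 0.927, 3))
  r <- effect_size_r(triples[, 1], triples[, 2])
  expect_equal(round(r, triples[, 4]), triples[, 3], tolerance = 1e-12)
  expect_equal(effect_size_r(0, 100), 0)
  expect_error(effect_size_r(1, 0), "positive")
  expect_error(effect_size_r(1, -5), "positive")
})

test_that("with random effects and AR(1) disabled the fit is OLS", {
  cfg <- test_config(n_dyads = 15, seed = 31)
  p <- generate_epoch_panel(cfg)
  fit <- quiet_fit(p, random_slope = FALSE, random_intercepts = FALSE,
                   ar1 = FALSE)
  ols <- lm(react ~ react_lag + partner_react * talk * coop,
            data = p[!is.na(p$react_lag), ])
  expect_equal(fit$fixed_effects$b, unname(coef(ols)), tolerance = 1e-8)
})

test_that("between-within df reproduce the complete-design bookkeeping", {
  cfg <- test_config(seed = 32)
  fit <- quiet_fit(generate_epoch_panel(cfg))
  fe <- fit$fixed_effects
  dyad_terms <- c("talk", "coop", "talk:coop")
  expect_true(all(fe$df[fe$term %in% dyad_terms] == 63))
  expect_true(all(fe$df[!fe$term %in% dyad_terms] == 1067))
  # confidence intervals and r are internally consistent
  expect_equal(fe$ci_upper - fe$b, qt(0.975, fe$df) * fe$se,
               tolerance = 1e-10)
  expect_equal(fe$r, effect_size_r(fe$t_value, fe$df), tolerance = 1e-12)
  expect_equal(sign(fe$r), sign(fe$t_value))
})

test_that("variance components are non-negative and phi is inside (-1,1)", {
  cfg <- test_config(seed = 33)
  fit <- quiet_fit(generate_epoch_panel(cfg))
  expect_true(all(fit$variance_components$variance >= 0))
  expect_lt(abs(fit$ar1_phi["est"]), 1)
  expect_equal(nrow(fit$dyad_slopes), 67)
})

test_that("near-noiseless data recover the structure to high precision", {
  cfg <- sim_config(n_dyads = 20, beta_sync = 0.3, sigma_sync = 0.2,
                    rho_lag = -0.25, phi_ar1 = 0, sigma_resid = 1e-3,
                    sd_dyad_intercept = 0,
                    sd_participant_intercept = 0, seed = 34)
  p <- generate_epoch_panel(cfg)
  truth <- attr(p, "truth")$dyad_slopes$true_slope
  ols <- per_dyad_ols(p)
  expect_lt(max(abs(unname(ols) - truth)), 2e-3)
  fit <- quiet_fit(p, ar1 = FALSE)
  # the fixed slope estimates the mean of this sample's dyad slopes
  expect_lt(abs(fit$fixed_effects$b[
    fit$fixed_effects$term == "partner_react"] - mean(truth)), 0.01)
  # shrinkage is negligible without noise: BLUP slopes equal OLS slopes
  sl <- extract_dyad_slopes(fit)
  expect_lt(max(abs(sl$slope - unname(ols))), 0.01)
})

test_that("BLUP slopes shrink to the fixed slope when variance is zero", {
  cfg <- sim_config(n_dyads = 67, beta_sync = 0.3, sigma_sync = 0,
                    rho_lag = -0.25, phi_ar1 = 0.4, seed = 35)
  p <- generate_epoch_panel(cfg)
  fit <- quiet_fit(p)
  sl <- extract_dyad_slopes(fit)
  resid_sd <- sqrt(fit$variance_components$variance[
    fit$variance_components$component == "residual"])
  expect_lt(sd(sl$deviation), 0.1 * resid_sd)
  expect_lt(abs(mean(sl$deviation)), 0.05)
})

test_that("predicted dyad slopes track the simulated truth", {
  cfg <- test_config(seed = 36)
  p <- generate_epoch_panel(cfg)
  fit <- quiet_fit(p)
  sl <- extract_dyad_slopes(fit)
  truth <- attr(p, "truth")$dyad_slopes
  expect_gt(cor(sl$slope, truth$true_slope), 0.6)
})

test_that("slope-variance LRT df follow the removed parameter count", {
  cfg <- test_config(n_dyads = 25, seed = 37)
  p <- generate_epoch_panel(cfg)
  fit_sns <- quiet_fit(p, branch = "sns")
  lrt_sns <- test_random_slope(fit_sns)
  expect_equal(lrt_sns$df, 2)  # slope variance + intercept covariance
  fit_pns <- quiet_fit(p, branch = "pns")
  lrt_pns <- test_random_slope(fit_pns)
  expect_equal(lrt_pns$df, 3)  # + covariance with the random lagged slope
  expect_gte(lrt_sns$chi2, 0)
  expect_match(lrt_pns$boundary_note, "boundary")
})

test_that("condition marginal means equal cell means in a balanced design", {
  cfg <- sim_config(n_dyads = 16, b0 = 0.2, beta_sync = 0, sigma_sync = 0,
                    rho_lag = 0, phi_ar1 = 0, sigma_resid = 0.05,
                    sd_dyad_intercept = 0, sd_participant_intercept = 0,
                    cond_effects = c(talk = 0.3, coop = -0.1,
                                     talk_coop = 0.05),
                    cell_weights = c(1, 1, 1, 1), seed = 38)
  p <- generate_epoch_panel(cfg)
  fit <- quiet_fit(p, ar1 = FALSE)
  cm <- fit$condition_means
  truth_mean <- function(talk, coop)
    0.2 + 0.3 * talk - 0.1 * coop + 0.05 * talk * coop
  for (i in seq_len(nrow(cm))) {
    expect_lt(abs(cm$mean[i] - truth_mean(cm$talk[i], cm$coop[i])), 0.06)
  }
})

test_that("the joint-information likelihood matches the engine exactly", {
  cfg <- test_config(n_dyads = 20, seed = 39)
  p <- generate_epoch_panel(cfg)
  fit <- quiet_fit(p, se_method = "joint")
  expect_lt(abs(fit$joint_information$logLik_check), 1e-6)
  # the lagged term's joint SE exceeds the plug-in SE; the concurrent
  # (exogenous) term's SE is essentially unchanged
  plug <- quiet_fit(p)
  se_j <- fit$fixed_effects$se[fit$fixed_effects$term == "react_lag"]
  se_p <- plug$fixed_effects$se[plug$fixed_effects$term == "react_lag"]
  expect_gt(se_j, se_p)
  sx_j <- fit$fixed_effects$se[fit$fixed_effects$term == "partner_react"]
  sx_p <- plug$fixed_effects$se[plug$fixed_effects$term == "partner_react"]
  expect_lt(abs(sx_j - sx_p) / sx_p, 0.2)
})
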