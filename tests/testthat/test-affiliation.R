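make_affil <- function(n_dyads = 120, seed = 51, eff = NULL, rc = NULL) {
  eff <- eff %||% list(similarity = c(), friendship = c(),
                       negative_affect = c())
  cfg <- sim_config(n_dyads = n_dyads, outcome_effects = eff,
                    resid_corr = rc %||% default_resid_corr(), seed = seed)
  p <- generate_epoch_panel(cfg)
  list(cfg = cfg, panel = p,
       table = generate_affiliation_outcomes(p, cfg))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the multivariate fit carries the Table layout per outcome", {
  d <- make_affil()
  fit <- suppressWarnings(fit_multivariate_affiliation(d$table))
  expect_s3_class(fit, "affiliation_fit")
  for (o in fit$outcomes) {
    fe <- fit$fixed_effects[[o]]
    expect_equal(nrow(fe), 16)   # intercept + 15 crossing terms
    expect_true(all(is.finite(fe$b)) && all(fe$se > 0))
    # r recomputed from each row's t and df matches the reported r
    expect_equal(fe$r, effect_size_r(fe$t_value, fe$df), tolerance = 1e-12)
    expect_equal(fe$ci_upper - fe$b, qt(0.975, fe$df) * fe$se,
                 tolerance = 1e-10)
  }
  # between-within df with dyad-only grouping: rows - dyads - 47
  n_obs <- nrow(fit$data)
  expect_equal(unique(unlist(lapply(fit$fixed_effects, `[[`, "df"))),
               n_obs - d$cfg$n_dyads - 47)
  # cross-outcome random-intercept matrix is positive semi-definite
  ev <- eigen(fit$random_correlations, symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("uncorrelated outcomes: multivariate equals separate fits", {
  d <- make_affil(rc = diag(3), seed = 52)
  multi <- suppressWarnings(
    fit_multivariate_affiliation(d$table, correlated_intercepts = FALSE))
  for (o in multi$outcomes) {
    long1 <- multi$data[multi$data$outcome == o, ]
    sep <- nlme::lme(value ~ talk * coop * react * sync,
                     random = ~ 1 | dyad_id, data = long1, method = "ML",
                     control = nlme::lmeControl(opt = "optim"))
    b_sep <- nlme::fixef(sep)
    fe <- multi$fixed_effects[[o]]
    # order: intercept then the 15 crossing terms (lme orders by degree)
    expect_equal(fe$b[fe$term == "(Intercept)"],
                 unname(b_sep["(Intercept)"]), tolerance = 1e-3)
    for (tm in c("react", "sync", "talk:coop:react:sync")) {
      nm <- names(b_sep)[vapply(names(b_sep), function(x)
        setequal(strsplit(x, ":")[[1]], strsplit(tm, ":")[[1]]),
        logical(1))]
      # agreement to optimizer tolerance: the likelihood factorises by
      # outcome, so the joint and separate optima coincide
      expect_lt(abs(fe$b[fe$term == tm] - unname(b_sep[nm])), 2e-3)
    }
  }
})

test_that("independent outcomes give near-zero estimated covariation", {
  d <- make_affil(n_dyads = 200, rc = diag(3), seed = 53)
  fit <- suppressWarnings(fit_multivariate_affiliation(d$table))
  # with no dyad-level outcome structure in the generator, the estimated
  # outcome-intercept covariance matrix collapses toward zero (on the
  # scale of the ~1-point residual SDs); correlations of such degenerate
  # variances are not identified, so covariances are what should vanish
  sds <- sqrt(fit$random_variances)
  covs <- outer(sds, sds) * fit$random_correlations
  expect_true(all(abs(covs[upper.tri(covs)]) < 0.05))
  expect_true(all(fit$random_variances < 0.1))
})

test_that("planted four-way structure is recovered by the model", {
  eff <- list(similarity = c(), negative_affect = c(),
              friendship = c("talk:react:sync" = 4.2))
  d <- make_affil(n_dyads = 500, eff = eff, seed = 54)
  fit <- suppressWarnings(fit_multivariate_affiliation(d$table))
  fe <- fit$fixed_effects$friendship
  row <- fe[fe$term == "talk:react:sync", ]
  expect_lt(abs(row$b - 4.2), 3 * row$se)
  expect_lt(row$p_value, 0.05)
})

test_that("Tukey adjustment never reports smaller p than unadjusted", {
  eff <- list(similarity = c(), negative_affect = c(),
              friendship = c("talk:react:sync" = 4.2, "talk" = 0.3))
  d <- make_affil(n_dyads = 150, eff = eff, seed = 55)
  fit <- suppressWarnings(fit_multivariate_affiliation(d$table))
  tuk <- suppressWarnings(
    probe_simple_effects(fit, "friendship", "talk"))
  raw <- suppressWarnings(
    probe_simple_effects(fit, "friendship", "talk", adjust = "none"))
  expect_true(all(tuk$adj_p_value >= raw$adj_p_value - 1e-12))
  # a two-group family reduces the adjustment to the plain t test
  tuk2 <- suppressWarnings(probe_simple_effects(
    fit, "friendship", "talk", family = "moderator_only"))
  raw2 <- suppressWarnings(probe_simple_effects(
    fit, "friendship", "talk", family = "moderator_only", adjust = "none"))
  expect_equal(tuk2$adj_p_value, raw2$adj_p_value, tolerance = 1e-10)
})

test_that("probed contrasts track a constructed crossover interaction", {
  # strong talk-by-synchrony crossover on similarity: at high synchrony
  # talking raises the outcome, at low synchrony it lowers it
  eff <- list(similarity = c("talk:sync" = 6), friendship = c(),
              negative_affect = c())
  d <- make_affil(n_dyads = 250, eff = eff, seed = 56)
  fit <- suppressWarnings(fit_multivariate_affiliation(d$table))
  pr <- suppressWarnings(probe_simple_effects(fit, "similarity", "talk"))
  expect_equal(nrow(pr), choose(8, 2))  # Tukey family over the 8-cell grid
  # pure talk contrasts within a cell: "(talk-1 <cell>) - (talk1 <cell>)"
  sides <- strsplit(gsub("[()]", "", pr$contrast), " - ", fixed = TRUE)
  lhs <- vapply(sides, `[`, "", 1)
  rhs <- vapply(sides, `[`, "", 2)
  cell_of <- function(x) sub("^talk-?1 ", "", x)
  talk_of <- function(x) sub("^talk(-?1) .*$", "\\1", x)
  sel <- cell_of(lhs) == cell_of(rhs) & talk_of(lhs) != talk_of(rhs)
  expect_equal(sum(sel), 4)  # one per react x sync cell
  # generator cell-mean oracle: contrast (talk=-1) - (talk=+1) = -12*sync,
  # so its sign is opposite the sign of the probed synchrony level
  sync_probe <- fit$predictor_summary[
    fit$predictor_summary$predictor == "sync", ]
  sync_vals <- sync_probe$mean + c(-1, 1) * sync_probe$sd
  expect_true(sync_vals[1] < 0 && sync_vals[2] > 0)
  at_hi <- !grepl("sync-", cell_of(lhs)[sel])
  est <- pr$estimate[sel]
  expect_true(all(est[at_hi] < 0))
  expect_true(all(est[!at_hi] > 0))
})

test_that("probing errors on outcomes absent from the model", {
  d <- make_affil(n_dyads = 60, seed = 57)
  fit <- suppressWarnings(fit_multivariate_affiliation(d$table))
  expect_error(probe_simple_effects(fit, "positive_affect", "talk"),
               "not in the model")
})
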