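#' Partial effect size r from a t statistic
#'
#' Converts a slope's t statistic and its denominator degrees of freedom
#' into a partial correlation effect size,
#' \deqn{r = t / \sqrt{t^2 + df},}
#' signed as the t statistic.
#'
#' @param t t statistic(s).
#' @param df degrees of freedom, strictly positive.
#' @return Numeric vector of r values in (-1, 1).
#' @examples
#' effect_size_r(3.218, 63)   # 0.376
#' effect_size_r(2.00, 288)   # 0.117
#' @export
effect_size_r <- function(t, df) {
  if (any(!is.finite(df)) || any(df <= 0))
    stop("df must be positive", call. = FALSE)
  t / sqrt(t^2 + df)
}

#' Fit the three-level dyadic synchrony model
#'
#' Models each participant's epoch-level reactivity (the outcome series) as
#' a function of its own lag-1 value ("lagged partner"), the other dyad
#' member's concurrent reactivity ("synchrony"), the +1/-1 coded talking
#' and cooperation conditions, and all 2-way and the 3-way interaction of
#' synchrony with the conditions:
#' \deqn{y_{t} = \beta_0 + \beta_{lag} y_{t-1} + \beta_{sync} x_t +
#'   \beta_T T + \beta_C C + \ldots + u_{dyad} + u_{ppt} + s_{dyad} x_t +
#'   \varepsilon_t}
#' with random intercepts for dyad and participant, a dyad-level random
#' synchrony slope (unstructured covariance; plus a random lagged slope
#' for the parasympathetic specification), AR(1) epoch-level residuals,
#' and maximum-likelihood estimation so that likelihood-ratio tests across
#' nested random structures are valid. Denominator degrees of freedom use
#' the between-within rule (each term gets the df of the level at which it
#' varies: dyad-level condition terms vs. within-series terms). Each row's
#' partial effect size r is computed with [effect_size_r()].
#'
#' The first epoch of each series (undefined lag) is dropped, so 10 epochs
#' yield 9 modelled rows per directed series.
#'
#' @param panel an \code{"epoch_panel"} (from [generate_epoch_panel()] or
#'   [build_synchrony_panel()]).
#' @param branch label stored on the fit: \code{"sns"} (sympathetic) or
#'   \code{"pns"} (parasympathetic).
#' @param random_lag also give the lagged term a dyad-level random slope
#'   (default: yes for the parasympathetic branch).
#' @param random_slope,random_intercepts,ar1 structure switches; with all
#'   three off the model reduces to ordinary least squares (fit by ML
#'   generalized least squares).
#' @param se_method \code{"plugin"} (default) reports the engine's
#'   generalized-least-squares standard errors, which condition on the
#'   estimated covariance parameters — the convention of the modelling
#'   tradition this implements; \code{"joint"} replaces fixed-effect and
#'   covariance-parameter uncertainty with Wald inference from the joint
#'   observed information via [joint_information()], which restores
#'   nominal coverage for the lagged term in this dynamic specification
#'   (see the methods vignette).
#' @param control an [nlme::lmeControl()] list.
#' @return Object of class \code{"synchrony_fit"}: list with
#'   \code{fixed_effects} (term, b, se, ci_lower, ci_upper, t_value, df,
#'   p_value, r), \code{variance_components} (variance estimates with 95\%
#'   CIs), \code{ar1_phi} (estimate and CI), \code{dyad_slopes},
#'   \code{condition_means}, \code{n_dyads}, \code{notes}, and the
#'   underlying \code{nlme} fit as \code{fit}.
#' @export
fit_synchrony_model <- function(panel, branch = c("sns", "pns"),
                                random_lag = identical(branch, "pns"),
                                random_slope = TRUE,
                                random_intercepts = TRUE, ar1 = TRUE,
                                se_method = c("plugin", "joint"),
                                control = nlme::lmeControl(
                                  maxIter = 200, msMaxIter = 200,
                                  niterEM = 50, opt = "nlminb")) {
  branch <- match.arg(branch)
  se_method <- match.arg(se_method)
  force(random_lag)
  dat <- panel[!is.na(panel$react_lag) & !is.na(panel$react) &
                 !is.na(panel$partner_react), , drop = FALSE]
  dat <- as.data.frame(dat)
  dat <- dat[order(dat$dyad_id, dat$participant_id, dat$epoch), ]
  fixed <- react ~ react_lag + partner_react * talk * coop
  corr <- if (ar1) nlme::corAR1(form = ~ epoch | dyad_id / participant_id)
          else NULL
  notes <- character()

  if (!random_intercepts && !random_slope) {
    fit <- nlme::gls(fixed, data = dat, correlation = corr, method = "ML")
  } else {
    slope_terms <- if (random_slope && random_lag) ~ partner_react + react_lag
                   else if (random_slope) ~ partner_react
                   else if (random_lag) ~ react_lag
                   else ~ 1
    make_fit <- function(pd) {
      nlme::lme(fixed,
                random = list(dyad_id = pd(slope_terms),
                              participant_id = ~ 1),
                correlation = corr, data = dat, method = "ML",
                control = control)
    }
    fit <- tryCatch(make_fit(nlme::pdSymm), error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msg <- conditionMessage(fit)
      fit <- tryCatch(make_fit(nlme::pdDiag), error = function(e) e)
      if (inherits(fit, "error"))
        stop("synchrony model failed to converge (unstructured: ", diag_msg,
             "; diagonal: ", conditionMessage(fit), ")", call. = FALSE)
      notes <- c(notes,
                 "unstructured random-effects covariance failed to converge; downgraded to diagonal")
    } else {
      # the approximate var-cov of the covariance parameters can come out
      # non-positive-definite at a just-converged optimum; a restart with a
      # different optimizer usually lands on a cleaner one
      iv_ok <- !is.null(tryCatch(nlme::intervals(fit, which = "var-cov"),
                                 error = function(e) NULL))
      if (!iv_ok) {
        ctrl2 <- control
        ctrl2$opt <- "optim"
        ctrl2$optimMethod <- "BFGS"
        ctrl2$maxIter <- 300; ctrl2$msMaxIter <- 400; ctrl2$niterEM <- 100
        fit2 <- tryCatch(nlme::lme(fixed,
                                   random = list(dyad_id = nlme::pdSymm(slope_terms),
                                                 participant_id = ~ 1),
                                   correlation = corr, data = dat,
                                   method = "ML", control = ctrl2),
                         error = function(e) NULL)
        if (!is.null(fit2) &&
            !is.null(tryCatch(nlme::intervals(fit2, which = "var-cov"),
                              error = function(e) NULL))) {
          fit <- fit2
          notes <- c(notes, "restarted with BFGS for variance-component intervals")
        }
      }
    }
  }

  tt <- summary(fit)$tTable
  df <- if ("DF" %in% colnames(tt)) tt[, "DF"]
        else rep(nrow(dat) - nrow(tt), nrow(tt))
  fe <- data.frame(
    term = rownames(tt), b = tt[, "Value"], se = tt[, "Std.Error"],
    df = df, t_value = tt[, "t-value"], p_value = tt[, "p-value"],
    row.names = NULL)
  fe$ci_lower <- fe$b - qt(0.975, fe$df) * fe$se
  fe$ci_upper <- fe$b + qt(0.975, fe$df) * fe$se
  fe$r <- effect_size_r(fe$t_value, fe$df)
  fe <- fe[, c("term", "b", "ci_lower", "ci_upper", "se", "t_value", "df",
               "p_value", "r")]

  vc <- extract_variance_components(fit, random_slope, random_lag)
  phi <- extract_ar1(fit)
  slopes <- if (inherits(fit, "lme") && random_slope)
    dyad_slope_table(fit, dat) else NULL
  if (inherits(fit, "lme") && random_slope &&
      vc$variance[vc$component == "synchrony_slope"] < 1e-10)
    notes <- c(notes, "synchrony slope variance at boundary (~0)")

  out <- list(branch = branch, fit = fit, fixed_effects = fe,
              variance_components = vc, ar1_phi = phi,
              dyad_slopes = slopes,
              condition_means = condition_marginal_means(fit, dat),
              n_dyads = length(unique(dat$dyad_id)),
              n_obs = nrow(dat), random_lag = random_lag,
              se_method = se_method,
              data = dat, notes = notes)
  class(out) <- "synchrony_fit"
  if (se_method == "joint" && inherits(fit, "lme") && random_slope && ar1)
    out <- apply_joint_inference(out)
  out
}

## replace plug-in uncertainty with Wald inference from the joint
## observed information of (beta, G, sigma_p^2, sigma^2, phi)
apply_joint_inference <- function(out) {
  ji <- joint_information(out)
  fe <- out$fixed_effects
  se <- ji$se_beta[fe$term]
  fe$se <- unname(se)
  fe$t_value <- fe$b / fe$se
  fe$p_value <- 2 * pt(-abs(fe$t_value), fe$df)
  fe$ci_lower <- fe$b - qt(0.975, fe$df) * fe$se
  fe$ci_upper <- fe$b + qt(0.975, fe$df) * fe$se
  fe$r <- effect_size_r(fe$t_value, fe$df)
  out$fixed_effects <- fe

  # variance components: Wald on the log-variance scale
  vc <- out$variance_components
  var_map <- c(dyad_intercept = "var((Intercept))",
               synchrony_slope = "var(partner_react)",
               lagged_slope = "var(react_lag)",
               participant_intercept = "participant_intercept_var",
               residual = "residual_var")
  for (i in seq_len(nrow(vc))) {
    nm <- var_map[[vc$component[i]]]
    if (is.null(nm) || !nm %in% names(ji$params)) next
    v <- ji$params[[nm]]
    se_v <- ji$se_theta[[nm]]
    if (v > 0 && is.finite(se_v)) {
      half <- 1.96 * se_v / v
      vc$ci_lower[i] <- v * exp(-half)
      vc$ci_upper[i] <- v * exp(half)
    }
  }
  out$variance_components <- vc

  # AR(1): Wald on the Fisher-z scale
  ph <- ji$params[["phi"]]
  se_ph <- ji$se_theta[["phi"]]
  if (is.finite(se_ph) && abs(ph) < 1) {
    z <- atanh(ph)
    se_z <- se_ph / (1 - ph^2)
    out$ar1_phi <- c(est = ph, lower = tanh(z - 1.96 * se_z),
                     upper = tanh(z + 1.96 * se_z))
  }
  out$joint_information <- ji[c("logLik_check", "se_beta", "se_theta")]
  out$notes <- c(out$notes, "uncertainty from joint observed information")
  out
}

#' @export
print.synchrony_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Dyadic synchrony model (%s branch): %d dyads, %d rows\n",
              x$branch, x$n_dyads, x$n_obs))
  fe <- x$fixed_effects
  fe[-1] <- lapply(fe[-1], round, digits)
  print(fe, row.names = FALSE)
  cat("\nVariance components:\n")
  vc <- x$variance_components
  vc[-1] <- lapply(vc[-1], round, digits + 1)
  print(vc, row.names = FALSE)
  if (!is.null(x$ar1_phi))
    cat(sprintf("\nAR(1) phi = %.3f, 95%% CI [%.3f, %.3f]\n",
                x$ar1_phi["est"], x$ar1_phi["lower"], x$ar1_phi["upper"]))
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

extract_variance_components <- function(fit, random_slope, random_lag) {
  if (!inherits(fit, "lme")) {
    return(data.frame(component = "residual",
                      variance = fit$sigma^2,
                      ci_lower = NA_real_, ci_upper = NA_real_))
  }
  iv <- tryCatch(nlme::intervals(fit, which = "var-cov"),
                 error = function(e) NULL)
  sd_ci <- function(group, name) {
    if (is.null(iv)) return(c(NA_real_, NA_real_))
    blk <- iv$reStruct[[group]]
    row <- grep(paste0("sd\\(", ifelse(name == "(Intercept)",
                                       "\\(Intercept\\)", name), "\\)"),
                rownames(blk))
    if (!length(row)) return(c(NA_real_, NA_real_))
    unlist(blk[row[1], c("lower", "upper")])^2
  }
  rows <- list()
  add <- function(component, variance, ci) {
    rows[[length(rows) + 1]] <<- data.frame(
      component = component, variance = variance,
      ci_lower = ci[1], ci_upper = ci[2])
  }
  re <- fit$modelStruct$reStruct
  dyad_mat <- as.matrix(re$dyad_id) * fit$sigma^2
  add("dyad_intercept", dyad_mat["(Intercept)", "(Intercept)"],
      sd_ci("dyad_id", "(Intercept)"))
  if (random_slope)
    add("synchrony_slope", dyad_mat["partner_react", "partner_react"],
        sd_ci("dyad_id", "partner_react"))
  if (random_lag && "react_lag" %in% rownames(dyad_mat))
    add("lagged_slope", dyad_mat["react_lag", "react_lag"],
        sd_ci("dyad_id", "react_lag"))
  ppt_mat <- as.matrix(re$participant_id) * fit$sigma^2
  add("participant_intercept", ppt_mat["(Intercept)", "(Intercept)"],
      sd_ci("participant_id", "(Intercept)"))
  sig_ci <- if (is.null(iv) || is.null(iv$sigma)) c(NA_real_, NA_real_)
            else unlist(iv$sigma[c("lower", "upper")])^2
  add("residual", fit$sigma^2, sig_ci)
  do.call(rbind, rows)
}

extract_ar1 <- function(fit) {
  cs <- fit$modelStruct$corStruct
  if (is.null(cs)) return(NULL)
  est <- coef(cs, unconstrained = FALSE)
  iv <- tryCatch(nlme::intervals(fit, which = "var-cov")$corStruct,
                 error = function(e) NULL)
  ci <- if (is.null(iv)) c(NA_real_, NA_real_)
        else unlist(iv[1, c("lower", "upper")])
  c(est = unname(est), lower = unname(ci[1]), upper = unname(ci[2]))
}

## per-dyad total synchrony coefficient: the fixed average slope, plus the
## condition-moderation terms evaluated at the dyad's +1/-1 codes, plus the
## BLUP of the dyad's random deviation
dyad_slope_table <- function(fit, dat) {
  b <- nlme::fixef(fit)
  re <- nlme::ranef(fit, level = 1)
  dev <- if ("partner_react" %in% colnames(re)) re[, "partner_react"]
         else rep(0, nrow(re))
  codes <- unique(dat[, c("dyad_id", "talk", "coop")])
  codes <- codes[match(rownames(re), as.character(codes$dyad_id)), ]
  pick <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  fx <- pick("partner_react") +
    pick("partner_react:talk") * codes$talk +
    pick("partner_react:coop") * codes$coop +
    pick("partner_react:talk:coop") * codes$talk * codes$coop
  data.frame(dyad_id = rownames(re), slope = fx + dev,
             deviation = dev, row.names = NULL)
}

## model-implied reactivity means per condition cell (covariates held at
## their grand means, the estimated-marginal-means convention), with
## dyad-level between-within df
condition_marginal_means <- function(fit, dat) {
  if (!inherits(fit, "lme")) return(NULL)
  grid <- expand.grid(talk = c(1, -1), coop = c(1, -1))
  grid$react_lag <- mean(dat$react_lag)
  grid$partner_react <- mean(dat$partner_react)
  X <- model.matrix(formula(fit)[-2], grid)
  X <- X[, names(nlme::fixef(fit)), drop = FALSE]
  b <- nlme::fixef(fit)
  V <- vcov(fit)
  est <- drop(X %*% b)
  se <- sqrt(diag(X %*% V %*% t(X)))
  n_dyads <- length(unique(dat$dyad_id))
  df <- n_dyads - 1 - 3
  data.frame(talk = grid$talk, coop = grid$coop, mean = est, se = se,
             df = df, t_value = est / se,
             p_value = 2 * pt(-abs(est / se), df),
             ci_lower = est - qt(0.975, df) * se,
             ci_upper = est + qt(0.975, df) * se)
}

#' Likelihood-ratio test for the dyad-level synchrony slope variance
#'
#' Refits the model without the dyad-level random synchrony slope (and its
#' covariance terms) on identical rows and compares likelihoods:
#' \eqn{\chi^2 = -2(\ell_{reduced} - \ell_{full})}, with df equal to the
#' number of removed (co)variance parameters — 2 for the sympathetic
#' specification (slope variance + intercept-slope covariance), 3 for the
#' parasympathetic one (an additional covariance with the random lagged
#' slope). The reference distribution ignores that the variance sits on
#' the boundary of its parameter space, making the test conservative; the
#' caveat is recorded in the result.
#'
#' @param fit a \code{"synchrony_fit"} from [fit_synchrony_model()] (must
#'   have been fit with a random slope and by ML).
#' @return List of class \code{"slope_lrt"}: \code{chi2}, \code{df},
#'   \code{p_value}, \code{slope_variance}, \code{logLik_full},
#'   \code{logLik_reduced}, \code{boundary_note}.
#' @export
test_random_slope <- function(fit) {
  stopifnot(inherits(fit, "synchrony_fit"))
  if (!inherits(fit$fit, "lme"))
    stop("full fit has no random effects", call. = FALSE)
  reduced <- fit_synchrony_model(
    fit$data, branch = fit$branch, random_lag = fit$random_lag,
    random_slope = FALSE)
  if (fit$n_obs != reduced$n_obs)
    stop("full and reduced models were fit on different rows", call. = FALSE)
  ll_full <- logLik(fit$fit)
  ll_red <- logLik(reduced$fit)
  df <- attr(ll_full, "df") - attr(ll_red, "df")
  chi2 <- max(0, 2 * as.numeric(ll_full - ll_red))
  out <- list(chi2 = chi2, df = df,
              p_value = pchisq(chi2, df, lower.tail = FALSE),
              slope_variance = fit$variance_components$variance[
                fit$variance_components$component == "synchrony_slope"],
              logLik_full = as.numeric(ll_full),
              logLik_reduced = as.numeric(ll_red),
              boundary_note = paste(
                "variance components are tested at the boundary of the",
                "parameter space; the chi-square reference is conservative"))
  class(out) <- "slope_lrt"
  out
}

#' @export
print.slope_lrt <- function(x, ...) {
  cat(sprintf(
    "Synchrony slope variance = %.4f, chi2(%d) = %.3f, p = %.3f\n",
    x$slope_variance, x$df, x$chi2, x$p_value))
  cat(x$boundary_note, "\n")
  invisible(x)
}

#' Per-dyad synchrony coefficients
#'
#' Returns each dyad's total synchrony coefficient: the fixed average
#' slope plus the best linear unbiased prediction (BLUP) of the dyad's
#' random deviation. BLUPs are shrunken toward the fixed slope, so with no
#' true slope variance all dyads collapse onto the average; deviations sum
#' to approximately zero.
#'
#' @param fit a \code{"synchrony_fit"} fit with a random slope.
#' @return Data frame: \code{dyad_id}, \code{slope}, \code{deviation}.
#' @export
extract_dyad_slopes <- function(fit) {
  stopifnot(inherits(fit, "synchrony_fit"))
  if (is.null(fit$dyad_slopes))
    stop("fit has no dyad-level random slope", call. = FALSE)
  fit$dyad_slopes
}
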