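#' Multivariate multilevel affiliation model
#'
#' Relates per-dyad synchrony coefficients and per-participant mean
#' reactivity to the affiliation outcomes (perceived similarity,
#' friendship interest, negative affect) in a single multivariate
#' multilevel model: the outcomes are stacked long with an outcome
#' indicator, each outcome receives its own fixed-effect set of the full
#' condition x reactivity x synchrony crossing (up to the 4-way
#' interaction), random intercepts for each outcome are estimated at the
#' dyad level and allowed to correlate, and residual variances differ by
#' outcome. Predictors enter on their natural scale. Between-within
#' denominator degrees of freedom assign every term to the
#' within-dyad level (the stacked rows), and each row's partial effect
#' size r is computed with [effect_size_r()].
#'
#' If the unstructured cross-outcome random-intercept matrix fails to
#' converge (a non-positive-definite Hessian), the model is refit with
#' uncorrelated outcome intercepts and the downgrade is flagged.
#'
#' @param table an \code{"affiliation_table"} (one row per participant
#'   with \code{dyad_id}, \code{talk}, \code{coop}, \code{react},
#'   \code{sync} and the outcome columns). For real data \code{sync} is
#'   the dyad's extracted slope (attached to both members) and
#'   \code{react} the member's own mean reactivity.
#' @param branch label stored on the fit (\code{"sns"} or \code{"pns"}).
#' @param outcomes character vector of outcome columns to stack; defaults
#'   to the three modelled outcomes.
#' @param correlated_intercepts start from the unstructured cross-outcome
#'   covariance (default) or force the diagonal structure.
#' @param method estimation method (\code{"ML"} so nested model
#'   comparisons remain valid).
#' @return Object of class \code{"affiliation_fit"}: \code{fixed_effects}
#'   (per-outcome tables with b, CI, SE, t, df, p, r),
#'   \code{random_correlations} (cross-outcome random-intercept
#'   correlation matrix), \code{residual_sd} by outcome, \code{notes},
#'   \code{data} (the stacked frame) and the underlying \code{nlme} fit.
#' @export
fit_multivariate_affiliation <- function(table, branch = c("sns", "pns"),
                                         outcomes = affil_outcomes(),
                                         correlated_intercepts = TRUE,
                                         method = "ML") {
  branch <- match.arg(branch)
  need <- c("dyad_id", "participant_id", "talk", "coop", "react", "sync",
            outcomes)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("affiliation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  long <- do.call(rbind, lapply(outcomes, function(o)
    data.frame(dyad_id = table$dyad_id,
               participant_id = table$participant_id,
               talk = table$talk, coop = table$coop,
               react = table$react, sync = table$sync,
               outcome = o, value = table[[o]],
               stringsAsFactors = FALSE)))
  long$outcome <- factor(long$outcome, levels = outcomes)
  long <- long[complete.cases(long), ]

  fixed <- value ~ outcome + outcome:(talk * coop * react * sync)
  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 300, niterEM = 50,
                           opt = "optim")
  make_fit <- function(pd) {
    nlme::lme(fixed, random = list(dyad_id = pd(~ 0 + outcome)),
              weights = nlme::varIdent(form = ~ 1 | outcome),
              data = long, method = method, control = ctrl)
  }
  notes <- character()
  fit <- NULL
  if (correlated_intercepts) {
    fit <- tryCatch(make_fit(nlme::pdSymm), error = function(e) e)
    if (inherits(fit, "error")) {
      notes <- c(notes, paste(
        "correlated outcome intercepts failed to converge",
        "; refit with uncorrelated intercepts"))
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    fit <- tryCatch(make_fit(nlme::pdDiag), error = function(e) e)
    if (inherits(fit, "error"))
      stop("affiliation model failed to converge: ",
           conditionMessage(fit), call. = FALSE)
    if (correlated_intercepts) attr(fit, "downgraded") <- TRUE
  }

  fe <- affiliation_fixed_tables(fit, outcomes)
  G <- as.matrix(fit$modelStruct$reStruct$dyad_id) * fit$sigma^2
  Dg <- sqrt(diag(G))
  corr <- if (all(Dg > 0)) G / outer(Dg, Dg) else G * NA
  vw <- fit$modelStruct$varStruct
  w <- if (is.null(vw)) setNames(rep(1, length(outcomes)), outcomes)
       else coef(vw, unconstrained = FALSE, allCoef = TRUE)
  resid_sd <- fit$sigma * w[outcomes]
  names(resid_sd) <- outcomes

  out <- list(branch = branch, fit = fit, fixed_effects = fe,
              random_correlations = corr,
              random_variances = diag(G),
              residual_sd = resid_sd, outcomes = outcomes,
              data = long, notes = notes,
              predictor_summary = data.frame(
                predictor = c("react", "sync"),
                mean = c(mean(table$react), mean(table$sync)),
                sd = c(sd(table$react), sd(table$sync))))
  class(out) <- "affiliation_fit"
  out
}

## map stacked-model coefficients to one Table-style block per outcome
affiliation_fixed_tables <- function(fit, outcomes) {
  b <- nlme::fixef(fit)
  V <- vcov(fit)
  tt <- summary(fit)$tTable
  df <- tt[1, "DF"]  # between-within: all terms vary within dyads
  terms15 <- c("talk", "coop", "react", "sync",
               "talk:coop", "talk:react", "coop:react", "talk:sync",
               "coop:sync", "react:sync",
               "talk:coop:react", "talk:coop:sync", "talk:react:sync",
               "coop:react:sync", "talk:coop:react:sync")
  lapply(setNames(outcomes, outcomes), function(o) {
    ref <- outcomes[1]
    rows <- list()
    # intercept: reference outcome's intercept, plus dummy for the others
    L <- setNames(numeric(length(b)), names(b))
    L["(Intercept)"] <- 1
    if (o != ref) {
      dn <- paste0("outcome", o)
      L[dn] <- 1
    }
    rows[["(Intercept)"]] <- L
    for (tm in terms15) {
      cand <- c(paste0("outcome", o, ":", tm),
                paste0(tm, ":outcome", o))
      nm <- cand[cand %in% names(b)][1]
      if (is.na(nm)) {
        # nlme/R may order interaction factors differently; search
        pat <- paste0("outcome", o)
        parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
        hits <- names(b)[vapply(names(b), function(x) {
          px <- strsplit(x, ":", fixed = TRUE)[[1]]
          setequal(px, c(pat, parts))
        }, logical(1))]
        nm <- hits[1]
      }
      L <- setNames(numeric(length(b)), names(b))
      L[nm] <- 1
      rows[[tm]] <- L
    }
    Lm <- do.call(rbind, rows)
    est <- drop(Lm %*% b)
    se <- sqrt(diag(Lm %*% V %*% t(Lm)))
    tv <- est / se
    data.frame(term = names(rows), b = est,
               ci_lower = est - qt(0.975, df) * se,
               ci_upper = est + qt(0.975, df) * se,
               se = se, t_value = tv, df = df,
               p_value = 2 * pt(-abs(tv), df),
               r = effect_size_r(tv, df), row.names = NULL)
  })
}

#' @export
print.affiliation_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Multivariate affiliation model (%s branch)\n", x$branch))
  for (o in x$outcomes) {
    cat("\n==", o, "==\n")
    fe <- x$fixed_effects[[o]]
    fe[-1] <- lapply(fe[-1], round, digits)
    print(fe, row.names = FALSE)
  }
  cat("\nCross-outcome random-intercept correlations:\n")
  print(round(x$random_correlations, digits))
  cat("\nResidual SD by outcome:\n")
  print(round(x$residual_sd, digits))
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tukey-adjusted simple effects of an affiliation model
#'
#' Probes a fitted affiliation model within each level of the requested
#' condition moderators, at plus and minus one sample standard deviation
#' of reactivity and synchrony (SDs computed from the analysis sample):
#' estimated marginal means of the outcome are computed at every
#' condition x (+/-1 SD reactivity) x (+/-1 SD synchrony) cell, and the
#' pairwise contrasts across the named moderator are Tukey-adjusted. Only
#' adjusted p-values are reported.
#'
#' @param fit an \code{"affiliation_fit"}.
#' @param outcome which outcome to probe.
#' @param moderator condition code to contrast (\code{"talk"} or
#'   \code{"coop"}); must be in the model.
#' @param at_sd probe reactivity/synchrony at \code{mean +/- at_sd * SD}.
#' @param adjust multiplicity adjustment passed to emmeans (default
#'   \code{"tukey"}).
#' @param family \code{"grid"} (default) takes the pairwise-contrast
#'   family over the full moderator x reactivity x synchrony cell grid;
#'   \code{"moderator_only"} contrasts only the two moderator levels
#'   averaged over the probe points (a two-group family, for which the
#'   Tukey adjustment reduces to the unadjusted two-sided test).
#' @return Data frame of Tukey-adjusted contrasts with estimate, SE, df,
#'   t and the adjusted p-value; unadjusted p-values are not reported.
#' @export
probe_simple_effects <- function(fit, outcome = "friendship",
                                 moderator = c("talk", "coop"),
                                 at_sd = 1, adjust = "tukey",
                                 family = c("grid", "moderator_only")) {
  stopifnot(inherits(fit, "affiliation_fit"))
  moderator <- match.arg(moderator)
  family <- match.arg(family)
  if (!outcome %in% fit$outcomes)
    stop("outcome '", outcome, "' is not in the model", call. = FALSE)
  ps <- fit$predictor_summary
  react_at <- ps$mean[ps$predictor == "react"] +
    c(-1, 1) * at_sd * ps$sd[ps$predictor == "react"]
  sync_at <- ps$mean[ps$predictor == "sync"] +
    c(-1, 1) * at_sd * ps$sd[ps$predictor == "sync"]
  rg <- suppressMessages(
    emmeans::ref_grid(fit$fit,
                      at = list(talk = c(-1, 1), coop = c(-1, 1),
                                react = react_at, sync = sync_at,
                                outcome = outcome),
                      data = fit$data, nesting = NULL))
  spec <- if (family == "grid")
    as.formula(paste0("~ ", moderator, " * react * sync"))
  else as.formula(paste0("~ ", moderator))
  em <- suppressMessages(emmeans::emmeans(rg, spec))
  ctr <- suppressMessages(
    summary(emmeans::contrast(em, method = "pairwise", adjust = adjust)))
  out <- as.data.frame(ctr)
  names(out)[names(out) == "p.value"] <- "adj_p_value"
  attr(out, "adjust") <- adjust
  out
}
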