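#' Joint observed-information inference for a synchrony fit
#'
#' Standard errors reported by generalized-least-squares machinery treat
#' the covariance parameters (random-effect variances, residual AR(1)
#' autocorrelation) as known when computing fixed-effect uncertainty. For
#' a dynamic specification — the outcome's own lag on the right-hand side
#' together with autocorrelated residuals — the mean and covariance
#' parameters are *not* information-orthogonal: the sampling errors of the
#' lagged coefficient and of the residual autocorrelation are strongly
#' coupled, and the plug-in standard error of the lagged term is too
#' small. Because the marginal likelihood of the model is fully specified,
#' the remedy is classical: evaluate the observed information of the
#' complete parameter vector (fixed effects, random-effect covariance,
#' residual variance, AR(1) autocorrelation) at the maximum-likelihood
#' estimate and invert it.
#'
#' The log-likelihood is recomputed independently of the fitting engine
#' from the model's closed form: per dyad,
#' \deqn{y_d \sim N(X_d\beta,\; Z_d G Z_d' + \sigma_p^2 S_d +
#'   \sigma^2 \Phi_d(\phi)),}
#' with \eqn{S_d} the participant-block indicator and \eqn{\Phi_d} the
#' AR(1) correlation within each directed series. The Hessian is obtained
#' by central finite differences. Agreement of this evaluator with the
#' fitting engine's log-likelihood at the optimum is checked to 1e-3.
#'
#' @param fit a \code{"synchrony_fit"} with random intercepts, a dyad
#'   slope and AR(1) residuals (the full specification).
#' @return List: \code{vcov_full} (covariance of all parameters),
#'   \code{se_beta} (fixed-effect SEs), \code{se_theta} (covariance
#'   parameter SEs on their natural scale), \code{params} (the MLE on the
#'   natural scale), \code{logLik_check} (evaluator minus engine
#'   log-likelihood).
#' @export
joint_information <- function(fit) {
  stopifnot(inherits(fit, "synchrony_fit"))
  lme_fit <- fit$fit
  if (!inherits(lme_fit, "lme"))
    stop("joint information requires the mixed-model fit", call. = FALSE)
  dat <- fit$data
  slope_cols <- c("(Intercept)", "partner_react",
                  if (fit$random_lag) "react_lag")
  re <- lme_fit$modelStruct$reStruct
  G <- as.matrix(re$dyad_id) * lme_fit$sigma^2
  G <- G[slope_cols, slope_cols, drop = FALSE]
  v_ppt <- as.numeric(as.matrix(re$participant_id)) * lme_fit$sigma^2
  sigma2 <- lme_fit$sigma^2
  phi <- as.numeric(coef(lme_fit$modelStruct$corStruct,
                         unconstrained = FALSE))
  beta <- nlme::fixef(lme_fit)

  X <- model.matrix(formula(lme_fit)[-2], dat)[, names(beta), drop = FALSE]
  k <- length(slope_cols)
  pre <- lapply(split(seq_len(nrow(dat)), dat$dyad_id), function(ix) {
    dd <- dat[ix, ]
    o <- order(dd$participant_id, dd$epoch)
    ix <- ix[o]; dd <- dd[o, ]
    Z <- cbind(1, dd$partner_react,
               if (fit$random_lag) dd$react_lag)
    ppt <- as.integer(factor(dd$participant_id))
    S <- outer(ppt, ppt, "==") * 1
    lag_gap <- abs(outer(dd$epoch, dd$epoch, "-"))
    lag_gap[S == 0] <- NA  # no residual correlation across series
    list(y = dat$react[ix], X = X[ix, , drop = FALSE], Z = Z, S = S,
         gap = lag_gap)
  })

  ## natural-scale parameter vector: beta, vech(G), v_ppt, sigma2, phi
  theta0 <- c(G[lower.tri(G, diag = TRUE)], v_ppt, sigma2, phi)
  par0 <- c(beta, theta0)
  nb <- length(beta)
  ll <- function(par) {
    b <- par[seq_len(nb)]
    th <- par[-seq_len(nb)]
    Gm <- matrix(0, k, k)
    Gm[lower.tri(Gm, diag = TRUE)] <- th[seq_len(k * (k + 1) / 2)]
    Gm <- Gm + t(Gm) - diag(diag(Gm), k)
    vp <- th[k * (k + 1) / 2 + 1]
    s2 <- th[k * (k + 1) / 2 + 2]
    ph <- th[k * (k + 1) / 2 + 3]
    if (s2 <= 0 || vp < 0 || abs(ph) >= 1) return(-Inf)
    tot <- 0
    for (d in pre) {
      Phi <- ph^d$gap
      Phi[is.na(Phi)] <- 0
      V <- d$Z %*% Gm %*% t(d$Z) + vp * d$S + s2 * Phi
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      r <- d$y - d$X %*% b
      z <- backsolve(ch, r, transpose = TRUE)
      tot <- tot - sum(log(diag(ch))) - 0.5 * sum(z^2) -
        0.5 * length(r) * log(2 * pi)
    }
    tot
  }
  check <- ll(par0) - as.numeric(logLik(lme_fit))
  if (!is.finite(check) || abs(check) > 1e-3)
    warning(sprintf(
      "independent log-likelihood evaluator differs from engine by %.2g",
      check))
  H <- fd_hessian(ll, par0)
  Vfull <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(Vfull) || any(diag(Vfull) <= 0))
    stop("joint observed information is not positive-definite", call. = FALSE)
  nm_theta <- c(vech_names(slope_cols), "participant_intercept_var",
                "residual_var", "phi")
  dimnames(Vfull) <- list(c(names(beta), nm_theta),
                          c(names(beta), nm_theta))
  list(vcov_full = Vfull,
       se_beta = sqrt(diag(Vfull)[seq_len(nb)]),
       se_theta = sqrt(diag(Vfull)[-seq_len(nb)]),
       params = setNames(par0, c(names(beta), nm_theta)),
       logLik_check = check)
}

vech_names <- function(cols) {
  k <- length(cols)
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  apply(idx, 1, function(ij)
    if (ij[1] == ij[2]) paste0("var(", cols[ij[1]], ")")
    else paste0("cov(", cols[ij[2]], ",", cols[ij[1]], ")"))
}

## central-difference Hessian; steps scale with parameter magnitude
fd_hessian <- function(f, x, rel = 1e-3, abs_min = 1e-5) {
  n <- length(x)
  h <- pmax(abs(x) * rel, abs_min)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}
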