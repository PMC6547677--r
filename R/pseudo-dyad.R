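#' Pseudo-dyad (surrogate pairing) null analysis
#'
#' Tests whether apparent synchrony exceeds what the shared task and
#' environment alone produce: participants are randomly re-paired with
#' other participants of the same sex assigned to the same experimental
#' conditions (never with their true partner), the synchrony model is
#' refit on the re-paired panel, and the slope-variance likelihood-ratio
#' test is recorded. If synchrony is a dyadic process the re-paired slope
#' variance should be indistinguishable from zero; if it reflects a common
#' task-driven signal, pseudo-dyads will show it too.
#'
#' Strata with a single dyad cannot be re-paired without reuniting the
#' true pair and are skipped with a warning.
#'
#' @param panel an \code{"epoch_panel"}.
#' @param n_repairings number of random re-pairings.
#' @param seed integer seed; the re-pairing sequence is fully reproducible.
#' @param branch,random_lag passed to [fit_synchrony_model()].
#' @return Object of class \code{"pseudo_dyad_result"}: data frame
#'   \code{repairings} (slope_variance, lrt_chi2, lrt_df, lrt_p per
#'   re-pairing), \code{prop_nonsignificant} at alpha = 0.05, and the
#'   stratum table.
#' @export
pseudo_dyad_null <- function(panel, n_repairings = 100, seed = 1L,
                             branch = "sns", random_lag = FALSE) {
  ps <- panel_series(panel)
  meta <- ps$meta
  meta$stratum <- interaction(meta$sex, meta$talk, meta$coop, drop = TRUE)
  strata <- split(seq_len(nrow(meta)), meta$stratum)
  usable <- vapply(strata, function(ix)
    length(unique(meta$dyad_id[ix])) >= 2, logical(1))
  if (any(!usable)) {
    warning("skipping stratum(s) with a single dyad: ",
            paste(names(strata)[!usable], collapse = ", "))
    strata <- strata[usable]
  }
  if (!length(strata)) stop("no stratum with >= 2 dyads", call. = FALSE)
  set.seed(seed)
  res <- vector("list", n_repairings)
  for (r in seq_len(n_repairings)) {
    pairs <- repair_strata(meta, strata)
    shuffled <- assemble_pseudo_panel(ps, pairs)
    fit <- fit_synchrony_model(shuffled, branch = branch,
                               random_lag = random_lag)
    lrt <- test_random_slope(fit)
    res[[r]] <- data.frame(repairing = r,
                           slope_variance = lrt$slope_variance,
                           lrt_chi2 = lrt$chi2, lrt_df = lrt$df,
                           lrt_p = lrt$p_value)
  }
  rep_tab <- do.call(rbind, res)
  out <- list(repairings = rep_tab,
              n_repairings = n_repairings,
              prop_nonsignificant = mean(rep_tab$lrt_p > 0.05),
              median_slope_variance = median(rep_tab$slope_variance),
              strata = table(meta$stratum))
  class(out) <- "pseudo_dyad_result"
  out
}

#' @export
print.pseudo_dyad_result <- function(x, ...) {
  cat(sprintf(
    "Pseudo-dyad null: %d re-pairings; median slope variance %.4f;\n",
    x$n_repairings, x$median_slope_variance))
  cat(sprintf("  %.0f%% of re-pairings non-significant (LRT p > 0.05)\n",
              100 * x$prop_nonsignificant))
  invisible(x)
}

## draw one stratified re-pairing avoiding every true partnership
repair_strata <- function(meta, strata, max_tries = 200) {
  out <- list()
  for (s in names(strata)) {
    ix <- strata[[s]]
    pids <- meta$participant_id[ix]
    partners <- meta$partner_id[ix]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      perm <- sample(pids)
      a <- perm[seq(1, length(perm), by = 2)]
      b <- perm[seq(2, length(perm), by = 2)]
      true_partner <- partners[match(a, pids)]
      if (!any(b == true_partner)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not re-pair stratum ", s,
           " without reuniting a true pair", call. = FALSE)
    out[[s]] <- data.frame(a = a, b = b)
  }
  do.call(rbind, out)
}

assemble_pseudo_panel <- function(ps, pairs) {
  meta <- ps$meta
  rows <- vector("list", 2L * nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (ori in 1:2) {
      self <- if (ori == 1) pairs$a[i] else pairs$b[i]
      other <- if (ori == 1) pairs$b[i] else pairs$a[i]
      mi <- meta[meta$participant_id == self, ]
      so <- ps$series[[as.character(self)]]
      sp <- ps$series[[as.character(other)]]
      Tt <- length(so$outcome)
      rows[[(i - 1L) * 2L + ori]] <- data.frame(
        dyad_id = i, participant_id = self, partner_id = other,
        sex = mi$sex, talk = mi$talk, coop = mi$coop,
        epoch = so$epoch,
        react = so$outcome,
        react_lag = c(NA_real_, so$outcome[-Tt]),
        partner_react = sp$actor, stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  class(panel) <- c("epoch_panel", "data.frame")
  panel
}
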