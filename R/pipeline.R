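#' Pipeline run configuration
#'
#' A single configuration object driving [run_pipeline()]: stage toggles,
#' every stage parameter, the top-level seed (all stochastic stages derive
#' their streams from it) and the output directory. Round-trips losslessly
#' through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param sim a [sim_config()] for the simulate stage.
#' @param stages named logical vector toggling \code{simulate_raw}
#'   (raw-IBI path: artifact injection, QC, segmentation and index
#'   computation; otherwise the epoch panel feeds the models directly),
#'   \code{qc}, \code{synchrony}, \code{null} and \code{affiliation}.
#' @param ratio_threshold,qc_strategy QC stage parameters.
#' @param artifact_rate per-interval split probability injected into the
#'   raw series before QC (exercises the QC stage; 0 leaves series clean).
#' @param epoch_s,pad_s segmentation parameters.
#' @param band_hz,fs_hz band-pass and resampling parameters for logRSA.
#' @param n_repairings pseudo-dyad stage re-pairings.
#' @param probe_moderators condition codes probed in the affiliation stage.
#' @param seed top-level seed.
#' @param out_dir output directory for stage tables, manifest and report.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c(simulate_raw = FALSE, qc = TRUE,
                                  synchrony = TRUE, null = FALSE,
                                  affiliation = TRUE),
                       ratio_threshold = 0.6,
                       qc_strategy = "merge_adjacent",
                       artifact_rate = 0,
                       epoch_s = 30, pad_s = 12,
                       band_hz = c(0.12, 0.40), fs_hz = 10,
                       n_repairings = 20,
                       probe_moderators = c("talk", "coop"),
                       seed = 1L, out_dir = "dyadsync-run") {
  cfg <- list(sim = sim, stages = stages,
              ratio_threshold = ratio_threshold,
              qc_strategy = qc_strategy, artifact_rate = artifact_rate,
              epoch_s = epoch_s, pad_s = pad_s, band_hz = band_hz,
              fs_hz = fs_hz, n_repairings = n_repairings,
              probe_moderators = probe_moderators,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$resid_corr <- as.vector(x$sim$resid_corr)
  x$sim$outcome_effects <- lapply(x$sim$outcome_effects, as.list)
  # named atomic vectors must become maps or YAML drops their names
  for (nm in c("cond_effects", "sync_cond_effects", "outcome_intercepts",
               "outcome_sd"))
    x$sim[[nm]] <- as.list(x$sim[[nm]])
  x$stages <- as.list(x$stages)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$resid_corr <- matrix(unlist(x$sim$resid_corr), 3, 3,
                             dimnames = list(affil_outcomes(),
                                             affil_outcomes()))
  x$sim$outcome_effects <- lapply(x$sim$outcome_effects,
                                  function(e) unlist(e) %||% c())
  for (nm in c("cond_effects", "sync_cond_effects", "outcome_intercepts",
               "outcome_sd"))
    x$sim[[nm]] <- unlist(x$sim[[nm]])
  x$stages <- unlist(x$stages)
  sim <- do.call(sim_config, x$sim[setdiff(names(x$sim), character())])
  cfg <- x
  cfg$sim <- sim
  class(cfg) <- "run_config"
  cfg
}

#' Run the full dyadic synchrony pipeline
#'
#' Executes the stages in order — simulate, (optionally) raw-signal QC and
#' index derivation, reactivity, synchrony models per branch, pseudo-dyad
#' null, affiliation — writing per-stage tables, a JSON manifest (package
#' version, seeds, parameter hash) and a human-readable report of the
#' model tables to \code{config$out_dir}. Stage outputs are pure functions
#' of (inputs, config, seed): rerunning with the same configuration
#' yields byte-identical manifests.
#'
#' When the raw-signal path is enabled, each participant's reactivity is
#' measured from generated interbeat intervals (artifact injection, QC,
#' 54-s segmentation, logRSA) rather than taken from the epoch panel, and
#' the parasympathetic branch alone is modelled (the raw generator targets
#' the logRSA trajectory).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  st <- config$stages
  results <- list()
  stage <- "simulate"
  res <- tryCatch({
    sim <- config$sim
    sim$seed <- config$seed
    say("stage simulate: %d dyads", sim$n_dyads)
    panel <- generate_epoch_panel(sim, seed = config$seed)
    write.csv(panel, file.path(config$out_dir, "epoch_panel.csv"),
              row.names = FALSE)
    results$panel <- panel

    if (isTRUE(st[["simulate_raw"]])) {
      say("stage simulate: raw IBI series")
      series <- generate_dyad_ibi(sim, panel = panel,
                                  seed = config$seed + 2L)
      meta <- attr(series, "participants")
      if (config$artifact_rate > 0) {
        series <- lapply(seq_along(series), function(i)
          inject_artifacts(series[[i]], config$artifact_rate,
                           seed = config$seed + 100L + i))
        names(series) <- meta$participant_id
      }
      stage <- "qc"
      if (isTRUE(st[["qc"]])) {
        say("stage qc: ratio %.2f, strategy %s", config$ratio_threshold,
            config$qc_strategy)
        qc <- qc_beat_series(series, config$ratio_threshold,
                             config$qc_strategy)
        series <- qc$series
        write.csv(qc$report, file.path(config$out_dir, "qc_report.csv"),
                  row.names = FALSE)
        results$qc <- qc$report
      }
      stage <- "indices"
      task_len <- sim$epochs_per_task * config$epoch_s
      idx <- lapply(seq_along(series), function(i) {
        task <- segment_epochs(series[[i]], c(0, task_len),
                               config$epoch_s, config$pad_s,
                               dyad_id = meta$dyad_id[i],
                               participant_id = meta$participant_id[i])
        base <- segment_epochs(series[[i]], c(-sim$baseline_s, 0),
                               config$epoch_s, config$pad_s,
                               dyad_id = meta$dyad_id[i],
                               participant_id = meta$participant_id[i],
                               allow_degraded = TRUE)
        list(task = compute_indices(task, band_hz = config$band_hz,
                                    fs_hz = config$fs_hz),
             base = compute_indices(base, band_hz = config$band_hz,
                                    fs_hz = config$fs_hz))
      })
      task_idx <- do.call(rbind, lapply(idx, `[[`, "task"))
      base_idx <- do.call(rbind, lapply(idx, `[[`, "base"))
      write.csv(task_idx, file.path(config$out_dir, "indices_task.csv"),
                row.names = FALSE)
      write.csv(base_idx, file.path(config$out_dir, "indices_baseline.csv"),
                row.names = FALSE)
      stage <- "reactivity"
      baseline <- aggregate(log_rsa ~ participant_id, base_idx, mean,
                            na.rm = TRUE)
      names(baseline)[2] <- "baseline"
      task <- task_idx[, c("dyad_id", "participant_id", "epoch_index",
                           "log_rsa")]
      names(task)[4] <- "value"
      task$epoch <- task$epoch_index + 1L
      reac <- residualized_change(task, baseline)
      reac <- merge(reac, meta[, c("participant_id", "sex", "talk", "coop")],
                    by = "participant_id")
      reac$reactivity_panel_branch <- "pns"
      write.csv(reac, file.path(config$out_dir, "reactivity.csv"),
                row.names = FALSE)
      results$reactivity <- reac
      model_panel <- build_synchrony_panel(
        reac[, c("dyad_id", "participant_id", "epoch", "reactivity",
                 "talk", "coop", "sex")])
      branches <- "pns"
    } else {
      model_panel <- panel
      branches <- c("sns")
    }

    stage <- "synchrony"
    if (isTRUE(st[["synchrony"]])) {
      fits <- lapply(setNames(branches, branches), function(br) {
        say("stage synchrony: %s branch", br)
        fit <- fit_synchrony_model(model_panel, branch = br,
                                   random_lag = br == "pns")
        write.csv(fit$fixed_effects,
                  file.path(config$out_dir,
                            sprintf("synchrony_%s_fixed.csv", br)),
                  row.names = FALSE)
        write.csv(fit$variance_components,
                  file.path(config$out_dir,
                            sprintf("synchrony_%s_varcomp.csv", br)),
                  row.names = FALSE)
        write.csv(fit$dyad_slopes,
                  file.path(config$out_dir,
                            sprintf("synchrony_%s_dyad_slopes.csv", br)),
                  row.names = FALSE)
        fit
      })
      results$synchrony <- fits

      stage <- "null"
      if (isTRUE(st[["null"]])) {
        say("stage null: %d re-pairings", config$n_repairings)
        results$null <- lapply(fits, function(f)
          pseudo_dyad_null(model_panel, config$n_repairings,
                           seed = config$seed + 7L, branch = f$branch,
                           random_lag = f$random_lag))
        for (br in names(results$null))
          write.csv(results$null[[br]]$repairings,
                    file.path(config$out_dir,
                              sprintf("pseudo_dyad_%s.csv", br)),
                    row.names = FALSE)
      }

      stage <- "affiliation"
      if (isTRUE(st[["affiliation"]])) {
        say("stage affiliation")
        affil <- generate_affiliation_outcomes(panel, config$sim,
                                               seed = config$seed + 11L)
        # in the full pipeline the synchrony predictor is the extracted
        # per-dyad coefficient, as in the analysis the model emulates
        sl <- extract_dyad_slopes(fits[[1]])
        affil$sync <- sl$slope[match(affil$dyad_id, sl$dyad_id)]
        write.csv(affil, file.path(config$out_dir, "affiliation_table.csv"),
                  row.names = FALSE)
        afit <- fit_multivariate_affiliation(affil,
                                             branch = fits[[1]]$branch)
        for (o in afit$outcomes)
          write.csv(afit$fixed_effects[[o]],
                    file.path(config$out_dir,
                              sprintf("affiliation_%s.csv", o)),
                    row.names = FALSE)
        results$affiliation <- afit
        results$probes <- lapply(
          setNames(config$probe_moderators, config$probe_moderators),
          function(m) probe_simple_effects(afit, moderator = m))
      }
    }
    results
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package = "dyadsync",
    version = as.character(packageVersion("dyadsync")),
    seed = config$seed,
    stages = as.list(config$stages),
    n_dyads = config$sim$n_dyads,
    parameter_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_report(res, file.path(config$out_dir, "report.txt"))
  res$manifest <- manifest
  invisible(res)
}

## hash of the scientific parameters (output location excluded)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  write_run_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("dyadsync pipeline report")
  w("========================")
  fmt_fe <- function(fe) {
    w("%-45s %8s %8s %8s %7s %7s %5s %7s %7s",
      "Term", "b", "CI_lo", "CI_hi", "SE", "t", "df", "p", "r")
    for (i in seq_len(nrow(fe)))
      w("%-45s %8.3f %8.3f %8.3f %7.3f %7.3f %5d %7.3f %7.3f",
        fe$term[i], fe$b[i], fe$ci_lower[i], fe$ci_upper[i], fe$se[i],
        fe$t_value[i], as.integer(fe$df[i]), fe$p_value[i], fe$r[i])
  }
  for (br in names(res$synchrony)) {
    fit <- res$synchrony[[br]]
    w("")
    w("Synchrony model (%s branch), %d dyads", br, fit$n_dyads)
    w("----------------------------------------")
    fmt_fe(fit$fixed_effects)
    w("")
    w("Random effects (variances):")
    vc <- fit$variance_components
    for (i in seq_len(nrow(vc)))
      w("  %-22s %8.4f  [%.4f, %.4f]", vc$component[i], vc$variance[i],
        vc$ci_lower[i], vc$ci_upper[i])
    if (!is.null(fit$ar1_phi))
      w("AR(1) phi = %.3f [%.3f, %.3f]", fit$ar1_phi["est"],
        fit$ar1_phi["lower"], fit$ar1_phi["upper"])
  }
  if (!is.null(res$null)) {
    for (br in names(res$null)) {
      n <- res$null[[br]]
      w("")
      w("Pseudo-dyad null (%s): %d re-pairings, %.0f%% non-significant",
        br, n$n_repairings, 100 * n$prop_nonsignificant)
    }
  }
  if (!is.null(res$affiliation)) {
    for (o in res$affiliation$outcomes) {
      w("")
      w("Affiliation model: %s", o)
      w("----------------------------------------")
      fmt_fe(res$affiliation$fixed_effects[[o]])
    }
  }
  invisible(path)
}
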