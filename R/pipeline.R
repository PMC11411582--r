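# Orchestration: a serialisable run configuration, validation, and an
# end-to-end pipeline (simulate -> preprocess -> analyse -> report) with a
# provenance manifest. All randomness flows from the single config seed
# through derive_seed().

run_config_defaults <- function() {
  list(
    seed = 1L,
    n_participants = 4L,
    n_parsing_trials = 240L,
    n_exposure_trials = 280L,
    sampling_rate = 250,
    n_channels = 16L,
    freqs = log_freqs(4, 50, 12),
    response_mode = "every_trial",
    fit_once = FALSE,
    stages = c("simulate", "preprocess", "analyze", "report"),
    ica = TRUE,
    filter = TRUE,
    out_dir = NULL,
    spec_overrides = list()
  )
}

#' Build a pipeline run configuration
#'
#' @param ... named overrides of the defaults (seed, participant count, trial
#'   counts, sampling rate, channel count, analysis frequencies, response
#'   mode, `fit_once`, stage toggles, output directory, and
#'   `spec_overrides` passed to [generative_spec()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks structural validity, unknown keys, and every generative-spec
#' invariant; returns diagnostics instead of raising.
#'
#' @param config a `run_config` or plain named list.
#' @return character vector of diagnostics (empty when valid).
#' @export
validate_config <- function(config) {
  diags <- character(0)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    diags <- c(diags, paste0("unknown key: ", unknown))
  }
  for (nm in c("n_participants", "n_parsing_trials", "sampling_rate")) {
    if (!is.null(config[[nm]]) && (!is.numeric(config[[nm]]) ||
                                   config[[nm]] <= 0)) {
      diags <- c(diags, paste0(nm, " must be a positive number"))
    }
  }
  if (!is.null(config$n_parsing_trials) &&
      config$n_parsing_trials %% 30 != 0) {
    diags <- c(diags, "n_parsing_trials must be divisible by 30")
  }
  sp <- tryCatch(
    do.call(generative_spec,
            c(list(sampling_rate = config$sampling_rate %||% 250,
                   n_channels = config$n_channels %||% 64),
              config$spec_overrides)),
    error = function(e) conditionMessage(e))
  if (is.character(sp)) diags <- c(diags, sp)
  diags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [load_run_config()] returns a `run_config`;
#'   [save_run_config()] returns `path` invisibly.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname load_run_config
#' @param config a `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Per simulated participant: build the graph and sequences, simulate the EEG
#' session and behaviour, preprocess (filter, optional ICA ocular cleaning,
#' epoch, reject, wavelet power, z-score), and run the analyses (P300 window
#' amplitudes, novel/learned decoding, predictive decoding, pattern
#' similarity, behavioural summaries). Group statistics are computed across
#' participants and, when `out_dir` is set, result tables are written as CSV
#' with a JSON run manifest.
#'
#' @param config a `run_config`.
#' @return object of class `pipeline_result`: list with `participants`
#'   (per-participant results), `group` (group statistics), `config`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  diags <- validate_config(config)
  if (length(diags)) stop("invalid config: ", paste(diags, collapse = "; "))
  stages <- config$stages
  if (!"simulate" %in% stages) stop("nothing to do: simulate stage disabled")
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages) {
      stop("stage '", stage, "' requires stage '", dep, "'")
    }
  }
  need("preprocess", "simulate")
  need("analyze", "preprocess")
  need("report", "analyze")

  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    sd_p <- derive_seed(config$seed, p)
    res <- list(participant = p, seed = sd_p)
    graph <- build_graph(seed = derive_seed(sd_p, 1))
    spec <- do.call(generative_spec,
                    c(list(sampling_rate = config$sampling_rate,
                           n_channels = config$n_channels),
                      config$spec_overrides))
    trials <- build_parsing_sequence(graph, n = config$n_parsing_trials,
                                     seed = derive_seed(sd_p, 2))
    behavior <- simulate_behavior(trials, spec, mode = config$response_mode,
                                  seed = derive_seed(sd_p, 3))
    posttest <- simulate_posttest_answers(
      build_posttest(graph, seed = derive_seed(sd_p, 4)), spec,
      seed = derive_seed(sd_p, 5))
    exposure <- NULL
    if (config$n_exposure_trials > 0) {
      exposure_trials <- build_exposure_sequence(
        graph, n = config$n_exposure_trials, seed = derive_seed(sd_p, 6))
      exposure <- simulate_behavior(exposure_trials, spec,
                                    seed = derive_seed(sd_p, 7))
    }
    res$graph <- graph
    res$trials <- trials
    res$behavior <- behavior
    res$posttest <- posttest
    res$exposure <- exposure

    if ("preprocess" %in% stages) {
      session <- simulate_session(trials, spec, graph,
                                  seed = derive_seed(sd_p, 8))
      if (config$filter) {
        session <- suppressWarnings(
          filter_continuous(session, high = min(200, 0.9 *
                                                  config$sampling_rate / 2)))
      }
      if (config$ica) {
        session <- remove_ocular_components(session,
                                            seed = derive_seed(sd_p, 9))
      }
      epochs <- epoch_and_baseline(session)
      epochs$rejected <- reject_artifacts(epochs)
      sp_avg <- spectral_power(epochs, freqs = config$freqs)
      feats <- zscore_features(sp_avg)
      sp_cls <- spectral_power(epochs, freqs = config$freqs,
                               window_ms = c(250, 450))
      feats_cls <- zscore_features(sp_cls)
      sp_win <- spectral_power(epochs, freqs = config$freqs,
                               output = "windowed")
      feats_win <- zscore_features(sp_win)
      res$epochs_rejected <- sum(epochs$rejected)
      res$p300 <- window_amplitude(epochs)
      res$p300_early <- window_amplitude(epochs, window = c(50, 250))
      res$features <- feats
      res$features_cls <- feats_cls
      res$features_win <- feats_win
      res$epochs_meta <- epochs$metadata
    }

    if ("analyze" %in% stages) {
      pc <- pca_select(res$features, seed = derive_seed(sd_p, 10))
      res$pc <- pc
      md <- res$features$metadata
      cond <- transition_condition(md$transition_label)
      sel <- cond %in% c("novel", "learned")
      if (sum(cond[sel] == "novel") >= 5 && sum(cond[sel] == "learned") >= 5) {
        res$decoding <- classify_conditions(
          res$features_cls$z[sel, , drop = FALSE], cond[sel] == "novel",
          fit_once = config$fit_once, seed = derive_seed(sd_p, 11))
      }
      res$predictive <- predictive_decode(res$features_win, graph,
                                          trials = trials)
      pairs <- find_pairs(trials, behavior, graph)
      res$pairs <- pairs
      res$similarity <- pair_similarity(pc, pairs,
                                        trial_index = md$index)
      res$parse_by_cond <- tapply(behavior$parse,
                                  factor(behavior$condition,
                                         levels = c("novel", "learned",
                                                    "nonboundary")), mean)
    }
    participants[[p]] <- res
  }

  group <- NULL
  if ("report" %in% stages) {
    group <- list()
    np <- length(participants)
    p300_means <- do.call(rbind, lapply(participants, function(r) {
      data.frame(participant = r$participant,
                 condition = names(r$p300$per_condition),
                 value = as.numeric(r$p300$per_condition))
    }))
    group$p300_contrasts <- tryCatch(condition_contrasts(p300_means),
                                     error = function(e) NULL)
    group$parsing <- parsing_summary(lapply(participants, `[[`, "behavior"))
    group$posttest <- posttest_score(lapply(participants, `[[`, "posttest"))
    aucs <- vapply(participants, function(r) {
      if (is.null(r$decoding)) NA_real_ else r$decoding$auc
    }, numeric(1))
    group$decoding_auc <- aucs
    group$predictive_auc <- vapply(participants, function(r) {
      r$predictive$whole_epoch
    }, numeric(1))
    sim_means <- do.call(rbind, lapply(participants, function(r) {
      cm <- r$similarity$condition_means
      data.frame(participant = r$participant, condition = names(cm),
                 value = as.numeric(cm))
    }))
    sim_means <- sim_means[!is.na(sim_means$value), , drop = FALSE]
    group$similarity_contrasts <- tryCatch(condition_contrasts(sim_means),
                                           error = function(e) NULL)
  }

  manifest <- list(
    package = "eventseg",
    version = as.character(utils::packageVersion("eventseg")),
    seed = config$seed,
    n_participants = config$n_participants,
    stages = stages,
    fit_once = config$fit_once,
    config_hash = digest_config(config))

  out <- structure(list(participants = participants, group = group,
                        config = config, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir) && "report" %in% stages) {
    write_pipeline_outputs(out, config$out_dir)
  }
  out
}

# stable hash of the configuration for the manifest (no external digest dep)
digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  g <- result$group
  rows <- list()
  add <- function(test, statistic, df, p, extra = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(test = test,
                                             statistic = statistic, df = df,
                                             p = p, extra = extra)
  }
  if (!is.null(g$p300_contrasts)) {
    a <- g$p300_contrasts$anova
    add("p300_anova", a$statistic, paste(a$df1, a$df2, sep = ","), a$p,
        a$eta_sq)
  }
  pa <- g$parsing$parse_stats$anova
  add("parse_anova", pa$statistic, paste(pa$df1, pa$df2, sep = ","), pa$p,
      pa$eta_sq)
  if (!is.null(g$posttest$wilcoxon)) {
    add("posttest_wilcoxon", g$posttest$wilcoxon$V, NA, g$posttest$wilcoxon$p,
        g$posttest$mean)
  }
  add("decoding_auc_mean", mean(g$decoding_auc, na.rm = TRUE), NA, NA, NA)
  add("predictive_auc_mean", mean(g$predictive_auc, na.rm = TRUE), NA, NA, NA)
  stats_df <- do.call(rbind, rows)
  utils::write.csv(stats_df, file.path(out_dir, "group_statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(g$parsing$summary, file.path(out_dir,
                                                "parsing_summary.csv"),
                   row.names = FALSE)
  per_auc <- data.frame(participant = seq_along(g$decoding_auc),
                        decoding_auc = g$decoding_auc,
                        predictive_auc = g$predictive_auc)
  utils::write.csv(per_auc, file.path(out_dir, "participant_auc.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", length(x$participants), " participants, stages: ",
      paste(x$config$stages, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$group)) {
    cat("  mean decoding AUC: ",
        round(mean(x$group$decoding_auc, na.rm = TRUE), 3),
        "; mean predictive AUC: ",
        round(mean(x$group$predictive_auc, na.rm = TRUE), 3), "\n", sep = "")
  }
  invisible(x)
}
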