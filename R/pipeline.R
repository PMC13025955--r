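## End-to-end experiment orchestration: simulate -> prepare -> build-graph ->
## train -> evaluate -> explain -> baseline, driven by one config, with
## stage-tagged logging and a manifest tying outputs to content digests and
## seeds.

log_stage <- function(con, stage, msg, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(msg, ...))
  message(line)
  if (!is.null(con))
    writeLines(jsonlite::toJSON(list(stage = stage, message = sprintf(msg, ...),
                                     time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                                auto_unbox = TRUE), con)
}

digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}

#' Validate and normalize an experiment configuration
#'
#' Accepts a YAML file path or a list. Required: `outcome` (one of plos,
#' mort30, mort90), `out_dir`, `seed`. Optional: `synth` (arguments to
#' [synth_config()]), `split` (ratios), `group_by`, `mask` (named rates),
#' `resample` (none/undersample/oversample), `model` (ie-HGCN
#' hyperparameters), `ablation` (`full`, `providers`, `units`),
#' `use_enc_features`, `baselines` (subset of lr/mlp/gbt), `explain`
#' (logical).
#'
#' @param config list or path to a YAML file.
#' @return validated config list.
#' @export
experiment_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outcome) || !config$outcome %in% OUTCOMES)
    stopf("config$outcome must be one of %s", paste(OUTCOMES, collapse = ", "))
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  if (is.null(config$seed)) stopf("config$seed is required (all randomness is seeded)")
  config$split <- config$split %||% c(8, 1, 1)
  config$group_by <- config$group_by %||% "encounter"
  config$resample <- config$resample %||% "none"
  if (!config$resample %in% c("none", "undersample", "oversample"))
    stopf("unknown resample mode '%s'", config$resample)
  config$ablation <- config$ablation %||% "full"
  if (!config$ablation %in% c("full", "providers", "units"))
    stopf("unknown ablation '%s'", config$ablation)
  config$use_enc_features <- config$use_enc_features %||% TRUE
  config$baselines <- config$baselines %||% character(0)
  config$model <- config$model %||% list()
  config
}

#' Run the full experiment pipeline
#'
#' Executes the stages in dependency order, writing each stage's artifacts
#' under `out_dir` and a `manifest.json` recording content digests and seeds
#' (written even when a stage fails, with the failing stage named).
#'
#' @param config a config list or YAML path (see [experiment_config()]).
#' @return the manifest list, invisibly on success.
#' @export
run_experiment <- function(config) {
  cfg <- experiment_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(cfg$out_dir, "log.jsonl"), open = "a")
  on.exit(close(logcon), add = TRUE)
  manifest <- list(tool_version = as.character(utils::packageVersion("medhgps")),
                   seed = cfg$seed, outcome = cfg$outcome, stages = list())
  stage <- "init"
  ok <- tryCatch({
    ## simulate
    stage <- "simulate"
    log_stage(logcon, stage, "generating synthetic cohort")
    scfg <- do.call(synth_config, c(cfg$synth %||% list(),
                                    list(seed = child_seed(cfg$seed, "simulate"))))
    cohort <- generate_cohort(scfg)
    sim_dir <- file.path(cfg$out_dir, "cohort")
    write_cohort(cohort, sim_dir)
    manifest$stages$simulate <- list(seed = scfg$seed,
                                     outputs = digest_files(list.files(sim_dir, full.names = TRUE)))

    ## prepare
    stage <- "prepare"
    log_stage(logcon, stage, "labels, splits and feature matrix")
    enc <- cohort$encounters
    if (!is.null(cfg$mask))
      enc <- mask_features(enc, unlist(cfg$mask),
                           seed = child_seed(cfg$seed, "mask"))
    splits <- split_indices(enc, ratios = cfg$split,
                            seed = child_seed(cfg$seed, "split"),
                            group_by = cfg$group_by)
    labels <- derive_outcomes(enc, reference_rows = splits$train)
    fm <- build_feature_matrix(enc, train_ids = splits$train)
    prep_dir <- file.path(cfg$out_dir, "prepared")
    dir.create(prep_dir, showWarnings = FALSE)
    utils::write.csv(labels, file.path(prep_dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(data.frame(encounter_id = rownames(fm$X), fm$X,
                                check.names = FALSE),
                     file.path(prep_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(fm$fitted_stats, file.path(prep_dir, "transform.json"),
                         auto_unbox = TRUE, digits = NA)
    train_ids <- splits$train
    if (cfg$resample != "none") {
      ytr <- align_labels(labels, train_ids, cfg$outcome)
      train_ids <- resample_training(train_ids, ytr, cfg$resample,
                                     seed = child_seed(cfg$seed, "resample"))
    }
    manifest$stages$prepare <- list(
      outputs = digest_files(list.files(prep_dir, full.names = TRUE)),
      plos_threshold = attr(labels, "plos_threshold_days"))

    ## build-graph
    stage <- "build-graph"
    log_stage(logcon, stage, "heterogeneous graph construction")
    g <- build_heterograph(enc, cohort$assignments, cohort$transfers, fm)
    if (cfg$ablation == "providers") g <- subgraph(g, c("ENC", "providers"),
                                                   cfg$use_enc_features)
    if (cfg$ablation == "units") g <- subgraph(g, c("ENC", "units"),
                                               cfg$use_enc_features)
    if (cfg$ablation == "full" && !cfg$use_enc_features)
      g <- subgraph(g, names(g$schema), FALSE)
    graph_dir <- file.path(cfg$out_dir, "graph")
    write_heterograph(g, graph_dir)
    manifest$stages$build_graph <- list(
      outputs = digest_files(list.files(graph_dir, full.names = TRUE)))

    ## train
    stage <- "train"
    log_stage(logcon, stage, "training ie-HGCN (%s)", cfg$outcome)
    sp_train <- splits
    sp_train$train <- train_ids
    fit <- do.call(iehgcn, c(list(graph = g, labels = labels,
                                  splits = sp_train, outcome = cfg$outcome,
                                  seed = child_seed(cfg$seed, "train")),
                             cfg$model))
    model_dir <- file.path(cfg$out_dir, "model")
    dir.create(model_dir, showWarnings = FALSE)
    jsonlite::write_json(c(fit$hyper,
                           list(best_epoch = fit$report$best_epoch,
                                best_val_auroc = fit$report$best_val_auroc,
                                stopping = fit$report$stopping)),
                         file.path(model_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(fit$report$history,
                     file.path(model_dir, "history.csv"), row.names = FALSE)
    manifest$stages$train <- list(
      best_val_auroc = fit$report$best_val_auroc,
      outputs = digest_files(list.files(model_dir, full.names = TRUE)))

    ## evaluate
    stage <- "evaluate"
    log_stage(logcon, stage, "test-set metrics")
    p <- predict(fit, g)
    yte <- align_labels(labels, splits$test, cfg$outcome)
    mets <- classification_metrics(yte, p[splits$test])
    ci <- bootstrap_ci(yte, p[splits$test], "auroc", n_boot = 200L,
                       seed = child_seed(cfg$seed, "boot"))
    metrics_out <- c(unclass(mets)[c("auroc", "auprc", "f1", "precision",
                                     "recall", "specificity", "threshold", "n")],
                     list(auroc_ci = as.list(ci)))
    jsonlite::write_json(metrics_out, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$evaluate <- metrics_out["auroc"]

    ## explain
    if (isTRUE(cfg$explain %||% TRUE)) {
      stage <- "explain"
      log_stage(logcon, stage, "meta-path importance")
      att <- mean_attention(fit, g)
      mpa <- metapath_importance(att)
      utils::write.csv(mpa, file.path(cfg$out_dir, "metapaths.csv"),
                       row.names = FALSE)
      manifest$stages$explain <- list(top_path = mpa$path[1])
    }

    ## baselines
    if (length(cfg$baselines)) {
      stage <- "baseline"
      log_stage(logcon, stage, "network-feature baselines: %s",
                paste(cfg$baselines, collapse = ", "))
      nf <- network_features(enc, cohort$assignments, cohort$transfers,
                             provider_graph = build_provider_graph(
                               cohort$assignments, splits$train))
      Xb <- cbind(fm$X, nf[rownames(fm$X), , drop = FALSE])
      bl <- lapply(cfg$baselines, function(k)
        fit_baseline(Xb, labels, splits, k, outcome = cfg$outcome,
                     seed = child_seed(cfg$seed, paste0("baseline_", k))))
      names(bl) <- cfg$baselines
      bmet <- lapply(bl, function(b)
        unclass(b$metrics)[c("auroc", "auprc", "f1", "precision", "recall",
                             "specificity")])
      jsonlite::write_json(bmet, file.path(cfg$out_dir, "baselines.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$stages$baseline <- lapply(bmet, function(m) m["auroc"])
    }
    TRUE
  }, error = function(e) {
    manifest$stages$failed <<- list(stage = stage, error = conditionMessage(e))
    log_stage(logcon, stage, "FAILED: %s", conditionMessage(e))
    FALSE
  })
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!ok)
    stopf("pipeline failed at stage '%s': %s", manifest$stages$failed$stage,
          manifest$stages$failed$error)
  invisible(manifest)
}
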