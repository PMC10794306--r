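#' Run the full analysis pipeline
#'
#' Orchestrates simulate, preprocess + feature extraction, group statistics,
#' 2-D projection, and LOSO evaluation, writing a self-describing artifact
#' set under `out_dir`:
#' `participants.csv` (and optionally recordings), `features.csv` with a
#' JSON sidecar of the preprocessing parameters, `stats.csv`,
#' `projection_<condition>.csv`, `metrics.json`, per-fold CSVs, boxplot
#' figures, and `manifest.json` (configuration snapshot, seed and package
#' version). Re-running with an identical configuration resumes from the
#' feature table on disk instead of recomputing it; any change to the
#' configuration invalidates the resume.
#'
#' @param config A [study_config()]; all stage seeds derive from its
#'   `master_seed`.
#' @param out_dir Output directory.
#' @param low_hz,high_hz,epoch_length_s,threshold_uv,emd,zscore
#'   Preprocessing / feature parameters (see [preprocess_recording()] and
#'   [extract_features()]).
#' @param n_trees Random-forest size for both tasks.
#' @param conditions Stimulus conditions to evaluate.
#' @param projection_method `"umap"` or `"tsne"`.
#' @param write_recordings Write continuous signals to disk (large; off by
#'   default).
#' @param figures Produce PDF boxplot figures.
#' @return Invisibly, a list with the in-memory `study`, `features`,
#'   `stats`, `projections`, `classification` and `regression` panels,
#'   `chance_level`, and `paths`.
#' @export
run_pipeline <- function(config, out_dir,
                         low_hz = 1, high_hz = 40, epoch_length_s = 2,
                         threshold_uv = 100, emd = TRUE, zscore = FALSE,
                         n_trees = 200,
                         conditions = c("TGT", "IGN", "ALL"),
                         projection_method = "umap",
                         write_recordings = FALSE, figures = TRUE) {
  validate_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(low_hz = low_hz, high_hz = high_hz,
                 epoch_length_s = epoch_length_s,
                 threshold_uv = threshold_uv, emd = emd, zscore = zscore,
                 n_trees = n_trees)
  cfg_json <- as.character(jsonlite::toJSON(
    c(unclass(config), params), auto_unbox = TRUE, digits = NA))
  manifest_path <- file.path(out_dir, "manifest.json")
  features_path <- file.path(out_dir, "features.csv")

  resume <- FALSE
  if (file.exists(manifest_path) && file.exists(features_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path),
                     error = function(e) NULL)
    resume <- !is.null(prev) && identical(prev$config_json, cfg_json)
  }

  # --- simulate ----------------------------------------------------------
  study <- generate_study(config)
  write_study(study, out_dir, signals = write_recordings)

  # --- preprocess + features --------------------------------------------
  if (resume) {
    message("run_pipeline: resuming from existing feature table")
    features <- read.csv(features_path, stringsAsFactors = FALSE)
  } else {
    features <- study_features(study, low_hz = low_hz, high_hz = high_hz,
                               epoch_length_s = epoch_length_s,
                               threshold_uv = threshold_uv, emd = emd,
                               zscore = zscore)
    write.csv(features, features_path, row.names = FALSE)
    jsonlite::write_json(params, file.path(out_dir, "features.json"),
                         auto_unbox = TRUE)
  }

  # --- group statistics --------------------------------------------------
  stats_tbl <- compare_all(features)
  write.csv(stats_tbl, file.path(out_dir, "stats.csv"), row.names = FALSE)

  # --- projection --------------------------------------------------------
  projections <- list()
  for (cond in conditions) {
    pr <- project_features(features, method = projection_method,
                           condition = cond,
                           seed = derive_seed(config$master_seed, 0,
                                              stream = 21L))
    projections[[cond]] <- pr
    out <- cbind(pr$meta, x = pr$coordinates[, 1], y = pr$coordinates[, 2])
    write.csv(out, file.path(out_dir, paste0("projection_", cond, ".csv")),
              row.names = FALSE)
  }

  # --- evaluation --------------------------------------------------------
  clf <- list(); reg <- list()
  for (cond in conditions) {
    clf[[cond]] <- classify_loso(features, cond, n_trees = n_trees,
                                 seed = derive_seed(config$master_seed, 0,
                                                    stream = 22L))
    reg[[cond]] <- regress_loso(features, cond, n_trees = n_trees,
                                seed = derive_seed(config$master_seed, 0,
                                                   stream = 23L))
    write.csv(clf[[cond]]$per_fold,
              file.path(out_dir, paste0("folds_classification_", cond,
                                        ".csv")), row.names = FALSE)
    write.csv(reg[[cond]]$per_fold,
              file.path(out_dir, paste0("folds_regression_", cond, ".csv")),
              row.names = FALSE)
  }
  chance <- chance_level(study$participants$group)
  metrics <- list(
    chance_level_percent = chance,
    classification = lapply(clf, function(p)
      list(pooled = p$pooled, median = as.list(p$summary["median", ]))),
    regression = lapply(reg, function(p)
      list(pooled = p$pooled, median = as.list(p$summary["median", ]))))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- figures -----------------------------------------------------------
  if (figures) {
    plot_feature_boxplots(features,
                          file.path(out_dir, "features_boxplots.pdf"))
    plot_fold_metrics(clf, reg,
                      file.path(out_dir, "evaluation_boxplots.pdf"),
                      chance = chance)
  }

  jsonlite::write_json(
    list(config_json = cfg_json,
         package_version = as.character(utils::packageVersion("eegtda")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    manifest_path, auto_unbox = TRUE)

  invisible(list(study = study, features = features, stats = stats_tbl,
                 projections = projections, classification = clf,
                 regression = reg, chance_level = chance,
                 paths = list(out_dir = out_dir, features = features_path,
                              metrics = file.path(out_dir, "metrics.json"),
                              manifest = manifest_path)))
}

#' Boxplots of each topological feature by group and condition
#'
#' @param features Feature table.
#' @param file Optional PDF path; if `NULL`, plots to the active device.
#' @return Invisibly `NULL`.
#' @export
plot_feature_boxplots <- function(features, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 10, height = 6)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(2, 3), mar = c(3, 4, 2, 1))
  for (f in tda_feature_names()) {
    graphics::boxplot(features[[f]] ~ interaction(features$group,
                                                  features$condition),
                      las = 2, col = c("#4daf4a", "#e41a1c"),
                      main = f, xlab = "", ylab = f)
  }
  invisible(NULL)
}

#' Boxplots of per-fold LOSO metrics across conditions
#'
#' @param clf,reg Named lists of classification / regression
#'   `metric_panel`s by condition.
#' @param file Optional PDF path.
#' @param chance Chance level (percent) drawn on the accuracy panel.
#' @return Invisibly `NULL`.
#' @export
plot_fold_metrics <- function(clf, reg, file = NULL, chance = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 9, height = 6)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(2, 3), mar = c(3, 4, 2, 1))
  grab <- function(panels, metric)
    lapply(panels, function(p) p$per_fold[[metric]])
  graphics::boxplot(grab(clf, "accuracy"), names = names(clf),
                    main = "accuracy", ylab = "accuracy")
  if (!is.null(chance)) graphics::abline(h = chance / 100, lty = 2)
  graphics::boxplot(grab(clf, "f1"), names = names(clf), main = "f1",
                    ylab = "f1")
  for (metric in c("median_error", "mae", "mse"))
    graphics::boxplot(grab(reg, metric), names = names(reg), main = metric,
                      ylab = metric)
  invisible(NULL)
}
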