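#' Default end-to-end pipeline configuration
#'
#' Collects every stage's settings with the published defaults: simulate a
#' 20-subject cohort, detect the seven events, extract seven-phase
#' descriptive features, screen 50 by t-test, keep the top 20 by mean
#' absolute Shapley value (floor 0.002) and evaluate a linear SVM with
#' subject-wise folds.
#'
#' @param simulate List: `n_per_group`, `cycles_per_subject`, `seed`,
#'   `noise_acc`, `noise_gyro`, `effect_scale`.
#' @param detector List of [detector_config()] overrides.
#' @param features List: `mode` (`"seven"`, `"two"` or `"spatiotemporal"`).
#' @param selection List: `k`, `top`, `floor`.
#' @param model List: `kind`, `seed`.
#' @param pooled_selection Select features once on the full table instead of
#'   fold-internally.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), detector = list(),
                            features = list(), selection = list(),
                            model = list(), pooled_selection = FALSE) {
  merge_defaults <- function(defaults, over) {
    defaults[names(over)] <- over
    defaults
  }
  structure(list(
    simulate = merge_defaults(list(n_per_group = 10, cycles_per_subject = 4,
                                   seed = 1, noise_acc = 0.05,
                                   noise_gyro = 0.05, effect_scale = 1),
                              simulate),
    detector = detector,
    features = merge_defaults(list(mode = "seven"), features),
    selection = merge_defaults(list(k = 50, top = 20, floor = 0.002),
                               selection),
    model = merge_defaults(list(kind = "svm_linear", seed = 1), model),
    pooled_selection = isTRUE(pooled_selection)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulate-detect-features-select-evaluate pipeline
#'
#' Executes every stage with the supplied configuration, writing each
#' stage's output (IMU CSVs, event annotation JSON, feature CSV, selection
#' JSON, evaluation JSON) plus a manifest with the configuration, seeds and
#' an MD5 content hash of every output file. Rerunning with the same
#' configuration reproduces identical feature files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_gait_pipeline <- function(config = pipeline_config(),
                              out_dir = tempfile("gaitpipe")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dcfg <- do.call(detector_config, config$detector)

  sim <- config$simulate
  cohort <- simulate_cohort(cohort_spec(
    n_per_group = sim$n_per_group,
    cycles_per_subject = sim$cycles_per_subject, seed = sim$seed,
    noise_acc = sim$noise_acc, noise_gyro = sim$noise_gyro,
    effect_scale = sim$effect_scale))
  sig_dir <- file.path(out_dir, "signals")
  dir.create(sig_dir, showWarnings = FALSE)
  dropped_total <- 0L
  for (sub in cohort$subjects) {
    write_imu_csv(sub$recording$left,
                  file.path(sig_dir, paste0(sub$subject_id, "_left.csv")))
    write_imu_csv(sub$recording$right,
                  file.path(sig_dir, paste0(sub$subject_id, "_right.csv")))
    write_gait_events(sub$truth$right,
                      file.path(sig_dir,
                                paste0(sub$subject_id, "_truth.json")))
    det <- detect_gait_events(sub$recording, dcfg)
    dropped_total <- dropped_total + nrow(det$dropped)
    write_gait_events(det$right,
                      file.path(sig_dir,
                                paste0(sub$subject_id, "_events.json")))
  }
  readr::write_csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
                   progress = FALSE)

  feats <- build_feature_table(cohort, config$features$mode, config = dcfg)
  feat_path <- file.path(out_dir, "features.csv")
  readr::write_csv(feats, feat_path, progress = FALSE)

  sel <- config$selection
  descriptive <- config$features$mode %in% c("two", "seven")
  selection <- NULL
  if (descriptive) {
    subject_tab <- aggregate_by_subject(feats)
    screened <- suppressWarnings(ttest_prescreen(subject_tab, k = sel$k))
    gbt <- gbt_config(seed = config$model$seed)
    shap <- shap_values(fit_gbt(screened, gbt), screened)
    selection <- rank_and_select(shap, top = sel$top, floor = sel$floor)
    jsonlite::write_json(
      list(screened = feature_columns(screened),
           selected = as.character(selection),
           importance = tidy(shap)),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(summary_plot_data(shap),
                     file.path(out_dir, "summary_data.csv"),
                     progress = FALSE)
  }

  spec <- model_spec(config$model$kind, seed = config$model$seed)
  ev <- loso_evaluate(feats, spec,
                      screen_k = if (descriptive) sel$k else NULL,
                      top = if (descriptive) sel$top else NULL,
                      floor = sel$floor,
                      pooled_selection = config$pooled_selection,
                      gbt = gbt_config(seed = config$model$seed))
  jsonlite::write_json(
    list(kind = ev$kind, mean_accuracy = ev$mean_accuracy,
         sd_accuracy = ev$sd_accuracy, folds = ev$folds,
         predictions = ev$predictions),
    file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("insolegait")),
    config = unclass(config),
    config_hash = unname(tools::md5sum(
      write_pipeline_config(config, file.path(out_dir, "config.yaml")))),
    quality = list(dropped_strides = dropped_total,
                   excluded_feature_strides = attr(feats, "excluded")),
    mean_accuracy = ev$mean_accuracy,
    files = purrr::map(setNames(files, sub(paste0(out_dir, "/"), "",
                                           files)),
                       ~ unname(tools::md5sum(.x))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
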