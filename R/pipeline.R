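#' Default run configuration
#'
#' All defaults match the framework's fixed settings: missingness
#' threshold 0.3, three quantile classes, 70/30 stratified split, 5 CV
#' folds, weight grid 0 to 1 in steps of 0.1, logistic iteration cap
#' 3000, 500 trees with minimum leaf size 3.
#'
#' @param data Path to the cohort CSV (header row; empty cells are
#'   missing) — or a data.frame.
#' @param manifest Path to a YAML manifest — or a `variable_manifest`.
#' @param output_dir Directory for run artifacts.
#' @param seed Integer seed for every stochastic stage.
#' @param ... Overrides: `tau_m`, `K`, `split_ratio`, `cv_folds`,
#'   `weight_grid`, `hyperparams`, `index_weights`, `outcome` (list with
#'   `variable`, `tau`; disabled by default), `trivial_baseline` (TRUE),
#'   `perturb_magnitude` (1).
#' @return A `run_config` list.
#' @export
run_config <- function(data, manifest, output_dir = tempfile("riskstrat_run"),
                       seed = 1L, ...) {
  cfg <- list(data = data, manifest = manifest, output_dir = output_dir,
              seed = stopifnot_scalar_seed(seed), tau_m = 0.3, K = 3L,
              split_ratio = 0.7, cv_folds = 5L,
              weight_grid = seq(0, 1, by = 0.1),
              hyperparams = default_hyperparams(), index_weights = NULL,
              outcome = NULL, trivial_baseline = TRUE, perturb_magnitude = 1)
  utils::modifyList(cfg, list(...))
}

read_cohort_csv <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA", "."), check.names = FALSE)
}

#' Run the full risk-stratification pipeline
#'
#' Executes harmonize -> risk induction -> stratified split -> hybrid
#' training (with the cross-validated weight search) -> evaluation ->
#' attribution, with strict fit/apply separation: every transform
#' statistic, quantile edge, and model parameter is estimated on the
#' training partition only and applied unchanged to the held-out
#' partition. All reports are written as CSV/JSON under
#' `config$output_dir`, alongside a run manifest capturing the
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all fitted objects and reports:
#'   `signals_fit`, `labels`, `split`, `model`, `metrics` (per model),
#'   `baseline`, `correlation`, `stability`, `attribution`,
#'   `perturbation`, `paths`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log_stage <- function(...) message("[riskstrat] ", ...)

  dat <- if (is.character(config$data)) read_cohort_csv(config$data) else config$data
  manifest <- if (is.character(config$manifest)) read_manifest(config$manifest)
              else config$manifest

  log_stage("validate: ", nrow(dat), " records in")
  val <- validate_cohort(dat, manifest)
  log_stage("validate: ", val$report$n_records, " records out (",
            val$report$duplicates, " duplicates, ",
            val$report$implausible, " implausible cells)")

  ## provisional labels on the full cohort only to stratify the split;
  ## all model-facing statistics are refit on the training partition
  sm_all <- fit_transform_signals(val$data, manifest, config$tau_m)
  idx_all <- build_risk_index(sm_all, config$index_weights)
  labels_all <- discretize_by_quantiles(idx_all, config$K)
  split <- make_split(labels_all$class_labels, ratio = config$split_ratio,
                      cv_folds = config$cv_folds, seed = config$seed)
  train_df <- val$data[split$train_indices, , drop = FALSE]
  test_df <- val$data[split$test_indices, , drop = FALSE]
  log_stage("split: ", length(split$train_indices), " train / ",
            length(split$test_indices), " test")

  sm_fit <- fit_transform_signals(train_df, manifest, config$tau_m)
  sm_test <- apply_transform(test_df, sm_fit, manifest)
  idx_train <- build_risk_index(sm_fit, config$index_weights)
  labels_train <- discretize_by_quantiles(idx_train, config$K)
  idx_test <- build_risk_index(sm_test, config$index_weights)
  y_train <- labels_train$class_labels
  y_test <- trivial_baseline(labels_train, idx_test)
  log_stage("risk induction: K = ", config$K, ", train class counts ",
            paste(tabulate(y_train + 1L, config$K), collapse = "/"))

  model <- fit_hybrid(sm_fit$signals, y_train, grid = config$weight_grid,
                      folds = config$cv_folds, seed = config$seed,
                      hyperparams = config$hyperparams)
  log_stage("hybrid: w = ", model$w, " (linear) / ", 1 - model$w,
            " (nonlinear), C = ", model$training_metadata$C)

  pred_test <- predict(model, sm_test$signals)
  p1 <- predict_linear(model$linear, sm_test$signals, model$classes)
  p2 <- predict_forest(model$forest, sm_test$signals, model$classes)
  metrics <- list(
    hybrid = classification_metrics(y_test, pred_test$class, pred_test$prob),
    linear = classification_metrics(y_test, argmax_class(p1), p1),
    nonlinear = classification_metrics(y_test, argmax_class(p2), p2))

  baseline <- NULL
  if (isTRUE(config$trivial_baseline)) {
    bl_pred <- trivial_baseline(labels_train, idx_train)
    baseline <- classification_metrics(y_train, bl_pred)
    log_stage("trivial baseline (fit partition): accuracy ",
              signif(baseline$accuracy, 6))
  }

  correlation <- representation_correlation(pred_test$R, idx_test)
  stability <- stability_table(model$fold_metrics)
  attribution <- attribute_signals(model, sm_test,
                                   references = reference_vector(sm_fit))
  perturbation <- perturb_sensitivity(model, sm_test,
                                      magnitude = config$perturb_magnitude)

  outcome <- NULL
  if (!is.null(config$outcome)) {
    outcome <- threshold_outcome(val$data[[config$outcome$variable]],
                                 config$outcome$tau, config$outcome$variable)
  }

  ## artifacts
  write_signal_matrix(sm_fit, out("harmonized_train.csv"), out("transform_params.json"))
  write_risk_labels(labels_train, out("labels_train.csv"), out("risk_index.json"))
  write_attribution(attribution, out("attribution.csv"))
  utils::write.csv(perturbation, out("perturbation.csv"), row.names = FALSE)
  utils::write.csv(stability, out("stability.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(metrics$hybrid$confusion_normalized),
                   out("confusion_hybrid_normalized.csv"))
  metrics_json <- lapply(metrics, function(m)
    m[c("accuracy", "precision_macro", "recall_macro", "f1_macro",
        "roc_auc_macro", "n_evaluated")])
  jsonlite::write_json(
    list(test = metrics_json,
         trivial_baseline_fit_accuracy = baseline$accuracy,
         correlation = correlation,
         hybrid_weight_linear = model$w,
         linear_C = model$training_metadata$C),
    out("metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = config$seed, tau_m = config$tau_m, K = config$K,
         split_ratio = config$split_ratio, cv_folds = config$cv_folds,
         weight_grid = config$weight_grid,
         hyperparams = config$hyperparams,
         exclusion_report = val$report[c("duplicates", "implausible",
                                         "sentinel_missing", "n_records")],
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("riskstrat"))),
    out("run_manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    signals_fit = sm_fit, signals_test = sm_test, labels = labels_train,
    split = split, model = model, metrics = metrics, baseline = baseline,
    correlation = correlation, stability = stability,
    attribution = attribution, perturbation = perturbation,
    outcome = outcome, exclusion_report = val$report,
    paths = config$output_dir))
}
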