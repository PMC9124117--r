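#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's configuration for the full workflow: simulate (or
#' load) a cohort, preprocess it, select features on the training partition,
#' train the ABO-optimized network, and evaluate on the held-out test
#' partition. Every randomized stage derives its own seed deterministically
#' from the single global `seed`, so a run is reproducible bit-for-bit from
#' (input, config, seed).
#'
#' @param seed Global integer seed.
#' @param input_csv,schema_path Optional paths to an existing cohort CSV and
#'   schema sidecar; when `NULL` (default) a synthetic cohort is generated.
#' @param cohort Named list of [cohort_spec()] overrides for the simulate
#'   stage (e.g. `list(n_patients = 500)`).
#' @param horizon_days Survival horizon for label derivation (default 1826).
#' @param max_missing Row-drop threshold for [impute_cohort()].
#' @param train_fraction,stratify Outer train/test split parameters
#'   (defaults 0.7, stratified).
#' @param selection A [selection_control()] for [hybrid_select()].
#' @param arch Optional [network_arch()]; by default sized from the selected
#'   features at training time.
#' @param train_abo An [abo_config()] for network training.
#' @param scope,train_objective Passed to [train_with_abo()].
#' @param cutoff Classification cutoff (default 0.5).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            input_csv = NULL, schema_path = NULL,
                            cohort = list(),
                            horizon_days = 1826,
                            max_missing = 0.3,
                            train_fraction = 0.7,
                            stratify = TRUE,
                            selection = selection_control(),
                            arch = NULL,
                            train_abo = abo_config(n_buffalo = 30,
                                                   max_iterations = 500),
                            scope = "all_weights",
                            train_objective = "mse",
                            cutoff = 0.5) {
  structure(
    list(seed = as.integer(seed), input_csv = input_csv,
         schema_path = schema_path, cohort = cohort,
         horizon_days = horizon_days, max_missing = max_missing,
         train_fraction = train_fraction, stratify = stratify,
         selection = selection, arch = arch, train_abo = train_abo,
         scope = scope, train_objective = train_objective, cutoff = cutoff),
    class = "pipeline_config"
  )
}

#' Pipeline stages
#'
#' Each stage function runs one step of the workflow and, given an output
#' directory, writes its artifacts as plain CSV (with schema sidecars where
#' applicable). [run_pipeline()] chains them in workflow order —
#' simulate/load, preprocess, select, train, evaluate — and writes a
#' manifest recording the configuration hash and seed; reruns with the same
#' configuration produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return `simulate_stage()`: list with `table` and `truth`.
#'   `preprocess_stage()`: the cleaned, imputed, labelled cohort table.
#'   `select_stage()`: a [feature_mask()]. `train_stage()`: an `abann` fit.
#'   `evaluate_stage()`: a [metrics_report()]. `run_pipeline()`: a list with
#'   all of the above, invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
simulate_stage <- function(config, dir = NULL) {
  args <- config$cohort
  args$n_patients <- args$n_patients %||% 2000L
  args$seed <- args$seed %||% derive_seed(config$seed, "simulate")
  args$horizon_days <- args$horizon_days %||% config$horizon_days
  cohort <- generate_cohort(do.call(cohort_spec, args))
  if (!is.null(dir)) {
    write_cohort(cohort$table, file.path(dir, "cohort.csv"))
    readr::write_csv(
      tibble(feature = cohort$truth$informative_features,
             coefficient = cohort$truth$coefficients),
      file.path(dir, "ground_truth.csv"), progress = FALSE
    )
  }
  cohort
}

#' @rdname pipeline-stages
#' @param table A cohort table (from [simulate_stage()] or [read_cohort()]).
#' @export
preprocess_stage <- function(config, table, dir = NULL) {
  cleaned <- clean_table(table)
  imputed <- impute_cohort(cleaned, max_missing = config$max_missing)
  date_cols <- c("transplant_date", "dialysis_start_date",
                 "last_followup_date")
  if (all(date_cols %in% names(imputed))) {
    lab <- derive_graft_outcome(imputed, horizon_days = config$horizon_days)
    label <- lab$label
  } else {
    out_col <- cols_with_tag(imputed, "outcome")
    if (!length(out_col)) {
      abort("Need either the three date columns or an outcome column to label records.",
            class = "graftann_data_error")
    }
    label <- as.integer(imputed[[out_col[1]]])
  }
  preop <- cols_with_tag(imputed, "preop")
  out <- keep_cols(imputed, preop)
  out$label <- label
  sc <- c(cohort_schema(out), label = "outcome")
  run_log <- attr(imputed, "run_log")
  out <- cohort_table(out, sc)
  attr(out, "run_log") <- run_log
  if (!is.null(dir)) {
    write_cohort(out, file.path(dir, "preprocessed.csv"))
    if (!is.null(run_log)) {
      readr::write_csv(run_log, file.path(dir, "run_log.csv"), progress = FALSE)
    }
  }
  out
}

#' @rdname pipeline-stages
#' @param train Training partition of the preprocessed table.
#' @export
select_stage <- function(config, train, dir = NULL) {
  feats <- train[, cols_with_tag(train, "preop"), drop = FALSE]
  mask <- hybrid_select(feats, train$label, control = config$selection,
                        seed = derive_seed(config$seed, "select"))
  if (!is.null(dir)) {
    readr::write_csv(as_tibble(mask), file.path(dir, "feature_mask.csv"),
                     progress = FALSE)
    readr::write_csv(as_tibble(feature_ranking(feats, train$label,
                                               bins = config$selection$bins)),
                     file.path(dir, "feature_ranking.csv"), progress = FALSE)
  }
  mask
}

#' @rdname pipeline-stages
#' @param mask The selected [feature_mask()].
#' @export
train_stage <- function(config, train, mask, dir = NULL) {
  feats <- train[, selected_features(mask), drop = FALSE]
  fit <- train_with_abo(
    feats, train$label, arch = config$arch, abo = config$train_abo,
    scope = config$scope, objective = config$train_objective,
    seed = derive_seed(config$seed, "train")
  )
  if (!is.null(dir)) {
    write_network_params(fit$params, file.path(dir, "network_params.csv"))
    readr::write_csv(
      tibble(iteration = seq_along(fit$history), objective = fit$history),
      file.path(dir, "training_history.csv"), progress = FALSE
    )
  }
  fit
}

#' @rdname pipeline-stages
#' @param fit The trained `abann` model.
#' @param test Held-out test partition.
#' @export
evaluate_stage <- function(config, fit, test, mask, dir = NULL) {
  feats <- test[, selected_features(mask), drop = FALSE]
  prob <- predict(fit, feats, type = "prob")
  pred <- as.integer(prob >= config$cutoff)
  report <- metrics_report(test$label, pred, scores = prob)
  if (!is.null(dir)) {
    readr::write_csv(
      tibble(row = seq_along(prob), probability = prob, class = pred,
             label = test$label),
      file.path(dir, "predictions.csv"), progress = FALSE
    )
    readr::write_csv(as_tibble(report), file.path(dir, "metrics.csv"),
                     progress = FALSE)
  }
  report
}

#' @rdname pipeline-stages
#' @export
run_pipeline <- function(config = pipeline_config(), dir = NULL) {
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  truth <- NULL
  if (is.null(config$input_csv)) {
    cohort <- simulate_stage(config, dir)
    table <- cohort$table
    truth <- cohort$truth
  } else {
    table <- read_cohort(config$input_csv,
                         config$schema_path %||%
                           paste0(config$input_csv, ".schema"))
  }
  prepared <- preprocess_stage(config, table, dir)
  parts <- split_train_test(prepared, train_fraction = config$train_fraction,
                            seed = derive_seed(config$seed, "split"),
                            stratify = config$stratify)
  mask <- select_stage(config, parts$train, dir)
  fit <- train_stage(config, parts$train, mask, dir)
  report <- evaluate_stage(config, fit, parts$test, mask, dir)
  if (!is.null(dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("graftann")),
      seed = config$seed,
      config_hash = rlang::hash(config),
      n_train = nrow(parts$train), n_test = nrow(parts$test),
      n_features_selected = sum(mask$selected),
      artifacts = sort(setdiff(list.files(dir), "manifest.json"))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(metrics = report, mask = mask, fit = fit,
                 train = parts$train, test = parts$test, truth = truth))
}
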