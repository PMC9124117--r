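#' Feature masks
#'
#' A feature mask is a tibble with one row per candidate feature and columns
#' `feature`, `gain` (information gain in bits, `NA` when not computed),
#' `selected` (logical) and `provenance` (which stage produced the mask:
#' `"full"`, `"ig_filter"`, `"abo_wrapper"` or `"backward_elimination"`).
#' A mask always selects at least one feature.
#'
#' @param feature Character vector of feature names.
#' @param selected Logical vector.
#' @param gain Optional numeric information-gain vector.
#' @param provenance Stage label.
#' @return A `feature_mask` tibble.
#' @export
feature_mask <- function(feature, selected, gain = NA_real_,
                         provenance = "full") {
  if (!any(selected)) {
    abort("A feature mask must select at least one feature.",
          class = "graftann_config_error")
  }
  out <- tibble(feature = feature, gain = gain, selected = selected,
                provenance = provenance)
  class(out) <- c("feature_mask", class(out))
  out
}

#' @rdname feature_mask
#' @param mask A `feature_mask`.
#' @export
selected_features <- function(mask) mask$feature[mask$selected]

#' Information-gain filter
#'
#' Ranks every feature by information gain about the labels and keeps those
#' with gain strictly above `threshold` (default 0: a feature with zero gain
#' is rejected as uninformative). If nothing passes, the single top-ranked
#' feature is kept so the mask is never empty.
#'
#' @param data Data frame of candidate features (training rows only).
#' @param labels Class labels.
#' @param threshold Non-negative gain threshold in bits (default 0).
#' @param bins Equal-frequency bin count for continuous features.
#' @return A [feature_mask()] with provenance `"ig_filter"`.
#' @export
ig_filter <- function(data, labels, threshold = 0, bins = 10) {
  if (threshold < 0) {
    abort("`threshold` must be non-negative.", class = "graftann_config_error")
  }
  gains <- vapply(data, information_gain, numeric(1),
                  labels = labels, bins = bins)
  selected <- unname(gains > threshold)
  if (!any(selected)) selected[which.max(gains)] <- TRUE
  feature_mask(names(data), selected, gain = unname(gains),
               provenance = "ig_filter")
}

#' Control parameters for hybrid feature selection
#'
#' @param use_ig,use_wrapper,use_elimination Stage toggles; with all three
#'   disabled [hybrid_select()] returns the full mask.
#' @param ig_threshold Gain threshold for the filter stage (default 0).
#' @param bins Discretization bins for information gain.
#' @param classifier Internal classifier scoring candidate subsets:
#'   `"logistic"` (a binomial GLM; fast and deterministic, the default) or
#'   `"abann"` (the ABO-trained perceptron itself, markedly slower).
#' @param val_fraction Fraction of the training rows held out as the
#'   internal validation split used by the wrapper and elimination stages
#'   (default 0.2, stratified, fixed within a run). Test rows are never
#'   seen: selection operates on the training partition only.
#' @param abo [abo_config()] for the wrapper search; its iteration budget is
#'   deliberately modest because each evaluation fits a classifier.
#' @return A `selection_control` list.
#' @export
selection_control <- function(use_ig = TRUE, use_wrapper = TRUE,
                              use_elimination = TRUE, ig_threshold = 0,
                              bins = 10,
                              classifier = c("logistic", "abann"),
                              val_fraction = 0.2,
                              abo = abo_config(n_buffalo = 20,
                                               max_iterations = 25)) {
  structure(
    list(use_ig = use_ig, use_wrapper = use_wrapper,
         use_elimination = use_elimination, ig_threshold = ig_threshold,
         bins = bins, classifier = match.arg(classifier),
         val_fraction = val_fraction, abo = abo),
    class = "selection_control"
  )
}

# Stratified fit/validation row split of the training partition.
internal_split <- function(labels, val_fraction, seed) {
  n <- length(labels)
  parts <- split_train_test(
    tibble(label = labels, row = seq_len(n)),
    train_fraction = 1 - val_fraction, seed = seed, stratify = TRUE
  )
  list(fit = parts$train$row, val = parts$test$row)
}

fit_internal_classifier <- function(data, labels, method, seed = 1L) {
  df <- dplyr::mutate(as_tibble(data),
                      dplyr::across(dplyr::where(is.character), factor))
  if (method == "logistic") {
    df$.y <- labels
    suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
  } else {
    train_with_abo(df, labels,
                   abo = abo_config(n_buffalo = 10, max_iterations = 40,
                                    seed = seed))
  }
}

predict_internal_classifier <- function(model, data, method) {
  df <- dplyr::mutate(as_tibble(data),
                      dplyr::across(dplyr::where(is.character), factor))
  if (method == "logistic") {
    as.integer(suppressWarnings(predict(model, newdata = df,
                                        type = "response")) >= 0.5)
  } else {
    predict(model, df, type = "class")
  }
}

# Validation accuracy of a classifier trained on the given feature subset;
# NA on classifier failure (the caller maps it to worst-case fitness).
subset_accuracy <- function(data, labels, cols, split, method, seed = 1L) {
  tryCatch({
    fit <- fit_internal_classifier(data[split$fit, cols, drop = FALSE],
                                   labels[split$fit], method, seed = seed)
    pred <- predict_internal_classifier(fit, data[split$val, cols, drop = FALSE],
                                        method)
    mean(pred == labels[split$val])
  }, error = function(e) NA_real_)
}

#' ABO wrapper feature-subset search
#'
#' Searches feature subsets with the buffalo optimizer: each buffalo's
#' continuous position is binarized through a sigmoid transfer into a
#' candidate subset, whose fitness is `1 - validation accuracy` of the
#' internal classifier trained on it (internal stratified split of the
#' supplied training rows; test rows are never touched). One buffalo is
#' seeded at the incoming mask, so the returned subset never scores worse
#' than the input on the same split. Subset evaluations are memoized.
#'
#' @param data Training-partition features.
#' @param labels Training labels.
#' @param mask Incoming [feature_mask()] (default: all features).
#' @param control A [selection_control()].
#' @param seed Integer seed governing the internal split and the search.
#' @return A [feature_mask()] with provenance `"abo_wrapper"`, carrying the
#'   attributes `fitness` (best objective value) and `n_classifier_failures`.
#' @export
abo_wrapper_select <- function(data, labels, mask = NULL,
                               control = selection_control(), seed = 1L) {
  if (is.null(mask)) mask <- feature_mask(names(data), rep(TRUE, ncol(data)))
  cand <- selected_features(mask)
  if (length(cand) < 2L) {
    out <- mask
    out$provenance <- "abo_wrapper"
    return(out)
  }
  split <- internal_split(labels, control$val_fraction,
                          derive_seed(seed, "internal_split"))
  memo <- new.env(parent = emptyenv())
  failures <- 0L
  objective <- function(v) {
    bmask <- binarize_position(v)
    key <- paste0(as.integer(bmask), collapse = "")
    if (!is.null(memo[[key]])) return(memo[[key]])
    acc <- subset_accuracy(data, labels, cand[bmask], split,
                           control$classifier, seed = seed)
    if (is.na(acc)) {
      failures <<- failures + 1L
      acc <- 0
    }
    memo[[key]] <- 1 - acc
    memo[[key]]
  }
  cfg <- control$abo
  if (is.null(cfg$seed)) cfg$seed <- derive_seed(seed, "wrapper")
  res <- abo_minimize(objective, dims = length(cand), config = cfg,
                      init = matrix(1, nrow = 1, ncol = length(cand)))
  best <- binarize_position(res$best_x)
  selected <- setNames(rep(FALSE, nrow(mask)), mask$feature)
  selected[cand[best]] <- TRUE
  out <- feature_mask(mask$feature, unname(selected[mask$feature]),
                      gain = mask$gain, provenance = "abo_wrapper")
  if (failures > 0L) {
    inform(sprintf("Wrapper search: %d candidate subset(s) failed to fit and were scored worst-case.",
                   failures))
  }
  attr(out, "fitness") <- res$best_f
  attr(out, "n_classifier_failures") <- failures
  out
}

#' One-by-one backward feature elimination
#'
#' Scans the selected features one by one (weakest information gain first),
#' tentatively removing each and retraining the internal classifier on the
#' internal validation split. A feature is permanently dropped only when its
#' removal *strictly* improves validation accuracy — if removal hurts or
#' ties, the feature is deemed necessary and kept. Passes repeat until every
#' currently selected feature has been tested since the last removal, so the
#' final validation accuracy can never fall below the initial one.
#'
#' @inheritParams abo_wrapper_select
#' @return A [feature_mask()] with provenance `"backward_elimination"` and
#'   attributes `initial_accuracy`, `final_accuracy` and `elimination_log`
#'   (a tibble of every tested removal).
#' @export
backward_eliminate <- function(data, labels, mask = NULL,
                               control = selection_control(), seed = 1L) {
  if (is.null(mask)) mask <- feature_mask(names(data), rep(TRUE, ncol(data)))
  selected <- selected_features(mask)
  split <- internal_split(labels, control$val_fraction,
                          derive_seed(seed, "internal_split"))
  base_acc <- subset_accuracy(data, labels, selected, split,
                              control$classifier, seed = seed)
  if (is.na(base_acc)) {
    abort("Internal classifier failed on the full incoming subset.",
          class = "graftann_data_error")
  }
  initial_acc <- base_acc
  log <- list()
  if (length(selected) > 1L) {
    gains <- vapply(data[selected], information_gain, numeric(1),
                    labels = labels, bins = control$bins)
    repeat {
      removed_any <- FALSE
      scan <- selected[order(gains[selected])]
      for (f in scan) {
        if (length(selected) <= 1L) break
        trial <- setdiff(selected, f)
        acc <- subset_accuracy(data, labels, trial, split,
                               control$classifier, seed = seed)
        drop <- !is.na(acc) && acc > base_acc
        log[[length(log) + 1L]] <- tibble(
          feature = f, accuracy_without = acc, accuracy_with = base_acc,
          dropped = drop
        )
        if (drop) {
          selected <- trial
          base_acc <- acc
          removed_any <- TRUE
        }
      }
      if (!removed_any || length(selected) <= 1L) break
    }
  }
  out <- feature_mask(mask$feature, mask$feature %in% selected,
                      gain = mask$gain, provenance = "backward_elimination")
  attr(out, "initial_accuracy") <- initial_acc
  attr(out, "final_accuracy") <- base_acc
  attr(out, "elimination_log") <- dplyr::bind_rows(log)
  out
}

#' Hybrid feature selection
#'
#' Composes the three selection stages in order: information-gain filter at
#' threshold zero, ABO wrapper subset search, and one-by-one backward
#' elimination. Each stage only removes (or keeps) features, so the final
#' subset is nested in the filter's output. Individual stages can be
#' disabled through [selection_control()]; with all stages off, the full
#' mask is returned unchanged.
#'
#' @inheritParams abo_wrapper_select
#' @return The final [feature_mask()], with the intermediate stage masks in
#'   the `"stages"` attribute.
#' @export
hybrid_select <- function(data, labels, control = selection_control(),
                          seed = 1L) {
  stages <- list()
  mask <- if (control$use_ig) {
    ig_filter(data, labels, threshold = control$ig_threshold,
              bins = control$bins)
  } else {
    feature_mask(names(data), rep(TRUE, ncol(data)))
  }
  stages$ig_filter <- mask
  if (control$use_wrapper && sum(mask$selected) > 1L) {
    mask <- abo_wrapper_select(data, labels, mask, control = control,
                               seed = seed)
    stages$abo_wrapper <- mask
  }
  if (control$use_elimination && sum(mask$selected) > 1L) {
    mask <- backward_eliminate(data, labels, mask, control = control,
                               seed = seed)
    stages$backward_elimination <- mask
  }
  attr(mask, "stages") <- stages
  mask
}
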