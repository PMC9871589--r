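#' Flatten volumes and reduce by principal components
#'
#' Concatenates each subject's GM and WM voxels into one feature vector
#' and projects onto principal components fitted on `fit_ids` only, so
#' held-out subjects are transformed with a training-set basis. External
#' precomputed features (e.g. regional volumes or cortical thickness from
#' an upstream morphometry toolkit) can be used instead via
#' `feature_matrix`.
#'
#' @param cohort an [cohort()] with volumes.
#' @param n_components number of components (`NULL` = `min(50,
#'   length(fit_ids) - 1)`).
#' @param fit_ids subject ids defining the reduction basis (default: all).
#' @param feature_matrix optional subjects x features matrix replacing the
#'   flattened voxels (rows aligned with the cohort, or named by subject
#'   id).
#' @return an `epcog_features` list: `features` (subjects x components),
#'   `explained_variance` (per component), `basis` (the fitted `prcomp`),
#'   `provenance`.
#' @export
flatten_and_reduce <- function(cohort, n_components = NULL, fit_ids = NULL,
                               feature_matrix = NULL) {
  fit_ids <- fit_ids %||% cohort$subject_id
  fit_rows <- match(fit_ids, cohort$subject_id)
  if (anyNA(fit_rows)) {
    abort("fit_ids contains unknown subject ids", class = "epcog_argument_error")
  }
  if (is.null(feature_matrix)) {
    flat <- t(vapply(cohort$volume, function(v) as.numeric(v),
                     numeric(length(cohort$volume[[1]]))))
    provenance <- "flattened GM+WM voxels"
  } else {
    flat <- as.matrix(feature_matrix)
    if (!is.null(rownames(flat))) {
      flat <- flat[cohort$subject_id, , drop = FALSE]
    }
    if (anyNA(flat)) {
      abort("external features must not contain missing values",
            class = "epcog_argument_error")
    }
    provenance <- "external feature CSV"
  }
  n_components <- n_components %||% min(50L, length(fit_rows) - 1L)
  if (n_components > length(fit_rows) - 1L) {
    abort(sprintf("n_components (%d) must be <= |fit set| - 1 (%d)",
                  n_components, length(fit_rows) - 1L),
          class = "epcog_argument_error")
  }
  basis <- prcomp(flat[fit_rows, , drop = FALSE], center = TRUE,
                  scale. = FALSE, rank. = n_components)
  scores <- predict(basis, flat)[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- cohort$subject_id
  ev <- basis$sdev^2 / sum(basis$sdev^2)
  structure(list(features = scores,
                 explained_variance = ev[seq_len(n_components)],
                 basis = basis, provenance = provenance),
            class = "epcog_features")
}

#' Fit one classical baseline classifier
#'
#' `RF` = random forest with 500 trees, `SVM` = radial-basis-kernel
#' support vector machine with probability outputs, `GBM` = gradient
#' boosting (binary logistic).
#'
#' @param features subjects x features numeric matrix.
#' @param labels `"EP"`/`"HC"` vector aligned with the rows.
#' @param model_kind `"RF"`, `"SVM"` or `"GBM"`.
#' @param seed integer seed.
#' @return an `epcog_baseline` with the fitted classifier and a
#'   `predict_prob(features)` closure returning EP probabilities.
#' @export
fit_ml_baseline <- function(features, labels, model_kind = c("RF", "SVM", "GBM"),
                            seed = 1) {
  model_kind <- match.arg(model_kind)
  y <- factor(as.character(labels), levels = c("HC", "EP"))
  if (nlevels(droplevels(y)) < 2) {
    abort("both classes must be present in the fit labels",
          class = "epcog_argument_error")
  }
  fit <- with_seed(seed, switch(
    model_kind,
    RF = randomForest::randomForest(x = features, y = y, ntree = 500),
    SVM = e1071::svm(x = features, y = y, kernel = "radial",
                     probability = TRUE),
    GBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(features,
                                  label = as.numeric(y == "EP")),
      nrounds = 100)
  ))
  predict_prob <- switch(
    model_kind,
    RF = function(x) predict(fit, x, type = "prob")[, "EP"],
    SVM = function(x) {
      attr(predict(fit, x, probability = TRUE), "probabilities")[, "EP"]
    },
    GBM = function(x) predict(fit, xgboost::xgb.DMatrix(x))
  )
  structure(list(fit = fit, model_kind = model_kind,
                 n_trees = if (model_kind == "RF") fit$ntree,
                 predict_prob = predict_prob),
            class = "epcog_baseline")
}

#' Cross-validated baseline on the same folds as the deep model
#'
#' Per fold, PCA is refitted on the training split only and the chosen
#' classifier is trained and evaluated; using a shared [make_folds()]
#' assignment yields per-fold metric tables aligned row-for-row with the
#' network's for paired comparison.
#'
#' @inheritParams fit_ml_baseline
#' @param cohort an [cohort()] with volumes.
#' @param folds a [make_folds()] tibble.
#' @param n_components PCA components per fold (`NULL` = `min(50,
#'   n_train - 1)`).
#' @param feature_matrix optional external features (see
#'   [flatten_and_reduce()]).
#' @return an `epcog_cv` object (classification metrics only).
#' @export
baseline_cv <- function(cohort, folds, model_kind = c("RF", "SVM", "GBM"),
                        n_components = NULL, feature_matrix = NULL,
                        seed = 1) {
  model_kind <- match.arg(model_kind)
  k <- max(folds$fold)
  fold_metrics <- vector("list", k)
  predictions <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds$subject_id[folds$fold == f]
    train_ids <- setdiff(cohort$subject_id, test_ids)
    red <- flatten_and_reduce(cohort, n_components = n_components,
                              fit_ids = train_ids,
                              feature_matrix = feature_matrix)
    bl <- fit_ml_baseline(red$features[train_ids, , drop = FALSE],
                          cohort$diagnosis[match(train_ids, cohort$subject_id)],
                          model_kind, seed = derive_seed(seed, f))
    prob <- bl$predict_prob(red$features[test_ids, , drop = FALSE])
    truth <- as.character(cohort$diagnosis)[match(test_ids, cohort$subject_id)]
    pred_class <- ifelse(prob >= 0.5, "EP", "HC")
    cc <- confusion_counts(truth, pred_class)
    m <- confusion_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    m$auc <- roc_auc(prob, truth)
    fold_metrics[[f]] <- dplyr::mutate(m, fold = f, .before = 1)
    predictions[[f]] <- tibble(fold = f, subject_id = test_ids,
                               truth = truth, pred = pred_class,
                               ep_prob = unname(prob))
  }
  metrics <- dplyr::bind_rows(fold_metrics)
  long <- tidyr::pivot_longer(metrics, -"fold", names_to = "metric")
  aggregate <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n_undefined = sum(is.na(.data$value)), .groups = "drop")
  structure(list(folds = folds, metrics = metrics, aggregate = aggregate,
                 predictions = dplyr::bind_rows(predictions),
                 models = NULL, k = k, model_kind = model_kind),
            class = "epcog_cv")
}
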