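#' Classification metrics from confusion counts
#'
#' `acc = (tp + tn) / total`, `F1 = 2tp / (2tp + fp + fn)`,
#' `spe = tn / (fp + tn)`, with EP as the positive class. A metric whose
#' denominator is zero is reported as `NA` (an explicit undefined marker,
#' never silently zeroed) and excluded from fold aggregation.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return tibble with `acc`, `f1`, `spe`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total < 1) {
    abort("confusion counts sum to zero", class = "epcog_argument_error")
  }
  tibble(
    acc = (tp + tn) / total,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    spe = if (fp + tn > 0) tn / (fp + tn) else NA_real_
  )
}

#' Confusion counts from labels
#'
#' @param truth,pred vectors of `"EP"`/`"HC"` labels.
#' @return list with `tp`, `fp`, `tn`, `fn` (positive class = EP).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  list(tp = sum(truth == "EP" & pred == "EP"),
       fp = sum(truth == "HC" & pred == "EP"),
       tn = sum(truth == "HC" & pred == "HC"),
       fn = sum(truth == "EP" & pred == "HC"))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair-ordering probability: the fraction of
#' (EP, HC) pairs where the EP score is higher, with ties credited 1/2
#' (realized through average ranks). Single-class input returns `NA`.
#'
#' @param scores positive-class (EP) scores.
#' @param labels `"EP"`/`"HC"` labels.
#' @return scalar AUC in \[0, 1\], or `NA`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "EP"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression metrics per cognition dimension
#'
#' `MAE = mean |y - y_hat|`; `R^2 = 1 - SS_res / SS_tot`, which is
#' negative when predictions are worse than the mean predictor and `NA`
#' when `y` has zero variance.
#'
#' @param y,y_hat numeric matrices (subjects x dimensions) or vectors.
#' @return tibble with one row per dimension (`dimension`, `mae`, `r2`)
#'   plus an `"aggregate"` row averaging the defined values.
#' @export
regression_metrics <- function(y, y_hat) {
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  if (is.vector(y_hat)) y_hat <- matrix(y_hat, ncol = 1)
  if (!all(dim(y) == dim(y_hat))) {
    abort("`y` and `y_hat` shapes differ", class = "epcog_shape_error")
  }
  if (nrow(y) < 2) {
    abort("need at least two samples", class = "epcog_argument_error")
  }
  dims <- colnames(y) %||% paste0("dim", seq_len(ncol(y)))
  rows <- purrr::map(seq_len(ncol(y)), function(j) {
    e <- y[, j] - y_hat[, j]
    ss_tot <- sum((y[, j] - mean(y[, j]))^2)
    tibble(dimension = dims[j],
           mae = mean(abs(e)),
           r2 = if (ss_tot > 0) 1 - sum(e^2) / ss_tot else NA_real_)
  })
  per_dim <- dplyr::bind_rows(rows)
  dplyr::bind_rows(per_dim,
                   tibble(dimension = "aggregate",
                          mae = mean(per_dim$mae, na.rm = TRUE),
                          r2 = mean(per_dim$r2, na.rm = TRUE)))
}

#' Stratified k-fold assignment
#'
#' Subjects are shuffled within each stratum (default diagnosis x gender),
#' strata are concatenated, and positions are dealt round-robin over the k
#' folds. Folds therefore partition the cohort with sizes differing by at
#' most one, and every fold's share of each stratum is within one subject
#' of proportional allocation — the stratified sampling used so the
#' train/test gender ratios match.
#'
#' @param cohort an [cohort()] (volumes not required).
#' @param k number of folds.
#' @param strat_keys metadata columns defining strata.
#' @param seed shuffle seed.
#' @return tibble `subject_id`, `fold` (1..k).
#' @export
make_folds <- function(cohort, k = 5, strat_keys = c("diagnosis", "gender"),
                       seed = 1) {
  n <- nrow(cohort)
  if (k > n) {
    abort(sprintf("k = %d exceeds cohort size %d", k, n),
          class = "epcog_argument_error")
  }
  strata <- interaction(as.data.frame(cohort)[, strat_keys], drop = TRUE)
  with_seed(seed, {
    order_ids <- unlist(lapply(levels(strata), function(s) {
      ids <- which(strata == s)
      if (length(ids) > 1) sample(ids) else ids
    }))
    tibble(subject_id = cohort$subject_id[order_ids],
           fold = rep_len(seq_len(k), n)) |>
      dplyr::arrange(match(.data$subject_id, cohort$subject_id))
  })
}

#' Balanced-accuracy-optimal decision threshold
#'
#' Scans the midpoints between consecutive sorted scores (plus 0.5) and
#' returns the cut maximizing balanced accuracy; ties break toward the
#' threshold closest to 0.5.
#'
#' @param scores positive-class probabilities/scores.
#' @param labels `"EP"`/`"HC"` labels of the same subjects.
#' @return scalar threshold.
#' @export
calibrate_threshold <- function(scores, labels) {
  labels <- as.character(labels)
  s <- sort(unique(scores))
  cand <- unique(c(0.5, (head(s, -1) + tail(s, -1)) / 2))
  bal <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- mean(pred[labels == "EP"])
    spec <- mean(!pred[labels == "HC"])
    (sens + spec) / 2
  }, numeric(1))
  best <- which(bal >= max(bal) - 1e-12)
  cand[best][which.min(abs(cand[best] - 0.5))]
}

# fold-wise fit of imputation/binning/standardization + training + test
# metrics; `paper_mode` fits preprocessing on the full cohort instead of
# the training split (mimicking whole-dataset normalization)
fit_fold <- function(cohort, fold_ids, model_cfg, train_cfg,
                     paper_mode = FALSE) {
  test_rows <- which(cohort$subject_id %in% fold_ids)
  train_rows <- setdiff(seq_len(nrow(cohort)), test_rows)
  fit_rows <- if (paper_mode) seq_len(nrow(cohort)) else train_rows
  needs_cog <- any(c("CLC", "CLR") %in% model_cfg$heads)
  clc <- clr <- NULL
  binning <- standardization <- NULL
  test_scores <- NULL
  if (needs_cog) {
    sc_all <- impute_missing(score_table(cohort), fit_rows = fit_rows)
    sc_all <- sc_all[, model_cfg$clc_dimensions, drop = FALSE]
    if ("CLC" %in% model_cfg$heads) {
      binning <- fit_binning(sc_all[fit_rows, , drop = FALSE],
                             model_cfg$n_categories)
      clc <- bin_scores(binning, sc_all)
    }
    if ("CLR" %in% model_cfg$heads) {
      standardization <- standardize_scores(sc_all, fit_rows = fit_rows)
      clr <- standardization$z
    }
    test_scores <- sc_all[test_rows, , drop = FALSE]
  }
  fit <- train_model(cohort[train_rows, ], model_cfg, train_cfg,
                     clc_labels = if (!is.null(clc))
                       clc[train_rows, , drop = FALSE],
                     clr_targets = if (!is.null(clr))
                       clr[train_rows, , drop = FALSE])
  gender_all <- if (model_cfg$use_gender_embedding) as.character(cohort$gender)
  # decision threshold calibrated on training-set predictions (balanced
  # accuracy), never on held-out data; probabilities rank well but their
  # offset depends on the training trajectory
  train_prob <- forward(fit, cohort$volume[train_rows],
                        gender = gender_all[train_rows])$ep_prob
  thr <- calibrate_threshold(train_prob,
                             as.character(cohort$diagnosis)[train_rows])
  pred <- forward(fit, cohort$volume[test_rows], gender = gender_all[test_rows])
  truth <- as.character(cohort$diagnosis)[test_rows]
  pred_class <- ifelse(pred$ep_prob >= thr, "EP", "HC")
  cc <- confusion_counts(truth, pred_class)
  cls <- confusion_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
  cls$auc <- roc_auc(pred$ep_prob, truth)
  reg <- NULL
  if ("CLR" %in% model_cfg$heads) {
    pred_orig <- invert_scores(pred$clr_values, standardization)
    reg <- regression_metrics(test_scores, pred_orig)
    agg <- reg[reg$dimension == "aggregate", ]
    cls$mae <- agg$mae
    cls$r2 <- agg$r2
  }
  clc_acc <- NULL
  if ("CLC" %in% model_cfg$heads) {
    truth_cat <- bin_scores(binning, test_scores)
    clc_acc <- colMeans(pred$clc_class == truth_cat)
    cls$clc_acc <- mean(clc_acc)
  }
  prob <- pred$ep_prob
  list(metrics = cls, model = fit, regression = reg, clc_accuracy = clc_acc,
       predictions = tibble(subject_id = cohort$subject_id[test_rows],
                            truth = truth, pred = pred_class,
                            ep_prob = prob))
}

#' Stratified k-fold cross-validation of the multi-task model
#'
#' For every fold, imputation means, binning edges and standardization
#' statistics are fitted on the training split only (`paper_mode = TRUE`
#' fits them on the full cohort instead, mimicking whole-dataset
#' preprocessing at the cost of a mild leak), the network is trained on
#' the training split, and all metrics are computed on the held-out fold.
#'
#' @inheritParams make_folds
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param paper_mode fit preprocessing on the full cohort.
#' @param keep_models retain the k fitted models (memory permitting).
#' @return an `epcog_cv` object: `folds` (assignment), `metrics`
#'   (per-fold), `aggregate` (mean and SD per metric over the defined
#'   folds), `predictions`; `tidy()`, `glance()` and `autoplot()` methods
#'   apply.
#' @export
cross_validate <- function(cohort, model_cfg, train_cfg, k = 5,
                           strat_keys = c("diagnosis", "gender"),
                           paper_mode = FALSE, seed = 1,
                           keep_models = FALSE) {
  folds <- make_folds(cohort, k = k, strat_keys = strat_keys,
                      seed = derive_seed(seed, 10))
  fold_metrics <- vector("list", k)
  predictions <- vector("list", k)
  models <- if (keep_models) vector("list", k)
  for (f in seq_len(k)) {
    fold_cfg <- train_cfg
    fold_cfg$seed <- derive_seed(seed, 20 + f)
    res <- tryCatch(
      fit_fold(cohort, folds$subject_id[folds$fold == f], model_cfg,
               fold_cfg, paper_mode = paper_mode),
      error = function(e) {
        abort(sprintf("fold %d failed: %s", f, conditionMessage(e)),
              class = "epcog_training_error")
      })
    fold_metrics[[f]] <- dplyr::mutate(res$metrics, fold = f, .before = 1)
    predictions[[f]] <- dplyr::mutate(res$predictions, fold = f, .before = 1)
    if (keep_models) models[[f]] <- res$model
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
                 models = models, k = k),
            class = "epcog_cv")
}

#' @export
print.epcog_cv <- function(x, ...) {
  cat(sprintf("<epcog_cv  %d folds>\n", x$k))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-8s %.3f +/- %.3f%s\n", agg$metric[i], agg$mean[i],
                agg$sd[i],
                if (agg$n_undefined[i] > 0)
                  sprintf("  (%d undefined fold(s) dropped)", agg$n_undefined[i])
                else ""))
  }
  invisible(x)
}

#' Demographic and cognition group-comparison table
#'
#' Per continuous variable (age and the six cognition dimensions, observed
#' values only): group means (SD) and the two-tailed pooled-variance
#' Student t-test p-value. Per categorical variable (gender, ethnicity):
#' counts and the Pearson chi-square p-value (1 df, no continuity
#' correction). Degenerate cells are reported as `NA`.
#'
#' @param cohort an [cohort()] (volumes not required).
#' @return tibble with `variable`, `type`, `hc`, `ep` (formatted cells)
#'   and `p_value`.
#' @export
cohort_summary <- function(cohort) {
  hc <- as.data.frame(cohort)[cohort$diagnosis == "HC", ]
  ep <- as.data.frame(cohort)[cohort$diagnosis == "EP", ]
  if (nrow(hc) == 0 || nrow(ep) == 0) {
    abort("both diagnostic groups must be non-empty",
          class = "epcog_argument_error")
  }
  cont_row <- function(name, a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- if (length(a) > 1 && length(b) > 1 && (sd(a) > 0 || sd(b) > 0)) {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    } else NA_real_
    tibble(variable = name, type = "continuous",
           hc = sprintf("%.2f (%.2f)", mean(a), sd(a)),
           ep = sprintf("%.2f (%.2f)", mean(b), sd(b)),
           p_value = p)
  }
  cat_row <- function(name, va, vb) {
    lev <- sort(unique(c(va, vb)))
    tab <- rbind(table(factor(va, lev)), table(factor(vb, lev)))
    p <- if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
             all(colSums(tab) > 0)) {
      # asymptotic Pearson chi-square is the intended statistic even at
      # small counts; silence the small-expected-count advisory
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    } else NA_real_
    tibble(variable = name, type = "categorical",
           hc = paste(tab[1, ], collapse = "/"),
           ep = paste(tab[2, ], collapse = "/"),
           p_value = p)
  }
  out <- list(cont_row("age", hc$age, ep$age),
              cat_row("gender", as.character(hc$gender),
                      as.character(ep$gender)),
              cat_row("ethnicity", as.character(hc$ethnicity),
                      as.character(ep$ethnicity)))
  for (d in COG_DIMS) {
    out <- c(out, list(cont_row(d, hc[[d]], ep[[d]])))
  }
  dplyr::bind_rows(out)
}
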