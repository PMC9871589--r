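test_that("confusion metrics follow the printed formulas", {
  m <- confusion_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(m$acc, 0.7)
  expect_equal(m$f1, 6 / 9)
  expect_equal(m$spe, 0.8)
  perfect <- confusion_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(perfect), c(acc = 1, f1 = 1, spe = 1))
  # degenerate denominators give explicit undefined markers, never zeros
  deg <- confusion_metrics(tp = 3, fp = 0, tn = 0, fn = 1)
  expect_true(is.na(deg$spe))
  expect_false(is.na(deg$acc))
  expect_error(confusion_metrics(0, 0, 0, 0), class = "epcog_argument_error")
})

test_that("AUC equals the Mann-Whitney pair-ordering probability", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c("EP", "EP", "HC", "HC")), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("EP", "EP", "HC", "HC")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("EP", "HC"), 3)), 0.5)
  expect_true(is.na(roc_auc(c(0.4, 0.6), c("EP", "EP"))))
})

test_that("classification and regression metrics match brute-force oracles", {
  set.seed(81)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    truth <- sample(c("EP", "HC"), n, replace = TRUE)
    pred <- sample(c("EP", "HC"), n, replace = TRUE)
    cc <- confusion_counts(truth, pred)
    got <- confusion_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    want <- oracle_confusion(truth, pred)
    expect_equal(unlist(got), want, tolerance = 1e-9)

    scores <- round(runif(n), 2) # rounding forces occasional ties
    if (length(unique(truth)) == 2) {
      expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth),
                   tolerance = 1e-9)
    }
    y <- rnorm(n); yhat <- rnorm(n)
    rm_ <- regression_metrics(y, yhat)
    expect_equal(rm_$mae[1], oracle_mae(y, yhat), tolerance = 1e-9)
    expect_equal(rm_$r2[1], oracle_r2(y, yhat), tolerance = 1e-9)
  }
})

test_that("regression metrics handle identities and degenerate cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(y, y)$mae[1], 0)
  expect_equal(regression_metrics(y, y)$r2[1], 1)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2[1], 0)
  expect_equal(regression_metrics(c(1, 2), c(2, 4))$mae[1], 1.5)
  expect_true(is.na(regression_metrics(c(2, 2, 2), c(1, 2, 3))$r2[1]))
  expect_error(regression_metrics(1, 1), class = "epcog_argument_error")
})

test_that("stratified folds partition 77 subjects as published", {
  coh <- meta_cohort_77()
  folds <- make_folds(coh, k = 5, seed = 3)
  sizes <- sort(as.integer(table(folds$fold)))
  expect_equal(sizes, c(15L, 15L, 15L, 16L, 16L))
  expect_setequal(folds$subject_id, coh$subject_id)
  expect_equal(anyDuplicated(folds$subject_id), 0L)
  # 15 females over 5 folds: every fold holds 3 +/- 1
  fem <- coh$subject_id[coh$gender == "female"]
  fem_per_fold <- table(folds$fold[folds$subject_id %in% fem])
  expect_true(all(fem_per_fold >= 2 & fem_per_fold <= 4))
  # per-stratum proportionality within one subject
  strata <- interaction(coh$diagnosis, coh$gender)
  for (s in levels(strata)) {
    ids <- coh$subject_id[strata == s]
    per_fold <- tabulate(folds$fold[folds$subject_id %in% ids], 5)
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(make_folds(coh[1:3, ], k = 5), class = "epcog_argument_error")
})

test_that("cohort summary reproduces group statistics", {
  coh <- meta_cohort_77()
  s <- cohort_summary(coh)
  expect_equal(s$p_value[s$variable == "gender"], 0.8167646, tolerance = 1e-6)
  expect_equal(s$p_value[s$variable == "ethnicity"], 0.8523565,
               tolerance = 1e-6)
  # identical groups: t = 0, p = 1
  half <- as.data.frame(coh)[coh$diagnosis == "HC", ]
  mirrored <- half
  mirrored$diagnosis <- "EP"
  mirrored$subject_id <- paste0("m", half$subject_id)
  both <- cohort(rbind(half, mirrored))
  s2 <- cohort_summary(both)
  expect_equal(s2$p_value[s2$variable == "age"], 1)
})

test_that("chi-square p-values match an exact small-table oracle", {
  # analytic 1-df chi-square against a direct transcription of the
  # Pearson statistic
  tabs <- list(rbind(c(31, 8), c(31, 7)), rbind(c(28, 11), c(28, 10)),
               rbind(c(10, 5), c(3, 12)))
  for (tab in tabs) {
    n <- sum(tab)
    expect_stat <- outer(rowSums(tab), colSums(tab)) / n
    x2 <- sum((tab - expect_stat)^2 / expect_stat)
    p_oracle <- 1 - pchisq(x2, df = 1)
    p_got <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    expect_equal(p_got, p_oracle, tolerance = 1e-3)
  }
})

test_that("fold fitting never reads held-out labels or scores", {
  coh <- tiny_cohort(n_hc = 6, n_ep = 6, dims = c(8, 8, 8), seed = 91)
  mc <- model_config(c(8, 8, 8), conv_channels = c(4), heads = c("EP", "CLR"))
  tc <- train_config(learning_rate = 1e-3, batch_size = 6, epochs = 3,
                     augmentation = FALSE, seed = 1)
  # stratify on gender only, so corrupting held-out diagnoses cannot
  # change the fold assignment itself
  folds <- make_folds(coh, k = 2, strat_keys = "gender", seed = 7)
  run_fold1 <- function(cohort) {
    epcog:::fit_fold(cohort, folds$subject_id[folds$fold == 1], mc,
                     tc)$predictions
  }
  clean <- run_fold1(coh)
  poisoned <- coh
  bad_rows <- which(poisoned$subject_id %in%
                      folds$subject_id[folds$fold == 1])
  poisoned$diagnosis[bad_rows] <- rev(poisoned$diagnosis[bad_rows])
  for (d in c("psp", "vig", "wme", "vel", "vil", "pso")) {
    poisoned[[d]][bad_rows] <- poisoned[[d]][bad_rows] + 37
  }
  dirty <- run_fold1(poisoned)
  # identical probabilities: the fitted pipeline saw none of the changes
  expect_equal(clean$ep_prob, dirty$ep_prob, tolerance = 1e-12)
})

test_that("cross-validation reports one row per fold and aggregates", {
  coh <- tiny_cohort(n_hc = 6, n_ep = 6, dims = c(8, 8, 8), seed = 92)
  mc <- model_config(c(8, 8, 8), conv_channels = c(4), heads = "EP")
  tc <- train_config(learning_rate = 1e-3, batch_size = 6, epochs = 2,
                     augmentation = FALSE, seed = 1)
  cv <- cross_validate(coh, mc, tc, k = 3, seed = 5)
  expect_equal(nrow(cv$metrics), 3)
  expect_s3_class(tidy(cv), "tbl_df")
  g <- glance(cv)
  expect_equal(g$acc, mean(cv$metrics$acc))
  expect_equal(nrow(cv$predictions), nrow(coh))
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
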