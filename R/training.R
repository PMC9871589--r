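#' Training configuration
#'
#' Defaults follow the published recipe: Adam with starting learning rate
#' 1e-4 decayed by 0.7 after every 60 epochs, weight decay 0.02, batch
#' size 10, 300 epochs, with random rotation/flip augmentation.
#'
#' @param learning_rate starting learning rate.
#' @param lr_decay_factor,lr_decay_every multiplicative decay and its
#'   epoch period.
#' @param weight_decay optimizer weight-decay rate (the regularization
#'   term of the composite loss).
#' @param batch_size,epochs batch size and epoch count.
#' @param augmentation random flip/rotation augmentation on or off.
#' @param max_rotation_deg rotation half-range in degrees.
#' @param loss_weights named weights for `ep`, `clc`, `clr` loss terms.
#' @param seed integer seed driving shuffling, dropout and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, lr_decay_factor = 0.7,
                         lr_decay_every = 60, weight_decay = 0.02,
                         batch_size = 10, epochs = 300,
                         augmentation = TRUE, max_rotation_deg = 10,
                         loss_weights = c(ep = 1, clc = 1, clr = 1),
                         seed = 1) {
  stopifnot(learning_rate > 0, lr_decay_factor > 0, lr_decay_every >= 1,
            weight_decay >= 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = lr_decay_every,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 augmentation = isTRUE(augmentation),
                 max_rotation_deg = max_rotation_deg,
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-entropy loss
#'
#' `-sum_i s_i log(s_hat_i)` for one-hot truth `s` and predicted
#' probabilities `s_hat`; matrices are treated as one sample per row and
#' averaged over the batch. Predictions are floored at 1e-12 before the
#' logarithm.
#'
#' @param true one-hot vector or matrix (rows = samples).
#' @param pred probability vector/matrix of the same shape; each sample
#'   must sum to 1 within 1e-6.
#' @return scalar loss.
#' @export
cross_entropy <- function(true, pred) {
  if (is.vector(true)) true <- matrix(true, nrow = 1)
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
  if (!all(dim(true) == dim(pred))) {
    abort("`true` and `pred` shapes differ", class = "epcog_shape_error")
  }
  if (!all(is.finite(pred)) || any(abs(rowSums(pred) - 1) > 1e-6)) {
    abort("each predicted distribution must be finite and sum to 1",
          class = "epcog_argument_error")
  }
  mean(-rowSums(true * log(pmax(pred, 1e-12))))
}

#' Mean-square-error loss
#'
#' Squared Euclidean distance `||g - g_hat||^2` per sample, averaged over
#' the batch (so learning-rate semantics do not depend on batch size).
#'
#' @param truth,pred numeric vectors (one sample) or matrices (rows =
#'   samples).
#' @return scalar loss.
#' @export
mse_loss <- function(truth, pred) {
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1)
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
  if (!all(dim(truth) == dim(pred))) {
    abort("`truth` and `pred` shapes differ", class = "epcog_shape_error")
  }
  mean(rowSums((truth - pred)^2))
}

#' Composite multi-task loss breakdown
#'
#' The training objective is the sum of the EP cross-entropy, the CLC
#' cross-entropy, the CLR mean-square error and the regularization
#' (weight-decay) term; disabled heads contribute zero. The decay term is
#' realized inside the optimizer; its reported value here is
#' `(wd/2) * sum(theta^2)` for transparency.
#'
#' @param l_ce_sz,l_ce_c,l_mse component losses (`NULL` for disabled heads).
#' @param l_reg regularization value.
#' @param loss_weights named weights (`ep`, `clc`, `clr`).
#' @return tibble with one row: `l_ce_sz`, `l_ce_c`, `l_mse`, `l_reg`,
#'   `l_total`.
#' @export
total_loss <- function(l_ce_sz, l_ce_c = NULL, l_mse = NULL, l_reg = 0,
                       loss_weights = c(ep = 1, clc = 1, clr = 1)) {
  w <- loss_weights
  tibble(
    l_ce_sz = l_ce_sz %||% 0,
    l_ce_c = l_ce_c %||% 0,
    l_mse = l_mse %||% 0,
    l_reg = l_reg,
    l_total = w[["ep"]] * (l_ce_sz %||% 0) + w[["clc"]] * (l_ce_c %||% 0) +
      w[["clr"]] * (l_mse %||% 0) + l_reg
  )
}

#' Random flip/rotation augmentation of an input volume
#'
#' A left-right flip with probability 1/2, followed by rotation about a
#' random principal axis by an angle drawn uniformly from
#' `[-max_deg, +max_deg]` degrees, trilinearly resampled and clamped to
#' \[0, 1\]. Deterministic given `seed`.
#'
#' @param volume a `multichannel_volume` (or 3D array, treated as one
#'   channel).
#' @param seed integer seed.
#' @param max_deg rotation half-range in degrees.
#' @return augmented volume of the same shape/class.
#' @export
augment <- function(volume, seed, max_deg = 10) {
  with_seed(seed, {
    flip <- runif(1) < 0.5
    axis <- sample(3L, 1)
    angle <- runif(1, -max_deg, max_deg) * pi / 180
    transform_volume(volume, flip = flip, axis = axis, angle = angle)
  })
}

# deterministic core of `augment`; exported for identity/involution checks
#' @rdname augment
#' @param flip apply the left-right (first-axis) flip.
#' @param axis rotation axis (1 = H, 2 = W, 3 = D).
#' @param angle rotation angle in radians.
#' @export
transform_volume <- function(volume, flip = FALSE, axis = 1L, angle = 0) {
  dm <- dim(volume)
  single <- length(dm) == 3L
  arr <- if (single) array(volume, c(dm, 1L)) else volume
  dims <- dim(arr)[1:3]
  out <- arr
  for (ch in seq_len(dim(arr)[4])) {
    v <- arr[, , , ch]
    if (flip) v <- v[dims[1]:1, , , drop = FALSE]
    if (angle != 0) {
      v <- cpp_rotate_trilinear(as.numeric(v), dims, axis, angle)
    }
    out[, , , ch] <- clamp01(array(v, dims))
  }
  if (single) out <- array(out, dm)
  attributes_from <- attributes(volume)
  if (!is.null(attributes_from$class)) {
    attributes(out) <- attributes_from
  }
  out
}

# one-hot matrix from integer classes in 1..k
one_hot <- function(classes, k) {
  m <- matrix(0, length(classes), k)
  m[cbind(seq_along(classes), classes)] <- 1
  m
}

reg_value <- function(params, wd) {
  if (wd == 0) return(0)
  wd / 2 * sum(vapply(params, function(z) sum(z^2), numeric(1)))
}

# Forward + composite loss + parameter gradients on one prepared batch.
# `labels`: list(ep = integer 1/2 (2 = EP), clc = n x dims category matrix,
# clr = n x dims standardized scores). Used by the training loop, the
# finite-difference gradient check, and the head-isolation tests.
loss_and_gradients <- function(model, x, labels, gender = NULL,
                               loss_weights = c(ep = 1, clc = 1, clr = 1),
                               weight_decay = 0, training = TRUE,
                               update_running = FALSE, drop_masks = NULL,
                               compute_grads = TRUE) {
  cfg <- model$config
  n <- dim(x)[3]
  fw <- forward_pass(model, x, gender = gender, training = training,
                     keep_cache = compute_grads,
                     update_running = update_running,
                     drop_masks = drop_masks)
  d_heads <- list()
  p_ep <- softmax_rows(fw$ep_logits)
  y_ep <- one_hot(labels$ep, 2)
  l_ep <- cross_entropy(y_ep, p_ep)
  if (compute_grads) d_heads$ep <- loss_weights[["ep"]] * (p_ep - y_ep) / n
  l_clc <- NULL
  if ("CLC" %in% cfg$heads) {
    nd <- length(cfg$clc_dimensions)
    k <- cfg$n_categories
    dlogits <- matrix(0, n, nd * k)
    ces <- numeric(nd)
    for (d in seq_len(nd)) {
      cols <- (d - 1) * k + seq_len(k)
      pd <- softmax_rows(fw$clc_logits[, cols, drop = FALSE])
      yd <- one_hot(labels$clc[, d], k)
      ces[d] <- cross_entropy(yd, pd)
      dlogits[, cols] <- (pd - yd) / (n * nd)
    }
    l_clc <- mean(ces) # mean over dimensions keeps scale comparable to EP CE
    if (compute_grads) d_heads$clc <- loss_weights[["clc"]] * dlogits
  }
  l_clr <- NULL
  if ("CLR" %in% cfg$heads) {
    l_clr <- mse_loss(labels$clr, fw$clr_values)
    if (compute_grads) {
      d_heads$clr <- loss_weights[["clr"]] * 2 * (fw$clr_values - labels$clr) / n
    }
  }
  breakdown <- total_loss(l_ep, l_clc, l_clr,
                          reg_value(model$params, weight_decay), loss_weights)
  out <- list(loss = breakdown, forward = fw)
  if (compute_grads) {
    bw <- backward_pass(model, fw, d_heads)
    if (weight_decay > 0) {
      for (nm in names(bw$grads)) {
        bw$grads[[nm]] <- bw$grads[[nm]] + weight_decay * model$params[[nm]]
      }
    }
    out$grads <- bw$grads
  }
  out
}

# epoch learning rate under the step-decay schedule
schedule_lr <- function(config, epoch) {
  config$learning_rate *
    config$lr_decay_factor^floor((epoch - 1) / config$lr_decay_every)
}

#' Train the multi-task model on a cohort
#'
#' End-to-end optimization of the composite loss with Adam under the
#' configured schedule. CLC categories and CLR targets may be supplied
#' explicitly (as done per fold by [cross_validate()], where imputation,
#' binning and standardization are fitted on the training split); when
#' omitted they are derived from the cohort's own scores.
#'
#' @param cohort an [cohort()] with volumes.
#' @param model_config a [model_config()].
#' @param config a [train_config()].
#' @param clc_labels optional n x dims integer category matrix.
#' @param clr_targets optional n x dims standardized score matrix.
#' @param verbose print per-epoch losses.
#' @return the trained `epcog_model`, with a `history` element (tibble of
#'   per-epoch `epoch`, `lr`, loss components) and any internally fitted
#'   preprocessing in `preprocessing`.
#' @export
train_model <- function(cohort, model_config, config = train_config(),
                        clc_labels = NULL, clr_targets = NULL,
                        verbose = FALSE) {
  if (nrow(cohort) == 0) {
    abort("cohort is empty", class = "epcog_argument_error")
  }
  cfg <- model_config
  model <- build_model(cfg, seed = derive_seed(config$seed, 1))
  prep <- list()
  if (any(c("CLC", "CLR") %in% cfg$heads) &&
      (is.null(clc_labels) || is.null(clr_targets))) {
    sc <- impute_missing(score_table(cohort))
    sc <- sc[, cfg$clc_dimensions, drop = FALSE]
    if ("CLC" %in% cfg$heads && is.null(clc_labels)) {
      prep$binning <- fit_binning(sc, cfg$n_categories)
      clc_labels <- bin_scores(prep$binning, sc)
    }
    if ("CLR" %in% cfg$heads && is.null(clr_targets)) {
      prep$standardization <- standardize_scores(sc)
      clr_targets <- prep$standardization$z
    }
  }
  y <- as.integer(cohort$diagnosis) # 1 = HC, 2 = EP
  gender <- if (cfg$use_gender_embedding) as.character(cohort$gender)
  volumes <- cohort$volume
  n <- length(volumes)
  adam_m <- lapply(model$params, function(z) array(0, dim(z) %||% length(z)))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  history <- vector("list", config$epochs)
  set.seed(derive_seed(config$seed, 2))
  for (epoch in seq_len(config$epochs)) {
    lr <- schedule_lr(config, epoch)
    idx <- sample(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_losses <- NULL
    for (bi in batches) {
      vols <- volumes[bi]
      if (config$augmentation) {
        aug_seeds <- sample.int(2147483646L, length(bi))
        vols <- purrr::map2(vols, aug_seeds, augment,
                            max_deg = config$max_rotation_deg)
      }
      x <- make_batch(vols, cfg$pad_dims)
      labels <- list(ep = y[bi],
                     clc = if (!is.null(clc_labels))
                       clc_labels[bi, , drop = FALSE],
                     clr = if (!is.null(clr_targets))
                       clr_targets[bi, , drop = FALSE])
      lg <- tryCatch(
        loss_and_gradients(model, x, labels, gender = gender[bi],
                           loss_weights = config$loss_weights,
                           weight_decay = config$weight_decay,
                           training = TRUE, update_running = TRUE),
        error = function(e) {
          abort(sprintf("training diverged at epoch %d: %s", epoch,
                        conditionMessage(e)),
                class = "epcog_training_error")
        })
      model$running <- lg$forward$running
      if (!is.finite(lg$loss$l_total)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
              class = "epcog_training_error")
      }
      t_step <- t_step + 1
      for (nm in names(model$params)) {
        g <- lg$grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        mhat <- adam_m[[nm]] / (1 - b1^t_step)
        vhat <- adam_v[[nm]] / (1 - b2^t_step)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_losses <- rbind(ep_losses, lg$loss)
    }
    history[[epoch]] <- dplyr::summarise_all(ep_losses, mean)
    history[[epoch]]$epoch <- epoch
    history[[epoch]]$lr <- lr
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f", epoch, lr,
                      history[[epoch]]$l_total))
    }
  }
  # recalibrate batch-norm running statistics with a clean pass over the
  # un-augmented training set, so inference normalization matches what the
  # decision boundary was learned under
  model$running <- recalibrate_bn(model, volumes, gender, config$batch_size)
  model$history <- dplyr::bind_rows(history)[, c("epoch", "lr", "l_ce_sz",
                                                 "l_ce_c", "l_mse", "l_reg",
                                                 "l_total")]
  model$preprocessing <- prep
  model$train_config <- config
  model
}

# average per-batch normalization moments over the training set
recalibrate_bn <- function(model, volumes, gender, batch_size) {
  n <- length(volumes)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  acc_mu <- acc_var <- NULL
  total <- 0
  for (idx in chunks) {
    x <- make_batch(volumes[idx], model$config$pad_dims)
    fw <- forward_pass(model, x, gender = gender[idx], training = TRUE,
                       keep_cache = TRUE)
    w <- length(idx)
    mus <- lapply(fw$caches, `[[`, "mu")
    vars <- lapply(fw$caches, `[[`, "var")
    if (is.null(acc_mu)) {
      acc_mu <- lapply(mus, function(z) z * w)
      acc_var <- lapply(vars, function(z) z * w)
    } else {
      acc_mu <- purrr::map2(acc_mu, mus, function(a, b) a + b * w)
      acc_var <- purrr::map2(acc_var, vars, function(a, b) a + b * w)
    }
    total <- total + w
  }
  running <- model$running
  for (i in seq_along(acc_mu)) {
    running[[paste0("conv", i, ".mean")]] <- acc_mu[[i]] / total
    running[[paste0("conv", i, ".var")]] <- acc_var[[i]] / total
  }
  running
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every point of the Cartesian grid by training on an inner
#' stratified split of the supplied cohort and scoring EP accuracy on the
#' held-in validation part, so the outer test folds are never touched.
#' Ties break toward smaller learning rate, then smaller batch, then
#' smaller weight decay.
#'
#' @param cohort training cohort.
#' @param model_config a [model_config()].
#' @param base_config a [train_config()] supplying everything the grid
#'   does not vary.
#' @param space named list with `lr`, `batch`, `wd` candidate vectors
#'   (default: the published grid).
#' @param val_frac validation fraction of the inner split.
#' @param seed seed for the split and training.
#' @return list with `best` (a [train_config()]) and `log` (one row per
#'   evaluated candidate).
#' @export
grid_search <- function(cohort, model_config, base_config = train_config(),
                        space = list(lr = c(1e-3, 1e-4, 1e-5),
                                     batch = c(4, 8, 10, 12),
                                     wd = c(0.0, 0.1, 0.2, 0.3, 0.4)),
                        val_frac = 0.2, seed = 1) {
  grid <- expand.grid(lr = space$lr, batch = space$batch, wd = space$wd,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) {
    abort("empty search space", class = "epcog_argument_error")
  }
  # inner stratified split on diagnosis x gender
  strata <- interaction(cohort$diagnosis, cohort$gender, drop = TRUE)
  val_idx <- integer()
  with_seed(derive_seed(seed, 3), {
    for (s in levels(strata)) {
      ids <- which(strata == s)
      k <- max(1L, round(length(ids) * val_frac))
      val_idx <- c(val_idx, sample(ids, min(k, length(ids))))
    }
  })
  train_idx <- setdiff(seq_len(nrow(cohort)), val_idx)
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cand <- base_config
    cand$learning_rate <- grid$lr[i]
    cand$batch_size <- as.integer(grid$batch[i])
    cand$weight_decay <- grid$wd[i]
    cand$seed <- derive_seed(seed, 100 + i)
    acc <- tryCatch({
      fit <- train_model(cohort[train_idx, ], model_config, cand)
      pred <- forward(fit, cohort$volume[val_idx],
                      gender = if (model_config$use_gender_embedding)
                        as.character(cohort$gender)[val_idx])
      pred_class <- ifelse(pred$ep_prob >= 0.5, "EP", "HC")
      mean(pred_class == as.character(cohort$diagnosis)[val_idx])
    }, error = function(e) NA_real_) # diverged candidates rank last
    results[[i]] <- tibble(lr = grid$lr[i], batch = grid$batch[i],
                           wd = grid$wd[i], val_accuracy = acc)
  }
  log <- dplyr::bind_rows(results)
  ranked <- dplyr::arrange(log, dplyr::desc(.data$val_accuracy), .data$lr,
                           .data$batch, .data$wd)
  best <- base_config
  best$learning_rate <- ranked$lr[1]
  best$batch_size <- as.integer(ranked$batch[1])
  best$weight_decay <- ranked$wd[1]
  list(best = best, log = log)
}
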