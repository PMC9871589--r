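test_that("cross-entropy matches its closed forms and a loop oracle", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(cross_entropy(c(0, 1, 0), rep(1, 3) / 3), log(3))
  expect_error(cross_entropy(c(1, 0), c(0.5, 0.4, 0.1)),
               class = "epcog_shape_error")
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.2)),
               class = "epcog_argument_error")
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(2:8, 1); k <- sample(2:5, 1)
    truth <- t(vapply(seq_len(n), function(i) {
      z <- numeric(k); z[sample(k, 1)] <- 1; z
    }, numeric(k)))
    p <- matrix(runif(n * k), n, k); p <- p / rowSums(p)
    per_sample <- vapply(seq_len(n),
                         function(i) -sum(truth[i, ] * log(p[i, ])),
                         numeric(1))
    expect_equal(cross_entropy(truth, p), mean(per_sample), tolerance = 1e-9)
  }
})

test_that("mean-square error matches arithmetic and a loop oracle", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(0, 3), 9)
  set.seed(52)
  g <- matrix(rnorm(24), 4, 6); p <- matrix(rnorm(24), 4, 6)
  per_sample <- vapply(1:4, function(i) sum((g[i, ] - p[i, ])^2), numeric(1))
  expect_equal(mse_loss(g, p), mean(per_sample), tolerance = 1e-9)
  expect_error(mse_loss(1:3, 1:4), class = "epcog_shape_error")
})

test_that("the composite loss is additive over enabled heads", {
  b <- total_loss(0.7, l_reg = 0.1)
  expect_equal(b$l_total, 0.8)
  expect_equal(b$l_ce_c, 0)
  z <- total_loss(0, 0, 0, 0)
  expect_equal(z$l_total, 0)
  w <- total_loss(1, 1, 1, 0, loss_weights = c(ep = 1, clc = 0.5, clr = 2))
  expect_equal(w$l_total, 3.5)
})

test_that("zeroed auxiliary loss weights isolate gradient flow", {
  dims <- c(4, 4, 4)
  cfg <- model_config(dims, conv_channels = c(3), head_hidden = 4,
                      dropout = 0)
  m <- build_model(cfg, seed = 7)
  set.seed(53)
  x <- array(runif(prod(dims) * 2 * 2), c(prod(dims), 2, 2))
  labels <- list(ep = c(1L, 2L), clc = matrix(1L, 2, 6),
                 clr = matrix(0, 2, 6))
  lg <- epcog:::loss_and_gradients(m, x, labels,
                                   loss_weights = c(ep = 1, clc = 0, clr = 0))
  expect_true(all(abs(lg$grads$clc.W2) == 0))
  expect_true(all(abs(lg$grads$clr.W2) == 0))
  expect_gt(sum(abs(lg$grads$ep.W2)), 0)
  expect_gt(sum(abs(lg$grads$conv1.W)), 0)
})

test_that("augmentation primitives: identity, involution, range", {
  v <- random_volume(c(8, 8, 8), seed = 61)
  # zero rotation and no flip is the identity
  expect_equal(as.numeric(transform_volume(v, flip = FALSE, angle = 0)),
               as.numeric(v), tolerance = 1e-6)
  # two flips compose to the identity
  flipped <- transform_volume(v, flip = TRUE, angle = 0)
  expect_equal(as.numeric(transform_volume(flipped, flip = TRUE, angle = 0)),
               as.numeric(v), tolerance = 1e-12)
  expect_false(identical(as.numeric(flipped), as.numeric(v)))
  # deterministic given the seed
  expect_identical(augment(v, seed = 5), augment(v, seed = 5))
  # range is preserved over random draws
  v16 <- random_volume(c(16, 16, 16), seed = 62)
  for (s in 1:100) {
    a <- augment(v16, seed = s)
    expect_true(min(a) >= 0 && max(a) <= 1)
  }
})

test_that("a tiny model overfits a tiny cohort and logs every epoch", {
  coh <- tiny_cohort(n_hc = 4, n_ep = 4, dims = c(8, 8, 8), seed = 71)
  cfg <- model_config(c(8, 8, 8), conv_channels = c(4), heads = "EP",
                      dropout = 0)
  tc <- train_config(learning_rate = 1e-3, batch_size = 4, epochs = 50,
                     augmentation = FALSE, weight_decay = 0, seed = 1)
  fit <- train_model(coh, cfg, tc)
  expect_equal(nrow(fit$history), 50)
  expect_lt(fit$history$l_total[50], fit$history$l_total[1])
  # identical seeds reproduce the history bit for bit
  fit2 <- train_model(coh, cfg, tc)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("the learning rate decays by 0.7 after every 60 epochs", {
  tc <- train_config(learning_rate = 1e-4)
  lrs <- vapply(1:130, function(e) epcog:::schedule_lr(tc, e), numeric(1))
  expect_equal(lrs[60], 1e-4)
  expect_equal(lrs[61], 0.7e-4)
  expect_equal(lrs[61] / lrs[60], 0.7)
  expect_equal(lrs[121], 0.49e-4)
  # and the schedule is what the training history records
  coh <- tiny_cohort(n_hc = 2, n_ep = 2, dims = c(8, 8, 8), seed = 72)
  cfg <- model_config(c(8, 8, 8), conv_channels = c(2), heads = "EP")
  fit <- train_model(coh, cfg,
                     train_config(learning_rate = 1e-3, batch_size = 4,
                                  epochs = 61, augmentation = FALSE,
                                  seed = 1))
  expect_equal(fit$history$lr[60], 1e-3)
  expect_equal(fit$history$lr[61], 0.7e-3)
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  coh <- tiny_cohort(n_hc = 5, n_ep = 5, dims = c(8, 8, 8), seed = 73)
  cfg <- model_config(c(8, 8, 8), conv_channels = c(2), heads = "EP")
  base <- train_config(epochs = 2, batch_size = 4, augmentation = FALSE,
                       seed = 1)
  single <- grid_search(coh, cfg, base,
                        space = list(lr = 1e-3, batch = 4, wd = 0))
  expect_equal(nrow(single$log), 1)
  expect_equal(single$best$learning_rate, 1e-3)

  # a diverging candidate loses to a working one
  two <- grid_search(coh, cfg, base,
                     space = list(lr = c(1e30, 1e-3), batch = 4, wd = 0))
  expect_equal(two$best$learning_rate, 1e-3)

  # the full published grid enumerates 3 x 4 x 5 = 60 candidates
  grid <- expand.grid(lr = c(1e-3, 1e-4, 1e-5), batch = c(4, 8, 10, 12),
                      wd = c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(nrow(grid), 60)
})

test_that("divergence is reported with the epoch index", {
  coh <- tiny_cohort(n_hc = 2, n_ep = 2, dims = c(8, 8, 8), seed = 74)
  cfg <- model_config(c(8, 8, 8), conv_channels = c(2), heads = "EP")
  tc <- train_config(learning_rate = 1e300, batch_size = 4, epochs = 3,
                     augmentation = FALSE, seed = 1)
  expect_error(train_model(coh, cfg, tc), regexp = "epoch",
               class = "epcog_training_error")
})
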