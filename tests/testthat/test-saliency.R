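test_that("gradcam matches the closed-form oracle on a one-block toy", {
  m <- toy_saliency_model()
  vol <- random_volume(c(2, 2, 2), seed = 3)
  got <- gradcam(m, vol, target = list(head = "EP", class = 2), layer = 1)
  want <- toy_gradcam_oracle(m, vol, class = 2)
  expect_equal(array(got, c(2, 2, 2)), want, tolerance = 1e-6)
  expect_identical(dim(got), c(2L, 2L, 2L))
  expect_true(all(got >= 0))
  # the other class, too
  got1 <- gradcam(m, vol, target = list(head = "EP", class = 1), layer = 1)
  expect_equal(array(got1, c(2, 2, 2)), toy_gradcam_oracle(m, vol, 1),
               tolerance = 1e-6)
})

test_that("a constant logit yields an all-zero map", {
  m <- toy_saliency_model(w2 = matrix(0, 2, 2))
  vol <- random_volume(c(2, 2, 2), seed = 4)
  got <- gradcam(m, vol, target = list(head = "EP", class = 2), layer = 1)
  expect_true(all(got == 0))
  # and normalization leaves all-zero maps untouched
  expect_true(all(normalize_saliency(got) == 0))
})

test_that("saliency targets a logit, so shifting the other logit is inert", {
  m <- toy_saliency_model()
  vol <- random_volume(c(2, 2, 2), seed = 5)
  base <- gradcam(m, vol, target = list(head = "EP", class = 2), layer = 1)
  m2 <- m
  m2$params$ep.b2[1] <- m2$params$ep.b2[1] + 5 # non-target logit
  shifted <- gradcam(m2, vol, target = list(head = "EP", class = 2),
                     layer = 1)
  expect_equal(as.numeric(base), as.numeric(shifted), tolerance = 1e-12)
})

test_that("gradcam++ coincides with gradcam on a single-hot toy", {
  # conv responds only at one voxel: with one channel and one positive
  # activation the two weightings agree up to scale, hence after
  # max-normalization the maps are identical
  m <- toy_saliency_model()
  m$params$conv1.W <- matrix(0, 1, 54)
  m$params$conv1.W[1, 14] <- 1 # centre tap of channel 1
  m$params$conv1.b <- -0.85
  gm <- array(0.1, c(2, 2, 2)); gm[1, 1, 1] <- 1
  vol <- stack_channels(probability_map(gm, "GM"),
                        probability_map(array(0.1, c(2, 2, 2)), "WM"))
  g1 <- normalize_saliency(gradcam(m, vol, list(head = "EP", class = 2), 1))
  g2 <- normalize_saliency(gradcam_pp(m, vol, list(head = "EP", class = 2), 1))
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-9)
  expect_true(all(g2 >= 0))
})

test_that("gradcam++ departs from gradcam when channel activations differ", {
  # two single-tap channels firing at different voxels with different
  # magnitudes: the ++ weighting is nonlinear in the activation, so the
  # two normalized maps mix the channels in different proportions
  cfg <- model_config(c(2, 2, 2), conv_channels = c(2), head_hidden = 2,
                      heads = "EP", dropout = 0)
  m <- build_model(cfg, seed = 11)
  m$params$conv1.W <- matrix(0, 2, 54)
  m$params$conv1.W[1, 14] <- 1 # channel 1: centre tap on GM
  m$params$conv1.W[2, 41] <- 1 # channel 2: centre tap on WM
  m$params$conv1.b <- c(-0.5, -0.5)
  m$params$conv1.gamma <- c(1, 1); m$params$conv1.beta <- c(0, 0)
  m$running$conv1.mean <- c(0, 0); m$running$conv1.var <- c(1, 1)
  m$params$ep.W1 <- rbind(c(1, 0), c(0, 1))
  m$params$ep.b1 <- c(10, 10)
  m$params$ep.W2 <- rbind(c(0, 1), c(0, 0.5))
  m$params$ep.b2 <- c(0, 0)
  gm <- array(0.1, c(2, 2, 2)); gm[1, 1, 1] <- 1
  wm <- array(0.2, c(2, 2, 2)); wm[2, 2, 2] <- 0.9
  vol <- stack_channels(probability_map(gm, "GM"), probability_map(wm, "WM"))
  g1 <- normalize_saliency(gradcam(m, vol, list(head = "EP", class = 2), 1))
  g2 <- normalize_saliency(gradcam_pp(m, vol, list(head = "EP", class = 2), 1))
  expect_gt(max(abs(g1 - g2)), 1e-3)
})

test_that("cohort averaging normalizes first and checks compatibility", {
  m <- toy_saliency_model()
  v1 <- random_volume(c(2, 2, 2), seed = 21)
  v2 <- random_volume(c(2, 2, 2), seed = 22)
  s1 <- gradcam(m, v1, list(head = "EP", class = 2), 1)
  s2 <- gradcam(m, v2, list(head = "EP", class = 2), 1)
  avg1 <- average_saliency(list(s1))
  expect_equal(as.numeric(avg1), as.numeric(normalize_saliency(s1)))
  same <- average_saliency(list(s1, s1))
  expect_equal(as.numeric(same), as.numeric(normalize_saliency(s1)),
               tolerance = 1e-12)
  both <- average_saliency(list(s1, s2))
  expect_true(max(both) <= 1 + 1e-12)
  s_other <- gradcam(m, v1, list(head = "EP", class = 1), 1)
  expect_error(average_saliency(list(s1, s_other)),
               class = "epcog_argument_error")
})

test_that("maps export as NIfTI next to their reference volume", {
  m <- toy_saliency_model()
  vol <- random_volume(c(2, 2, 2), seed = 31)
  s <- gradcam(m, vol, list(head = "EP", class = 2), 1)
  path <- tempfile(fileext = ".nii.gz")
  export_saliency(s, vol, path)
  back <- RNifti::readNifti(path)
  expect_equal(as.numeric(back), as.numeric(s / max(max(s), 1)),
               tolerance = 1e-6)
  wrong <- array(0, c(4, 4, 4))
  expect_error(export_saliency(s, wrong, path), class = "epcog_shape_error")
  expect_error(gradcam(m, vol, target = list(head = "CLR"), layer = 1),
               class = "epcog_argument_error")
})

test_that("dice of top voxels behaves at the extremes", {
  map <- structure(array(runif(64), c(4, 4, 4)),
                   class = c("saliency_map", "array"))
  all_region <- array(TRUE, c(4, 4, 4))
  expect_gt(saliency_dice(map, all_region, 0.25), 0)
  none <- array(FALSE, c(4, 4, 4))
  expect_equal(saliency_dice(map, none, 0.25), 0)
})
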