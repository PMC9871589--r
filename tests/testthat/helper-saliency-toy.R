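# A hand-parameterized one-conv-block model whose GradCam map can be
# computed in closed form: known conv weights, identity-like batch norm
# (running mean 0, var 1), all-active hidden units in the EP head.
toy_saliency_model <- function(seed = 7, w2 = NULL) {
  cfg <- model_config(c(2, 2, 2), conv_channels = c(1), head_hidden = 2,
                      heads = "EP", dropout = 0)
  m <- build_model(cfg, seed = seed)
  set.seed(seed)
  m$params$conv1.W <- matrix(rnorm(54, 0, 0.3), 1, 54)
  m$params$conv1.b <- 0.05
  m$params$conv1.gamma <- 1
  m$params$conv1.beta <- 0
  m$running$conv1.mean <- 0
  m$running$conv1.var <- 1
  m$params$ep.W1 <- matrix(c(0.6, -0.4), 1, 2)
  m$params$ep.b1 <- c(10, 10) # keep both hidden units active
  m$params$ep.W2 <- w2 %||% matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  m$params$ep.b2 <- c(0, 0)
  m
}

toy_gradcam_oracle <- function(m, vol, class = 2) {
  # activation: BN(running 0/1) then ReLU of the direct convolution
  conv <- oracle_conv3(vol, m$params$conv1.W, m$params$conv1.b)[, , , 1]
  act <- pmax(conv / sqrt(1 + 1e-5), 0)
  # logit gradient w.r.t. the activation: through GAP of the pooled 1^3
  # map, gradient lands on the argmax voxel only
  dfeat <- sum(m$params$ep.W2[, class] * m$params$ep.W1[1, ])
  grad <- array(0, dim(act))
  grad[which.max(act)] <- dfeat
  w <- mean(grad)
  pmax(act * w, 0)
}

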