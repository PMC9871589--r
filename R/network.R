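#' Configure the multi-task 3D convolutional network
#'
#' The encoder is a sequence of blocks, one per entry of `conv_channels`:
#' 3D convolution (kernel 3, stride 1, padding 1), batch normalization,
#' rectifier, 2x max-pool. Global average pooling turns the last block's
#' feature maps into one feature vector per subject, which feeds up to
#' three independent MLP subbranches: `EP` (diagnosis logits, always
#' enabled), `CLC` (one n-way softmax group per cognition dimension) and
#' `CLR` (one regression output per dimension, in standardized score
#' units). An optional orthogonal gender embedding is concatenated to the
#' feature vector before the heads.
#'
#' Each pooling stage halves the grid, so the input dims must be divisible
#' by `2^length(conv_channels)`. With `pad_input = TRUE` (default) inputs
#' are zero-padded up to the next compatible grid — e.g. a 120^3 volume
#' with four blocks is padded to 128^3; with `pad_input = FALSE` a
#' non-divisible input is a configuration error naming the smallest
#' compatible padded dims.
#'
#' @param input_dims (H, W, D) of the incoming volumes.
#' @param conv_channels output channels of each conv block.
#' @param head_hidden hidden width of each MLP subbranch.
#' @param n_categories category count n for the CLC head (>= 2).
#' @param heads subset of `c("EP", "CLC", "CLR")`; `EP` is mandatory.
#' @param clc_dimensions cognition dimensions covered by the CLC/CLR heads
#'   (default: all six jointly).
#' @param use_gender_embedding concatenate a 2-d orthogonal gender code to
#'   the encoder features.
#' @param dropout dropout rate inside the MLP heads during training.
#' @param pad_input zero-pad inputs up to pooling-compatible dims.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @return a `model_config` list.
#' @export
model_config <- function(input_dims,
                         conv_channels = c(16, 32, 64, 128),
                         head_hidden = 64,
                         n_categories = 2,
                         heads = c("EP", "CLC", "CLR"),
                         clc_dimensions = COG_DIMS,
                         use_gender_embedding = FALSE,
                         dropout = 0.2,
                         pad_input = TRUE,
                         bn_momentum = 0.1) {
  input_dims <- as.integer(input_dims)
  stopifnot(length(input_dims) == 3L, all(input_dims >= 1L))
  heads <- unique(match.arg(heads, c("EP", "CLC", "CLR"), several.ok = TRUE))
  if (!"EP" %in% heads) {
    abort("the EP head is always enabled", class = "epcog_config_error")
  }
  if ("CLC" %in% heads && n_categories < 2) {
    abort("`n_categories` must be >= 2 when CLC is enabled",
          class = "epcog_config_error")
  }
  L <- length(conv_channels)
  div <- 2L^L
  pad_dims <- as.integer(ceiling(input_dims / div) * div)
  if (!identical(pad_dims, input_dims) && !pad_input) {
    abort(sprintf(paste0("input dims (%s) are not divisible by 2^%d blocks; ",
                         "pad to (%s) or enable `pad_input`"),
                  paste(input_dims, collapse = "x"), L,
                  paste(pad_dims, collapse = "x")),
          class = "epcog_config_error")
  }
  structure(list(
    input_dims = input_dims, pad_dims = pad_dims,
    conv_channels = as.integer(conv_channels),
    head_hidden = as.integer(head_hidden),
    n_categories = as.integer(n_categories), heads = heads,
    clc_dimensions = clc_dimensions,
    use_gender_embedding = isTRUE(use_gender_embedding),
    dropout = dropout, bn_momentum = bn_momentum,
    feature_dim = as.integer(conv_channels[L]) +
      2L * isTRUE(use_gender_embedding)
  ), class = "model_config")
}

#' Orthogonal gender embedding
#'
#' `male -> (1, 0)`, `female -> (0, 1)`: unit-norm, mutually orthogonal
#' codes concatenated to the encoder feature vector when enabled.
#'
#' @param gender character/factor vector of `"male"`/`"female"`.
#' @return numeric matrix with 2 columns, one row per subject.
#' @export
encode_gender <- function(gender) {
  g <- as.character(gender)
  if (!all(g %in% c("male", "female"))) {
    abort("gender must be 'male' or 'female'", class = "epcog_argument_error")
  }
  cbind(as.numeric(g == "male"), as.numeric(g == "female"))
}

head_out_dim <- function(config, head) {
  switch(head,
         EP = 2L,
         CLC = length(config$clc_dimensions) * config$n_categories,
         CLR = length(config$clc_dimensions))
}

#' Build a model with deterministic initial parameters
#'
#' He-scaled normal initialization for weights, zeros for biases, unit
#' gain / zero shift for batch-norm; identical seeds give bit-identical
#' parameters.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return an `epcog_model`: list of `config`, flat `params`, batch-norm
#'   `running` statistics.
#' @export
build_model <- function(config, seed = 1) {
  with_seed(seed, {
    params <- list()
    running <- list()
    c_in <- 2L
    for (i in seq_along(config$conv_channels)) {
      c_out <- config$conv_channels[i]
      fan_in <- 27 * c_in
      params[[paste0("conv", i, ".W")]] <-
        matrix(rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)), c_out, fan_in)
      params[[paste0("conv", i, ".b")]] <- numeric(c_out)
      params[[paste0("conv", i, ".gamma")]] <- rep(1, c_out)
      params[[paste0("conv", i, ".beta")]] <- numeric(c_out)
      running[[paste0("conv", i, ".mean")]] <- numeric(c_out)
      running[[paste0("conv", i, ".var")]] <- rep(1, c_out)
      c_in <- c_out
    }
    fdim <- config$feature_dim
    for (h in config$heads) {
      hd <- config$head_hidden
      od <- head_out_dim(config, h)
      key <- tolower(h)
      params[[paste0(key, ".W1")]] <-
        matrix(rnorm(fdim * hd, 0, sqrt(2 / fdim)), fdim, hd)
      params[[paste0(key, ".b1")]] <- numeric(hd)
      params[[paste0(key, ".W2")]] <-
        matrix(rnorm(hd * od, 0, sqrt(2 / hd)), hd, od)
      params[[paste0(key, ".b2")]] <- numeric(od)
    }
    structure(list(config = config, params = params, running = running),
              class = "epcog_model")
  })
}

#' @export
print.epcog_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<epcog_model  input %s (padded %s)  blocks [%s]  heads {%s}  %d parameters>\n",
              paste(cfg$input_dims, collapse = "x"),
              paste(cfg$pad_dims, collapse = "x"),
              paste(cfg$conv_channels, collapse = ","),
              paste(cfg$heads, collapse = ", "),
              n_parameters(x)))
  invisible(x)
}

#' Trainable parameter count
#' @param model an `epcog_model`.
#' @return integer total; per-tensor breakdown in attribute `"by_tensor"`.
#' @export
n_parameters <- function(model) {
  by_tensor <- vapply(model$params, length, integer(1))
  structure(sum(by_tensor), by_tensor = by_tensor)
}

# centre-pad each volume of a list to pad_dims and stack into (V, C, N)
make_batch <- function(volumes, pad_dims) {
  n <- length(volumes)
  V <- prod(pad_dims)
  out <- array(0, c(V, 2L, n))
  for (i in seq_len(n)) {
    v <- volumes[[i]]
    dm <- dim(v)[1:3]
    if (any(dm > pad_dims)) {
      abort(sprintf("volume dims (%s) exceed model input dims (%s)",
                    paste(dm, collapse = "x"), paste(pad_dims, collapse = "x")),
            class = "epcog_shape_error")
    }
    off <- (pad_dims - dm) %/% 2L
    pad <- array(0, c(pad_dims, 2L))
    pad[off[1] + seq_len(dm[1]), off[2] + seq_len(dm[2]),
        off[3] + seq_len(dm[3]), ] <- v
    out[, , i] <- pad
  }
  out
}

BN_EPS <- 1e-5

# Forward pass over a (V, 2, N) batch. Returns logits per enabled head and
# (optionally) the full cache needed for backpropagation / saliency.
forward_pass <- function(model, x, gender = NULL, training = FALSE,
                         keep_cache = FALSE, update_running = FALSE,
                         drop_masks = NULL) {
  cfg <- model$config
  p <- model$params
  if (cfg$use_gender_embedding && is.null(gender)) {
    abort("this model expects gender input", class = "epcog_argument_error")
  }
  if (!cfg$use_gender_embedding && !is.null(gender)) gender <- NULL
  dims <- cfg$pad_dims
  n <- dim(x)[3]
  caches <- list()
  for (i in seq_along(cfg$conv_channels)) {
    W <- p[[paste0("conv", i, ".W")]]
    conv <- cpp_conv3d_forward(x, dims[1], dims[2], dims[3], W,
                               p[[paste0("conv", i, ".b")]])
    if (training) {
      mom <- cpp_channel_moments(conv)
      mu <- as.numeric(mom$mean)
      vr <- as.numeric(mom$var)
      if (update_running) {
        m <- cfg$bn_momentum
        key_m <- paste0("conv", i, ".mean")
        key_v <- paste0("conv", i, ".var")
        model$running[[key_m]] <- (1 - m) * model$running[[key_m]] + m * mu
        model$running[[key_v]] <- (1 - m) * model$running[[key_v]] + m * vr
      }
    } else {
      mu <- model$running[[paste0("conv", i, ".mean")]]
      vr <- model$running[[paste0("conv", i, ".var")]]
    }
    bn <- cpp_bn_relu_forward(conv, mu, vr,
                              p[[paste0("conv", i, ".gamma")]],
                              p[[paste0("conv", i, ".beta")]], BN_EPS)
    act <- bn$act
    pool <- cpp_maxpool3d(act, dims[1], dims[2], dims[3])
    if (keep_cache) {
      caches[[i]] <- list(x = x, mu = mu, var = vr, xhat = bn$xhat,
                          act = act, argmax = pool$argmax, dims = dims)
    }
    x <- pool$out
    dims <- dims %/% 2L
  }
  # global average pooling: one feature per channel per subject
  Vl <- dim(x)[1]
  feat <- t(apply(x, 3, colMeans))
  if (dim(x)[2] == 1L) feat <- matrix(feat, ncol = 1L)
  if (cfg$use_gender_embedding) feat <- cbind(feat, encode_gender(gender))
  out <- list()
  head_cache <- list()
  for (h in cfg$heads) {
    key <- tolower(h)
    pre <- sweep(feat %*% p[[paste0(key, ".W1")]], 2,
                 p[[paste0(key, ".b1")]], "+")
    hid <- pmax(pre, 0)
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- drop_masks[[key]] %||%
        matrix(runif(length(hid)) >= cfg$dropout, nrow(hid), ncol(hid))
      hid <- hid * mask / (1 - cfg$dropout)
    }
    logits <- sweep(hid %*% p[[paste0(key, ".W2")]], 2,
                    p[[paste0(key, ".b2")]], "+")
    out[[key]] <- logits
    if (keep_cache) head_cache[[key]] <- list(pre = pre, hid = hid, mask = mask)
  }
  res <- list(ep_logits = out$ep, clc_logits = out$clc, clr_values = out$clr,
              feat = feat, n = n, training = training)
  if (keep_cache) {
    res$caches <- caches
    res$head_cache <- head_cache
    res$gap_in_dim <- c(Vl, dim(x)[2])
  }
  if (update_running) res$running <- model$running
  res
}

# Backward pass: head-output gradients -> parameter gradients (flat list
# matching model$params) and, when `stop_at_layer` is set, the gradient at
# that block's post-ReLU activation (the GradCam target).
backward_pass <- function(model, fwd, d_heads, stop_at_layer = NULL,
                          need_dx = FALSE) {
  cfg <- model$config
  p <- model$params
  grads <- lapply(p, function(z) array(0, dim(z) %||% length(z)))
  feat <- fwd$feat
  n <- fwd$n
  dfeat <- matrix(0, nrow(feat), ncol(feat))
  for (h in cfg$heads) {
    key <- tolower(h)
    dout <- d_heads[[key]]
    if (is.null(dout)) next
    hc <- fwd$head_cache[[key]]
    grads[[paste0(key, ".W2")]] <- t(hc$hid) %*% dout
    grads[[paste0(key, ".b2")]] <- colSums(dout)
    dhid <- dout %*% t(p[[paste0(key, ".W2")]])
    if (!is.null(hc$mask)) dhid <- dhid * hc$mask / (1 - cfg$dropout)
    dpre <- dhid * (hc$pre > 0)
    grads[[paste0(key, ".W1")]] <- t(feat) %*% dpre
    grads[[paste0(key, ".b1")]] <- colSums(dpre)
    dfeat <- dfeat + dpre %*% t(p[[paste0(key, ".W1")]])
  }
  if (cfg$use_gender_embedding) {
    dfeat <- dfeat[, seq_len(ncol(dfeat) - 2L), drop = FALSE]
  }
  # GAP backward
  Vl <- fwd$gap_in_dim[1]
  Cl <- fwd$gap_in_dim[2]
  dx <- array(0, c(Vl, Cl, n))
  for (i in seq_len(n)) {
    dx[, , i] <- matrix(dfeat[i, ] / Vl, Vl, Cl, byrow = TRUE)
  }
  layer_grad <- NULL
  for (i in rev(seq_along(cfg$conv_channels))) {
    cache <- caches_i <- fwd$caches[[i]]
    dims <- cache$dims
    V <- prod(dims)
    C <- dim(cache$act)[2]
    dact <- cpp_maxpool3d_backward(dx, cache$argmax, V, C, n)
    if (!is.null(stop_at_layer) && stop_at_layer == i) {
      layer_grad <- dact
    }
    bnb <- cpp_bn_relu_backward(dact, cache$act, cache$xhat, cache$var,
                                p[[paste0("conv", i, ".gamma")]], BN_EPS,
                                isTRUE(fwd$training))
    dconv <- bnb$dx
    grads[[paste0("conv", i, ".gamma")]] <- as.numeric(bnb$dgamma)
    grads[[paste0("conv", i, ".beta")]] <- as.numeric(bnb$dbeta)
    want_dx <- (i > 1) || need_dx
    cb <- cpp_conv3d_backward(cache$x, dconv, dims[1], dims[2], dims[3],
                              p[[paste0("conv", i, ".W")]], want_dx)
    grads[[paste0("conv", i, ".W")]] <- cb$dW
    grads[[paste0("conv", i, ".b")]] <- as.numeric(cb$db)
    if (want_dx) dx <- cb$dx
    if (!is.null(stop_at_layer) && stop_at_layer == i) break
  }
  list(grads = grads, layer_grad = layer_grad,
       dx = if (need_dx) dx else NULL)
}

#' Run the network on a batch of input volumes
#'
#' Inference mode: batch-norm uses running statistics and dropout is off,
#' so identical inputs give identical outputs. All enabled heads are
#' computed from the same encoder feature vector.
#'
#' @param model a trained (or freshly built) `epcog_model`.
#' @param volumes list of `multichannel_volume` arrays.
#' @param gender optional gender vector (required iff the model uses the
#'   gender embedding).
#' @param batch_size inference chunk size.
#' @return list with `ep_logits` (n x 2), `ep_prob` (positive-class
#'   probability), `clc_logits` (n x dims x categories array, if enabled),
#'   `clc_class` (n x dims category matrix), `clr_values` (n x dims, in
#'   standardized units).
#' @export
forward <- function(model, volumes, gender = NULL, batch_size = 16L) {
  cfg <- model$config
  n <- length(volumes)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  ep <- NULL; clc <- NULL; clr <- NULL
  for (idx in chunks) {
    x <- make_batch(volumes[idx], cfg$pad_dims)
    fw <- forward_pass(model, x, gender = gender[idx], training = FALSE)
    ep <- rbind(ep, fw$ep_logits)
    if (!is.null(fw$clc_logits)) clc <- rbind(clc, fw$clc_logits)
    if (!is.null(fw$clr_values)) clr <- rbind(clr, fw$clr_values)
  }
  out <- list(ep_logits = ep, ep_prob = softmax_rows(ep)[, 2])
  if (!is.null(clc)) {
    nd <- length(cfg$clc_dimensions)
    arr <- array(clc, c(nrow(clc), cfg$n_categories, nd))
    arr <- aperm(arr, c(1, 3, 2)) # n x dims x categories
    dimnames(arr) <- list(NULL, cfg$clc_dimensions, NULL)
    out$clc_logits <- arr
    out$clc_class <- apply(arr, c(1, 2), which.max)
  }
  if (!is.null(clr)) {
    colnames(clr) <- cfg$clc_dimensions
    out$clr_values <- clr
  }
  out
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}
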