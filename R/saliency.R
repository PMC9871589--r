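#' GradCam attention volume
#'
#' Explains a head's pre-softmax logit (the standard class-activation
#' target) with respect to a conv block's post-rectifier activation:
#' channel weights are the spatially averaged gradients, the map is the
#' rectified weighted activation sum, trilinearly upsampled to the input
#' grid and cropped back to the un-padded dims.
#'
#' @param model a trained `epcog_model`.
#' @param volume one `multichannel_volume`.
#' @param target list with `head` (`"EP"`, `"CLC"`, `"CLR"`), `class`
#'   (logit index within the head, e.g. 2 = EP class), and for the
#'   cognition heads `dimension` (name). Default: the EP class logit.
#' @param layer conv block index (default: last).
#' @param gender gender string if the model embeds gender.
#' @return a `saliency_map`: non-negative 3D array (input spatial dims)
#'   with attributes `target`, `layer`, `normalized`.
#' @export
gradcam <- function(model, volume, target = list(head = "EP", class = 2),
                    layer = NULL, gender = NULL) {
  gc <- saliency_internals(model, volume, target, layer, gender)
  w <- colMeans(gc$grad) # spatially averaged gradient per channel
  map <- pmax(as.numeric(gc$act %*% w), 0)
  finish_saliency(map, gc, target)
}

#' GradCam++ attention volume
#'
#' As [gradcam()], but with the pixel-wise second/third-order weighting of
#' the GradCam++ formulation replacing the global gradient average:
#' `alpha = g^2 / (2 g^2 + sum(A g^3))` per voxel and channel, and channel
#' weights `w_k = sum(alpha * relu(g))`.
#'
#' @inheritParams gradcam
#' @return a `saliency_map`.
#' @export
gradcam_pp <- function(model, volume, target = list(head = "EP", class = 2),
                       layer = NULL, gender = NULL) {
  gc <- saliency_internals(model, volume, target, layer, gender)
  A <- gc$act
  g <- gc$grad
  w <- vapply(seq_len(ncol(A)), function(ch) {
    gk <- g[, ch]
    denom <- 2 * gk^2 + sum(A[, ch] * gk^3)
    alpha <- ifelse(abs(denom) > 1e-12, gk^2 / denom, 0)
    sum(alpha * pmax(gk, 0))
  }, numeric(1))
  map <- pmax(as.numeric(A %*% w), 0)
  finish_saliency(map, gc, target)
}

# shared forward + logit-gradient plumbing for both saliency variants
saliency_internals <- function(model, volume, target, layer, gender) {
  cfg <- model$config
  layer <- layer %||% length(cfg$conv_channels)
  if (layer < 1 || layer > length(cfg$conv_channels)) {
    abort("invalid conv block index", class = "epcog_argument_error")
  }
  head <- match.arg(target$head, c("EP", "CLC", "CLR"))
  if (!head %in% cfg$heads) {
    abort(sprintf("head %s is not enabled in this model", head),
          class = "epcog_argument_error")
  }
  x <- make_batch(list(volume), cfg$pad_dims)
  fw <- forward_pass(model, x, gender = gender, training = FALSE,
                     keep_cache = TRUE)
  key <- tolower(head)
  od <- head_out_dim(cfg, head)
  sel <- matrix(0, 1, od)
  col <- if (head == "EP") {
    target$class %||% 2
  } else {
    d <- match(target$dimension %||% cfg$clc_dimensions[1], cfg$clc_dimensions)
    if (is.na(d)) abort("unknown cognition dimension", class = "epcog_key_error")
    if (head == "CLC") (d - 1) * cfg$n_categories + (target$class %||% 1) else d
  }
  sel[1, col] <- 1
  d_heads <- setNames(list(sel), key)
  bw <- backward_pass(model, fw, d_heads, stop_at_layer = layer)
  cache_act <- fw$caches[[layer]]$act # post-ReLU, pre-pool activation
  C <- dim(cache_act)[2]
  act <- matrix(cache_act[, , 1], ncol = C)
  grad <- matrix(bw$layer_grad[, , 1], ncol = C)
  list(act = act, grad = grad, dims = fw$caches[[layer]]$dims,
       input_dims = cfg$input_dims, pad_dims = cfg$pad_dims, layer = layer)
}

finish_saliency <- function(map, gc, target) {
  up <- cpp_resample_trilinear(map, gc$dims, gc$pad_dims)
  off <- (gc$pad_dims - gc$input_dims) %/% 2L
  out <- array(up, gc$pad_dims)[off[1] + seq_len(gc$input_dims[1]),
                                off[2] + seq_len(gc$input_dims[2]),
                                off[3] + seq_len(gc$input_dims[3]),
                                drop = FALSE]
  out <- pmax(array(out, gc$input_dims), 0)
  structure(out, class = c("saliency_map", "array"), target = target,
            layer = gc$layer, normalized = FALSE)
}

#' @export
print.saliency_map <- function(x, ...) {
  t <- attr(x, "target")
  cat(sprintf("<saliency_map %s  head %s  layer %d  max %.4g%s>\n",
              paste(dim(x), collapse = "x"), t$head, attr(x, "layer"),
              max(x), if (attr(x, "normalized")) "  (normalized)" else ""))
  invisible(x)
}

#' Normalize a saliency map to unit maximum
#'
#' All-zero maps stay all-zero.
#' @param map a `saliency_map`.
#' @return the normalized map.
#' @export
normalize_saliency <- function(map) {
  m <- max(map)
  out <- if (m > 0) map / m else map
  attr(out, "normalized") <- TRUE
  out
}

#' Cohort-average saliency
#'
#' Voxel-wise mean of per-subject max-normalized maps (normalizing first
#' prevents any one subject from dominating the average).
#'
#' @param maps list of `saliency_map`s with identical dims and target.
#' @return a `saliency_map`.
#' @export
average_saliency <- function(maps) {
  if (length(maps) == 0) {
    abort("no maps supplied", class = "epcog_argument_error")
  }
  t0 <- attr(maps[[1]], "target")
  d0 <- dim(maps[[1]])
  for (m in maps[-1]) {
    if (!identical(dim(m), d0) || !identical(attr(m, "target"), t0)) {
      abort("maps must share dims and target", class = "epcog_argument_error")
    }
  }
  acc <- array(0, d0)
  for (m in maps) acc <- acc + normalize_saliency(m)
  structure(acc / length(maps), class = c("saliency_map", "array"),
            target = t0, layer = attr(maps[[1]], "layer"), normalized = TRUE)
}

#' Export a saliency map as NIfTI next to its reference volume
#'
#' @param map a `saliency_map`.
#' @param reference the input volume it explains (affine source).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
export_saliency <- function(map, reference, path) {
  ref_dims <- dim(reference)[1:3]
  if (!identical(dim(map), as.integer(ref_dims))) {
    abort(sprintf("map dims (%s) do not match reference (%s)",
                  paste(dim(map), collapse = "x"),
                  paste(ref_dims, collapse = "x")),
          class = "epcog_shape_error")
  }
  write_probability_map(array(map / max(max(map), 1), dim(map)), path,
                        affine = attr(reference, "affine") %||% diag(4))
  invisible(path)
}

#' Overlap between the hottest saliency voxels and a reference region
#'
#' Dice coefficient between the top-`fraction` voxels of the map and a
#' logical region mask — the saliency-recovery statistic for implanted
#' synthetic effects.
#'
#' @param map a `saliency_map`.
#' @param region logical array of the reference region.
#' @param fraction top fraction of voxels (default 0.01).
#' @return scalar Dice in \[0, 1\].
#' @export
saliency_dice <- function(map, region, fraction = 0.01) {
  stopifnot(identical(dim(map), dim(region)))
  k <- max(1L, round(length(map) * fraction))
  thr <- sort(as.numeric(map), decreasing = TRUE)[k]
  top <- map >= thr
  2 * sum(top & region) / (sum(top) + sum(region))
}
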