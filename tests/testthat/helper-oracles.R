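# Independent brute-force oracles. These deliberately use naive loops and
# direct formula transcription so they share no code path with the
# implementation they check.

# trilinear interpolation at voxel centres, axes rescaled independently,
# border values extended outward
oracle_trilinear <- function(src, tgt_dims) {
  sd <- dim(src)
  out <- array(0, tgt_dims)
  for (d in seq_len(tgt_dims[3])) {
    for (w in seq_len(tgt_dims[2])) {
      for (h in seq_len(tgt_dims[1])) {
        # 0-based target centre mapped into source coordinates
        s <- (c(h, w, d) - 0.5) * sd / tgt_dims - 0.5
        s <- pmin(pmax(s, 0), sd - 1)
        f0 <- floor(s)
        fr <- s - f0
        acc <- 0
        for (od in 0:1) for (ow in 0:1) for (oh in 0:1) {
          idx <- pmin(f0 + c(oh, ow, od), sd - 1) + 1
          wgt <- prod(ifelse(c(oh, ow, od) == 1, fr, 1 - fr))
          acc <- acc + wgt * src[idx[1], idx[2], idx[3]]
        }
        out[h, w, d] <- acc
      }
    }
  }
  out
}

# linear-scan equal-width binner: largest k with score >= edges[k]
oracle_bin <- function(score, edges) {
  n <- length(edges) - 1L
  k <- 1L
  for (j in seq_len(n + 1L)) {
    if (score >= edges[j]) k <- j
  }
  min(k, n)
}

# pair-counting AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "EP"]
  neg <- scores[labels == "HC"]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# direct transcription of the printed metric formulas
oracle_confusion <- function(truth, pred) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "EP" && pred[i] == "EP") tp <- tp + 1
    if (truth[i] == "HC" && pred[i] == "EP") fp <- fp + 1
    if (truth[i] == "HC" && pred[i] == "HC") tn <- tn + 1
    if (truth[i] == "EP" && pred[i] == "HC") fn <- fn + 1
  }
  c(acc = (tp + tn) / (tp + fp + tn + fn),
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    spe = if (fp + tn > 0) tn / (fp + tn) else NA_real_)
}

oracle_mae <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i])
  s / length(y)
}

oracle_r2 <- function(y, yhat) {
  yb <- mean(y)
  ss_res <- 0; ss_tot <- 0
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - yb)^2
  }
  if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
}

# direct per-voxel 3D convolution (kernel 3, stride 1, zero padding 1)
# weight layout: Cout x (27 * Cin), kernel offsets fastest (dh, dw, dd)
oracle_conv3 <- function(x, weight, bias) {
  dm <- dim(x)[1:3]
  cin <- dim(x)[4]
  cout <- nrow(weight)
  out <- array(0, c(dm, cout))
  for (co in seq_len(cout)) {
    for (d in seq_len(dm[3])) for (w in seq_len(dm[2])) for (h in seq_len(dm[1])) {
      acc <- bias[co]
      for (ci in seq_len(cin)) {
        for (dd in -1:1) for (dw in -1:1) for (dh in -1:1) {
          sh <- h + dh; sw <- w + dw; sd <- d + dd
          if (sh < 1 || sh > dm[1] || sw < 1 || sw > dm[2] ||
              sd < 1 || sd > dm[3]) next
          r <- (ci - 1) * 27 + (dh + 2) + 3 * (dw + 1) + 9 * (dd + 1)
          acc <- acc + weight[co, r] * x[sh, sw, sd, ci]
        }
      }
      out[h, w, d, co] <- acc
    }
  }
  out
}

# small volume-free cohort for metadata-level tests
meta_cohort_77 <- function(seed = 1) {
  cfg <- simulation_config(seed = seed)
  simulate_cohort(cfg, include_volumes = FALSE)
}

# tiny imaging cohort for pipeline tests (no missing scores by default)
tiny_cohort <- function(n_hc = 6, n_ep = 6, dims = c(8, 8, 8),
                        effect_size = 3, seed = 1, ...) {
  cfg <- simulation_config(n_hc = n_hc, n_ep = n_ep, dims = dims,
                           n_blobs = 5, effect_size = effect_size,
                           noise_sd = 0.05, seed = seed,
                           missing_counts = setNames(rep(0, 6),
                             c("psp", "vig", "wme", "vel", "vil", "pso")),
                           ...)
  simulate_cohort(cfg)
}

random_volume <- function(dims = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  stack_channels(probability_map(array(runif(prod(dims)), dims), "GM"),
                 probability_map(array(runif(prod(dims)), dims), "WM"))
}
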