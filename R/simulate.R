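#' Simulation configuration for synthetic cohorts
#'
#' The generator emulates the statistical structure of the clinical cohort
#' the model was designed for: 39 healthy controls and 38 early-psychosis
#' patients, a 62/15 male/female split, cognition scores whose per-group
#' means and SDs match the published cohort table, the published
#' missing-entry counts (at most one missing dimension per subject), and a
#' diagnosis-linked gray-matter reduction concentrated in a subset of
#' template regions. Imaging is a smooth Gaussian-blob phantom, not
#' anatomy; see the methods vignette for what that does and does not test.
#'
#' A latent per-patient severity (standard normal truncated to \[-3, 3\])
#' drives both the imaging effect and the cognition deficit, so the
#' auxiliary cognition tasks genuinely share signal with the diagnosis.
#' The per-voxel GM reduction fraction is
#' `effect_size * noise_sd * exp(severity / 4)` inside the effect region:
#' `effect_size` is therefore a Cohen's-d-like contrast in units of the
#' voxel noise SD. Cognition dimension d of a patient with severity z is
#' `mean_EP(d) + slope(d) * z * sd_EP(d) + noise`, with the noise SD shrunk
#' by `sqrt(1 - slope^2 * Var(z))` so group sample moments converge to the
#' calibration targets as n grows.
#'
#' @param n_hc,n_ep group sizes.
#' @param dims volume grid (H, W, D).
#' @param n_blobs Gaussian basis blobs in the GM template.
#' @param effect_regions indices of blobs carrying the diagnosis effect.
#' @param effect_size standardized GM reduction (>= 0, unitless).
#' @param noise_sd i.i.d. voxel noise SD.
#' @param cognition_calibration data frame `dimension, hc_mean, hc_sd,
#'   ep_mean, ep_sd`; defaults to the published cohort table.
#' @param severity_cognition_slope named per-dimension loading of latent
#'   severity on scores (negative = deficit grows with severity); defaults
#'   load processing speed, verbal and visual learning most strongly, the
#'   three dimensions with significant published group differences.
#' @param missing_counts named per-dimension missing-entry counts.
#' @param gender_counts,ethnicity_counts per-group category counts, lists
#'   with `hc` and `ep` integer vectors; `NULL` = published counts when the
#'   group sizes are the published ones, otherwise proportional.
#' @param age_calibration data frame of group mean/SD plus range bounds.
#' @param seed integer master seed; everything downstream is deterministic
#'   given it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_hc = 39, n_ep = 38,
                              dims = c(32, 32, 32),
                              n_blobs = 12,
                              effect_regions = 1,
                              effect_size = 1,
                              noise_sd = 0.05,
                              cognition_calibration = NULL,
                              severity_cognition_slope = NULL,
                              missing_counts = NULL,
                              gender_counts = NULL,
                              ethnicity_counts = NULL,
                              age_calibration = NULL,
                              seed = 1) {
  stopifnot(n_hc >= 0, n_ep >= 0, effect_size >= 0, noise_sd >= 0,
            all(dims >= 1))
  cal <- cognition_calibration %||% data.frame(
    dimension = COG_DIMS,
    hc_mean = c(55.00, 51.16, 50.00, 53.81, 51.31, 57.15),
    hc_sd   = c(9.54, 5.50, 6.79, 6.91, 7.54, 4.57),
    ep_mean = c(38.23, 42.88, 49.35, 44.54, 44.27, 49.42),
    ep_sd   = c(10.51, 12.70, 9.77, 7.37, 9.30, 9.22)
  )
  slope <- severity_cognition_slope %||%
    c(psp = -0.6, vig = -0.3, wme = -0.2, vel = -0.6, vil = -0.5, pso = -0.3)
  miss <- missing_counts %||%
    c(psp = 5, vig = 3, wme = 4, vel = 1, vil = 1, pso = 1)
  prop_counts <- function(n, ref) {
    # largest-remainder split of n in the reference proportions
    raw <- n * ref / sum(ref)
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      up <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[up] <- base[up] + 1
    }
    as.integer(base)
  }
  gc <- gender_counts %||% list(hc = prop_counts(n_hc, c(31, 8)),
                                ep = prop_counts(n_ep, c(31, 7)))
  ec <- ethnicity_counts %||% list(hc = prop_counts(n_hc, c(28, 11)),
                                   ep = prop_counts(n_ep, c(28, 10)))
  if (sum(gc$hc) != n_hc || sum(gc$ep) != n_ep) {
    abort("gender_counts must sum to the group sizes", class = "epcog_config_error")
  }
  age <- age_calibration %||% data.frame(
    group = c("HC", "EP"), mean = c(24.54, 24.29), sd = c(5.35, 4.23),
    min = 16.22, max = 43.69
  )
  if (sum(miss) > n_hc + n_ep) {
    abort("more missing entries than subjects can carry at one each",
          class = "epcog_config_error")
  }
  structure(list(
    n_hc = n_hc, n_ep = n_ep, dims = as.integer(dims), n_blobs = n_blobs,
    effect_regions = effect_regions, effect_size = effect_size,
    noise_sd = noise_sd, cognition_calibration = cal,
    severity_cognition_slope = slope, missing_counts = miss,
    gender_counts = gc, ethnicity_counts = ec, age_calibration = age,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# variance of a standard normal truncated to [-a, a]
trunc_norm_var <- function(a = 3) {
  1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)
}

rtrunc_norm <- function(n, a = 3) {
  lo <- stats::pnorm(-a)
  stats::qnorm(lo + stats::runif(n) * (1 - 2 * lo))
}

gaussian_blob <- function(dims, centre, sigma) {
  g1 <- function(n, c, s) exp(-((seq_len(n) - c)^2) / (2 * s^2))
  outer(outer(g1(dims[1], centre[1], sigma),
              g1(dims[2], centre[2], sigma)),
        g1(dims[3], centre[3], sigma))
}

#' Build the GM/WM template pair for a synthetic cohort
#'
#' The GM template is a sum of `n_blobs` 3D Gaussians rescaled into
#' \[0, 1\]; the WM template is the complementary smooth map
#' `(1 - GM) * envelope`, where the envelope is a broad central Gaussian,
#' so both maps are valid probability volumes. Deterministic given `seed`.
#'
#' @inheritParams simulation_config
#' @param seed integer seed.
#' @return an `epcog_template`: list with `gm`, `wm` ([probability_map()]s)
#'   and the blob parameters.
#' @export
make_template <- function(dims, n_blobs, seed = 1) {
  dims <- as.integer(dims)
  with_seed(seed, {
    blobs <- purrr::map(seq_len(max(n_blobs, 0)), function(i) {
      list(centre = runif(3, 0.2, 0.8) * dims,
           sigma = runif(1, 0.06, 0.14) * min(dims),
           amp = runif(1, 0.5, 1))
    })
    gm <- array(0, dims)
    for (b in blobs) gm <- gm + b$amp * gaussian_blob(dims, b$centre, b$sigma)
    if (max(gm) > 0) gm <- gm / max(gm)
    env <- gaussian_blob(dims, (dims + 1) / 2, 0.35 * min(dims))
    wm <- (1 - gm) * env
    structure(list(gm = probability_map(clamp01(gm), "GM"),
                   wm = probability_map(clamp01(wm), "WM"),
                   blobs = blobs, dims = dims),
              class = "epcog_template")
  })
}

#' Effect-region mask of a template
#'
#' Soft mask in \[0, 1\]: the maximum over the selected blobs of each
#' blob's unit-peak Gaussian. `threshold` binarizes it to the "implanted
#' region" used in saliency-recovery checks.
#'
#' @param template an [make_template()] result.
#' @param effect_regions blob indices.
#' @param threshold if non-`NULL`, return a logical array `mask >= threshold`.
#' @return numeric (or logical) 3D array.
#' @export
effect_region_mask <- function(template, effect_regions, threshold = NULL) {
  mask <- array(0, template$dims)
  for (i in effect_regions) {
    b <- template$blobs[[i]]
    mask <- pmax(mask, gaussian_blob(template$dims, b$centre, b$sigma))
  }
  if (!is.null(threshold)) mask >= threshold else mask
}

#' Simulate one subject
#'
#' See [simulation_config()] for the generative model. With
#' `effect_size = 0` and `noise_sd = 0` the returned volume equals the
#' template exactly; with `severity = 0` scores equal the group means plus
#' calibrated noise.
#'
#' @param template an [make_template()] result.
#' @param config a [simulation_config()].
#' @param diagnosis `"EP"` or `"HC"`.
#' @param severity latent severity scalar (patients; controls use 0).
#' @param subject_seed integer seed for this subject's draws.
#' @param subject_id identifier.
#' @return one-row tibble in [cohort()] layout (without gender/ethnicity).
#' @export
simulate_subject <- function(template, config, diagnosis, severity,
                             subject_seed, subject_id = "s1") {
  with_seed(subject_seed, {
    # metadata draws first so metadata-only simulation matches exactly
    cal <- config$cognition_calibration
    vz <- trunc_norm_var(3)
    scores <- vapply(seq_along(COG_DIMS), function(j) {
      d <- COG_DIMS[j]
      mu <- if (diagnosis == "EP") cal$ep_mean[j] else cal$hc_mean[j]
      sg <- if (diagnosis == "EP") cal$ep_sd[j] else cal$hc_sd[j]
      sl <- config$severity_cognition_slope[[d]]
      z <- if (diagnosis == "EP") severity else 0
      noise_sd <- sg * sqrt(max(0, 1 - (diagnosis == "EP") * sl^2 * vz))
      mu + sl * z * sg + rnorm(1, 0, noise_sd)
    }, numeric(1))
    ac <- config$age_calibration
    a <- ac[ac$group == diagnosis, ]
    age <- min(max(rnorm(1, a$mean, a$sd), a$min[1]), a$max[1])
    gm <- as.numeric(template$gm)
    wm <- as.numeric(template$wm)
    dims <- template$dims
    if (diagnosis == "EP" && config$effect_size > 0) {
      mask <- effect_region_mask(template, config$effect_regions)
      rho <- min(config$effect_size * config$noise_sd * exp(severity / 4), 0.9)
      gm <- gm * (1 - rho * as.numeric(mask))
    }
    nv <- prod(dims)
    if (config$noise_sd > 0) {
      gm <- gm + rnorm(nv, 0, config$noise_sd)
      wm <- wm + rnorm(nv, 0, config$noise_sd)
    }
    vol <- stack_channels(probability_map(clamp01(array(gm, dims)), "GM"),
                          probability_map(clamp01(array(wm, dims)), "WM"))
    out <- tibble(subject_id = subject_id, diagnosis = diagnosis,
                  gender = NA_character_, ethnicity = NA_character_,
                  age = age, severity = severity)
    for (j in seq_along(COG_DIMS)) out[[COG_DIMS[j]]] <- scores[j]
    out$volume <- list(vol)
    out
  })
}

#' Simulate a full cohort
#'
#' Generates `n_hc + n_ep` subjects from one template, assigns gender and
#' ethnicity per the configured counts, and knocks out the configured
#' number of cognition entries completely at random with at most one
#' missing dimension per subject. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param include_volumes generate imaging volumes (set `FALSE` for
#'   metadata-only cohorts, e.g. demographic summaries).
#' @return an [cohort()]; the template is attached as attribute
#'   `"template"` and the config as `"sim_config"`.
#' @export
simulate_cohort <- function(config, include_volumes = TRUE) {
  template <- make_template(config$dims, config$n_blobs,
                            derive_seed(config$seed, 0))
  n <- config$n_hc + config$n_ep
  with_seed(derive_seed(config$seed, 1), {
    subject_seeds <- sample.int(2147483646L, n)
    severities <- rtrunc_norm(config$n_ep)
    gender <- c(rep(c("male", "female"), config$gender_counts$hc),
                rep(c("male", "female"), config$gender_counts$ep))
    ethnicity <- c(rep(c("caucasian", "other"), config$ethnicity_counts$hc),
                   rep(c("caucasian", "other"), config$ethnicity_counts$ep))
    diagnosis <- rep(c("HC", "EP"), c(config$n_hc, config$n_ep))
    rows <- vector("list", n)
    cfg <- config
    if (!include_volumes) {
      cfg$noise_sd <- config$noise_sd # volumes skipped below regardless
    }
    for (i in seq_len(n)) {
      sev <- if (diagnosis[i] == "EP") severities[i - config$n_hc] else 0
      id <- sprintf("%s%03d", tolower(diagnosis[i]),
                    if (diagnosis[i] == "HC") i else i - config$n_hc)
      if (include_volumes) {
        rows[[i]] <- simulate_subject(template, cfg, diagnosis[i], sev,
                                      subject_seeds[i], id)
      } else {
        r <- simulate_subject(strip_template(template), cfg, diagnosis[i],
                              sev, subject_seeds[i], id)
        r$volume <- list(NULL)
        rows[[i]] <- r
      }
    }
    meta <- dplyr::bind_rows(rows)
    meta$gender <- gender
    meta$ethnicity <- ethnicity
    # missing-at-random knockout, at most one missing dimension per subject
    eligible <- seq_len(n)
    for (d in names(config$missing_counts)) {
      k <- config$missing_counts[[d]]
      if (k == 0) next
      if (length(eligible) < k) {
        abort("infeasible missing pattern: not enough subjects left",
              class = "epcog_config_error")
      }
      hit <- sample(eligible, k)
      meta[[d]][hit] <- NA_real_
      eligible <- setdiff(eligible, hit)
    }
    out <- cohort(meta, provenance = sprintf("simulated (seed %d)", config$seed))
    attr(out, "template") <- template
    attr(out, "sim_config") <- config
    out
  })
}

# 1-voxel template stand-in so metadata-only simulation skips volume work
strip_template <- function(template) {
  t2 <- template
  t2$dims <- c(1L, 1L, 1L)
  t2$gm <- probability_map(array(0, c(1, 1, 1)), "GM")
  t2$wm <- probability_map(array(0, c(1, 1, 1)), "WM")
  t2$blobs <- purrr::map(t2$blobs, function(b) {
    list(centre = c(1, 1, 1), sigma = 1, amp = 0)
  })
  t2
}
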