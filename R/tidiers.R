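#' Tidy per-fold cross-validation metrics
#'
#' @param x an `epcog_cv`.
#' @param ... unused.
#' @return tibble with one row per fold and one column per metric.
#' @export
tidy.epcog_cv <- function(x, ...) {
  as_tibble(x$metrics)
}

#' One-row cross-validation summary (mean over folds)
#'
#' @inheritParams tidy.epcog_cv
#' @return one-row tibble of per-metric means with `<metric>_sd` columns.
#' @export
glance.epcog_cv <- function(x, ...) {
  agg <- x$aggregate
  out <- as.list(setNames(agg$mean, agg$metric))
  out <- c(out, setNames(as.list(agg$sd), paste0(agg$metric, "_sd")))
  out$k <- x$k
  as_tibble(out)
}

#' Tidy a trained model's parameter tensors
#'
#' @param x an `epcog_model`.
#' @param ... unused.
#' @return tibble `tensor`, `n`, `rms` (root-mean-square value).
#' @export
tidy.epcog_model <- function(x, ...) {
  tibble(tensor = names(x$params),
         n = vapply(x$params, length, integer(1)),
         rms = vapply(x$params, function(z) sqrt(mean(z^2)), numeric(1)))
}

#' One-row model summary
#'
#' @inheritParams tidy.epcog_model
#' @return tibble with parameter count, block structure, heads, and (if
#'   trained) the final training loss.
#' @export
glance.epcog_model <- function(x, ...) {
  tibble(
    n_parameters = as.integer(n_parameters(x)),
    n_blocks = length(x$config$conv_channels),
    heads = paste(x$config$heads, collapse = "+"),
    final_loss = if (!is.null(x$history)) {
      x$history$l_total[nrow(x$history)]
    } else NA_real_
  )
}

#' Plot per-fold cross-validation metrics
#'
#' @param object an `epcog_cv`.
#' @param ... unused.
#' @return a ggplot: one panel per metric, folds on the x axis, the fold
#'   mean as a horizontal line.
#' @export
autoplot.epcog_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      data = dplyr::summarise(dplyr::group_by(long, .data$metric),
                              mean = mean(.data$value, na.rm = TRUE),
                              .groups = "drop"),
      ggplot2::aes(yintercept = .data$mean), linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = "Cross-validated performance per fold")
}

#' Plot the training loss history of a model
#'
#' @param object a trained `epcog_model`.
#' @param ... unused.
#' @return a ggplot of each loss component over epochs.
#' @export
autoplot.epcog_model <- function(object, ...) {
  if (is.null(object$history)) {
    abort("model has no training history", class = "epcog_argument_error")
  }
  long <- tidyr::pivot_longer(object$history, c(-"epoch", -"lr"),
                              names_to = "component")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Training loss components")
}

#' Plot orthogonal mid-slices of a saliency map
#'
#' @param object a `saliency_map` (or any 3D array).
#' @param ... unused.
#' @return a ggplot heat map of the three mid-plane slices.
#' @export
autoplot.saliency_map <- function(object, ...) {
  dm <- dim(object)
  mid <- (dm + 1) %/% 2
  slice_df <- function(plane) {
    m <- switch(plane,
                sagittal = object[mid[1], , ],
                coronal = object[, mid[2], ],
                axial = object[, , mid[3]])
    df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
    df$value <- as.numeric(m)
    df$plane <- plane
    df
  }
  df <- dplyr::bind_rows(lapply(c("sagittal", "coronal", "axial"), slice_df))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "attention",
                  title = "Saliency mid-slices")
}
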