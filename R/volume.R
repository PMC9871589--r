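#' Tissue probability maps and multi-channel network inputs
#'
#' A `probability_map` is a 3D array of per-voxel tissue probabilities in
#' \[0, 1\] with a tissue tag (`"GM"` or `"WM"`) and an optional 4x4
#' voxel-to-world affine. A `multichannel_volume` stacks one GM and one WM
#' map into the H x W x D x 2 array the network consumes; when only one
#' tissue is available the supplied map is replicated into both channels so
#' the input dimensionality is preserved.
#'
#' Arrays are indexed (H, W, D) in the map's native orientation; no
#' reorientation is attempted (spatial registration is upstream). Affines
#' are carried through for export but never drive resampling: grids are
#' treated as already co-registered.
#'
#' @param voxels 3D numeric array of probabilities.
#' @param tissue `"GM"` or `"WM"`.
#' @param affine optional 4x4 voxel-to-world matrix; identity when `NULL`.
#' @return `probability_map()` returns a classed 3D array.
#' @examples
#' pm <- probability_map(array(0.5, c(8, 8, 8)), "GM")
#' dim(pm)
#' @export
probability_map <- function(voxels, tissue = c("GM", "WM"), affine = NULL) {
  tissue <- match.arg(tissue)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort(sprintf("`voxels` must be a 3D array, got shape (%s)",
                  paste(dim(voxels) %||% length(voxels), collapse = ", ")),
          class = "epcog_format_error")
  }
  if (anyNA(voxels) || any(voxels < 0) || any(voxels > 1)) {
    abort("probability values must lie in [0, 1] with no missing voxels",
          class = "epcog_range_error")
  }
  if (is.null(affine)) affine <- diag(4)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(voxels, class = c("probability_map", "array"),
            tissue = tissue, affine = affine)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map %s  %s  range [%.3f, %.3f]>\n",
              attr(x, "tissue"), paste(dim(x), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' Read a tissue probability map from a NIfTI file
#'
#' Values are clamped to \[0, 1\] on load (segmentation toolkits can emit
#' tiny float excursions outside the nominal range); the affine is
#' preserved. Non-3D images are rejected.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @inheritParams probability_map
#' @return a [probability_map()].
#' @export
load_probability_map <- function(path, tissue = c("GM", "WM")) {
  tissue <- match.arg(tissue)
  if (!file.exists(path)) {
    abort(sprintf("volume file not found: %s", path), class = "epcog_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf("cannot read '%s': %s",
                                                    path, conditionMessage(e)),
                                            class = "epcog_io_error"))
  dm <- dim(img)
  if (length(dm) != 3L) {
    abort(sprintf("expected a 3D scalar image, '%s' has shape (%s)",
                  path, paste(dm, collapse = ", ")),
          class = "epcog_format_error")
  }
  affine <- structure(RNifti::xform(img), class = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  probability_map(clamp01(array(as.numeric(img), dm)), tissue, affine)
}

#' Write a probability map (or any scalar volume) to NIfTI
#'
#' @param map a [probability_map()] or plain 3D array.
#' @param path output path (`.nii` or `.nii.gz`); written as float32.
#' @param affine optional 4x4 affine overriding the map's own.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path, affine = NULL) {
  affine <- affine %||% attr(map, "affine") %||% diag(4)
  arr <- array(as.numeric(map), dim(map))
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a probability map to new grid dimensions
#'
#' Trilinear interpolation with voxel-centre alignment, each axis rescaled
#' independently to its target extent (anisotropic scaling is accepted, as
#' when a 240 x 256 x 160 grid is taken to 120^3). Output is clamped to
#' \[0, 1\]; interpolation of values already in range cannot leave it, so
#' the clamp only guards float round-off.
#'
#' @param map a [probability_map()].
#' @param target_dims integer vector (H, W, D).
#' @return a [probability_map()] with the target dimensions.
#' @export
resample_volume <- function(map, target_dims) {
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3L || any(target_dims < 1L)) {
    abort("`target_dims` must be three positive integers",
          class = "epcog_argument_error")
  }
  if (identical(dim(map), target_dims)) {
    return(map)
  }
  out <- cpp_resample_trilinear(as.numeric(map), dim(map), target_dims)
  probability_map(clamp01(array(out, target_dims)),
                  tissue = attr(map, "tissue") %||% "GM",
                  affine = attr(map, "affine"))
}

#' Stack GM and WM maps into the two-channel network input
#'
#' Channel order is fixed (GM, WM). If only one tissue is supplied it is
#' replicated into both channels, preserving the H x W x D x 2 input shape
#' used by the encoder.
#'
#' @param gm,wm [probability_map()]s (at least one non-`NULL`).
#' @return a `multichannel_volume`: H x W x D x 2 array with
#'   `channel_names` attribute `c("GM", "WM")`.
#' @export
stack_channels <- function(gm = NULL, wm = NULL) {
  if (is.null(gm) && is.null(wm)) {
    abort("at least one of `gm`, `wm` must be supplied",
          class = "epcog_argument_error")
  }
  if (!is.null(gm) && !is.null(wm) && !identical(dim(gm), dim(wm))) {
    abort(sprintf("GM dims (%s) and WM dims (%s) differ",
                  paste(dim(gm), collapse = "x"),
                  paste(dim(wm), collapse = "x")),
          class = "epcog_shape_error")
  }
  ref <- gm %||% wm
  dm <- dim(ref)
  out <- array(0, c(dm, 2L))
  out[, , , 1L] <- as.numeric(gm %||% wm)
  out[, , , 2L] <- as.numeric(wm %||% gm)
  structure(out, class = c("multichannel_volume", "array"),
            channel_names = c("GM", "WM"),
            affine = attr(ref, "affine") %||% diag(4))
}

#' @export
print.multichannel_volume <- function(x, ...) {
  cat(sprintf("<multichannel_volume %s  channels (%s)>\n",
              paste(dim(x)[1:3], collapse = "x"),
              paste(attr(x, "channel_names"), collapse = ", ")))
  invisible(x)
}
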