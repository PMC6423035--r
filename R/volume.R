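#' @useDynLib nestmech, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Global axis convention (fixed across the whole package):
#   array axis 1 = U-D (up-down; gravity acts toward decreasing index),
#   array axis 2 = B-F (back-front; the wall/anchor plane is the index-1 face),
#   array axis 3 = R-L (right-left).
# The physical center of voxel (i, j, k) (1-based) is
# ((i-0.5), (j-0.5), (k-0.5)) * spacing, i.e. 0-based voxel (i,j,k) has center
# (i+0.5, j+0.5, k+0.5) * spacing.
NEST_AXES <- c("UD", "BF", "RL")

#' Resolve an axis identifier to an array dimension
#'
#' Axis ids follow the anatomical convention used throughout the package:
#' `"UD"` (up-down, array axis 1), `"BF"` (back-front, array axis 2, wall at
#' the low face) and `"RL"` (right-left, array axis 3). Integers 1:3 are
#' accepted as-is.
#'
#' @param axis Axis id (`"UD"`, `"BF"`, `"RL"`) or integer in 1:3.
#' @return Integer array dimension in 1:3.
#' @export
axis_index <- function(axis) {
  if (is.numeric(axis)) {
    axis <- as.integer(axis)
    if (length(axis) != 1L || is.na(axis) || axis < 1L || axis > 3L)
      stop("axis must be 1, 2 or 3, or one of ", paste(NEST_AXES, collapse = ", "))
    return(axis)
  }
  idx <- match(toupper(as.character(axis)), NEST_AXES)
  if (length(idx) != 1L || is.na(idx))
    stop("unknown axis id '", axis, "'; expected one of ",
         paste(NEST_AXES, collapse = ", "))
  idx
}

.check_spacing <- function(spacing, unit) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("spacing must be a single positive finite number")
  if (!unit %in% c("mm", "um"))
    stop("spacing unit must be 'mm' or 'um'")
  invisible(TRUE)
}

.check_dims <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop("data must be a 3D array")
  if (any(d < 1L)) stop("each axis must have extent >= 1")
  invisible(d)
}

#' Grayscale voxel volume
#'
#' A 3D grayscale image with isotropic voxel spacing, the in-memory analogue of
#' a micro-CT slice stack. Intensities carry 8-bit unsigned semantics
#' (0..255); values are validated but stored as a plain numeric/integer array.
#'
#' @param data 3D array of finite intensities in \[0, 255\].
#' @param spacing Isotropic voxel edge length.
#' @param unit Unit of `spacing`: `"mm"` (canonical) or `"um"`.
#' @return An object of class `voxel_volume` with fields `data`, `spacing`,
#'   `unit` and `axes`.
#' @export
voxel_volume <- function(data, spacing, unit = "mm") {
  .check_dims(data)
  .check_spacing(spacing, unit)
  if (!all(is.finite(data))) stop("voxel data must be finite")
  if (min(data) < 0 || max(data) > 255)
    stop("voxel intensities must lie in [0, 255] (8-bit semantics)")
  structure(list(data = data, spacing = spacing, unit = unit,
                 axes = NEST_AXES),
            class = "voxel_volume")
}

#' Binary mask volume
#'
#' @param data 3D logical array (or 0/1 numeric, coerced to logical).
#' @inheritParams voxel_volume
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing, unit = "mm") {
  .check_dims(data)
  .check_spacing(spacing, unit)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be 0/1 or logical")
    data <- array(as.logical(data), dim = dim(data))
  }
  if (anyNA(data)) stop("mask must not contain NA")
  structure(list(data = data, spacing = spacing, unit = unit,
                 axes = NEST_AXES),
            class = "mask_volume")
}

#' Integer label volume
#'
#' Non-negative integer labels with 0 = background; labels must be the
#' contiguous range `1..label_count`.
#'
#' @param data 3D integer array, values in `0:label_count`.
#' @param label_count Number of labels present (`>= 0`). Inferred from the data
#'   when missing.
#' @inheritParams voxel_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, unit = "mm", label_count = NULL) {
  .check_dims(data)
  .check_spacing(spacing, unit)
  storage.mode(data) <- "integer"
  if (anyNA(data) || min(data) < 0L) stop("labels must be non-negative integers")
  mx <- max(data)
  if (is.null(label_count)) label_count <- mx
  label_count <- as.integer(label_count)
  if (mx != label_count)
    stop("label_count (", label_count, ") does not match max label (", mx, ")")
  if (label_count > 0L) {
    present <- tabulate(data[data > 0L], nbins = label_count)
    if (any(present == 0L))
      stop("labels must be contiguous 1..label_count with no gaps")
  }
  structure(list(data = data, spacing = spacing, unit = unit,
                 axes = NEST_AXES, label_count = label_count),
            class = "label_volume")
}

#' Voxel spacing in millimetres
#'
#' @param vol A `voxel_volume`, `mask_volume` or `label_volume`.
#' @return Spacing converted to mm.
#' @export
spacing_mm <- function(vol) {
  if (vol$unit == "mm") vol$spacing else vol$spacing / 1000
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume %d x %d x %d (UD x BF x RL), spacing %g %s, range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing, x$unit, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("mask_volume %d x %d x %d (UD x BF x RL), spacing %g %s, %d foreground voxels\n",
              d[1], d[2], d[3], x$spacing, x$unit, sum(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume %d x %d x %d (UD x BF x RL), spacing %g %s, %d labels\n",
              d[1], d[2], d[3], x$spacing, x$unit, x$label_count))
  invisible(x)
}

.same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(spacing_mm(a), spacing_mm(b)))
}

#' Physical coordinates of voxel centers along one axis
#'
#' @param vol A volume object.
#' @param axis Axis id or index.
#' @return Numeric vector of center coordinates (mm) for each slice index.
#' @export
axis_coords_mm <- function(vol, axis) {
  ax <- axis_index(axis)
  s <- spacing_mm(vol)
  (seq_len(dim(vol$data)[ax]) - 0.5) * s
}

# Connected-component labelling (internal wrapper around the C++ kernel).
# Returns an integer array plus attribute "label_count".
.label_components <- function(mask_arr, connectivity) {
  d <- dim(mask_arr)
  lab <- cc_label3d(as.logical(mask_arr), as.integer(d), as.integer(connectivity))
  n <- attr(lab, "label_count")
  lab <- array(lab, dim = d)
  attr(lab, "label_count") <- n
  lab
}
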