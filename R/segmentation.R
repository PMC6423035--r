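# Segmentation pipeline for micro-CT style nest volumes:
# Gaussian smoothing -> (optional linear downsampling) -> inclusive grayscale
# thresholding -> retention of the largest connected component -> closed-pore
# extraction with a small-pore fill rule.
#
# Connectivity convention: 26 for material/foreground, 6 for background/pores
# (complementary connectivities avoid topological paradoxes); both are
# parameters of segmentation_params() since the choice affects pore counts.

#' Segmentation parameters
#'
#' Defaults reproduce the published recipe: grayscale window 40..255
#' (inclusive), Gaussian sigma 1 voxel, linear resampling by a factor of 2
#' (34.04 um to 68.1 um class spacing), and filling of closed pores smaller
#' than 125 voxels into the material mask. `min_pore_voxels` is a count at the
#' working resolution; see [min_pore_voxels_for()] to carry the rule across
#' voxel sizes as a physical volume.
#'
#' @param gray_low,gray_high Inclusive intensity bounds (0..255).
#' @param gaussian_sigma Smoothing sigma in voxels (0 disables).
#' @param resample_factor Integer downsampling factor (>= 1).
#' @param min_pore_voxels Closed pores smaller than this many voxels are added
#'   to the material mask.
#' @param connectivity_fg,connectivity_bg Voxel connectivity for foreground
#'   (default 26) and background/pores (default 6).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(gray_low = 40, gray_high = 255,
                                gaussian_sigma = 1, resample_factor = 2L,
                                min_pore_voxels = 125L,
                                connectivity_fg = 26L, connectivity_bg = 6L) {
  if (gray_low < 0 || gray_high > 255 || gray_low > gray_high)
    stop("need 0 <= gray_low <= gray_high <= 255")
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  resample_factor <- as.integer(resample_factor)
  if (is.na(resample_factor) || resample_factor < 1L)
    stop("resample_factor must be an integer >= 1")
  min_pore_voxels <- as.integer(min_pore_voxels)
  if (is.na(min_pore_voxels) || min_pore_voxels < 1L)
    stop("min_pore_voxels must be >= 1")
  if (!connectivity_fg %in% c(6L, 26L) || !connectivity_bg %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  structure(list(gray_low = gray_low, gray_high = gray_high,
                 gaussian_sigma = gaussian_sigma,
                 resample_factor = resample_factor,
                 min_pore_voxels = min_pore_voxels,
                 connectivity_fg = as.integer(connectivity_fg),
                 connectivity_bg = as.integer(connectivity_bg)),
            class = "segmentation_params")
}

#' Carry the small-pore fill rule across resolutions
#'
#' Converts a voxel-count threshold defined at a reference spacing into the
#' equivalent count at another spacing by matching physical volume (floored at
#' 1 voxel). The published rule (125 voxels) was stated at 68.1 um.
#'
#' @param spacing_mm Working voxel spacing (mm).
#' @param ref_voxels Reference voxel count (default 125).
#' @param ref_spacing_mm Reference spacing (mm, default 0.0681).
#' @return Integer voxel count at the working spacing.
#' @export
min_pore_voxels_for <- function(spacing_mm, ref_voxels = 125L,
                                ref_spacing_mm = 0.0681) {
  max(1L, as.integer(round(ref_voxels * (ref_spacing_mm / spacing_mm)^3)))
}

# Sampled, normalized discrete Gaussian kernel, truncated at radius ceil(4*sigma).
gaussian_kernel <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  t <- (-r):r
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of a grayscale volume
#'
#' Separable convolution with a normalized discrete Gaussian (truncation
#' radius 4 sigma, reflected boundaries), applied along each axis in turn.
#' The result is re-quantized to 8-bit by round-half-even. `sigma = 0` is the
#' identity.
#'
#' @param vol A [voxel_volume()].
#' @param sigma Kernel sigma in voxels (>= 0).
#' @return Smoothed `voxel_volume`.
#' @export
smooth_volume <- function(vol, sigma) {
  if (!inherits(vol, "voxel_volume")) stop("vol must be a voxel_volume")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(vol)
  k <- gaussian_kernel(sigma)
  d <- dim(vol$data)
  x <- as.numeric(vol$data)
  for (ax in 0:2) x <- conv_axis3d(x, as.integer(d), k, ax)
  x <- pmin(255, pmax(0, round(x)))
  voxel_volume(array(x, dim = d), vol$spacing, vol$unit)
}

#' Inclusive grayscale thresholding
#'
#' Mask is 1 where `gray_low <= value <= gray_high` (both ends inclusive, so
#' the 255 end stays reachable).
#'
#' @param vol A [voxel_volume()].
#' @param params A [segmentation_params()] (or use `gray_low`/`gray_high`).
#' @param gray_low,gray_high Bounds, overriding `params`.
#' @return A [mask_volume()].
#' @export
threshold_volume <- function(vol, params = segmentation_params(),
                             gray_low = params$gray_low,
                             gray_high = params$gray_high) {
  if (!inherits(vol, "voxel_volume")) stop("vol must be a voxel_volume")
  mask_volume(vol$data >= gray_low & vol$data <= gray_high,
              vol$spacing, vol$unit)
}

#' Keep only the largest connected foreground component
#'
#' Components are found at the foreground connectivity (default 26). Ties in
#' size are broken deterministically in favour of the component whose first
#' voxel comes earliest in raster (column-major linear index) order.
#'
#' @param mask A [mask_volume()].
#' @param connectivity 26 (default) or 6.
#' @return A `mask_volume` with only the largest component retained.
#' @export
keep_largest_component <- function(mask, connectivity = 26L) {
  if (!inherits(mask, "mask_volume")) stop("mask must be a mask_volume")
  if (!any(mask$data)) stop("empty mask: no foreground component to keep")
  lab <- .label_components(mask$data, connectivity)
  n <- attr(lab, "label_count")
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(sizes)  # first maximum = earliest raster first-voxel
  mask_volume(lab == keep, mask$spacing, mask$unit)
}

# Trilinear interpolation of a 3D array at fractional (1-based) index
# coordinates given per axis as vectors i1, i2, i3 of equal length.
.trilinear <- function(arr, i1, i2, i3) {
  d <- dim(arr)
  cl <- function(x, n) pmin(pmax(x, 1), n)
  l1 <- floor(i1); l2 <- floor(i2); l3 <- floor(i3)
  f1 <- i1 - l1;  f2 <- i2 - l2;  f3 <- i3 - l3
  g <- function(a, b, c) arr[cbind(cl(a, d[1]), cl(b, d[2]), cl(c, d[3]))]
  v <- (1 - f1) * (1 - f2) * (1 - f3) * g(l1,     l2,     l3) +
       f1       * (1 - f2) * (1 - f3) * g(l1 + 1, l2,     l3) +
       (1 - f1) * f2       * (1 - f3) * g(l1,     l2 + 1, l3) +
       f1       * f2       * (1 - f3) * g(l1 + 1, l2 + 1, l3) +
       (1 - f1) * (1 - f2) * f3       * g(l1,     l2,     l3 + 1) +
       f1       * (1 - f2) * f3       * g(l1 + 1, l2,     l3 + 1) +
       (1 - f1) * f2       * f3       * g(l1,     l2 + 1, l3 + 1) +
       f1       * f2       * f3       * g(l1 + 1, l2 + 1, l3 + 1)
  v
}

#' Downsample a volume by linear interpolation
#'
#' Samples the input at the centers of the coarse voxels by trilinear
#' interpolation. Output spacing = input spacing x factor; output shape =
#' `ceiling(shape / factor)`. `factor = 1` is the identity. Masks are
#' interpolated as 0/1 fields and re-binarized at 0.5.
#'
#' @param vol A `voxel_volume` or `mask_volume`.
#' @param factor Integer >= 1.
#' @return Volume of the same class at the coarser spacing.
#' @export
downsample_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(vol)
  is_mask <- inherits(vol, "mask_volume")
  if (!is_mask && !inherits(vol, "voxel_volume"))
    stop("vol must be a voxel_volume or mask_volume")
  d <- dim(vol$data)
  dn <- ceiling(d / factor)
  # coarse voxel i' center at old fractional index (i'-0.5)*factor + 0.5
  ax <- lapply(1:3, function(a) (seq_len(dn[a]) - 0.5) * factor + 0.5)
  grid <- expand.grid(i1 = ax[[1]], i2 = ax[[2]], i3 = ax[[3]])
  src <- if (is_mask) array(as.numeric(vol$data), dim = d) else vol$data
  v <- .trilinear(src, grid$i1, grid$i2, grid$i3)
  out <- array(v, dim = dn)
  if (is_mask) {
    mask_volume(out >= 0.5, vol$spacing * factor, vol$unit)
  } else {
    out <- array(pmin(255, pmax(0, round(out))), dim = dn)
    voxel_volume(out, vol$spacing * factor, vol$unit)
  }
}

#' Extract closed pores and apply the small-pore fill rule
#'
#' The background (non-material) is labelled at the background connectivity
#' (default 6); every background component touching any volume border is
#' exterior. The remaining components are closed pores. Pores smaller than
#' `min_pore_voxels` are added to the material mask ("filled"); survivors are
#' labelled `1..N` in raster order of their first voxel. Border-connected
#' cavities are never filled. The operation is idempotent on its own output.
#'
#' @param mask A [mask_volume()] of material.
#' @param params A [segmentation_params()].
#' @return List with `material` (updated `mask_volume`) and `pores`
#'   (a [label_volume()]).
#' @export
extract_closed_pores <- function(mask, params = segmentation_params()) {
  if (!inherits(mask, "mask_volume")) stop("mask must be a mask_volume")
  d <- dim(mask$data)
  bg <- !mask$data
  lab <- .label_components(bg, params$connectivity_bg)
  n <- attr(lab, "label_count")
  if (n == 0L) {
    return(list(material = mask,
                pores = label_volume(array(0L, dim = d), mask$spacing, mask$unit)))
  }
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  exterior <- setdiff(border, 0L)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  pore_labels <- setdiff(seq_len(n), exterior)
  fill <- pore_labels[sizes[pore_labels] < params$min_pore_voxels]
  keep <- pore_labels[sizes[pore_labels] >= params$min_pore_voxels]

  mat <- mask$data
  if (length(fill)) mat <- mat | array(lab %in% fill, dim = d)
  pores <- array(0L, dim = d)
  if (length(keep)) {
    remap <- integer(n)
    remap[keep] <- seq_along(keep)  # keep is ascending = raster order
    pos <- lab > 0L
    pores[pos] <- remap[lab[pos]]
  }
  list(material = mask_volume(mat, mask$spacing, mask$unit),
       pores = label_volume(pores, mask$spacing, mask$unit,
                            label_count = length(keep)))
}

#' Run the full segmentation pipeline
#'
#' Fixed, logged stage order: smooth, optional downsample, threshold, largest
#' component, closed-pore extraction. The downsampling stage is configurable:
#' `"pre_threshold"` (default; the grayscale stack is resampled before
#' segmentation, as in the original workflow), `"post_mask"` (the binary mask
#' is resampled after component retention) or `"none"`.
#'
#' @param vol A [voxel_volume()].
#' @param params A [segmentation_params()].
#' @param downsample_stage Where resampling happens (see above).
#' @return List with `material`, `pores` and a `provenance` record (stages and
#'   parameters actually used).
#' @export
segment_nest <- function(vol, params = segmentation_params(),
                         downsample_stage = c("pre_threshold", "post_mask", "none")) {
  downsample_stage <- match.arg(downsample_stage)
  stages <- character()
  v <- smooth_volume(vol, params$gaussian_sigma)
  stages <- c(stages, sprintf("smooth(sigma=%g)", params$gaussian_sigma))
  if (downsample_stage == "pre_threshold" && params$resample_factor > 1L) {
    v <- downsample_volume(v, params$resample_factor)
    stages <- c(stages, sprintf("downsample(factor=%d)", params$resample_factor))
  }
  m <- threshold_volume(v, params)
  stages <- c(stages, sprintf("threshold[%g,%g]", params$gray_low, params$gray_high))
  m <- keep_largest_component(m, params$connectivity_fg)
  stages <- c(stages, sprintf("keep_largest_component(conn=%d)", params$connectivity_fg))
  if (downsample_stage == "post_mask" && params$resample_factor > 1L) {
    m <- downsample_volume(m, params$resample_factor)
    stages <- c(stages, sprintf("downsample_mask(factor=%d)", params$resample_factor))
  }
  cp <- extract_closed_pores(m, params)
  stages <- c(stages, sprintf("extract_closed_pores(min=%d,conn=%d)",
                              params$min_pore_voxels, params$connectivity_bg))
  list(material = cp$material, pores = cp$pores,
       provenance = list(stages = stages, params = unclass(params),
                         downsample_stage = downsample_stage,
                         input_spacing = vol$spacing, input_unit = vol$unit,
                         output_spacing = cp$material$spacing))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `mask_volume`s (or logical arrays) on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  da <- if (inherits(a, "mask_volume")) a$data else a
  db <- if (inherits(b, "mask_volume")) b$data else b
  if (!identical(dim(da), dim(db))) stop("masks must share a grid")
  sa <- sum(da); sb <- sum(db)
  if (sa + sb == 0) return(1)
  2 * sum(da & db) / (sa + sb)
}
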