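test_that("smoothing matches an explicit 1D kernel convolution oracle", {
  # unit impulse of 255 at the center of a 9^3 volume, sigma = 1
  n <- 9L
  arr <- array(0, rep(n, 3))
  arr[5, 5, 5] <- 255
  got <- smooth_volume(voxel_volume(arr, 1), sigma = 1)
  # oracle: separable normalized discrete Gaussian applied axis by axis
  t <- -4:4
  k <- exp(-t^2 / 2); k <- k / sum(k)
  conv1 <- function(x) {
    out <- numeric(n)
    for (p in 1:n) for (q in seq_along(t)) {
      src <- p + t[q]
      if (src < 1) src <- 1 - src          # half-sample reflection
      if (src > n) src <- 2 * n + 1 - src
      out[p] <- out[p] + k[q] * x[src]
    }
    out
  }
  ref <- arr
  for (ax in 1:3) ref <- apply(ref, setdiff(1:3, ax), conv1) |>
    aperm(order(c(ax, setdiff(1:3, ax))))
  ref <- array(pmin(255, pmax(0, round(ref))), rep(n, 3))
  expect_equal(got$data, ref)
  # center response is the cube of the central kernel weight
  expect_equal(got$data[5, 5, 5], round(255 * k[5]^3))
})

test_that("smoothing is identity at sigma 0 and preserves constants", {
  set.seed(3)
  v <- voxel_volume(array(sample(0:255, 4^3, TRUE), c(4, 4, 4)), 1)
  expect_identical(smooth_volume(v, 0)$data, v$data)
  const <- voxel_volume(array(117, c(6, 5, 4)), 1)
  expect_true(all(smooth_volume(const, 1.5)$data == 117))
  expect_error(smooth_volume(v, -1), "sigma")
})

test_that("thresholding is inclusive at both ends", {
  v <- voxel_volume(array(c(39, 40, 255, 0, 254, 41), c(1, 2, 3)), 1)
  m <- threshold_volume(v, gray_low = 40, gray_high = 255)
  expect_identical(as.vector(m$data), c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_true(all(threshold_volume(v, gray_low = 0, gray_high = 255)$data))
  v2 <- voxel_volume(array(c(10, 100, 254), c(1, 1, 3)), 1)
  expect_true(!any(threshold_volume(v2, gray_low = 255, gray_high = 255)$data))
})

test_that("largest-component retention keeps size order and raster tie-break", {
  m <- array(FALSE, c(5, 12, 5))
  m[2:3, 2:3, 2:3] <- TRUE            # 8 voxels
  m[2, 8:10, 2] <- TRUE               # 3 voxels
  keep <- keep_largest_component(mask_volume(m, 1))
  expect_identical(sum(keep$data), 8L)
  expect_true(all(keep$data[2:3, 2:3, 2:3]))
  # single blob unchanged
  single <- mask_volume(array(c(rep(FALSE, 10), rep(TRUE, 4), rep(FALSE, 111)),
                              c(5, 5, 5)), 1)
  expect_identical(keep_largest_component(single)$data, single$data)
  # equal sizes: earlier raster-order first voxel wins (brute-force check)
  m2 <- array(FALSE, c(3, 9, 3))
  m2[2, 2:3, 2] <- TRUE
  m2[2, 7:8, 2] <- TRUE
  kept <- keep_largest_component(mask_volume(m2, 1))
  comps <- which(m2)
  expect_identical(which(kept$data), comps[1:2])
  expect_error(keep_largest_component(mask_volume(array(FALSE, c(2, 2, 2)), 1)),
               "empty mask")
})

test_that("downsampling halves the grid and scales spacing (34.04 um -> 68.1 um)", {
  v <- voxel_volume(array(rep(100, 8^3), c(8, 8, 8)), 34.04, "um")
  d <- downsample_volume(v, 2L)
  expect_equal(d$spacing, 68.08)
  expect_equal(round(d$spacing, 1), 68.1)
  expect_identical(dim(d$data), c(4L, 4L, 4L))
  expect_true(all(d$data == 100))          # constancy preserved
  expect_identical(downsample_volume(v, 1L), v)
  expect_error(downsample_volume(v, 0L), "factor")
  # odd extents round up: ceil(shape/factor)
  v2 <- voxel_volume(array(0, c(5, 7, 9)), 1)
  expect_identical(dim(downsample_volume(v2, 2L)$data), c(3L, 4L, 5L))
})

test_that("closed-pore rule: fill below 125 voxels, keep at 125, never fill border cavities", {
  params <- segmentation_params()  # min_pore_voxels = 125
  m124 <- pore_in_block(124L)
  r124 <- extract_closed_pores(m124, params)
  expect_identical(r124$pores$label_count, 0L)
  expect_true(all(r124$material$data))      # pore filled into material

  m125 <- pore_in_block(125L)
  r125 <- extract_closed_pores(m125, params)
  expect_identical(r125$pores$label_count, 1L)
  expect_identical(sum(r125$pores$data == 1L), 125L)
  expect_false(any(r125$material$data & r125$pores$data > 0L))

  # cavity opening to the border is exterior, never filled, never a pore
  m <- array(TRUE, c(10, 10, 10))
  m[5, 5, 1:5] <- FALSE   # tunnel to the k = 1 border
  rb <- extract_closed_pores(mask_volume(m, 1), params)
  expect_identical(rb$pores$label_count, 0L)
  expect_identical(rb$material$data, m)
})

test_that("extract_closed_pores is idempotent and partitions the volume", {
  b <- generate_phantom(phantom_params(seed = 2L))
  sp <- segmentation_params(resample_factor = 1L,
                            min_pore_voxels = min_pore_voxels_for(0.4))
  seg <- segment_nest(b$image, sp, downsample_stage = "none")
  again <- extract_closed_pores(seg$material, sp)
  expect_identical(again$material$data, seg$material$data)
  expect_identical(again$pores$data, seg$pores$data)
  # material + pores + exterior partition the voxel grid exactly
  n_total <- prod(dim(seg$material$data))
  n_mat <- sum(seg$material$data)
  n_pore <- sum(seg$pores$data > 0L)
  bg <- !(seg$material$data | seg$pores$data > 0L)
  expect_equal(n_mat + n_pore + sum(bg), n_total)
  expect_false(any(seg$material$data & seg$pores$data > 0L))
})

test_that("phantom recovery: Dice >= 0.95 and pore-count error <= 20% (seed 1)", {
  b <- generate_phantom(phantom_params(seed = 1L))
  sp <- segmentation_params(resample_factor = 1L,
                            min_pore_voxels = min_pore_voxels_for(0.4))
  seg <- segment_nest(b$image, sp, downsample_stage = "none")
  expect_gte(dice_coefficient(seg$material, b$material_truth), 0.95)
  nt <- b$pore_truth$label_count
  expect_lte(abs(seg$pores$label_count - nt) / nt, 0.20)
  expect_identical(seg$provenance$stages[1], "smooth(sigma=1)")
})

test_that("pipeline stage order is fixed and logged", {
  b <- generate_phantom(phantom_params(seed = 1L, width_rl = 30,
                                       height_ud = 20, depth_bf = 15,
                                       wall_thickness_anchor = 6,
                                       wall_thickness_rim = 3))
  seg <- segment_nest(b$image, segmentation_params(), "pre_threshold")
  st <- seg$provenance$stages
  expect_match(st[1], "^smooth")
  expect_match(st[2], "^downsample")
  expect_match(st[3], "^threshold")
  expect_match(st[4], "^keep_largest_component")
  expect_match(st[5], "^extract_closed_pores")
  expect_equal(seg$provenance$output_spacing, 0.8)
})
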