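test_that("slice stacks assemble along the U-D axis in the given order", {
  tmp <- withr_local_tempdir()
  set.seed(11)
  slices <- lapply(1:3, function(i) matrix(sample(0:255, 20, TRUE), 4, 5))
  paths <- file.path(tmp, sprintf("s%d.tiff", 1:3))
  for (i in 1:3) tiff::writeTIFF(slices[[i]] / 255, paths[i], bits.per.sample = 8)
  vol <- read_stack(paths, spacing = 34.04, unit = "um")
  expect_identical(dim(vol$data), c(3L, 4L, 5L))
  for (i in 1:3) expect_equal(vol$data[i, , ], slices[[i]])
  expect_equal(vol$spacing, 34.04)
  expect_equal(vol$unit, "um")
  expect_equal(spacing_mm(vol), 0.03404)
})

test_that("mixed slice shapes and missing spacing are explicit errors", {
  tmp <- withr_local_tempdir()
  tiff::writeTIFF(matrix(0, 4, 4), file.path(tmp, "a1.tiff"))
  tiff::writeTIFF(matrix(0, 4, 5), file.path(tmp, "a2.tiff"))
  expect_error(read_stack(file.path(tmp, c("a1.tiff", "a2.tiff")), spacing = 1),
               "mixed slice shapes")
  tiff::writeTIFF(matrix(0, 4, 4), file.path(tmp, "a2.tiff"))
  expect_error(read_stack(file.path(tmp, c("a1.tiff", "a2.tiff"))),
               "spacing")
  expect_error(read_stack(file.path(tmp, "nope.tiff"), spacing = 1),
               "unreadable")
})

test_that("filename ordering is numeric-aware", {
  got <- numeric_aware_sort(c("slice_10.tif", "slice_2.tif", "slice_1.tif"))
  expect_equal(basename(got), c("slice_1.tif", "slice_2.tif", "slice_10.tif"))
})

test_that("TIFF and MetaImage round-trips are lossless, spacing at full precision", {
  tmp <- withr_local_tempdir()
  set.seed(7)
  vol <- voxel_volume(array(sample(0:255, 5 * 6 * 7, TRUE), c(5, 6, 7)),
                      34.04, "um")
  for (fmt in c("tiff", "mhd")) {
    f <- file.path(tmp, paste0("v.", ifelse(fmt == "tiff", "tiff", "mhd")))
    write_volume(vol, f, fmt)
    back <- read_stack(f)
    expect_identical(as.integer(back$data), as.integer(vol$data))
    expect_identical(back$spacing, vol$spacing)
    expect_identical(back$unit, "um")
  }
  # slice-stack round trip through a directory read
  sdir <- file.path(tmp, "stack")
  write_volume(vol, sdir, "tiff_stack")
  back <- read_stack(sdir)
  expect_identical(as.integer(back$data), as.integer(vol$data))
  expect_identical(back$spacing, vol$spacing)
})

test_that("a 300-label volume is stored at 16-bit width without clipping", {
  tmp <- withr_local_tempdir()
  d <- c(6L, 10L, 5L)
  lab <- array(0L, d)
  lab[seq_len(300)] <- 1:300
  lv <- label_volume(lab, 0.5)
  f <- file.path(tmp, "lab.tiff")
  write_volume(lv, f, "tiff")
  back <- read_stack(f, type = "label")
  expect_identical(back$data, lv$data)
  expect_identical(back$label_count, 300L)
  f2 <- file.path(tmp, "lab.mhd")
  write_volume(lv, f2, "mhd")
  back2 <- read_stack(f2, type = "label")
  expect_identical(back2$data, lv$data)
})

test_that("8-bit BMP slices are readable", {
  tmp <- withr_local_tempdir()
  # hand-assemble a minimal 8-bit uncompressed BMP (3 wide x 2 tall)
  w <- 3L; h <- 2L; row_bytes <- 4L
  px_top <- as.raw(c(10, 20, 30))
  px_bottom <- as.raw(c(40, 50, 60))
  palette <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, 0)))
  offset <- 14L + 40L + 1024L
  int4 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
                               x %/% 16777216))
  int2 <- function(x) as.raw(c(x %% 256, x %/% 256))
  header <- c(charToRaw("BM"), int4(offset + row_bytes * h), as.raw(rep(0, 4)),
              int4(offset),
              int4(40L), int4(w), int4(h), int2(1L), int2(8L), int4(0L),
              int4(row_bytes * h), int4(2835L), int4(2835L), int4(256L), int4(0L))
  pad <- as.raw(0)
  body <- c(px_bottom, pad, px_top, pad)  # rows bottom-up
  f <- file.path(tmp, "s.bmp")
  writeBin(c(header, palette, body), f)
  m <- read_bmp8(f)
  expect_equal(m, rbind(c(10L, 20L, 30L), c(40L, 50L, 60L)))
  vol <- read_stack(f, spacing = 0.1)
  expect_identical(dim(vol$data), c(1L, 2L, 3L))
})

test_that("mesh export writes hexahedra with named node sets in VTK and INP", {
  mask <- mask_volume(array(TRUE, c(1, 1, 1)), 1)
  roi <- list(bird = list(shape = "cuboid", center = c(1, 0.5, 0.5),
                          half = c(0.3, 1, 1), force = c(-1, 0, 0)),
              egg = list(shape = "cuboid", center = c(0.5, 0.5, 0.5),
                         half = c(1, 1, 1), force = c(-0.1, 0, 0)))
  mod <- build_model(mask, material = material_model(155, 0.3, NULL),
                     pin_plane = "BF_low", load_rois = roi)
  expect_identical(nrow(mod$nodes), 8L)
  expect_identical(nrow(mod$elements), 1L)

  tmp <- withr_local_tempdir()
  vtk <- file.path(tmp, "m.vtk")
  export_mesh(mod, vtk, "vtk")
  got <- read_vtk_mesh(vtk)
  expect_identical(got$n_nodes, 8L)
  expect_identical(got$n_elements, 1L)
  expect_identical(sort(unique(as.vector(got$cells))), 1:8)

  inp <- file.path(tmp, "m.inp")
  export_mesh(mod, inp, "inp")
  nsets <- read_inp_nsets(inp)
  expect_setequal(names(nsets), c("PINNED", "BIRD", "EGG"))
  expect_setequal(nsets$PINNED, mod$pinned_nodes)
  expect_setequal(nsets$BIRD, mod$load_sets$bird$nodes)

  # a 2x2x2 solid produces the full 27-node lattice
  mask2 <- mask_volume(array(TRUE, c(2, 2, 2)), 1)
  mod2 <- build_model(mask2, material = material_model(155, 0.3, NULL),
                      pin_plane = "BF_low")
  expect_identical(nrow(mod2$nodes), 27L)
  expect_identical(nrow(mod2$elements), 8L)
  vtk2 <- file.path(tmp, "m2.vtk")
  export_mesh(mod2, vtk2, "vtk")
  expect_identical(read_vtk_mesh(vtk2)$n_elements, 8L)
})

test_that("volume constructors enforce their invariants", {
  expect_error(voxel_volume(array(0, c(2, 2)), 1), "3D")
  expect_error(voxel_volume(array(300, c(2, 2, 2)), 1), "8-bit")
  expect_error(voxel_volume(array(1, c(2, 2, 2)), -1), "positive")
  expect_error(mask_volume(array(2, c(2, 2, 2)), 1), "0/1")
  lab <- array(0L, c(2, 2, 2)); lab[1] <- 2L
  expect_error(label_volume(lab, 1), "contiguous|gaps")
  expect_error(axis_index("XX"), "unknown axis")
  expect_equal(axis_index("rl"), 3L)
})
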