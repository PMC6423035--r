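test_that("uniaxial bar reproduces sigma = F/A exactly and u = FL/AE", {
  mod <- bar_model(length_mm = 10, side_mm = 1, spacing = 0.25,
                   E = 155, nu = 0, force = 0.1569)
  f <- solve_fe(mod, gravity = FALSE)
  # constant-stress patch state: every centroid axial stress equals F/A
  expect_lt(max(abs(f$stress_tensor[, "sxx"] - 0.1569)) / 0.1569, 1e-8)
  expect_lt(max(abs(f$stress_tensor[, -1])), 1e-10)
  expect_equal(max(f$displacements[, "ud"]), 0.1569 * 10 / (1 * 155),
               tolerance = 1e-7)
  # equilibrium: reactions balance applied loads
  tot <- f$solver_report$total_applied_N + f$solver_report$total_reaction_N
  expect_lt(max(abs(tot)) / 0.1569, 1e-6)
})

test_that("bar stress is exact at any resolution (mesh independence)", {
  for (sp in c(0.5, 0.25)) {
    mod <- bar_model(length_mm = 6, side_mm = 1, spacing = sp, nu = 0,
                     force = 0.5)
    f <- solve_fe(mod, gravity = FALSE)
    expect_lt(max(abs(f$stress_tensor[, "sxx"] - 0.5)) / 0.5, 1e-8)
  }
})

test_that("zero loads with gravity off give an identically zero field", {
  mod <- bar_model(length_mm = 4, side_mm = 1, spacing = 0.5)
  mod$load_sets <- list()
  f <- solve_fe(mod, gravity = FALSE)
  expect_true(all(f$displacements == 0))
  expect_true(all(f$stress_tensor == 0))
  expect_true(all(f$max_principal == 0))
  expect_identical(f$solver_report$iterations, 0L)
})

test_that("slender cantilever tip deflection is within 10% of PL^3/3EI", {
  # length 12 mm, 1 mm square section, 4 elements through the thickness
  sp <- 0.25
  mask <- mask_volume(array(TRUE, dim = c(4, 48, 4)), sp)
  P <- 0.01
  roi <- list(tip = list(shape = "cuboid", center = c(0.5, 12 - sp / 2, 0.5),
                         half = c(1, sp, 1), force = c(-P, 0, 0)))
  mod <- build_model(mask, material = material_model(155, 0.3, NULL),
                     pin_plane = "BF_low", load_rois = roi)
  f <- solve_fe(mod, gravity = FALSE)
  tip <- min(f$displacements[, "ud"])
  euler <- -P * 12^3 / (3 * 155 * (1 / 12))
  expect_lt(abs(tip - euler) / abs(euler), 0.10)
})

test_that("doubling the loads doubles displacements and stresses (linearity)", {
  mod <- bar_model(length_mm = 5, side_mm = 1, spacing = 0.25, nu = 0.3,
                   force = 0.2)
  f1 <- solve_fe(mod, gravity = FALSE)
  mod2 <- mod
  mod2$load_sets$top$force <- mod$load_sets$top$force * 2
  f2 <- solve_fe(mod2, gravity = FALSE)
  expect_equal(f2$displacements, 2 * f1$displacements, tolerance = 1e-6)
  expect_lt(max(abs(f2$stress_tensor - 2 * f1$stress_tensor)),
            1e-6 * max(abs(f2$stress_tensor)))
})

test_that("gravity body force balances the calibrated weight", {
  mask <- mask_volume(array(TRUE, dim = c(8, 4, 4)), 0.5)
  gray <- voxel_volume(array(100, dim = c(8, 4, 4)), 0.5)
  mod <- build_model(mask, gray, material_model(155, 0.3, total_mass = 5.93),
                     pin_plane = "BF_low")
  # uniform grayscale -> equal densities summing exactly to the target mass
  expect_equal(length(unique(mod$material$density_field)), 1L)
  mass_g <- sum(mod$material$density_field) * 0.5^3 * 1e6
  expect_equal(mass_g, 5.93, tolerance = 1e-9)
  f <- solve_fe(mod, gravity = TRUE)
  w <- 5.93e-6 * STANDARD_GRAVITY_MM_S2  # N
  expect_equal(f$solver_report$total_applied_N[1], -w, tolerance = 1e-9)
  expect_equal(f$solver_report$total_reaction_N[1], w, tolerance = 1e-6 * w)
  expect_error(solve_fe(build_model(mask, material = material_model(155, 0.3, NULL),
                                    pin_plane = "BF_low"), gravity = TRUE),
               "total_mass")
})

test_that("principal stresses match closed forms", {
  uni <- diag(c(2, 0, 0))
  expect_equal(principal_stress(uni), c(2, 0, 0))
  shear <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(principal_stress(shear), c(1, 0, -1))
  hydro <- diag(rep(-3, 3))
  expect_equal(principal_stress(hydro), c(-3, -3, -3))
  expect_error(principal_stress(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
  expect_error(principal_stress(diag(2)), "3x3")
})

test_that("vectorized max principal agrees with per-element eigen decomposition", {
  set.seed(99)
  S <- matrix(stats::rnorm(6 * 200), 200, 6)
  S <- rbind(S, c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 0, 0, 0), c(5, -2, 1, 0, 0, 0))
  got <- nestmech:::.max_principal(S)
  ref <- apply(S, 1, function(r) {
    m <- matrix(c(r[1], r[4], r[6], r[4], r[2], r[5], r[6], r[5], r[3]), 3, 3)
    max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("rotating geometry and loads together permutes the stress field", {
  # bar along B-F loaded axially vs the same bar rotated to run along R-L
  sp <- 0.5
  mask_bf <- mask_volume(array(TRUE, dim = c(2, 12, 2)), sp)
  roi_bf <- list(tip = list(shape = "cuboid", center = c(0.5, 6, 0.5),
                            half = c(1, sp * 0.8, 1), force = c(0, 0.3, 0)))
  mod_bf <- build_model(mask_bf, material = material_model(155, 0.3, NULL),
                        pin_plane = "BF_low", load_rois = roi_bf)
  f_bf <- solve_fe(mod_bf, gravity = FALSE)

  mask_rl <- mask_volume(array(TRUE, dim = c(2, 2, 12)), sp)
  roi_rl <- list(tip = list(shape = "cuboid", center = c(0.5, 0.5, 6),
                            half = c(1, 1, sp * 0.8), force = c(0, 0, 0.3)))
  mod_rl <- build_model(mask_rl, material = material_model(155, 0.3, NULL),
                        pin_plane = "RL_low", load_rois = roi_rl)
  f_rl <- solve_fe(mod_rl, gravity = FALSE)

  # match elements through the axis swap (BF <-> RL) and compare swapped
  # tensor components: sxx<->sxx, syy<->szz, txy<->tzx, tyz<->tyz
  co_bf <- arrayInd(mod_bf$vox_idx, mod_bf$dims)
  co_rl <- arrayInd(mod_rl$vox_idx, mod_rl$dims)
  key_bf <- paste(co_bf[, 1], co_bf[, 2], co_bf[, 3])
  key_rl <- paste(co_rl[, 1], co_rl[, 3], co_rl[, 2])
  map <- match(key_bf, key_rl)
  expect_false(anyNA(map))
  got <- f_rl$stress_tensor[map, c("sxx", "szz", "syy", "tzx", "tyz", "txy")]
  expect_equal(unname(got), unname(f_bf$stress_tensor), tolerance = 1e-6)
})

test_that("model construction validates pins, ROIs and density inputs", {
  mask <- mask_volume(array(TRUE, c(2, 2, 2)), 1)
  expect_error(build_model(mask_volume(array(FALSE, c(2, 2, 2)), 1)),
               "mask is empty")
  roi_air <- list(air = list(shape = "cuboid", center = c(50, 50, 50),
                             half = c(1, 1, 1), force = c(-1, 0, 0)))
  expect_error(build_model(mask, material = material_model(155, 0.3, NULL),
                           load_rois = roi_air), "intersects no material")
  gray_bad <- voxel_volume(array(0, c(2, 2, 2)), 1)
  expect_error(build_model(mask, gray_bad, material_model(155, 0.3, 5.93)),
               "grayscale weights")
  expect_error(material_model(E = -1), "E must be")
  expect_error(material_model(nu = 0.5), "nu")
})

test_that("damage removal matches the digitized-ball oracle and guards the wall", {
  mask <- mask_volume(array(TRUE, c(20, 20, 20)), 1)
  # zero radius is the identity
  same <- apply_damage(mask, list(list(center = c(10, 10, 10), radius = 0)))
  expect_identical(same$data, mask$data)
  # ball fully inside: removed count equals the voxel-counting oracle
  r <- 4.3
  dam <- apply_damage(mask, list(list(center = c(10.5, 10.5, 10.5), radius = r)))
  grid <- expand.grid(i = 1:20, j = 1:20, k = 1:20)
  oracle <- sum((grid$i - 0.5 - 10.5)^2 + (grid$j - 0.5 - 10.5)^2 +
                  (grid$k - 0.5 - 10.5)^2 < r^2)
  expect_identical(sum(mask$data) - sum(dam$data), as.integer(oracle))
  expect_error(apply_damage(mask, list(list(center = c(100, 0, 0), radius = 1))),
               "outside the volume")
  # removing the whole pinned face is an explicit error
  thin <- mask_volume(array(TRUE, c(4, 4, 4)), 1)
  expect_error(apply_damage(thin, list(list(center = c(2, 0, 2), radius = 50))),
               "pinned face")
})
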