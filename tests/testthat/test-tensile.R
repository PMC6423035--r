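test_that("stress and strain follow sigma = F/A0 and eps = dL/L0 with unit handling", {
  rec <- tensile_record(force = c(0, 1, 2), displacement = c(0, 50, 100),
                        disp_unit = "um", A0 = 1, L0 = 10, cut_angle = 0)
  cur <- to_stress_strain(rec)
  expect_equal(cur$stress, c(0, 1, 2))                # 2 N / 1 mm^2 = 2 MPa
  expect_equal(cur$strain, c(0, 0.005, 0.01))         # 0.1 mm / 10 mm = 0.01
  rec_mm <- tensile_record(force = c(0, 1, 2), displacement = c(0, 0.05, 0.1),
                           disp_unit = "mm", A0 = 1, L0 = 10)
  expect_equal(to_stress_strain(rec_mm)$strain, cur$strain)
  # doubling A0 halves every stress and the peak exactly (linearity)
  rec2 <- tensile_record(c(0, 1, 2), c(0, 50, 100), "um", A0 = 2, L0 = 10)
  cur2 <- to_stress_strain(rec2)
  expect_equal(cur2$stress, cur$stress / 2)
  expect_equal(cur2$sigma_peak, cur$sigma_peak / 2)
})

test_that("record validation: unit tag, positivity, monotone displacement", {
  expect_error(tensile_record(1:5, 1:5, A0 = 1, L0 = 1), "unit tag")
  expect_error(tensile_record(1:5, 1:5, "um", A0 = 0, L0 = 1), "A0")
  expect_error(tensile_record(1:5, 1:5, "um", A0 = 1, L0 = -2), "L0")
  expect_error(tensile_record(1:5, c(1, 3, 2, 4, 5), "um", 1, 1),
               "non-decreasing")
  expect_error(tensile_record(1:2, 1:2, "um", 1, 1), "length")
})

test_that("modulus: exact on a line, robust to toe and softening branches", {
  # exact line through the origin, slope 100
  eps <- seq(0, 0.02, by = 0.0005)
  lin <- structure(list(stress = 100 * eps, strain = eps),
                   class = "stress_strain_curve")
  expect_equal(extract_modulus(lin)$E, 100, tolerance = 1e-12)

  # synthetic linear record at the published modulus: sigma = 155 eps
  rec <- tensile_record(155 * eps * 1.2, eps * 10 * 1000, "um", A0 = 1.2,
                        L0 = 10)
  expect_equal(signif(to_stress_strain(rec)$E, 3), 155)

  # toe artifact below eps = 0.002 must not bias the fit (piecewise oracle)
  toe_eps <- seq(0, 0.002, by = 1e-4)
  toe_sig <- 20 * toe_eps                      # shallow toe, slope 20
  main_eps <- seq(0.0021, 0.02, by = 1e-4)
  main_sig <- toe_sig[length(toe_sig)] + 200 * (main_eps - 0.002)
  toe_curve <- structure(list(stress = c(toe_sig, main_sig),
                              strain = c(toe_eps, main_eps)),
                         class = "stress_strain_curve")
  expect_lt(abs(extract_modulus(toe_curve)$E - 200) / 200, 0.01)

  # bilinear softening after 0.5 sigma_peak is excluded from the window
  e1 <- seq(0, 0.01, by = 2e-4)                # slope 300 up to sigma 3
  e2 <- seq(0.0102, 0.03, by = 2e-4)           # slope 50 afterwards, peak 3.99
  soft <- structure(list(stress = c(300 * e1, 3 + 50 * (e2 - 0.01)),
                         strain = c(e1, e2)),
                    class = "stress_strain_curve")
  em <- extract_modulus(soft)
  # 0.5 * peak = 1.995 is reached on the first branch -> pure slope 300
  expect_lt(abs(em$E - 300) / 300, 0.01)
  expect_lt(em$window[2], 0.01)

  flat <- structure(list(stress = rep(1, 10), strain = rep(0.001, 10)),
                    class = "stress_strain_curve")
  expect_error(extract_modulus(flat), "degenerate")
})

test_that("failure detection: peak, cliff, flags and drop events", {
  # monotone rise then cliff to zero
  eps <- seq(0, 0.1, by = 0.01)
  sig <- c(seq(0, 2, length.out = 10), 0)
  f <- detect_failure(structure(list(stress = sig, strain = eps),
                                class = "stress_strain_curve"))
  expect_equal(f$sigma_peak, 2)
  expect_equal(f$eps_fracture, 0.1)
  expect_false(f$flagged)

  # three engineered step drops -> exactly three drop events before failure
  eps2 <- seq(0, 0.13, by = 0.001)
  sig2 <- ifelse(eps2 <= 0.05, 40 * eps2, 2)
  sig2[eps2 > 0.07] <- 1.6
  sig2[eps2 > 0.09] <- 1.25
  sig2[eps2 > 0.11] <- 0.95
  f2 <- detect_failure(structure(list(stress = sig2, strain = eps2),
                                 class = "stress_strain_curve"))
  expect_identical(nrow(f2$drop_events), 3L)
  expect_true(f2$flagged)  # never fell below 0.1 * peak
  expect_equal(f2$eps_fracture, 0.13)

  # simulated mat fails near eps = 0.125, within the sampling step
  rec <- simulate_tensile_cohort(n = 1, seed = 11)[[1]]
  cur <- to_stress_strain(rec)
  step <- diff(cur$strain)[1]
  expect_lt(abs(cur$eps_fracture - 0.125), step + 1e-9)
  expect_gte(nrow(cur$drop_events), 3L)
})

test_that("aggregation: means, SD convention, permutation invariance, recovery", {
  c1 <- to_stress_strain(tensile_record(c(0, 1, 2), c(0, 50, 100), "um", 1, 10, 0, "a"))
  c2 <- to_stress_strain(tensile_record(c(0, 1.5, 3), c(0, 50, 100), "um", 1, 10, 90, "b"))
  agg <- aggregate_curves(list(c1, c2))
  expect_equal(agg$mean_sigma_f, 2.5)        # peaks 2 and 3
  expect_equal(agg$sd_sigma_f, stats::sd(c(2, 3)))
  expect_identical(agg$n_specimens, 2L)
  expect_equal(agg$by_orientation$cut_angle, c(0, 90))
  # single curve: mean = value, SD undefined by convention
  agg1 <- aggregate_curves(list(c1))
  expect_equal(agg1$mean_sigma_f, 2)
  expect_true(is.na(agg1$sd_sigma_f))
  # permutation invariance
  agg_rev <- aggregate_curves(list(c2, c1))
  expect_equal(agg_rev$mean_sigma_f, agg$mean_sigma_f)
  expect_equal(agg_rev$sd_sigma_f, agg$sd_sigma_f)
  expect_error(aggregate_curves(list()), "at least one")

  # Monte-Carlo cohort with known generator: mean recovered within 2 SE
  recs <- simulate_tensile_cohort(n = 30, mean_sigma_f = 2.75,
                                  sd_sigma_f = 0.79, seed = 7L)
  curves <- lapply(recs, to_stress_strain)
  agg30 <- aggregate_curves(curves)
  se <- 0.79 / sqrt(30)
  expect_lt(abs(agg30$mean_sigma_f - 2.75), 2 * se)
  expect_lt(abs(agg30$mean_E - 155) / 155, 0.1)
})

test_that("tensile CSV round-trips through read_tensile_csv", {
  tmp <- withr_local_tempdir()
  recs <- simulate_tensile_cohort(n = 4, seed = 3L)
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(specimen_id = r$specimen_id, force_N = r$force,
               displacement_um = r$displacement, A0_mm2 = r$A0, L0_mm = r$L0,
               cut_angle_deg = r$cut_angle)))
  f <- file.path(tmp, "spec.csv")
  utils::write.csv(df, f, row.names = FALSE)
  back <- read_tensile_csv(f)
  expect_identical(length(back), 4L)
  orig <- recs[[1]]
  got <- back[[orig$specimen_id]]
  expect_equal(got$force, orig$force)
  expect_equal(got$A0, orig$A0)
  expect_error(read_tensile_csv({
    f2 <- file.path(tmp, "bad.csv")
    utils::write.csv(df[, -2], f2, row.names = FALSE); f2
  }), "missing columns")
})
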