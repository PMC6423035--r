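# Reduction of tensile force-displacement records to engineering stress-strain
# curves: sigma = F/A0, eps = dL/L0 (no smoothing), elastic modulus from an
# ordinary least-squares fit over the linear regime, peak (fracture) stress,
# strain to fracture and post-peak stress-drop events, with aggregation over
# specimens by cut orientation.

#' A tensile force-displacement record
#'
#' @param force Force series (N).
#' @param displacement Extension series, same length as `force`,
#'   non-decreasing.
#' @param disp_unit Unit of `displacement`: `"um"` or `"mm"` (must be stated).
#' @param A0 Initial cross-section area (mm^2).
#' @param L0 Gauge length (mm).
#' @param cut_angle Cut orientation in degrees: 0 (longitudinal), 45 or 90
#'   (transverse).
#' @param specimen_id Identifier string.
#' @return A `tensile_record`.
#' @export
tensile_record <- function(force, displacement, disp_unit, A0, L0,
                           cut_angle = 0, specimen_id = "specimen") {
  if (missing(disp_unit) || !disp_unit %in% c("um", "mm"))
    stop("displacement unit tag missing or invalid (need 'um' or 'mm')")
  if (length(force) != length(displacement) || length(force) < 3L)
    stop("force and displacement must have equal length >= 3")
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be > 0")
  if (!is.finite(L0) || L0 <= 0) stop("L0 must be > 0")
  if (any(diff(displacement) < 0)) stop("displacement must be non-decreasing")
  if (!cut_angle %in% c(0, 45, 90)) stop("cut_angle must be 0, 45 or 90")
  structure(list(force = as.numeric(force),
                 displacement = as.numeric(displacement),
                 disp_unit = disp_unit, A0 = A0, L0 = L0,
                 cut_angle = cut_angle, specimen_id = specimen_id),
            class = "tensile_record")
}

#' Convert a tensile record to an engineering stress-strain curve
#'
#' `sigma_i = F_i / A0` (MPa with F in N and A0 in mm^2) and
#' `eps_i = dL_i / L0` after unit normalization; no smoothing is applied.
#' Modulus, peak stress and failure quantities are extracted with
#' [extract_modulus()] and [detect_failure()].
#'
#' @param rec A [tensile_record()].
#' @param fit_window Strain window passed to [extract_modulus()].
#' @return A `stress_strain_curve`: list with `stress` (MPa), `strain`, `E`
#'   (MPa), `sigma_peak` (MPa), `eps_fracture`, `fit_window`, `drop_events`,
#'   `cut_angle`, `specimen_id`.
#' @export
to_stress_strain <- function(rec, fit_window = NULL) {
  if (!inherits(rec, "tensile_record")) stop("rec must be a tensile_record")
  dl_mm <- if (rec$disp_unit == "um") rec$displacement / 1000 else rec$displacement
  curve <- structure(list(stress = rec$force / rec$A0,
                          strain = dl_mm / rec$L0,
                          E = NA_real_, sigma_peak = NA_real_,
                          eps_fracture = NA_real_, fit_window = NULL,
                          drop_events = NULL,
                          cut_angle = rec$cut_angle,
                          specimen_id = rec$specimen_id),
                     class = "stress_strain_curve")
  fail <- detect_failure(curve)
  curve$sigma_peak <- fail$sigma_peak
  curve$eps_fracture <- fail$eps_fracture
  curve$fracture_flagged <- fail$flagged
  curve$drop_events <- fail$drop_events
  em <- extract_modulus(curve, window = fit_window)
  curve$E <- em$E
  curve$fit_window <- em$window
  curve
}

#' Elastic modulus from the linear regime
#'
#' Ordinary least-squares slope of stress vs strain over the window
#' `eps in [toe, eps(0.5 * sigma_peak)]` (default toe 0.002), which excludes
#' the seating toe and the nonlinear pre-peak branch. When the default window
#' holds fewer than 5 samples the fit falls back to the first half of the
#' pre-peak strain range. The window actually used is returned.
#'
#' @param curve A `stress_strain_curve` (or any list with `stress`/`strain`).
#' @param window Optional explicit `(eps_lo, eps_hi)` window.
#' @param toe Lower strain bound of the default window.
#' @return List with `E` (MPa) and `window` (the fitted strain bounds).
#' @export
extract_modulus <- function(curve, window = NULL, toe = 0.002) {
  eps <- curve$strain; sig <- curve$stress
  ipk <- which.max(sig)
  if (is.null(window)) {
    half <- sig[ipk] / 2
    cross <- which(sig[seq_len(ipk)] >= half)[1]
    hi <- if (is.na(cross)) eps[ipk] else eps[cross]
    window <- c(toe, hi)
  }
  sel <- which(eps >= window[1] & eps <= window[2] & seq_along(eps) <= ipk)
  if (length(sel) < 5L) {
    # fallback: first half of the pre-peak strain range
    window <- c(min(eps), min(eps) + (eps[ipk] - min(eps)) / 2)
    sel <- which(eps >= window[1] & eps <= window[2] & seq_along(eps) <= ipk)
  }
  if (length(sel) < 2L || diff(range(eps[sel])) == 0)
    stop("degenerate modulus window: strain is constant over the fit range")
  fit <- stats::lm.fit(cbind(1, eps[sel]), sig[sel])
  list(E = unname(fit$coefficients[2]), window = window)
}

#' Peak stress, strain to fracture and stress-drop events
#'
#' `sigma_peak` is the global maximum of the stress series. Strain to fracture
#' is the strain at the first post-peak sample with stress below
#' `fail_frac * sigma_peak` (default 0.1); if the series never drops that far,
#' the final strain is returned and flagged. Drop events are post-peak
#' decreases between consecutive samples exceeding `drop_frac * sigma_peak`
#' (default 0.05), the signature of individual fiber failures before ultimate
#' failure.
#'
#' @param curve A `stress_strain_curve`.
#' @param fail_frac Failure threshold as a fraction of peak stress.
#' @param drop_frac Drop-event threshold as a fraction of peak stress.
#' @return List with `sigma_peak`, `eps_fracture`, `flagged` (TRUE when the
#'   curve never dropped below the failure threshold) and `drop_events` (data
#'   frame of post-peak drops: sample index, strain, drop magnitude in MPa).
#' @export
detect_failure <- function(curve, fail_frac = 0.1, drop_frac = 0.05) {
  sig <- curve$stress; eps <- curve$strain
  ipk <- which.max(sig)
  sigma_peak <- sig[ipk]
  post <- seq_along(sig) > ipk
  below <- which(post & sig < fail_frac * sigma_peak)
  if (length(below)) {
    eps_fr <- eps[below[1]]; flagged <- FALSE
  } else {
    eps_fr <- eps[length(eps)]; flagged <- TRUE
  }
  dec <- -diff(sig)
  idx <- which(dec > drop_frac * sigma_peak & seq_along(dec) >= ipk)
  drops <- data.frame(index = idx + 1L, strain = eps[idx + 1L],
                      drop_mpa = dec[idx])
  list(sigma_peak = sigma_peak, eps_fracture = eps_fr, flagged = flagged,
       drop_events = drops)
}

#' Aggregate stress-strain curves into a material summary
#'
#' Unweighted mean and sample (n-1) standard deviation of peak stress and
#' modulus, overall and by cut orientation. With a single specimen the SD is
#' reported as `NA` (undefined, by convention).
#'
#' @param curves List of `stress_strain_curve`s.
#' @return A `material_summary`: list with `mean_sigma_f`, `sd_sigma_f`,
#'   `mean_E`, `sd_E`, `n_specimens` and `by_orientation` (data frame).
#' @export
aggregate_curves <- function(curves) {
  if (length(curves) < 1L) stop("need at least one curve")
  peaks <- vapply(curves, `[[`, 0, "sigma_peak")
  mods <- vapply(curves, `[[`, 0, "E")
  angs <- vapply(curves, `[[`, 0, "cut_angle")
  sd1 <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  by <- do.call(rbind, lapply(sort(unique(angs)), function(a) {
    i <- angs == a
    data.frame(cut_angle = a, n = sum(i),
               mean_sigma_f = mean(peaks[i]), sd_sigma_f = sd1(peaks[i]),
               mean_E = mean(mods[i]), sd_E = sd1(mods[i]))
  }))
  structure(list(mean_sigma_f = mean(peaks), sd_sigma_f = sd1(peaks),
                 mean_E = mean(mods), sd_E = sd1(mods),
                 n_specimens = length(curves), by_orientation = by),
            class = "material_summary")
}

#' @export
print.material_summary <- function(x, ...) {
  cat(sprintf("material summary (n = %d): fracture stress %.3f +/- %.3f MPa, E %.1f MPa\n",
              x$n_specimens, x$mean_sigma_f, x$sd_sigma_f, x$mean_E))
  invisible(x)
}

#' Read tensile records from CSV
#'
#' Expected columns: `specimen_id`, `force_N`, `displacement_um`, `A0_mm2`,
#' `L0_mm`, `cut_angle_deg`; one row per sample, rows grouped by specimen in
#' acquisition order.
#'
#' @param path CSV file.
#' @return List of [tensile_record()]s.
#' @export
read_tensile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("specimen_id", "force_N", "displacement_um", "A0_mm2", "L0_mm",
            "cut_angle_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  lapply(split(df, df$specimen_id), function(g)
    tensile_record(g$force_N, g$displacement_um, "um", g$A0_mm2[1], g$L0_mm[1],
                   g$cut_angle_deg[1], as.character(g$specimen_id[1])))
}

#' Simulate a cohort of tensile records
#'
#' Synthetic specimens with a seating toe, a linear elastic regime, mild
#' pre-peak softening, discrete post-peak fiber-failure stress drops and final
#' failure near a prescribed strain. Peak stresses are drawn from a normal
#' distribution (negative draws are rejected); per-specimen moduli scatter
#' around `E_mean`. Used as the generator for recovery tests and as a stand-in
#' for measured curves.
#'
#' @param n Number of specimens.
#' @param mean_sigma_f,sd_sigma_f Peak-stress distribution (MPa).
#' @param E_mean Mean elastic modulus (MPa).
#' @param eps_fail Nominal strain to fracture.
#' @param cut_angles Angles cycled over specimens.
#' @param n_drops Post-peak fiber-failure drops per specimen.
#' @param seed Integer seed.
#' @return List of [tensile_record()]s.
#' @export
simulate_tensile_cohort <- function(n = 30, mean_sigma_f = 2.75,
                                    sd_sigma_f = 0.79, E_mean = 155,
                                    eps_fail = 0.125,
                                    cut_angles = c(0, 45, 90),
                                    n_drops = 3, seed = 7L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  A0 <- 1.2; L0 <- 10  # mm^2, mm
  lapply(seq_len(n), function(i) {
    sig_pk <- -1
    while (sig_pk <= 0.2) sig_pk <- stats::rnorm(1, mean_sigma_f, sd_sigma_f)
    E <- E_mean * stats::rlnorm(1, 0, 0.05)
    ang <- cut_angles[(i - 1) %% length(cut_angles) + 1]
    toe <- 0.0015
    # piecewise: quadratic toe -> linear regime (slope E) up to 0.6*sig_pk ->
    # parabolic cap tangent at both ends, apex (zero slope) at the peak
    sig_y <- 0.6 * sig_pk
    eps_y <- sig_y / E + toe / 2
    eps_pk <- eps_y + 2 * (sig_pk - sig_y) / E
    cc <- E^2 / (4 * (sig_pk - sig_y))
    eps <- seq(0, eps_fail * 1.15, length.out = 400)
    sig <- ifelse(eps < toe, 0.5 * E * eps^2 / toe,
           ifelse(eps < eps_y, E * (eps - toe / 2),
           ifelse(eps <= eps_pk, sig_pk - cc * (eps_pk - eps)^2, sig_pk)))
    # post-peak: staircase of fiber-failure drops, then failure
    if (any(eps > eps_pk)) {
      drop_eps <- seq(eps_pk, eps_fail, length.out = n_drops + 2)[2:(n_drops + 1)]
      level <- sig_pk
      for (de in drop_eps) {
        level <- level * 0.72
        sig[eps >= de] <- level
      }
      sig[eps >= eps_fail] <- 0.02 * sig_pk
    }
    force <- sig * A0
    tensile_record(force, eps * L0 * 1000, "um", A0, L0, ang,
                   sprintf("sim_%02d", i))
  })
}
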