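# Loading scenarios on a segmented (or phantom) nest: the worst case (two
# birds on the rim plus two eggs on the cup floor), eggs only, and the worst
# case on a locally damaged structure. Region statistics (rim band, egg
# region, anchor band) and the safety factor against the material's tensile
# fracture strength are reported; fracture strength enters only as a
# reporting threshold, never as a solver parameter.

#' Convert a mass to its weight under standard gravity
#'
#' `F = m * g` with g = 9.80665 m/s^2, truncated (not rounded) to 4 decimals
#' by convention, so 16 g -> 0.1569 N and 1.2 g -> 0.0117 N.
#'
#' @param mass_g Mass in grams.
#' @param truncate Truncate to 4 decimals (default TRUE).
#' @return Force in N.
#' @export
load_force_n <- function(mass_g, truncate = TRUE) {
  f <- mass_g * 1e-3 * 9.80665
  if (truncate) trunc(f * 1e4) / 1e4 else f
}

#' Scenario configuration
#'
#' Defaults: bird mass 16 g and egg mass 1.2 g (weights 0.1569 N and
#' 0.0117 N), bird footprints 5 x 5 mm cuboids placed on the rim at +/-45
#' degrees from the front midline (maximizing the moment arm about the wall
#' while matching observed standing positions), egg contact patches as
#' 10 x 6 mm ellipsoids beside the cup-floor low point, a 2.5 mm damage ball
#' under one bird site for the damaged scenario, and fracture strength
#' 2.75 MPa. Rim/anchor band fractions (10%) define reporting regions only.
#'
#' @param bird_mass_g,egg_mass_g Masses (g).
#' @param bird_angle_deg Bird positions, +/- this angle from the front midline.
#' @param bird_foot_mm Bird cuboid half-extents will be half of these
#'   footprint sides (B-F, R-L), in mm.
#' @param bird_depth_mm Vertical (U-D) extent of the bird contact cuboid.
#' @param egg_semi_mm Egg patch ellipsoid semi-axes (U-D, B-F, R-L), mm.
#' @param egg_offset_rl_mm Egg centers at +/- this R-L offset from the midline.
#' @param damage_radius_mm,damage_below_mm Damaged-scenario ball radius and
#'   depth below the rim at the first bird site.
#' @param fracture_strength_mpa Tensile fracture strength (MPa) used for the
#'   safety factor.
#' @param rim_band_frac,anchor_band_frac Region definitions: top fraction of
#'   the material U-D extent (rim) and fraction of the B-F extent from the
#'   wall (anchor).
#' @param egg_region_dilate Egg-region elements lie within the egg ROIs
#'   dilated by this factor.
#' @param material A [material_model()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(bird_mass_g = 16, egg_mass_g = 1.2,
                            bird_angle_deg = 45, bird_foot_mm = c(5, 5),
                            bird_depth_mm = 3, egg_semi_mm = c(2, 5, 3),
                            egg_offset_rl_mm = 5,
                            damage_radius_mm = 2.5, damage_below_mm = 4,
                            fracture_strength_mpa = 2.75,
                            rim_band_frac = 0.10, anchor_band_frac = 0.10,
                            egg_region_dilate = 1.5,
                            material = material_model()) {
  structure(list(bird_mass_g = bird_mass_g, egg_mass_g = egg_mass_g,
                 bird_angle_deg = bird_angle_deg, bird_foot_mm = bird_foot_mm,
                 bird_depth_mm = bird_depth_mm, egg_semi_mm = egg_semi_mm,
                 egg_offset_rl_mm = egg_offset_rl_mm,
                 damage_radius_mm = damage_radius_mm,
                 damage_below_mm = damage_below_mm,
                 fracture_strength_mpa = fracture_strength_mpa,
                 rim_band_frac = rim_band_frac,
                 anchor_band_frac = anchor_band_frac,
                 egg_region_dilate = egg_region_dilate,
                 material = material),
            class = "scenario_config")
}

# Geometric feature detection on the material mask: rim ring (top band of the
# material), bird standing points at +/- angle from the front midline on the
# ring's outermost band, and the cup-floor low point (lowest upward-exposed
# material voxel in the central region, below the rim).
.detect_features <- function(mask, config) {
  m <- mask$data
  s <- spacing_mm(mask)
  d <- dim(m)
  idx <- which(m)
  co <- arrayInd(idx, d)
  ud <- (co[, 1] - 0.5) * s
  bf <- (co[, 2] - 0.5) * s
  rl <- (co[, 3] - 0.5) * s
  ud_top <- max(ud)
  rl_c <- (min(rl) + max(rl)) / 2

  # rim ring: material within 2 voxels of the top
  ring <- ud >= ud_top - 2 * s
  if (!any(ring)) stop("rim detection failed: no material near the top")
  ang <- atan2(rl[ring] - rl_c, bf[ring]) * 180 / pi
  rad <- sqrt((rl[ring] - rl_c)^2 + bf[ring]^2)
  bird_pt <- function(theta) {
    sel <- which(abs(ang - theta) <= 12)
    if (!length(sel)) sel <- which(abs(ang - theta) <= 30)
    if (!length(sel))
      stop("rim detection failed: no rim material near ", theta, " degrees")
    b <- sel[which.max(rad[sel])]  # outermost band of the rim
    c(ud = ud_top, bf = bf[ring][b], rl = rl[ring][b])
  }
  birds <- list(bird_pt(config$bird_angle_deg), bird_pt(-config$bird_angle_deg))

  # cup floor: lowest upward-exposed voxel in the central half (R-L), below
  # the rim band
  up_exposed <- m & !(
    { shifted <- array(FALSE, d); shifted[1:(d[1] - 1), , ] <- m[2:d[1], , ]; shifted })
  uidx <- which(up_exposed)
  uco <- arrayInd(uidx, d)
  uud <- (uco[, 1] - 0.5) * s
  ubf <- (uco[, 2] - 0.5) * s
  url <- (uco[, 3] - 0.5) * s
  cen <- abs(url - rl_c) <= (max(rl) - min(rl)) / 4 & uud < ud_top - 4 * s
  if (!any(cen)) stop("floor detection failed: no interior floor found")
  flo <- which(cen)[which.min(uud[cen])]
  floor_pt <- c(ud = uud[flo], bf = ubf[flo], rl = url[flo])

  list(ud_top = ud_top, rl_center = rl_c, birds = birds, floor = floor_pt)
}

.scenario_rois <- function(mask, config) {
  feats <- .detect_features(mask, config)
  rois <- list()
  f_bird <- load_force_n(config$bird_mass_g)
  f_egg <- load_force_n(config$egg_mass_g)
  for (b in 1:2) {
    pt <- feats$birds[[b]]
    rois[[paste0("bird_", b)]] <- list(
      shape = "cuboid",
      center = c(pt["ud"] - config$bird_depth_mm / 2, pt["bf"], pt["rl"]),
      half = c(config$bird_depth_mm / 2, config$bird_foot_mm[1] / 2,
               config$bird_foot_mm[2] / 2),
      force = c(-f_bird, 0, 0))
  }
  for (e in 1:2) {
    off <- config$egg_offset_rl_mm * c(1, -1)[e]
    rois[[paste0("egg_", e)]] <- list(
      shape = "ellipsoid",
      center = c(feats$floor["ud"] + config$egg_semi_mm[1] / 2,
                 feats$floor["bf"], feats$rl_center + off),
      half = config$egg_semi_mm,
      force = c(-f_egg, 0, 0))
  }
  list(rois = rois, features = feats)
}

#' Assemble a named loading scenario
#'
#' `"worst_case"`: two bird cuboids on the rim placed symmetrically about the
#' front midline plus two egg patches at the cup-floor low point.
#' `"eggs_only"`: the two egg patches alone. `"damaged"`: the worst case on a
#' mask with a spherical damage site carved just below the first bird stand
#' (free-floating fragments produced by the damage are dropped before
#' meshing). The same geometry and parameters always resolve to identical
#' node sets.
#'
#' @param name `"worst_case"`, `"eggs_only"` or `"damaged"`.
#' @param mask Material [mask_volume()] (wall face at the low B-F boundary).
#' @param gray Optional matching [voxel_volume()] for relative density.
#' @param config A [scenario_config()].
#' @return An `fe_model` with a `scenario` attribute (name, config, egg ROI
#'   geometry for region statistics).
#' @export
make_scenario <- function(name = c("worst_case", "eggs_only", "damaged"),
                          mask, gray = NULL, config = scenario_config()) {
  name <- match.arg(name)
  sr <- .scenario_rois(mask, config)
  if (name == "damaged") {
    pt <- sr$features$birds[[1]]
    site <- list(center = c(pt["ud"] - config$damage_below_mm, pt["bf"], pt["rl"]),
                 radius = config$damage_radius_mm)
    mask <- apply_damage(mask, list(site))
    mask <- keep_largest_component(mask)
    sr <- .scenario_rois(mask, config)  # re-resolve on the damaged geometry
  }
  rois <- switch(name,
                 worst_case = sr$rois,
                 damaged = sr$rois,
                 eggs_only = sr$rois[grep("^egg_", names(sr$rois))])
  model <- build_model(mask, gray, config$material, "BF_low", rois)
  model$scenario <- list(name = name, config = config,
                         egg_rois = sr$rois[grep("^egg_", names(sr$rois))],
                         features = sr$features)
  model
}

#' Run a loading scenario and report region statistics
#'
#' Solves the model (gravity on by default), then reports the global maximum
#' principal stress with its location, per-region statistics (rim band = top
#' `rim_band_frac` of the material U-D extent; anchor band = material within
#' `anchor_band_frac` of the B-F extent from the wall; egg region = elements
#' inside the dilated egg ROIs) and the safety factor
#' `fracture_strength / global max` (infinite, flagged, for a stress-free
#' model).
#'
#' @param model An `fe_model` from [make_scenario()].
#' @param fracture_strength Tensile fracture strength (MPa).
#' @param gravity Include self-weight (default TRUE).
#' @param ... Passed to [solve_fe()] (e.g. `method`, `tol`).
#' @return A `scenario_report`: scenario name, `global_max` (MPa, element
#'   index and mm coordinates), `region_stats` data frame, `safety_factor`,
#'   `field` (the [solve_fe()] result) and solver metadata.
#' @export
run_scenario <- function(model, fracture_strength = 2.75, gravity = TRUE, ...) {
  field <- solve_fe(model, gravity = gravity, ...)
  h <- model$spacing
  co <- arrayInd(model$vox_idx, model$dims)
  cen <- (co - 0.5) * h  # element centroids, mm
  mp <- field$max_principal

  ud_rng <- range(cen[, 1])
  bf_rng <- range(cen[, 2])
  cfg <- if (!is.null(model$scenario)) model$scenario$config else scenario_config()
  rim <- cen[, 1] >= ud_rng[2] - cfg$rim_band_frac * diff(ud_rng)
  anchor <- cen[, 2] <= bf_rng[1] + cfg$anchor_band_frac * diff(bf_rng)
  egg <- rep(FALSE, nrow(cen))
  if (!is.null(model$scenario)) {
    for (roi in model$scenario$egg_rois) {
      rel <- sweep(cen, 2, roi$center)
      egg <- egg | rowSums(sweep(rel, 2, roi$half * cfg$egg_region_dilate, "/")^2) <= 1
    }
  }
  reg <- function(name, sel) data.frame(
    region = name, n_elements = sum(sel),
    mean_mpa = if (any(sel)) mean(mp[sel]) else NA_real_,
    max_mpa = if (any(sel)) max(mp[sel]) else NA_real_)
  stats <- rbind(reg("rim_band", rim), reg("egg_region", egg),
                 reg("anchor_band", anchor), reg("global", rep(TRUE, length(mp))))

  imax <- which.max(mp)
  gmax <- mp[imax]
  sf <- if (gmax > 0) fracture_strength / gmax else Inf
  structure(list(
    scenario = if (!is.null(model$scenario)) model$scenario$name else "custom",
    global_max = list(value = gmax, element = imax, location_mm = cen[imax, ]),
    region_stats = stats,
    fracture_strength = fracture_strength,
    safety_factor = sf,
    stress_free = gmax <= 0,
    n_elements = nrow(cen),
    solver = field$solver_report,
    field = field),
    class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario '%s': global max principal %.4g MPa at (%.1f, %.1f, %.1f) mm; safety factor %.3g\n",
              x$scenario, x$global_max$value, x$global_max$location_mm[1],
              x$global_max$location_mm[2], x$global_max$location_mm[3],
              x$safety_factor))
  print(x$region_stats, row.names = FALSE)
  invisible(x)
}

#' Compare scenario reports side by side
#'
#' @param reports List of `scenario_report`s on the same geometry (checked by
#'   element count when the geometries are undamaged).
#' @param check_geometry Require equal element counts (default TRUE; set FALSE
#'   when comparing damaged vs undamaged meshes).
#' @return Data frame: one row per scenario with global max, region means, the
#'   ratio of each global max to the first report's, and (when both are
#'   present) the eggs_only / worst_case global-max ratio as attribute
#'   `eggs_to_worst_ratio`.
#' @export
compare_scenarios <- function(reports, check_geometry = TRUE) {
  if (length(reports) < 2L) stop("need at least two reports")
  if (check_geometry) {
    ne <- vapply(reports, `[[`, 0, "n_elements")
    if (length(unique(ne)) != 1L)
      stop("geometry mismatch: reports have different element counts")
  }
  row <- function(r) {
    rs <- r$region_stats
    data.frame(scenario = r$scenario,
               global_max_mpa = r$global_max$value,
               rim_mean_mpa = rs$mean_mpa[rs$region == "rim_band"],
               egg_mean_mpa = rs$mean_mpa[rs$region == "egg_region"],
               anchor_mean_mpa = rs$mean_mpa[rs$region == "anchor_band"],
               safety_factor = r$safety_factor)
  }
  out <- do.call(rbind, lapply(reports, row))
  out$max_ratio_to_first <- out$global_max_mpa / out$global_max_mpa[1]
  nm <- out$scenario
  if ("eggs_only" %in% nm && "worst_case" %in% nm)
    attr(out, "eggs_to_worst_ratio") <-
      out$global_max_mpa[nm == "eggs_only"][1] /
      out$global_max_mpa[nm == "worst_case"][1]
  out
}

#' Desk-preset FE inputs from a phantom
#'
#' Runs the default segmentation on the phantom image (the small-pore rule
#' carried across resolution as a physical volume via
#' [min_pore_voxels_for()]), and returns the material mask and the matching
#' downsampled grayscale at the FE working resolution (generation spacing x
#' `factor`).
#'
#' @param bundle A `phantom_bundle`.
#' @param factor Resampling factor (default 2: 0.4 mm generation -> 0.8 mm FE).
#' @param sigma Smoothing sigma in voxels (default 1).
#' @return List with `mask`, `gray`, `pores` and the segmentation `provenance`.
#' @export
desk_fe_inputs <- function(bundle, factor = 2L, sigma = 1) {
  img <- bundle$image
  target_spacing <- spacing_mm(img) * factor
  sp <- segmentation_params(gaussian_sigma = sigma, resample_factor = factor,
                            min_pore_voxels = min_pore_voxels_for(target_spacing))
  seg <- segment_nest(img, sp, "pre_threshold")
  gray <- downsample_volume(smooth_volume(img, sigma), factor)
  list(mask = seg$material, gray = gray, pores = seg$pores,
       provenance = seg$provenance)
}
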