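# Synthetic nest phantom: a seeded generator producing a grayscale volume plus
# ground-truth material and closed-pore masks with the architecture of an
# edible-nest swiftlet nest -- a half-cup shell anchored to a vertical wall,
# wall cross-section graded from a thick anchor to a thin rim, and a layered
# strand pattern leaving closed pores elongated along the right-left axis,
# with closed porosity increasing from anchor to rim.
#
# Geometry primitive: the shell between two half-ellipsoids, clipped at a
# horizontal rim plane (top) and at the wall plane (back boundary), plus a
# solid anchor pad against the wall. Thickness and porosity are graded
# linearly along the back-front axis.

#' Phantom parameters
#'
#' Defaults encode the study conditions: overall extents 77.5 mm (R-L) x
#' 39.8 mm (U-D), nest mass 5.93 g, strand pitch 0.25 mm. The back-front depth
#' and the wall thicknesses are not published and are stated assumptions
#' (35 mm deep; 8 mm anchor wall thinning to 4 mm at the rim). Grayscale means
#' (background 5, material 70 at the rim grading to 90 at the denser anchor,
#' additive Gaussian noise sd 8) are chosen so that the published segmentation
#' threshold of 40 falls near the background/material midpoint. The desk
#' preset generates at 0.4 mm voxels; finer spacings are allowed up to
#' `voxel_budget` voxels.
#'
#' @param width_rl,height_ud,depth_bf Overall extents (mm).
#' @param wall_thickness_anchor,wall_thickness_rim Shell thickness at the wall
#'   and at the rim (mm); rim must be thinner.
#' @param fiber_pitch Strand pitch (mm). The void lattice coarsens this to an
#'   integer multiple near `coarse_pitch` so pores span several voxels.
#' @param coarse_pitch Target effective pitch of the void lattice (mm).
#' @param porosity_anchor,porosity_rim Target closed-pore volume fractions at
#'   the anchor and rim ends (rim >= anchor).
#' @param target_mass Nest mass (g) used downstream for density calibration.
#' @param voxel_spacing Isotropic voxel size (mm).
#' @param noise_sd Additive Gaussian grayscale noise (8-bit units).
#' @param mat_gray_anchor,mat_gray_rim,bg_gray Grayscale means (0..255).
#' @param seed Integer RNG seed; identical seed gives bit-identical output.
#' @param pad_depth Depth of the solid anchor pad against the wall (mm).
#' @param margin_voxels Background margin on every face except the wall face.
#' @param voxel_budget Maximum allowed number of voxels.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(width_rl = 77.5, height_ud = 39.8, depth_bf = 35,
                           wall_thickness_anchor = 8, wall_thickness_rim = 4,
                           fiber_pitch = 0.25, coarse_pitch = 2.0,
                           porosity_anchor = 0.02, porosity_rim = 0.09,
                           target_mass = 5.93, voxel_spacing = 0.4,
                           noise_sd = 8, mat_gray_anchor = 90,
                           mat_gray_rim = 70, bg_gray = 5, seed = 42L,
                           pad_depth = 2, margin_voxels = 2L,
                           voxel_budget = 3e7) {
  p <- list(width_rl = width_rl, height_ud = height_ud, depth_bf = depth_bf,
            wall_thickness_anchor = wall_thickness_anchor,
            wall_thickness_rim = wall_thickness_rim,
            fiber_pitch = fiber_pitch, coarse_pitch = coarse_pitch,
            porosity_anchor = porosity_anchor, porosity_rim = porosity_rim,
            target_mass = target_mass, voxel_spacing = voxel_spacing,
            noise_sd = noise_sd, mat_gray_anchor = mat_gray_anchor,
            mat_gray_rim = mat_gray_rim, bg_gray = bg_gray,
            seed = as.integer(seed), pad_depth = pad_depth,
            margin_voxels = as.integer(margin_voxels),
            voxel_budget = voxel_budget)
  lens <- c(p$width_rl, p$height_ud, p$depth_bf, p$wall_thickness_anchor,
            p$wall_thickness_rim, p$fiber_pitch, p$voxel_spacing)
  if (any(!is.finite(lens)) || any(lens <= 0)) stop("all lengths must be > 0")
  if (p$wall_thickness_rim >= p$wall_thickness_anchor)
    stop("wall_thickness_rim must be < wall_thickness_anchor")
  if (p$porosity_anchor < 0 || p$porosity_rim >= 1 ||
      p$porosity_rim < p$porosity_anchor)
    stop("need 0 <= porosity_anchor <= porosity_rim < 1")
  grays <- c(p$mat_gray_anchor, p$mat_gray_rim, p$bg_gray)
  if (any(grays < 0 | grays > 255)) stop("grayscale means must be in [0, 255]")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$target_mass <= 0) stop("target_mass must be > 0")
  structure(p, class = "phantom_params")
}

# Build the solid shell (no voids) as a logical array, given voxel-center
# coordinate arrays X0, X1, X2 (mm) and the ellipsoid center (c0, c2).
.phantom_shell <- function(p, X0, X1, X2, c0, c2) {
  A0 <- p$height_ud; A1 <- p$depth_bf; A2 <- p$width_rl / 2
  r_out <- ((X0 - c0) / A0)^2 + (X1 / A1)^2 + ((X2 - c2) / A2)^2
  tt <- p$wall_thickness_anchor +
    (p$wall_thickness_rim - p$wall_thickness_anchor) * pmin(pmax(X1 / A1, 0), 1)
  r_in <- ((X0 - c0) / pmax(A0 - tt, 1e-9))^2 + (X1 / pmax(A1 - tt, 1e-9))^2 +
    ((X2 - c2) / pmax(A2 - tt, 1e-9))^2
  below_rim <- X0 <= c0
  shell <- (r_out <= 1) & (r_in > 1) & below_rim
  # solid anchor pad spread on the wall (cavity filled near the wall plane)
  shell | ((r_out <= 1) & below_rim & (X1 <= p$pad_depth))
}

#' Generate a synthetic nest phantom
#'
#' Produces a grayscale volume plus ground-truth material and closed-pore
#' masks. Voids are carved on a quasi-periodic lattice of R-L-elongated
#' ellipsoids whose acceptance probability follows the anchor-to-rim porosity
#' ramp; any carved void that connects to the exterior background is filled
#' back, so every ground-truth pore is closed by construction. Identical
#' parameters and seed give bit-identical output.
#'
#' @param params A [phantom_params()].
#' @return A `phantom_bundle`: list with `image` ([voxel_volume()]),
#'   `material_truth` ([mask_volume()]), `pore_truth` ([label_volume()]),
#'   `params`, and `meta` (effective pitch, lattice spacings, void counts).
#' @export
generate_phantom <- function(params = phantom_params()) {
  p <- params
  s <- p$voxel_spacing
  if (p$wall_thickness_rim < s)
    stop("degenerate geometry: rim shell (", p$wall_thickness_rim,
         " mm) is thinner than one voxel (", s, " mm)")
  m <- p$margin_voxels
  n0 <- as.integer(ceiling(p$height_ud / s)) + 2L * m
  n1 <- as.integer(ceiling(p$depth_bf / s)) + m          # wall at the low BF face
  n2 <- as.integer(ceiling(p$width_rl / s)) + 2L * m
  if (as.double(n0) * n1 * n2 > p$voxel_budget)
    stop("requested volume (", n0, "x", n1, "x", n2,
         " voxels) exceeds the voxel budget (", format(p$voxel_budget), ")")
  d <- c(n0, n1, n2)

  x0 <- (seq_len(n0) - 0.5) * s
  x1 <- (seq_len(n1) - 0.5) * s
  x2 <- (seq_len(n2) - 0.5) * s
  # center the geometry so extents fit exactly inside the margins
  c0 <- m * s + p$height_ud      # rim plane height
  c2 <- m * s + p$width_rl / 2
  X0 <- array(x0, dim = d)
  X1 <- array(rep(x1, each = n0), dim = d)
  X2 <- array(rep(x2, each = n0 * n1), dim = d)

  shell <- .phantom_shell(p, X0, X1, X2, c0, c2)
  if (!any(shell)) stop("degenerate geometry: empty shell")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  # void lattice: effective pitch q coarsens the strand pitch to a resolvable
  # scale (integer multiple of fiber_pitch nearest coarse_pitch)
  q <- p$fiber_pitch * max(1, round(p$coarse_pitch / p$fiber_pitch))
  pitch <- c(ud = 1.1 * q, bf = 1.1 * q, rl = 2.2 * q)
  semi <- c(ud = 0.30 * q, bf = 0.30 * q, rl = 0.75 * q)
  void_vol <- 4 / 3 * pi * prod(semi)
  cell_vol <- prod(pitch)
  frac_full <- void_vol / cell_vol

  ext <- c(n0, n1, n2) * s
  centers <- expand.grid(
    u = seq(pitch["ud"] / 2, ext[1], by = pitch["ud"]),
    b = seq(pitch["bf"] / 2, ext[2], by = pitch["bf"]),
    r = seq(pitch["rl"] / 2, ext[3], by = pitch["rl"]))
  ns <- nrow(centers)
  jit <- matrix(stats::runif(3 * ns, -0.1 * q, 0.1 * q), ns, 3)
  centers$u <- centers$u + jit[, 1]
  centers$b <- centers$b + jit[, 2]
  centers$r <- centers$r + jit[, 3]
  accept_u <- stats::runif(ns)

  phi <- p$porosity_anchor +
    (p$porosity_rim - p$porosity_anchor) * pmin(pmax(centers$b / p$depth_bf, 0), 1)
  p_acc <- pmin(1, phi / frac_full)
  vi <- pmin(pmax(as.integer(ceiling(centers$u / s)), 1L), n0)
  vj <- pmin(pmax(as.integer(ceiling(centers$b / s)), 1L), n1)
  vk <- pmin(pmax(as.integer(ceiling(centers$r / s)), 1L), n2)
  in_mat <- shell[cbind(vi, vj, vk)]
  accepted <- which(in_mat & accept_u < p_acc)

  mat <- shell
  for (a in accepted) {
    cu <- centers$u[a]; cb <- centers$b[a]; cr <- centers$r[a]
    i_rng <- max(1L, floor((cu - semi[1]) / s)):min(n0, ceiling((cu + semi[1]) / s + 1))
    j_rng <- max(1L, floor((cb - semi[2]) / s)):min(n1, ceiling((cb + semi[2]) / s + 1))
    k_rng <- max(1L, floor((cr - semi[3]) / s)):min(n2, ceiling((cr + semi[3]) / s + 1))
    du <- ((i_rng - 0.5) * s - cu) / semi[1]
    db <- ((j_rng - 0.5) * s - cb) / semi[2]
    dr <- ((k_rng - 0.5) * s - cr) / semi[3]
    inside <- outer(outer(du^2, db^2, `+`), dr^2, `+`) < 1
    sub <- mat[i_rng, j_rng, k_rng]
    sub[inside] <- FALSE
    mat[i_rng, j_rng, k_rng] <- sub
  }

  # closure: background components touching any border are exterior; carved
  # voxels that joined the exterior are filled back, the rest are true pores
  lab <- .label_components(!mat, 6L)
  nlab <- attr(lab, "label_count")
  border <- unique(c(lab[1, , ], lab[n0, , ], lab[, 1, ], lab[, n1, ],
                     lab[, , 1], lab[, , n2]))
  exterior <- setdiff(border, 0L)
  carved <- shell & !mat
  refill <- carved & array(lab %in% exterior, dim = d)
  mat <- mat | refill

  pore_ids <- setdiff(seq_len(nlab), exterior)
  pores <- array(0L, dim = d)
  if (length(pore_ids)) {
    remap <- integer(nlab)
    remap[pore_ids] <- seq_along(pore_ids)
    pos <- lab > 0L
    pores[pos] <- remap[lab[pos]]
  }

  gray_mean <- ifelse(mat,
                      p$mat_gray_anchor +
                        (p$mat_gray_rim - p$mat_gray_anchor) *
                        pmin(pmax(X1 / p$depth_bf, 0), 1),
                      p$bg_gray)
  noise <- if (p$noise_sd > 0) stats::rnorm(length(gray_mean), 0, p$noise_sd) else 0
  gray <- array(pmin(255, pmax(0, round(gray_mean + noise))), dim = d)

  structure(list(
    image = voxel_volume(gray, s, "mm"),
    material_truth = mask_volume(mat, s, "mm"),
    pore_truth = label_volume(pores, s, "mm", label_count = length(pore_ids)),
    params = p,
    meta = list(pitch_eff = q, lattice_pitch = pitch, void_semi_axes = semi,
                n_sites = ns, n_accepted = length(accepted),
                n_closed_pores = length(pore_ids),
                rim_plane_mm = c0, center_rl_mm = c2,
                dims = d)),
    class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  d <- x$meta$dims
  cat(sprintf("phantom_bundle %d x %d x %d voxels at %g mm, %d closed pores (seed %d)\n",
              d[1], d[2], d[3], x$params$voxel_spacing,
              x$pore_truth$label_count, x$params$seed))
  invisible(x)
}

#' Ground-truth slice profiles of a phantom
#'
#' Per-slice material area and closed-pore percentage computed from the truth
#' masks; the reference against which segmentation recovery is judged.
#'
#' @param bundle A `phantom_bundle`.
#' @param axis Axis id (default `"BF"`, anchor to rim).
#' @return A [slice_profile()] data frame.
#' @export
ground_truth_profiles <- function(bundle, axis = "BF") {
  if (!inherits(bundle, "phantom_bundle")) stop("bundle must be a phantom_bundle")
  slice_profile(bundle$material_truth, bundle$pore_truth, axis)
}
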