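# Voxel-hexahedral small-strain linear-elastic finite elements: one 8-node
# trilinear brick per material voxel, isotropic Hooke's law, 2x2x2 Gauss
# quadrature, gravity body forces scaled by per-element density, fully pinned
# wall-face nodes, equal-share nodal loads over ROI node sets, and
# maximum-principal-stress recovery at element centroids.
#
# Unit system: mm - N - MPa - tonne/mm^3, with g = 9806.65 mm/s^2, so an
# elastic modulus in MPa and forces in N are directly consistent.

#' Standard gravity in mm/s^2
#' @export
STANDARD_GRAVITY_MM_S2 <- 9806.65

#' Isotropic linear-elastic material model
#'
#' @param E Elastic modulus (MPa), default 155.
#' @param nu Poisson's ratio in \[0, 0.5), default 0.3.
#' @param total_mass Total structure mass (g) to which the per-element density
#'   field is calibrated, default 5.93.
#' @return A `material_model`.
#' @export
material_model <- function(E = 155, nu = 0.3, total_mass = 5.93) {
  if (!is.finite(E) || E <= 0) stop("E must be > 0")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) stop("need 0 <= nu < 0.5")
  if (!is.null(total_mass) && (!is.finite(total_mass) || total_mass <= 0))
    stop("total_mass must be > 0 (or NULL to disable gravity)")
  structure(list(E = E, nu = nu, total_mass = total_mass,
                 density_field = NULL),
            class = "material_model")
}

# Isotropic constitutive matrix, engineering strain ordering
# (exx, eyy, ezz, gxy, gyz, gzx).
.hooke_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(0, 3), rep(mu, 3)))
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  D
}

# Local node coordinates, VTK/C3D8 ordering, on [-1,1]^3.
.hex8_local <- function() {
  matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
           -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
         ncol = 3, byrow = TRUE)
}

# Strain-displacement matrix B (6 x 24) at local point (xi, eta, zeta) for a
# cube of edge h; dof order is node-major (u1x u1y u1z u2x ...), axes
# (x, y, z) = (UD, BF, RL).
.hex8_B <- function(xi, eta, zeta, h) {
  loc <- .hex8_local()
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    sx <- loc[a, 1]; sy <- loc[a, 2]; sz <- loc[a, 3]
    dN <- c(sx * (1 + sy * eta) * (1 + sz * zeta),
            sy * (1 + sx * xi) * (1 + sz * zeta),
            sz * (1 + sx * xi) * (1 + sy * eta)) / 8 * (2 / h)
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[1]
    B[2, c0 + 2] <- dN[2]
    B[3, c0 + 3] <- dN[3]
    B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
    B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
    B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
  }
  B
}

# 24x24 stiffness of a cube voxel element (edge h mm), 2x2x2 Gauss quadrature.
hex8_stiffness <- function(E, nu, h) {
  D <- .hooke_D(E, nu)
  gp <- c(-1, 1) / sqrt(3)
  detJ <- (h / 2)^3
  Ke <- matrix(0, 24, 24)
  for (xi in gp) for (eta in gp) for (zeta in gp) {
    B <- .hex8_B(xi, eta, zeta, h)
    Ke <- Ke + t(B) %*% D %*% B * detJ
  }
  Ke
}

# Exposed voxel faces of the mesh, as a matrix of 4 node keys per face (one
# row per exposed face). Used both for the surface node set and for spreading
# a uniform traction over an ROI: each face carries an equal share of the ROI
# force, split equally over its 4 corner nodes, which reproduces constant
# stress states exactly (consistent loading for trilinear elements).
.exposed_face_keys <- function(m) {
  d <- dim(m)
  nd <- d + 1L
  key <- function(a, b, c) a + nd[1] * (b + nd[2] * c)  # 0-based corner coords
  shift <- function(arr, ax, by) {
    res <- array(FALSE, dim = d)
    n <- d[ax]
    if (abs(by) >= n) return(res)
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); dst <- src
    if (by >= 0) { src[[ax]] <- (1 + by):n; dst[[ax]] <- 1:(n - by) }
    else         { src[[ax]] <- 1:(n + by); dst[[ax]] <- (1 - by):n }
    res[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    res
  }
  # the 4 corner offsets of the voxel face exposed in direction (axis, side)
  face_offsets <- function(ax, side) {
    offs <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)
    fixed <- c("di", "dj", "dk")[ax]
    as.matrix(offs[offs[[fixed]] == side, , drop = FALSE])
  }
  blocks <- list()
  for (ax in 1:3) for (side in 0:1) {
    by <- if (side == 1L) 1L else -1L
    exposed <- which(m & !shift(m, ax, by))
    if (!length(exposed)) next
    co <- arrayInd(exposed, d) - 1L  # 0-based voxel coords
    offs <- face_offsets(ax, side)
    fk <- matrix(0L, length(exposed), 4)
    for (r in 1:4)
      fk[, r] <- key(co[, 1] + offs[r, 1], co[, 2] + offs[r, 2],
                     co[, 3] + offs[r, 3])
    blocks[[length(blocks) + 1L]] <- fk
  }
  do.call(rbind, blocks)
}

#' Build a voxel-hexahedral FE model from a material mask
#'
#' One hexahedral element per material voxel with shared corner nodes. Element
#' density is proportional to the voxel grayscale (uniform when `gray` is
#' `NULL`) and rescaled so the total mass equals `material$total_mass` (exact
#' to machine precision). Pinned nodes are the material-surface nodes lying on
#' the chosen wall face. Each load ROI is resolved to the exterior-surface
#' material nodes it intersects; its total force is spread as a uniform
#' traction (equal share per exposed face inside the ROI, a quarter per corner
#' node), which reproduces constant-stress states exactly; ROIs smaller than
#' one face fall back to equal nodal shares.
#'
#' @param mask Material [mask_volume()].
#' @param gray Matching [voxel_volume()] used for relative density (optional).
#' @param material A [material_model()].
#' @param pin_plane Wall face: `"BF_low"` (default; the anchor wall),
#'   or any of `"UD_low"`, `"UD_high"`, `"BF_high"`, `"RL_low"`, `"RL_high"`.
#' @param load_rois Named list of ROI specs, each
#'   `list(shape = "cuboid"|"ellipsoid", center = c(ud, bf, rl) mm,
#'   half = c(ud, bf, rl) mm half-extents/semi-axes, force = c(3) total N)`.
#' @return An `fe_model`: `nodes` (n x 3 mm), `elements` (m x 8, VTK order),
#'   `pinned_nodes`, `load_sets`, `material` (with calibrated
#'   `density_field`, tonne/mm^3), `spacing` (mm), `dims`, `vox_idx`.
#' @export
build_model <- function(mask, gray = NULL, material = material_model(),
                        pin_plane = "BF_low", load_rois = list()) {
  if (!inherits(mask, "mask_volume")) stop("mask must be a mask_volume")
  if (!any(mask$data)) stop("mask is empty")
  if (!is.null(gray)) {
    if (!inherits(gray, "voxel_volume")) stop("gray must be a voxel_volume")
    if (!.same_grid(mask, gray)) stop("mask and gray must share the grid")
  }
  h <- spacing_mm(mask)
  d <- dim(mask$data)
  nd <- d + 1L

  vox_idx <- which(mask$data)
  co <- arrayInd(vox_idx, d) - 1L  # 0-based voxel coords
  m <- nrow(co)

  key <- function(a, b, c) a + nd[1] * (b + nd[2] * c)
  offs <- .hex8_local()  # -1/1 -> 0/1
  corner <- (offs + 1L) / 2L
  elem_keys <- matrix(0L, m, 8)
  for (a in 1:8)
    elem_keys[, a] <- key(co[, 1] + corner[a, 1], co[, 2] + corner[a, 2],
                          co[, 3] + corner[a, 3])
  node_keys <- sort(unique(as.vector(elem_keys)))
  lookup <- integer(prod(nd))
  lookup[node_keys + 1L] <- seq_along(node_keys)
  elements <- matrix(lookup[elem_keys + 1L], m, 8)

  # node coordinates (mm): corner lattice coords * h
  nk <- node_keys
  a <- nk %% nd[1]; rest <- nk %/% nd[1]
  b <- rest %% nd[2]; cc <- rest %/% nd[2]
  nodes <- cbind(a, b, cc) * h
  colnames(nodes) <- c("ud", "bf", "rl")

  # density calibration: rho_e proportional to grayscale, total mass exact
  w <- if (is.null(gray)) rep(1, m) else as.numeric(gray$data[vox_idx])
  mat <- material
  if (!is.null(mat$total_mass)) {
    if (sum(w) <= 0) stop("cannot calibrate density: all grayscale weights are zero")
    Ve <- h^3
    mass_tonne <- mat$total_mass * 1e-6
    mat$density_field <- w * (mass_tonne / (sum(w) * Ve))
  } else {
    mat$density_field <- rep(0, m)
  }

  # pinned set: surface nodes on the wall face
  pp <- strsplit(pin_plane, "_")[[1]]
  ax <- axis_index(pp[1])
  side <- match.arg(pp[2], c("low", "high"))
  plane_val <- if (side == "low") 0L else d[ax]
  node_ax <- cbind(a, b, cc)[, ax]
  pinned <- which(node_ax == plane_val)
  if (!length(pinned))
    stop("empty pinned set: no material nodes on face ", pin_plane,
         " (free-floating model)")

  # load ROIs resolved to exterior material surface nodes; force spread as a
  # uniform traction: equal share per exposed face fully inside the ROI, a
  # quarter of the face share to each corner node (exact for constant stress
  # states). ROIs too small to contain a whole face fall back to equal nodal
  # shares.
  face_keys <- .exposed_face_keys(mask$data)
  faces <- matrix(lookup[face_keys + 1L], ncol = 4)
  surf <- sort(unique(as.vector(faces)))
  load_sets <- list()
  n_nodes <- length(node_keys)
  for (nm in names(load_rois)) {
    roi <- load_rois[[nm]]
    ctr <- roi$center; half <- roi$half
    rel <- sweep(nodes[surf, , drop = FALSE], 2, ctr)
    inside <- if (identical(roi$shape, "ellipsoid")) {
      rowSums(sweep(rel, 2, half, "/")^2) <= 1
    } else {
      abs(rel[, 1]) <= half[1] & abs(rel[, 2]) <= half[2] & abs(rel[, 3]) <= half[3]
    }
    ids <- surf[inside]
    if (!length(ids))
      stop("load ROI '", nm, "' intersects no material surface node")
    node_in <- logical(n_nodes)
    node_in[ids] <- TRUE
    fin <- faces[node_in[faces[, 1]] & node_in[faces[, 2]] &
                   node_in[faces[, 3]] & node_in[faces[, 4]], , drop = FALSE]
    if (nrow(fin) > 0) {
      w <- tabulate(as.vector(fin), nbins = n_nodes)
      ids <- which(w > 0L)
      weights <- w[ids] / sum(w[ids])
    } else {
      weights <- rep(1 / length(ids), length(ids))
    }
    load_sets[[nm]] <- list(nodes = ids, force = roi$force, weights = weights)
  }

  structure(list(nodes = nodes, elements = elements, pinned_nodes = pinned,
                 load_sets = load_sets, material = mat, spacing = h,
                 dims = d, vox_idx = vox_idx),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("fe_model: %d nodes, %d hex elements at %g mm, %d pinned nodes, %d load sets\n",
              nrow(x$nodes), nrow(x$elements), x$spacing,
              length(x$pinned_nodes), length(x$load_sets)))
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients; deterministic fixed ordering.
.pcg <- function(A, b, tol = 1e-8, maxit = 50000L) {
  n <- length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), iterations = 0L, rel_residual = 0))
  Minv <- 1 / Matrix::diag(A)
  if (any(!is.finite(Minv)))
    stop("singular system: zero diagonal entries (insufficient constraints?)")
  x <- numeric(n)
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0)
      stop("system is not positive definite (insufficient constraints?)")
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel <= tol)
      return(list(x = x, iterations = it, rel_residual = rel))
    z <- Minv * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop("conjugate gradients did not converge in ", maxit,
       " iterations (relative residual ", signif(sqrt(sum(r^2)) / bnorm, 3), ")")
}

# Vectorized max principal stress from rows (sxx, syy, szz, txy, tyz, tzx).
.max_principal <- function(S) {
  sxx <- S[, 1]; syy <- S[, 2]; szz <- S[, 3]
  txy <- S[, 4]; tyz <- S[, 5]; tzx <- S[, 6]
  q <- (sxx + syy + szz) / 3
  p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * (txy^2 + tyz^2 + tzx^2)
  p <- sqrt(p2 / 6)
  out <- q  # hydrostatic limit
  nz <- p > 1e-300
  if (any(nz)) {
    bxx <- (sxx - q) / p; byy <- (syy - q) / p; bzz <- (szz - q) / p
    bxy <- txy / p; byz <- tyz / p; bzx <- tzx / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bzx) +
      bzx * (bxy * byz - byy * bzx)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    out[nz] <- (q + 2 * p * cos(phi))[nz]
  }
  out
}

#' Principal stresses of a symmetric 3x3 stress tensor
#'
#' Eigenvalues sorted descending, tension positive.
#'
#' @param tensor Symmetric 3x3 matrix (MPa).
#' @param tol Symmetry tolerance.
#' @return Numeric vector `(sigma1, sigma2, sigma3)`.
#' @export
principal_stress <- function(tensor, tol = 1e-8) {
  if (!is.matrix(tensor) || !all(dim(tensor) == c(3, 3)))
    stop("tensor must be a 3x3 matrix")
  if (max(abs(tensor - t(tensor))) > tol * max(1, max(abs(tensor))))
    stop("tensor is not symmetric")
  sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

#' Solve a voxel FE model
#'
#' Assembles the global stiffness (trilinear hexahedra, 2x2x2 Gauss points,
#' isotropic Hooke's law), applies equal nodal shares of each load set's total
#' force over its node set, optionally adds the consistent gravity body force
#' (equal 1/8 nodal shares of `rho * V * g` per element, directed along -U-D),
#' eliminates pinned dofs, and solves with Jacobi-preconditioned conjugate
#' gradients to a relative residual of `tol` (failure to converge is an
#' error). Stresses are recovered at element centroids; the maximum principal
#' stress is the largest eigenvalue of the centroid stress tensor.
#'
#' @param model An `fe_model`.
#' @param gravity Logical: include self-weight body forces.
#' @param method `"pcg"` (default) or `"direct"` (sparse Cholesky; identical
#'   result to solver tolerance, useful for repeated loads).
#' @param tol PCG relative-residual tolerance.
#' @param maxit PCG iteration cap.
#' @return A `stress_field`: `displacements` (n x 3 mm), `stress_tensor`
#'   (m x 6: sxx, syy, szz, txy, tyz, tzx, MPa), `max_principal` (m, MPa),
#'   `solver_report` (iterations, residual, totals of applied and reaction
#'   forces).
#' @export
solve_fe <- function(model, gravity = TRUE, method = c("pcg", "direct"),
                     tol = 1e-8, maxit = 50000L) {
  method <- match.arg(method)
  if (!inherits(model, "fe_model")) stop("model must be an fe_model")
  h <- model$spacing
  mat <- model$material
  Ke <- hex8_stiffness(mat$E, mat$nu, h)
  m <- nrow(model$elements)
  n_nodes <- nrow(model$nodes)
  ndof <- 3L * n_nodes

  dofmap <- matrix(0L, m, 24)
  for (a in 1:8) for (c in 1:3)
    dofmap[, 3 * (a - 1) + c] <- 3L * (model$elements[, a] - 1L) + c

  iv <- dofmap[, rep(1:24, times = 24)]
  jv <- dofmap[, rep(1:24, each = 24)]
  xv <- rep(as.vector(Ke), each = m)
  K <- Matrix::sparseMatrix(i = as.vector(iv), j = as.vector(jv), x = xv,
                            dims = c(ndof, ndof))
  rm(iv, jv, xv)

  f <- numeric(ndof)
  for (ls in model$load_sets) {
    w <- if (is.null(ls$weights)) rep(1 / length(ls$nodes), length(ls$nodes))
         else ls$weights
    for (c in 1:3) {
      idx <- 3L * (ls$nodes - 1L) + c
      f[idx] <- f[idx] + ls$force[c] * w
    }
  }
  if (gravity) {
    if (is.null(mat$total_mass))
      stop("gravity requested but material has no total_mass for density calibration")
    fe_g <- -mat$density_field * h^3 * STANDARD_GRAVITY_MM_S2 / 8  # N per node
    idxv <- as.vector(3L * (model$elements - 1L) + 1L)             # U-D dofs
    valv <- rep(fe_g, times = 8)
    acc <- rowsum(valv, idxv)
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
  }

  pinned_dofs <- as.vector(outer(3L * (model$pinned_nodes - 1L), 1:3, `+`))
  free <- setdiff(seq_len(ndof), pinned_dofs)
  Kff <- K[free, free]
  ff <- f[free]

  if (method == "pcg") {
    sol <- .pcg(Kff, ff, tol = tol, maxit = maxit)
  } else {
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Kff), "CsparseMatrix"),
                           LDL = FALSE, super = TRUE)
    x <- as.numeric(Matrix::solve(ch, ff))
    rel <- sqrt(sum((as.numeric(Kff %*% x) - ff)^2)) / max(sqrt(sum(ff^2)), 1e-300)
    sol <- list(x = x, iterations = NA_integer_, rel_residual = rel)
  }

  u <- numeric(ndof)
  u[free] <- sol$x

  # reactions and equilibrium bookkeeping
  resid <- as.numeric(K %*% u) - f
  reaction <- resid
  reaction[free] <- 0
  sum_by_comp <- function(v) vapply(1:3, function(c) sum(v[seq(c, ndof, by = 3)]), 0)
  report <- list(method = method, iterations = sol$iterations,
                 rel_residual = sol$rel_residual,
                 total_applied_N = sum_by_comp(f),
                 total_reaction_N = sum_by_comp(reaction))

  # centroid stress recovery
  B0 <- .hex8_B(0, 0, 0, h)
  DB <- .hooke_D(mat$E, mat$nu) %*% B0
  ue <- matrix(u[dofmap], m, 24)
  S <- ue %*% t(DB)
  colnames(S) <- c("sxx", "syy", "szz", "txy", "tyz", "tzx")

  structure(list(displacements = matrix(u, n_nodes, 3, byrow = TRUE,
                                        dimnames = list(NULL, c("ud", "bf", "rl"))),
                 stress_tensor = S,
                 max_principal = .max_principal(S),
                 solver_report = report),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("stress_field: %d elements, max principal %.4g MPa (%s, %s iterations, residual %.2e)\n",
              nrow(x$stress_tensor), max(x$max_principal),
              x$solver_report$method,
              format(x$solver_report$iterations), x$solver_report$rel_residual))
  invisible(x)
}

#' Remove spherical damage sites from a material mask
#'
#' Material voxels whose centers lie strictly inside any of the given balls
#' are removed (a zero-radius site is the identity). Closed-pore
#' classification must be re-run by the caller on the result. Removing every
#' material voxel on the pinned wall face is an error.
#'
#' @param mask Material [mask_volume()].
#' @param sites List of `list(center = c(ud, bf, rl) mm, radius = mm)`.
#' @param pin_plane Wall face checked for survival (default `"BF_low"`).
#' @return Damaged `mask_volume`.
#' @export
apply_damage <- function(mask, sites, pin_plane = "BF_low") {
  if (!inherits(mask, "mask_volume")) stop("mask must be a mask_volume")
  s <- spacing_mm(mask)
  d <- dim(mask$data)
  ext <- d * s
  out <- mask$data
  for (site in sites) {
    ctr <- site$center; r <- site$radius
    if (any(ctr < 0) || any(ctr > ext))
      stop("damage site center ", paste(signif(ctr, 4), collapse = ", "),
           " lies outside the volume")
    if (r <= 0) next
    i_rng <- max(1L, floor((ctr[1] - r) / s)):min(d[1], ceiling((ctr[1] + r) / s + 1))
    j_rng <- max(1L, floor((ctr[2] - r) / s)):min(d[2], ceiling((ctr[2] + r) / s + 1))
    k_rng <- max(1L, floor((ctr[3] - r) / s)):min(d[3], ceiling((ctr[3] + r) / s + 1))
    du <- (i_rng - 0.5) * s - ctr[1]
    db <- (j_rng - 0.5) * s - ctr[2]
    dr <- (k_rng - 0.5) * s - ctr[3]
    inside <- outer(outer(du^2, db^2, `+`), dr^2, `+`) < r^2
    sub <- out[i_rng, j_rng, k_rng]
    sub[inside] <- FALSE
    out[i_rng, j_rng, k_rng] <- sub
  }
  pp <- strsplit(pin_plane, "_")[[1]]
  ax <- axis_index(pp[1])
  idx <- if (pp[2] == "low") 1L else d[ax]
  face <- switch(ax, out[idx, , ], out[, idx, ], out[, , idx])
  if (!any(face))
    stop("damage removed the entire pinned face (", pin_plane, ")")
  mask_volume(out, mask$spacing, mask$unit)
}
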