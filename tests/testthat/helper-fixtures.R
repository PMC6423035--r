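# Shared fixtures, built lazily once per test run. The default phantom and the
# solved loading scenarios are expensive, so every test that needs them pulls
# from this cache instead of recomputing.

.fixture_env <- new.env(parent = emptyenv())

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_phantom <- function() {
  fixture("phantom42", generate_phantom(phantom_params(seed = 42L)))
}

desk_inputs <- function() {
  fixture("desk42", desk_fe_inputs(default_phantom()))
}

scenario_model <- function(name) {
  fixture(paste0("model_", name), {
    fe <- desk_inputs()
    make_scenario(name, fe$mask, fe$gray, scenario_config())
  })
}

scenario_result <- function(name) {
  fixture(paste0("report_", name), run_scenario(scenario_model(name)))
}

# gravity-off fields for the linearity/superposition checks
field_no_gravity <- function(which) {
  fixture(paste0("field_nog_", which), {
    model <- scenario_model("worst_case")
    if (which == "birds")
      model$load_sets <- model$load_sets[grep("^bird", names(model$load_sets))]
    if (which == "eggs")
      model$load_sets <- model$load_sets[grep("^egg", names(model$load_sets))]
    solve_fe(model, gravity = FALSE)
  })
}

# small uniaxial bar model along U-D: length_mm long, side_mm square section
bar_model <- function(length_mm = 10, side_mm = 1, spacing = 0.25,
                      E = 155, nu = 0, force = 0.1569) {
  n_ax <- round(length_mm / spacing)
  n_s <- round(side_mm / spacing)
  mask <- mask_volume(array(TRUE, dim = c(n_ax, n_s, n_s)), spacing)
  roi <- list(top = list(shape = "cuboid",
                         center = c(length_mm, side_mm / 2, side_mm / 2),
                         half = c(spacing * 0.8, side_mm, side_mm),
                         force = c(force, 0, 0)))
  build_model(mask, material = material_model(E, nu, total_mass = NULL),
              pin_plane = "UD_low", load_rois = roi)
}

# digitized solid ball of given radius (voxel units), spacing 1 mm
ball_mask <- function(radius, pad = 2L) {
  n <- as.integer(2 * ceiling(radius) + 1 + 2 * pad)
  ctr <- (n + 1) / 2
  x <- seq_len(n) - ctr
  inside <- outer(outer(x^2, x^2, `+`), x^2, `+`) <= radius^2
  mask_volume(inside, 1)
}

# digitized solid ellipsoid with semi-axes (mm) along (UD, BF, RL), spacing 1 mm
ellipsoid_label <- function(semi, pad = 2L) {
  n <- as.integer(2 * ceiling(semi) + 1 + 2 * pad)
  ctr <- (n + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(n[a]) - ctr[a]) / semi[a])^2)
  inside <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) <= 1
  label_volume(array(as.integer(inside), dim = n), 1)
}

# embed a pore of exactly n_vox voxels inside a solid block; returns the mask
pore_in_block <- function(n_vox, block = c(20L, 20L, 20L)) {
  m <- array(TRUE, dim = block)
  # carve a compact bar-shaped pore of n_vox voxels near the center
  len <- n_vox
  dims <- c(1L, 1L, len)
  if (len > 12L) { dims <- c(1L, ceiling(len / 12), 12L) }
  if (prod(dims) != n_vox) {
    # fall back to a flat slab plus remainder column
    full_rows <- n_vox %/% 12L
    rem <- n_vox %% 12L
    i0 <- 8L
    for (r in seq_len(full_rows)) m[i0, 8L + r, 5L:16L] <- FALSE
    if (rem > 0) m[i0, 8L + full_rows + 1L, 5L:(4L + rem)] <- FALSE
  } else {
    m[8L, 8L:(7L + dims[2]), 5L:(4L + dims[3])] <- FALSE
  }
  stopifnot(sum(!m) == n_vox)
  mask_volume(m, 1)
}
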