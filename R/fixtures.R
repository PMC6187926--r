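# Synthetic fixtures: small, fully specified domains generated by code so
# that every solver stage is testable offline.  Reduced-scale fixtures
# preserve the governing dimensionless groups (reaction-diffusion number
# A L^2 / (6 D c) and the Peclet number) rather than raw dimensions, so the
# solution structure matches the full-scale problem at a fraction of the
# cost.

#' Bare box grid
#'
#' Uniformly labelled Cartesian grid without device geometry; unit-test
#' scaffolding for solver components.
#'
#' @param dims integer length-3 cell counts.
#' @param spacing voxel edge, m.
#' @param label region name for every cell (default `"MEDIUM"`).
#' @param origin physical origin, m.
#' @return a `labeled_grid` (with `spec = NULL`).
#' @export
make_box_grid <- function(dims, spacing, label = "MEDIUM",
                          origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), spacing > 0)
  structure(list(spacing = spacing, dims = dims, origin = origin,
                 label = array(REGION_LABELS[[label]], dims),
                 sdf = NULL, spec = NULL, width_fraction = 1),
            class = "labeled_grid")
}

#' Minimal flow field with uniform velocity
#'
#' Fills every face with the given constant velocity vector (divergence-free
#' by construction); used by manufactured-solution transport tests.
#'
#' @param grid a `labeled_grid`.
#' @param vel length-3 velocity, m/s.
#' @return a `flow_field`.
#' @export
make_uniform_flow <- function(grid, vel) {
  d <- grid$dims
  structure(list(u = array(vel[1], d + c(1L, 0L, 0L)),
                 v = array(vel[2], d + c(0L, 1L, 0L)),
                 w = array(vel[3], d + c(0L, 0L, 1L)),
                 p = array(0, d), grid = grid,
                 settings = solver_settings(),
                 diagnostics = list(mass_balance = 0, max_divergence = 0)),
            class = "flow_field")
}

#' Constant-rate validation sphere fixture
#'
#' A lone sphere with Dirichlet surface concentration and a uniform
#' volumetric sink, whose exact solution is the quadratic radial profile of
#' [constant_rate_profile()].  The full/desk scale uses the reference
#' parameters (Rs = 500 um, c_surface = 0.2 mM, A = 0.005 mol/(m^3 s),
#' D = 1.83e-9 m^2/s); the ci scale shrinks the sphere while preserving the
#' group `A Rs^2 / (6 D c_surface)` (~0.569), so the normalized profile is
#' identical.
#'
#' @param scale `"ci"` (Rs = 125 um at 5 um spacing), `"desk"` (full-size
#'   sphere at 10 um spacing) or `"full"` (alias of desk; the discretization
#'   already resolves the sphere with 50 cells per radius).
#' @return a `fixture_case` list: grid, model, species, expected values with
#'   provenance tags, tolerance.
#' @export
make_validation_sphere <- function(scale = c("desk", "ci", "full")) {
  scale <- match.arg(scale)
  D <- 1.83e-9; c_surface <- 0.2
  if (scale == "ci") {
    Rs <- 125e-6
    A <- 0.005 * (500 / 125)^2      # preserves A Rs^2 / (6 D c_surface)
    spacing <- 5e-6
    tol <- 0.02
  } else {
    Rs <- 500e-6
    A <- 0.005
    spacing <- 10e-6
    tol <- 0.01
  }
  pad <- 2 * spacing
  n <- as.integer(ceiling(2 * (Rs + pad) / spacing))
  grid <- make_box_grid(c(n, n, n), spacing, label = "EXTERIOR")
  ctr <- rep(n * spacing / 2, 3)
  co <- grid_coord_arrays(grid)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  sdf <- array(sphere_sdf(pts, Rs, ctr), grid$dims)
  grid$label[sdf < 0] <- REGION_LABELS[["TISSUE"]]
  grid$sdf <- sdf
  grid$dirichlet_exterior <- c_surface   # tissue-side surface concentration
  model <- sphere_model(Rs = Rs, A = A, D = D, c_surface = c_surface)
  sp <- species_spec("oxygen_validation", D_medium = D, D_tissue = D,
                     S_tissue = 1, Vmax = 1, Km = 1, c_inlet = c_surface,
                     pdms_permeable = FALSE)
  expected <- list(
    surface_c = list(value = c_surface, provenance = "stated surface condition"),
    center_c = list(value = constant_rate_profile(model, 0),
                    provenance = "closed-form radial profile at b = 0"),
    group = list(value = A * Rs^2 / (6 * D * c_surface),
                 provenance = "dimensionless reaction-diffusion number"))
  structure(list(name = paste0("validation_sphere_", scale), grid = grid,
                 model = model, species = sp, center = ctr,
                 expected = expected, tolerance = tol, scale = scale),
            class = "fixture_case")
}

#' Solve the validation sphere and compare to the closed form
#'
#' @param fx fixture from [make_validation_sphere()].
#' @param settings solver settings.
#' @return list with the solved field, radii, the pointwise relative errors
#'   (normalized by the surface concentration) and `max_rel_error`.
#' @export
run_validation_sphere <- function(fx, settings = solver_settings()) {
  field <- solve_species(fx$grid, fx$species, flow = NULL, settings = settings,
                         constant_rate = fx$model$A)
  sel <- fx$grid$label == REGION_LABELS[["TISSUE"]]
  co <- grid_coord_arrays(fx$grid)
  b <- sqrt((co$x[sel] - fx$center[1])^2 + (co$y[sel] - fx$center[2])^2 +
            (co$z[sel] - fx$center[3])^2)
  b <- pmin(b, fx$model$Rs)
  exact <- constant_rate_profile(fx$model, b)
  err <- abs(field$c[sel] - exact) / fx$model$c_surface
  list(field = field, b = b, exact = exact, rel_error = err,
       max_rel_error = max(err))
}

#' Reduced-scale chip fixture
#'
#' A geometrically similar device at 1/4 linear scale with rescaled physics:
#' lengths scale by `s`, the flow rate by `s` (preserving the Peclet number
#' U L / D) and the consumption rates by `1/s^2` (preserving the
#' reaction-diffusion group Vmax L^2 / (D c)).  Orderings between trap types
#' and aggregate kinds are preserved by this scaling and can be tested in
#' seconds.
#'
#' @param scale `"ci"` (coarser voxels) or `"desk"`.
#' @param aggregate_kind,trap_kind forwarded to [geometry_spec()].
#' @param s linear scale factor.
#' @return a `fixture_case` with a ready-to-run `scenario`.
#' @export
make_mini_chip <- function(scale = c("ci", "desk"),
                           aggregate_kind = "toroid_horizontal",
                           trap_kind = "u_barrier", s = 0.25) {
  scale <- match.arg(scale)
  r <- 80e-6 * s
  geom <- geometry_spec(
    trap_kind = trap_kind,
    trap_height = 600e-6 * s,
    trap_length = 600e-6 * s,
    trap_footprint_area = 0.321e-6 * s^2,
    barrier_wall_thickness = 25e-6 * s,
    aggregate_kind = aggregate_kind,
    minor_radius = r,
    aspect_ratio = 2,
    margin = 1e-6 * s,
    channel_width = 1e-3 * s,
    channel_height = 800e-6 * s,
    channel_length = 2600e-6 * s,
    lid_thickness = 200e-6 * s,
    half_width = TRUE)
  phys <- default_physical_params()
  phys$Q <- phys$Q * s
  scale_species <- function(sp) { sp$Vmax <- sp$Vmax / s^2; sp }
  species <- lapply(list(default_species("oxygen"),
                         default_species("glucose")), scale_species)
  spacing <- if (scale == "ci") r / 3.2 else r / 5
  sc <- scenario(geometry = geom, physical = phys, species = species,
                 settings = solver_settings(),
                 spacing = spacing, coarse_ok = TRUE)
  structure(list(name = paste("mini_chip", trap_kind, aggregate_kind, scale,
                              sep = "_"),
                 scenario = sc, scale = scale, s = s,
                 expected = list(
                   orderings = list(
                     value = c("u_barrier > microwell in c_ave",
                               "vertical toroid highest c_ave and tau_max",
                               "spheroid tau_max > horizontal toroid tau_max"),
                     provenance = "qualitative orderings, tested at mini scale")),
                 tolerance = NA_real_),
            class = "fixture_case")
}

#' Grid-independence fixture suite
#'
#' The same scenario at successive resolutions, with the expected behaviour
#' (relative change between the two finest grids below the stated bound).
#'
#' @param sc base `scenario`.
#' @param spacings strictly decreasing spacings, m (>= 3).
#' @param target relative-change target between the two finest grids.
#' @return a `fixture_case` whose `cases` are per-spacing scenarios.
#' @export
make_grid_independence_suite <- function(sc, spacings, target = 0.005) {
  if (length(spacings) < 3) {
    stop("make_grid_independence_suite(): need at least 3 spacings")
  }
  if (any(diff(spacings) >= 0)) {
    stop("make_grid_independence_suite(): spacings must decrease")
  }
  cases <- lapply(spacings, function(hh) { s <- sc; s$spacing <- hh; s })
  structure(list(name = "grid_independence", cases = cases,
                 spacings = spacings,
                 expected = list(rel_change = list(
                   value = target,
                   provenance = "grid-independence criterion on tissue averages")),
                 tolerance = target),
            class = "fixture_case")
}

#' Stokes-sphere verification fixture
#'
#' An isolated no-slip sphere in a uniform far stream: the exact
#' low-Reynolds solution is imposed as Dirichlet data on the outer box so
#' the discretization error can be measured on a modest domain.  The exact
#' maximum surface shear stress is `1.5 mu U / a` at the equator.
#'
#' @param a sphere radius, m.
#' @param U far-field speed, m/s.
#' @param mu viscosity, Pa s.
#' @param box_factor outer box edge in units of `a`.
#' @param cells_per_radius resolution.
#' @return list with `grid`, `mms` (exact solution functions), `params`,
#'   `tau_exact`.
#' @export
make_stokes_sphere_case <- function(a = 50e-6, U = 1e-4,
                                    mu = default_physical_params()$mu,
                                    box_factor = 5, cells_per_radius = 10) {
  spacing <- a / cells_per_radius
  L <- box_factor * a
  n <- as.integer(round(L / spacing))
  grid <- make_box_grid(c(n, n, n), spacing)
  ctr <- rep(n * spacing / 2, 3)
  co <- grid_coord_arrays(grid)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  sdf <- array(sphere_sdf(pts, a, ctr), grid$dims)
  grid$label[sdf < 0] <- REGION_LABELS[["TISSUE"]]
  grid$sdf <- sdf
  comp <- function(i) {
    force(i)
    function(x, y, z) {
      dx <- x - ctr[1]; dy <- y - ctr[2]; dz <- z - ctr[3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      r <- pmax(r, a / 10)
      A <- 1 - 3 * a / (4 * r) - a^3 / (4 * r^3)
      B <- -3 * a / (4 * r) + 3 * a^3 / (4 * r^3)
      x1 <- dx / r
      xi <- switch(i, dx, dy, dz) / r
      val <- U * (A * (i == 1) + B * x1 * xi)
      val[r < a] <- 0
      val
    }
  }
  list(grid = grid,
       mms = list(u = comp(1), v = comp(2), w = comp(3)),
       params = physical_params(rho = 1000, mu = mu, Q = 1),
       U = U, a = a, mu = mu,
       tau_exact = 1.5 * mu * U / a)
}

# `aggtrap fixtures <name>`: write a fixture's config and expected values.
emit_fixture <- function(name, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- switch(name,
    validation_sphere = make_validation_sphere("ci"),
    mini_chip = make_mini_chip("ci"),
    stop("unknown fixture '", name, "'"))
  if (!is.null(fx$scenario)) {
    write_scenario_config(fx$scenario,
                          file.path(dir, paste0(fx$name, "_config.json")))
  }
  jsonlite::write_json(list(name = fx$name, expected = fx$expected,
                            tolerance = fx$tolerance),
                       file.path(dir, paste0(fx$name, "_expected.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote fixture '", fx$name, "' to ", dir)
  invisible(fx)
}
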