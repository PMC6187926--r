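test_that("Michaelis-Menten rate has the canonical landmarks", {
  expect_equal(mm_rate(0.00463, 0.0203, 0.00463), 0.0203 / 2)
  expect_equal(mm_rate(0, 1, 0.1), 0)
  expect_equal(mm_rate(0.00463, 0.0203, 0.00463), 0.01015)
  # monotone, bounded by Vmax
  cgrid <- seq(0, 1, length.out = 50)
  r <- mm_rate(cgrid, 0.0203, 0.00463)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 0.0203))
  expect_error(mm_rate(-0.1, 1, 1), "negative")
})

test_that("two-material slab reproduces the series-resistance closed form exactly", {
  nx <- 8L
  h <- 200e-6 / nx
  g <- make_box_grid(c(nx + 2L, 2L, 2L), h)
  g$label[1, , ] <- REGION_LABELS[["EXTERIOR"]]
  g$label[nx + 2L, , ] <- REGION_LABELS[["EXTERIOR"]]
  g$label[2:(nx / 2 + 1), , ] <- REGION_LABELS[["MEDIUM"]]
  g$label[(nx / 2 + 2):(nx + 1), , ] <- REGION_LABELS[["PDMS"]]
  phi0 <- 0; phiL <- 0.2
  sp <- default_species("oxygen")
  # boundary values given as concentrations on the adjacent cell's side
  g$dirichlet_exterior <- function(x, y, z) {
    ifelse(x < 100e-6, phi0 * 1, phiL * sp$S_pdms)
  }
  f <- solve_species(g, sp, flow = NULL, assume_still = TRUE)
  k1 <- sp$D_medium * 1 / 100e-6
  k2 <- sp$D_pdms * sp$S_pdms / 100e-6
  phi_star <- two_layer_slab(k1, k2, phi0, phiL)$phi_interface
  ax <- aggtrap:::grid_axes(g)
  x <- ax$x
  x0 <- h; x_if <- h + 100e-6   # Dirichlet plane and material interface
  exact <- ifelse(x < x_if, phi0 + (phi_star - phi0) * (x - x0) / 100e-6,
                  phi_star + (phiL - phi_star) * (x - x_if) / 100e-6)
  idx <- 2:(nx + 1)
  expect_equal(f$phi[idx, 1, 1], exact[idx], tolerance = 1e-7)
  # solubility jump recovered: c = S phi in PDMS, phi continuous
  pd <- g$label == REGION_LABELS[["PDMS"]]
  expect_equal(f$c[pd], sp$S_pdms * f$phi[pd])
})

test_that("still medium with ambient lid settles at exact partition equilibrium", {
  spec <- small_chip_spec()
  suppressWarnings(g <- build_domain(spec, 10e-6, coarse_ok = TRUE))
  sp <- default_species("oxygen")
  sp$Vmax <- 0     # no consumption: pure equilibrium
  f <- solve_species(g, sp, flow = NULL, assume_still = TRUE)
  expect_equal(max(abs(f$phi - 0.2), na.rm = TRUE), 0, tolerance = 1e-8)
  pdms <- g$label == REGION_LABELS[["PDMS"]]
  expect_equal(unique(round(f$c[pdms], 8)), 1.2)
  tis <- g$label == REGION_LABELS[["TISSUE"]]
  expect_equal(mean(f$c[tis]), 4.81 * 0.2, tolerance = 1e-7)
})

test_that("zero reaction with uniform inlet gives a uniform concentration", {
  g <- make_box_grid(c(20, 8, 10), 10e-6)
  p <- default_physical_params(); p$Q <- 1e-11
  fl <- solve_flow(g, p, solver_settings())
  sp <- plain_species(D = 2.6e-9, c_inlet = 0.2)
  f <- solve_species(g, sp, fl)
  expect_equal(max(abs(f$c - 0.2)), 0, tolerance = 1e-6)
})

test_that("flow field is required when medium cells are advected", {
  g <- make_box_grid(c(8, 4, 4), 10e-6)
  sp <- plain_species(D = 1e-9, c_inlet = 1)
  expect_error(solve_species(g, sp, flow = NULL), "flow field required")
})

test_that("sphere fixture: maximum principle, monotone parameter responses, conservation", {
  Rs <- 50e-6; D <- 1.83e-9; cs <- 0.2
  g <- sphere_fixture_grid(Rs, 4e-6, cs)
  base <- species_spec("ox", D_medium = D, D_tissue = D, S_tissue = 1,
                       Vmax = 0.4, Km = 0.00463, c_inlet = cs,
                       pdms_permeable = FALSE)
  st <- solver_settings(transport_residual_tol = 1e-6)
  f <- solve_species(g, base, flow = NULL, settings = st)
  tis <- g$label == REGION_LABELS[["TISSUE"]]
  # maximum principle: sinks only, so no interior value above the boundary
  expect_lte(max(f$c[tis]), cs * (1 + 1e-9))
  expect_gte(min(f$c[tis]), 0)
  # conservation: surface influx balances consumption
  expect_equal(f$influx, f$consumed, tolerance = 2e-3)
  # raising Vmax cannot raise the average
  sp2 <- base; sp2$Vmax <- base$Vmax * 2
  f2 <- solve_species(g, sp2, flow = NULL, settings = st)
  expect_lt(mean(f2$c[tis]), mean(f$c[tis]))
  # raising D_tissue cannot lower the minimum
  sp3 <- base; sp3$D_tissue <- base$D_tissue * 2
  f3 <- solve_species(g, sp3, flow = NULL, settings = st)
  expect_gt(min(f3$c[tis]), min(f$c[tis]))
})

test_that("Km -> 0 with Vmax = A recovers the constant-rate solution", {
  Rs <- 50e-6; D <- 1.83e-9; cs <- 0.2; A <- 0.3
  g <- sphere_fixture_grid(Rs, 4e-6, cs)
  sp <- species_spec("ox", D_medium = D, D_tissue = D, S_tissue = 1,
                     Vmax = A, Km = 1e-9, c_inlet = cs,
                     pdms_permeable = FALSE)
  st <- solver_settings(transport_residual_tol = 1e-6)
  f_mm <- solve_species(g, sp, flow = NULL, settings = st)
  f_cr <- solve_species(g, sp, flow = NULL, settings = st, constant_rate = A)
  tis <- g$label == REGION_LABELS[["TISSUE"]]
  expect_gt(min(f_cr$c[tis]), 0)  # stays positive, so the limits coincide
  expect_lt(max(abs(f_mm$c[tis] - f_cr$c[tis])) / cs, 1e-3)
})

test_that("removing the PDMS lid strictly lowers average tissue oxygen", {
  spec <- small_chip_spec()
  suppressWarnings(g_lid <- build_domain(spec, 10e-6, coarse_ok = TRUE))
  spec_nolid <- small_chip_spec(lid_thickness = 0)
  suppressWarnings(g_no <- build_domain(spec_nolid, 10e-6, coarse_ok = TRUE))
  sp <- default_species("oxygen")
  sp$Vmax <- sp$Vmax * 16   # mini-scale consumption (see fixture scaling)
  st <- solver_settings(transport_residual_tol = 1e-6)
  f_lid <- solve_species(g_lid, sp, flow = NULL, settings = st,
                         assume_still = TRUE)
  f_no <- solve_species(g_no, sp, flow = NULL, settings = st,
                        assume_still = TRUE)
  a_lid <- region_average(f_lid, g_lid)
  a_no <- region_average(f_no, g_no)
  expect_gt(a_lid, a_no)
})

test_that("advection scheme options assemble and agree at low Peclet", {
  g <- make_box_grid(c(16, 6, 6), 10e-6)
  p <- default_physical_params(); p$Q <- 2e-12  # low Pe
  fl <- solve_flow(g, p, solver_settings())
  sp <- plain_species(D = 2.6e-9, c_inlet = 0.2)
  res <- lapply(c("powerlaw", "upwind", "central"), function(s) {
    solve_species(g, sp, fl, settings = solver_settings(advection_scheme = s))
  })
  expect_equal(res[[1]]$c, res[[2]]$c, tolerance = 1e-4)
  expect_equal(res[[1]]$c, res[[3]]$c, tolerance = 1e-4)
})
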