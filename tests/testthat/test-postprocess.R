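fake_field <- function(grid, values) {
  structure(list(c = values, grid = grid), class = "concentration_field")
}

test_that("region statistics behave on constructed fields", {
  g <- make_box_grid(c(4, 4, 6), 10e-6, label = "TISSUE")
  f <- fake_field(g, array(0.5, g$dims))
  expect_equal(region_average(f, g), 0.5)
  expect_equal(region_min(f, g), 0.5)
  # linear-in-z field over a box: mean equals the mid-height value
  ax <- aggtrap:::grid_axes(g)
  vals <- array(rep(ax$z, each = 16), g$dims)
  fz <- fake_field(g, vals)
  expect_equal(region_average(fz, g), mean(range(ax$z)))
  expect_lte(region_min(fz, g), region_average(fz, g))
  expect_error(region_average(f, g, region = "MEDIUM"), "empty")
  expect_error(region_average(f, g, region = "bogus"), "unknown region")
})

test_that("hypoxic fraction counts tissue below threshold", {
  g <- make_box_grid(c(4, 4, 4), 10e-6, label = "TISSUE")
  f <- fake_field(g, array(0.5, g$dims))
  expect_equal(hypoxic_fraction(f, g), 0)
  expect_equal(hypoxic_fraction(f, g, threshold = 1), 1)
  # constant-rate sphere with a hypoxic core: fraction ~ (b/Rs)^3
  Rs <- 60e-6; cs <- 0.2; A <- 0.8; D <- 1.83e-9
  g2 <- sphere_fixture_grid(Rs, 2.5e-6, cs)
  sp <- plain_species(D = D, c_inlet = cs, Vmax = 1)
  f2 <- solve_species(g2, sp, flow = NULL, constant_rate = A)
  model <- sphere_model(Rs, A, D, cs)
  b <- as.numeric(hypoxic_radius(model))
  expect_true(is.finite(b))
  expect_equal(hypoxic_fraction(f2, g2), (b / Rs)^3, tolerance = 0.25)
})

test_that("plane Couette shear over a flat floor is exact", {
  g <- make_box_grid(c(6, 4, 12), 10e-6)
  g$label[, , 1] <- REGION_LABELS[["SOLID"]]
  gamma <- 50  # 1/s
  d <- g$dims; h <- g$spacing
  ax <- aggtrap:::grid_axes(g)
  wall_z <- h  # top of the solid layer
  f <- make_uniform_flow(g, c(0, 0, 0))
  for (k in seq_len(d[3])) f$u[, , k] <- gamma * max(ax$z[k] - wall_z, 0)
  mu <- 6.92e-4
  tau <- max_surface_shear(f, g, surface_region = "SOLID", mu = mu)
  expect_equal(tau, mu * gamma, tolerance = 1e-10)
})

test_that("pressure-driven slot flow recovers the 6 mu U / H wall shear", {
  # slot of height H = 20 cells between a solid floor layer and the top wall
  g <- make_box_grid(c(16, 4, 21), 10e-6)
  g$label[, , 1] <- REGION_LABELS[["SOLID"]]
  p <- default_physical_params(); p$Q <- 1e-11
  f <- solve_flow(g, p, solver_settings())
  H <- 20 * g$spacing
  open <- g$label[1, , ] == REGION_LABELS[["MEDIUM"]]
  U <- sum(f$u[1, , ]) * g$spacing^2 / (sum(open) * g$spacing^2)
  tau <- max_surface_shear(f, g, surface_region = "SOLID", mu = p$mu)
  expect_equal(tau, 6 * p$mu * U / H, tolerance = 0.05)
})

test_that("shear scales linearly with Q in Stokes mode", {
  g <- make_box_grid(c(16, 4, 21), 10e-6)
  g$label[, , 1] <- REGION_LABELS[["SOLID"]]
  p <- default_physical_params(); p$Q <- 1e-11
  f1 <- solve_flow(g, p, solver_settings())
  p$Q <- 3e-11
  f3 <- solve_flow(g, p, solver_settings())
  t1 <- max_surface_shear(f1, g, surface_region = "SOLID", mu = p$mu)
  t3 <- max_surface_shear(f3, g, surface_region = "SOLID", mu = p$mu)
  expect_equal(t3 / t1, 3, tolerance = 1e-6)
})

test_that("outputs round-trip: CSV metrics, VTK arrays, provenance schema", {
  fx <- make_mini_chip("ci", "spheroid", "u_barrier")
  sc <- fx$scenario
  sc$spacing <- sc$geometry$minor_radius / 2.5   # extra coarse smoke scale
  sc$output_dir <- file.path(tempdir(), "aggtrap-out")
  sc$stem <- "smoke"
  out <- suppressWarnings(run_scenario(sc))
  paths <- out$paths
  expect_true(all(file.exists(unlist(paths))))
  met <- utils::read.csv(paths$csv)
  expect_equal(met$c_ave_oxygen, out$metrics$c_ave_oxygen)
  expect_equal(met$tau_max, out$metrics$tau_max)
  lns <- readLines(paths$vtk)
  expect_true(any(grepl("SCALARS label int", lns)))
  expect_true(any(grepl("SCALARS c_oxygen", lns)))
  expect_true(any(grepl("SCALARS c_glucose", lns)))
  expect_true(any(grepl("VECTORS velocity", lns)))
  expect_true(validate_provenance(paths$json))
  # provenance completeness: the stored config regenerates the same metrics
  prov <- jsonlite::read_json(paths$json, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  sc2 <- scenario_from_list(prov$config)
  sc2$output_dir <- NULL
  out2 <- suppressWarnings(run_scenario(sc2))
  # unit conversion at the config boundary costs the last couple of bits, so
  # the physical metrics regenerate to solver precision (the convergence
  # diagnostics are solver noise and not compared)
  phys <- c("c_ave_oxygen", "c_min_oxygen", "c_ave_glucose", "c_min_glucose",
            "hypoxic_fraction", "tau_max", "vol_tissue", "vol_medium")
  expect_equal(unclass(out2$metrics)[phys], unclass(out$metrics)[phys],
               tolerance = 1e-8)
})
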