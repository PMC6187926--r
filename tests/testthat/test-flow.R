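# Shared small solves reused across blocks (computed once per test run).
chip10 <- local({
  spec <- small_chip_spec(half_width = FALSE, aggregate_kind = "spheroid")
  suppressWarnings(grid <- build_domain(spec, 10e-6, coarse_ok = TRUE))
  params <- default_physical_params()
  params$Q <- params$Q / 4
  flow <- solve_flow(grid, params, solver_settings())
  list(spec = spec, grid = grid, params = params, flow = flow)
})

test_that("inlet profile integrates to Q and matches duct closed forms", {
  g <- make_box_grid(c(4, 20, 16), 10e-6)
  Q <- 2.5e-11
  ip <- inlet_profile(Q, g)
  expect_equal(sum(ip$values) * g$spacing^2, Q, tolerance = 1e-12)
  # wide-slot limit: centreline over mean -> 3/2
  gs <- make_box_grid(c(4, 200, 20), 10e-6)
  ips <- inlet_profile(Q, gs)
  expect_equal(max(ips$values) / mean(ips$values[ips$open]), 1.5,
               tolerance = 0.01)
  # square duct (no-slip on all four sides): max/mean ~ 2.096
  gd <- make_box_grid(c(4, 42, 40), 10e-6)
  gd$label[, c(1, 42), ] <- REGION_LABELS[["SOLID"]]
  ipd <- inlet_profile(Q, gd)
  expect_equal(max(ipd$values) / mean(ipd$values[ipd$open]), 2.096,
               tolerance = 0.02)
  gb <- make_box_grid(c(4, 4, 4), 10e-6, label = "SOLID")
  expect_error(inlet_profile(Q, gb), "blocked")
})

test_that("empty channel keeps the fully developed profile and conserves mass", {
  g <- make_box_grid(c(24, 10, 12), 10e-6)
  p <- default_physical_params(); p$Q <- 1e-11
  f <- solve_flow(g, p, solver_settings())
  rep_ <- flow_report(f)
  expect_lt(max(abs(f$u[25, , ] - f$u[1, , ])) / max(f$u[1, , ]), 1e-6)
  expect_lt(rep_$mass_balance, 1e-8)
  expect_lt(f$diagnostics$max_divergence * g$spacing / rep_$max_velocity, 1e-7)
  # Stokes linearity: doubling Q doubles every velocity component
  p2 <- p; p2$Q <- 2 * p$Q
  f2 <- solve_flow(g, p2, solver_settings())
  expect_equal(f2$u, 2 * f$u, tolerance = 1e-9)
  expect_equal(f2$w, 2 * f$w, tolerance = 1e-9)
})

test_that("flow errors are informative", {
  g <- make_box_grid(c(8, 4, 4), 10e-6)
  g$label[1, , ] <- REGION_LABELS[["SOLID"]]
  expect_error(solve_flow(g, default_physical_params()), "INLET")
  g2 <- make_box_grid(c(8, 4, 4), 10e-6)
  g2$label[8, , ] <- REGION_LABELS[["SOLID"]]
  expect_error(solve_flow(g2, default_physical_params()), "OUTLET")
})

test_that("manufactured Stokes solution converges at the scheme design order", {
  mc <- manufactured_case("div_free_velocity", L = 1e-3, U0 = 1e-4,
                          mu = 6.92e-4)
  mms <- list(u = mc$u, v = mc$v, w = mc$w, fu = mc$fx, fv = mc$fy,
              fw = mc$fz)
  params <- physical_params(rho = 1000, mu = 6.92e-4, Q = 1)
  errs <- vapply(c(8L, 16L, 32L), function(n) {
    g <- make_box_grid(rep(n, 3), 1e-3 / n)
    f <- solve_flow(g, params, solver_settings(), mms = mms)
    d <- g$dims; h <- g$spacing
    ax <- aggtrap:::grid_axes(g)
    xf <- c(ax$x - h / 2, max(ax$x) + h / 2)
    ue <- array(0, d + c(1, 0, 0))
    for (i in seq_len(d[1] + 1)) for (k in seq_len(d[3]))
      ue[i, , k] <- mc$u(xf[i], ax$y, ax$z[k])
    max(abs(f$u - ue))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_gt(min(orders), 1.5)
})

test_that("solution is mirror-symmetric for y-symmetric geometry", {
  f <- chip10$flow
  d <- chip10$grid$dims
  umax <- f$diagnostics$velocity_scale
  u_flip <- f$u[, d[2]:1, ]
  expect_lt(max(abs(f$u - u_flip)) / umax, 1e-7)
  v_flip <- -f$v[, (d[2] + 1):1, ]
  expect_lt(max(abs(f$v - v_flip)) / umax, 1e-7)
})

test_that("velocity vanishes inside and on the aggregate; diagnostics sane", {
  g <- chip10$grid
  f <- chip10$flow
  d <- g$dims
  tis <- g$label == REGION_LABELS[["TISSUE"]]
  # faces adjacent to tissue cells carry zero velocity (no slip + no flow
  # inside the aggregate)
  uW <- f$u[1:d[1], , ][tis]; uE <- f$u[2:(d[1] + 1), , ][tis]
  expect_true(all(uW == 0) && all(uE == 0))
  rep_ <- flow_report(f)
  expect_lt(rep_$Re, 1)
  expect_lt(rep_$mass_balance, 1e-8)
  expect_true(all(rep_$cell_peclet > 0))
})

test_that("inertial Picard correction barely changes the Stokes field at Re << 1", {
  g <- make_box_grid(c(16, 8, 8), 10e-6)
  p <- default_physical_params(); p$Q <- 1e-11
  f0 <- solve_flow(g, p, solver_settings())
  fi <- solve_flow(g, p, solver_settings(include_inertia = TRUE,
                                         max_iterations = 5L))
  expect_lt(max(abs(fi$u - f0$u)) / max(abs(f0$u)), 1e-2)
})
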