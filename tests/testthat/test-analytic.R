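ref_model <- sphere_model(Rs = 500e-6, A = 0.005, D = 1.83e-9, c_surface = 0.2)

test_that("constant-rate sphere profile evaluates the closed form", {
  expect_equal(constant_rate_profile(ref_model, 500e-6), 0.2)
  # frozen value computed from the closed form: A/(6D) (0 - Rs^2) + cs
  expect_equal(constant_rate_profile(ref_model, 0), 0.08615665, tolerance = 1e-6)
  m0 <- sphere_model(Rs = 500e-6, A = 0, D = 1.83e-9, c_surface = 0.2)
  expect_equal(constant_rate_profile(m0, c(0, 2e-4, 5e-4)), rep(0.2, 3))
  expect_error(constant_rate_profile(ref_model, 6e-4))
  expect_error(constant_rate_profile(ref_model, -1e-6))
  # exactly quadratic: second differences are constant = 2 * A/(6D)
  b <- seq(0, 5e-4, length.out = 11)
  d2 <- diff(diff(constant_rate_profile(ref_model, b)))
  expect_equal(d2, rep(d2[1], 9))
  # d2/h^2 = 2 A/(6D) = A/(3D), i.e. the 1D Laplacian of the radial profile
  expect_equal(d2[1] / diff(b)[1]^2, ref_model$A / (3 * ref_model$D),
               tolerance = 1e-10)
})

test_that("hypoxic radius inverts the profile and has the right critical size", {
  # no core below the critical radius sqrt(6 D (cs - ct) / A) ~ 511 um
  crit <- sqrt(6 * 1.83e-9 * (0.1322 - 0.01322) / 0.005)
  expect_equal(crit, 511.15e-6, tolerance = 1e-4)
  below <- sphere_model(Rs = 0.99 * crit, A = 0.005, D = 1.83e-9,
                        c_surface = 0.1322)
  above <- sphere_model(Rs = 1.05 * crit, A = 0.005, D = 1.83e-9,
                        c_surface = 0.1322)
  expect_true(is.na(hypoxic_radius(below)))
  expect_false(attr(hypoxic_radius(below), "has_core"))
  b_above <- hypoxic_radius(above)
  expect_true(attr(b_above, "has_core"))
  # mutual inverse: profile at the hypoxic radius equals the threshold
  expect_equal(constant_rate_profile(above, as.numeric(b_above)),
               above$c_threshold)
  # threshold approaching the surface value pushes the radius to Rs
  near <- sphere_model(Rs = 600e-6, A = 0.005, D = 1.83e-9,
                       c_surface = 0.2, c_threshold = 0.2 - 1e-9)
  expect_equal(as.numeric(hypoxic_radius(near)), 600e-6, tolerance = 1e-3)
  # monotone increasing in Rs where defined
  radii <- seq(5.4e-4, 8e-4, length.out = 6)
  bs <- vapply(radii, function(R) {
    as.numeric(hypoxic_radius(sphere_model(R, 0.005, 1.83e-9, 0.1322)))
  }, numeric(1))
  expect_true(all(diff(bs) > 0))
})

test_that("1D Michaelis-Menten oracle has the right limits and conserves flux", {
  # Vmax = 0: uniform profile
  o0 <- mm_radial_oracle(2e-4, 1.83e-9, 0, 0.01, 0.2)
  expect_equal(o0$c, rep(0.2, length(o0$c)))
  # Km -> 0 with c > 0 recovers the constant-rate closed form within 0.1%
  o <- mm_radial_oracle(500e-6, 1.83e-9, 0.005, 1e-12, 0.2)
  expect_lt(max(abs(o$c - constant_rate_profile(ref_model, o$b))) / 0.2, 1e-3)
  # flux conservation: surface influx equals integrated consumption
  om <- mm_radial_oracle(300e-6, 1.83e-9, 0.0203, 0.00463, 0.2)
  expect_equal(om$influx, om$consumed, tolerance = 1e-3)
  # self-convergence: doubling the resolution barely moves the profile
  oa <- mm_radial_oracle(300e-6, 1.83e-9, 0.0203, 0.00463, 0.2, n = 400)
  ob <- mm_radial_oracle(300e-6, 1.83e-9, 0.0203, 0.00463, 0.2, n = 800)
  ca <- approx(oa$b, oa$c, xout = ob$b)$y
  expect_lt(max(abs(ca - ob$c)) / 0.2, 1e-4)
})

test_that("two-layer slab closed form behaves as series resistance", {
  expect_equal(two_layer_slab(1, 2, 0.3, 0.3),
               list(phi_interface = 0.3, flux = 0))
  expect_equal(two_layer_slab(5, 5, 0, 1)$phi_interface, 0.5)
  # reference layers: 100 um medium vs 100 um PDMS
  k1 <- 2.6e-9 * 1 / 100e-6
  k2 <- 3.4e-9 * 6 / 100e-6
  expect_equal(two_layer_slab(k1, k2, 0, 0.2)$phi_interface,
               0.2 * 20.4 / 23.0, tolerance = 1e-10)
  expect_error(two_layer_slab(-1, 2, 0, 1))
})

test_that("manufactured divergence-free velocity has vanishing discrete divergence", {
  mc <- manufactured_case("div_free_velocity", L = 1e-3)
  for (n in c(8L, 16L)) {
    g <- make_box_grid(rep(n, 3), 1e-3 / n)
    d <- g$dims; h <- g$spacing
    ax <- aggtrap:::grid_axes(g)
    u <- array(0, d + c(1, 0, 0)); v <- array(0, d + c(0, 1, 0))
    w <- array(0, d + c(0, 0, 1))
    xf <- c(ax$x - h / 2, max(ax$x) + h / 2)
    yf <- c(ax$y - h / 2, max(ax$y) + h / 2)
    zf <- c(ax$z - h / 2, max(ax$z) + h / 2)
    for (i in seq_len(d[1] + 1)) for (k in seq_len(d[3]))
      u[i, , k] <- mc$u(xf[i], ax$y, ax$z[k])
    for (j in seq_len(d[2] + 1)) for (k in seq_len(d[3]))
      v[, j, k] <- mc$v(ax$x, yf[j], ax$z[k])
    for (k in seq_len(d[3] + 1)) for (j in seq_len(d[2]))
      w[, j, k] <- mc$w(ax$x, ax$y[j], zf[k])
    divv <- (u[2:(d[1] + 1), , ] - u[1:d[1], , ] +
             v[, 2:(d[2] + 1), ] - v[, 1:d[2], ] +
             w[, , 2:(d[3] + 1)] - w[, , 1:d[3]]) / h
    expect_lt(max(abs(divv)), 1e-12 * max(abs(u)) / h)
  }
})

test_that("unknown manufactured case errors", {
  expect_error(manufactured_case("nope"), "unknown case")
})
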