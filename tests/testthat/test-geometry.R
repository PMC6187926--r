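test_that("torus signed distance has the closed-form landmarks", {
  R <- 160e-6; r <- 80e-6
  # torus centre (on the axis): distance R - r
  expect_equal(torus_sdf(c(0, 0, 0), R, r), 80e-6)
  # deepest interior: on the tube centreline circle
  expect_equal(torus_sdf(c(R, 0, 0), R, r), -r)
  # surface: at R + r from the axis in the midplane
  expect_equal(torus_sdf(c(R + r, 0, 0), R, r), 0)
  # arbitrary axis, matrix input
  ax <- c(1, 0, 0)
  pts <- rbind(c(0, R, 0), c(0, 0, R + r), c(0, 0, 0))
  expect_equal(torus_sdf(pts, R, r, axis = ax), c(-r, 0, R - r))
  expect_error(torus_sdf(c(0, 0, 0), R, r, axis = c(1, 1, 0)), "unit")
  expect_error(torus_sdf(c(0, 0, 0), r, R))
})

test_that("sphere signed distance and voxel volume converge", {
  Rs <- 115.6e-6
  expect_equal(sphere_sdf(c(0, 0, 0), Rs), -Rs)
  expect_equal(sphere_sdf(c(0, 0, 2 * Rs), Rs), Rs)
  h <- 2e-6
  n <- as.integer(ceiling(2 * (Rs + 2 * h) / h))
  g <- make_box_grid(rep(n, 3), h, label = "EXTERIOR")
  co <- aggtrap:::grid_coord_arrays(g)
  ctr <- rep(n * h / 2, 3)
  inside <- sphere_sdf(cbind(as.vector(co$x), as.vector(co$y),
                             as.vector(co$z)), Rs, ctr) < 0
  vox <- sum(inside) * h^3
  expect_equal(vox, 4 / 3 * pi * Rs^3, tolerance = 0.01)
})

test_that("equal-volume spheroid radius honours both conventions", {
  r <- 80e-6; R <- 160e-6
  expect_equal(equal_volume_spheroid_radius(r, R, "as_printed"),
               ((3 / 2) * r^2 * R)^(1 / 3))
  expect_equal(equal_volume_spheroid_radius(r, R, "as_printed"),
               115.38e-6, tolerance = 1e-4)
  Rs <- equal_volume_spheroid_radius(r, R, "true_equal_volume")
  expect_equal(Rs, 169.0e-6, tolerance = 1e-3)
  # true mode equates the sphere and torus volumes
  expect_equal(4 / 3 * pi * Rs^3, 2 * pi^2 * R * r^2, tolerance = 1e-12)
  expect_equal(equal_volume_spheroid_radius(0, R), 0)
  expect_error(equal_volume_spheroid_radius(r, R, "nonsense"))
})

test_that("voxelized domains conserve aggregate volume and partition labels", {
  spec <- geometry_spec(trap_height = 250e-6, channel_width = 600e-6,
                        channel_height = 300e-6, channel_length = 700e-6,
                        lid_thickness = 60e-6)
  expect_warning(g <- build_domain(spec, 8e-6), "margin")
  vols <- domain_volumes(g)
  expect_equal(vols[["TISSUE"]], 2 * pi^2 * 160e-6 * (80e-6)^2,
               tolerance = 0.02)
  # labels partition the grid
  expect_true(all(g$label %in% REGION_LABELS))
  expect_equal(sum(vols), prod(g$dims) * g$spacing^3)
  # refinement moves the tissue volume by less than 1%
  suppressWarnings(g2 <- build_domain(spec, 5e-6))
  expect_lt(abs(domain_volumes(g2)[["TISSUE"]] / vols[["TISSUE"]] - 1), 0.01)
})

test_that("vertical toroid keeps an open, medium-connected lumen", {
  spec <- small_chip_spec(aggregate_kind = "toroid_vertical",
                          half_width = FALSE)
  suppressWarnings(g <- build_domain(spec, 5e-6))
  expect_true(aggtrap:::lumen_is_open(g))
  spec_h <- small_chip_spec(half_width = FALSE)
  suppressWarnings(gh <- build_domain(spec_h, 5e-6))
  # horizontal toroid: lumen along z is blocked for x-directed flow queries
  expect_true(is.logical(aggtrap:::lumen_is_open(gh)))
})

test_that("clearance violations fail loudly with the offending direction", {
  expect_error(small_chip_spec(barrier_wall_thickness = 30e-6,
                               aggregate_kind = "toroid_vertical"),
               "clearance")
  expect_error(small_chip_spec(minor_radius = 40e-6), "clearance")
  # u-barrier taller than the channel is rejected
  expect_error(small_chip_spec(trap_height = 300e-6), "channel_height")
})

test_that("microwell geometry recesses the cavity below the channel floor", {
  spec <- small_chip_spec(trap_kind = "microwell")
  suppressWarnings(g <- build_domain(spec, 5e-6))
  ax <- aggtrap:::grid_axes(g)
  below <- which(ax$z < 0)
  tb <- aggtrap:::trap_box(spec)
  outside_x <- which(ax$x < tb$x[1] | ax$x > tb$x[2])
  # no medium below the channel floor outside the well footprint
  expect_true(all(g$label[outside_x, , below] != REGION_LABELS[["MEDIUM"]]))
  # substrate is impermeable (SOLID) by default; PDMS when flagged diffusive
  expect_true(any(g$label[, , below] == REGION_LABELS[["SOLID"]]))
  expect_false(any(g$label[, , below] == REGION_LABELS[["PDMS"]]))
  spec2 <- small_chip_spec(trap_kind = "microwell",
                           well_substrate_is_pdms = TRUE)
  suppressWarnings(g2 <- build_domain(spec2, 5e-6))
  expect_true(any(g2$label[, , below] == REGION_LABELS[["PDMS"]]))
})

test_that("boundary faces carry exactly one tag each, as configured", {
  spec <- small_chip_spec()
  suppressWarnings(g <- build_domain(spec, 10e-6, coarse_ok = TRUE))
  tags <- boundary_face_tags(g)
  expect_true(all(tags$tag %in% c("INLET", "OUTLET", "SYMMETRY",
                                  "LID_AMBIENT", "NOFLUX_WALL")))
  # medium faces at the streamwise ends
  expect_true(all(tags$tag[tags$side == "xlo" &
                           g$label[tags$index] == REGION_LABELS[["MEDIUM"]]] ==
                  "INLET"))
  expect_true(all(tags$tag[tags$side == "xhi" &
                           g$label[tags$index] == REGION_LABELS[["MEDIUM"]]] ==
                  "OUTLET"))
  # lid top is ambient; bottom is a no-flux wall
  expect_true(all(tags$tag[tags$side == "zhi" &
                           g$label[tags$index] == REGION_LABELS[["PDMS"]]] ==
                  "LID_AMBIENT"))
  expect_true(all(tags$tag[tags$side == "zlo"] == "NOFLUX_WALL"))
  # spanwise sides of medium and PDMS are symmetry planes
  ylo <- tags[tags$side == "ylo", ]
  expect_true(all(ylo$tag[g$label[ylo$index] != REGION_LABELS[["SOLID"]]] ==
                  "SYMMETRY"))
  # one record per boundary face
  expect_equal(anyDuplicated(tags[c("side", "index")]), 0L)
})

test_that("tissue cells never touch structural cells when the margin resolves", {
  spec <- small_chip_spec(margin = 8e-6, minor_radius = 15e-6)
  g <- build_domain(spec, 3.5e-6)
  tis <- g$label == REGION_LABELS[["TISSUE"]]
  bad <- array(FALSE, g$dims)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    dv <- c(0L, 0L, 0L); dv[ax] <- s
    nb <- aggtrap:::shift3(g$label, dv, REGION_LABELS[["MEDIUM"]])
    bad <- bad | (tis & (nb == REGION_LABELS[["PDMS"]] |
                         nb == REGION_LABELS[["SOLID"]]))
  }
  expect_false(any(bad))
})
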