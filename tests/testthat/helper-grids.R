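# Shared builders for small synthetic test domains.

# Sphere of tissue in an EXTERIOR box with a surface Dirichlet value.
sphere_fixture_grid <- function(Rs, spacing, c_surface, pad_cells = 2L) {
  pad <- pad_cells * spacing
  n <- as.integer(ceiling(2 * (Rs + pad) / spacing))
  grid <- make_box_grid(c(n, n, n), spacing, label = "EXTERIOR")
  ctr <- rep(n * spacing / 2, 3)
  co <- aggtrap:::grid_coord_arrays(grid)
  sdf <- array(sphere_sdf(cbind(as.vector(co$x), as.vector(co$y),
                                as.vector(co$z)), Rs, ctr), grid$dims)
  grid$label[sdf < 0] <- REGION_LABELS[["TISSUE"]]
  grid$sdf <- sdf
  grid$dirichlet_exterior <- c_surface
  grid$center <- ctr
  grid
}

# Radii of tissue cells from the fixture centre.
sphere_fixture_radii <- function(grid, Rs) {
  sel <- grid$label == REGION_LABELS[["TISSUE"]]
  co <- aggtrap:::grid_coord_arrays(grid)
  ctr <- grid$center
  b <- sqrt((co$x[sel] - ctr[1])^2 + (co$y[sel] - ctr[2])^2 +
            (co$z[sel] - ctr[3])^2)
  pmin(b, Rs)
}

# Species carrying a single diffusivity everywhere (no partition jump).
plain_species <- function(D, c_inlet, Vmax = 0, Km = 1e-3) {
  species_spec("test", D_medium = D, D_tissue = D, S_tissue = 1,
               Vmax = Vmax, Km = Km, c_inlet = c_inlet,
               pdms_permeable = FALSE)
}

# Compact full-physics device spec that voxelizes quickly.
small_chip_spec <- function(...) {
  args <- list(
    trap_kind = "u_barrier",
    trap_height = 150e-6, trap_length = 150e-6,
    trap_footprint_area = 150e-6 * 134e-6,
    barrier_wall_thickness = 6e-6,
    aggregate_kind = "toroid_horizontal",
    minor_radius = 20e-6, aspect_ratio = 2, margin = 0.25e-6,
    channel_width = 250e-6, channel_height = 200e-6,
    channel_length = 650e-6, lid_thickness = 50e-6,
    half_width = TRUE)
  args[names(list(...))] <- list(...)
  do.call(geometry_spec, args)
}
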