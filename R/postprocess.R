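# Metrics reported for each scenario: region averages/minima, hypoxic
# fraction, and the maximum tangential traction (shear stress) on the
# aggregate surface, plus VTK/CSV/JSON writers.

region_id <- function(region) {
  if (is.character(region)) {
    if (!region %in% names(REGION_LABELS)) {
      stop("unknown region '", region, "'")
    }
    REGION_LABELS[[region]]
  } else as.integer(region)
}

#' Volume-weighted mean concentration over a region
#'
#' Cells are uniform voxels, so the volume-weighted mean is the plain mean
#' over cells carrying the region label (no sub-cell interface correction;
#' resolution requirements are set by the grid-independence check).
#'
#' @param field a `concentration_field`.
#' @param grid a `labeled_grid` (defaults to the field's grid).
#' @param region region name (default `"TISSUE"`).
#' @return mean concentration, mol/m^3.
#' @export
region_average <- function(field, grid = field$grid, region = "TISSUE") {
  lab <- region_id(region)
  sel <- grid$label == lab
  if (!any(sel)) stop("region_average(): empty region ", region)
  mean(field$c[sel])
}

#' Minimum concentration over a region
#'
#' @inheritParams region_average
#' @return minimum concentration, mol/m^3.
#' @export
region_min <- function(field, grid = field$grid, region = "TISSUE") {
  lab <- region_id(region)
  sel <- grid$label == lab
  if (!any(sel)) stop("region_min(): empty region ", region)
  min(field$c[sel])
}

#' Hypoxic volume fraction
#'
#' Fraction of the tissue volume whose concentration lies below the given
#' threshold (default: the 10 mmHg oxygen equivalent).
#'
#' @inheritParams region_average
#' @param threshold concentration threshold, mol/m^3.
#' @return fraction in `[0, 1]`.
#' @export
hypoxic_fraction <- function(field, grid = field$grid,
                             threshold = HYPOXIA_THRESHOLD_MM) {
  stopifnot(threshold > 0)
  sel <- grid$label == REGION_LABELS[["TISSUE"]]
  if (!any(sel)) stop("hypoxic_fraction(): no tissue cells")
  mean(field$c[sel] < threshold)
}

# cell-centred velocity components from staggered face arrays
cell_center_velocity <- function(flow) {
  d <- flow$grid$dims
  list(u = (flow$u[1:d[1], , , drop = FALSE] + flow$u[2:(d[1] + 1), , , drop = FALSE]) / 2,
       v = (flow$v[, 1:d[2], , drop = FALSE] + flow$v[, 2:(d[2] + 1), , drop = FALSE]) / 2,
       w = (flow$w[, , 1:d[3], drop = FALSE] + flow$w[, , 2:(d[3] + 1), drop = FALSE]) / 2)
}

# trilinear interpolation of a cell-centred array at points (n x 3), m
trilinear <- function(A, grid, pts) {
  d <- grid$dims
  h <- grid$spacing
  o <- grid$origin
  # continuous index coordinates (cell centre i is at index i)
  ic <- (pts[, 1] - o[1]) / h + 0.5
  jc <- (pts[, 2] - o[2]) / h + 0.5
  kc <- (pts[, 3] - o[3]) / h + 0.5
  ic <- pmin(pmax(ic, 1), d[1]); jc <- pmin(pmax(jc, 1), d[2])
  kc <- pmin(pmax(kc, 1), d[3])
  i0 <- pmin(pmax(floor(ic), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(jc), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(kc), 1), d[3] - 1)
  fx <- ic - i0; fy <- jc - j0; fz <- kc - k0
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v000 <- A[idx(i0, j0, k0)];     v100 <- A[idx(i0 + 1, j0, k0)]
  v010 <- A[idx(i0, j0 + 1, k0)]; v110 <- A[idx(i0 + 1, j0 + 1, k0)]
  v001 <- A[idx(i0, j0, k0 + 1)]; v101 <- A[idx(i0 + 1, j0, k0 + 1)]
  v011 <- A[idx(i0, j0 + 1, k0 + 1)]; v111 <- A[idx(i0 + 1, j0 + 1, k0 + 1)]
  (v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
   v010 * (1 - fx) * fy * (1 - fz) + v110 * fx * fy * (1 - fz) +
   v001 * (1 - fx) * (1 - fy) * fz + v101 * fx * (1 - fy) * fz +
   v011 * (1 - fx) * fy * fz + v111 * fx * fy * fz)
}

#' Maximum shear stress on a surface
#'
#' Estimates the maximum tangential traction exerted by the medium on the
#' surface of a region.  For the aggregate (TISSUE) the surface normal comes
#' from the analytic signed-distance field (stair-step voxel normals destroy
#' traction accuracy); for flat structural surfaces the voxel face normal is
#' used.  At each medium cell adjacent to the surface, the wall-tangential
#' velocity is sampled along the outward normal at distances 1.5h and 3h
#' from the surface (trilinear interpolation of the cell-centred velocity)
#' and the wall gradient is taken from the one-sided quadratic fit through
#' the no-slip surface value, `du/dn|0 = (4 u(d) - u(2d)) / (2 d)`; the shear
#' stress is `mu` times its magnitude, exact for linear and quadratic
#' profiles (Couette, plane Poiseuille).
#'
#' @param flow a `flow_field`.
#' @param grid a `labeled_grid` (defaults to the flow's grid).
#' @param surface_region region whose wetted surface is probed, default
#'   `"TISSUE"`.
#' @param mu dynamic viscosity, Pa s.
#' @return maximum shear stress, Pa.
#' @export
max_surface_shear <- function(flow, grid = flow$grid,
                              surface_region = "TISSUE",
                              mu = default_physical_params()$mu) {
  stopifnot(inherits(flow, "flow_field"))
  lab <- region_id(surface_region)
  d <- grid$dims
  h <- grid$spacing
  fl <- grid$label == REGION_LABELS[["MEDIUM"]]
  reg <- grid$label == lab
  adj <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    dv <- c(0L, 0L, 0L); dv[ax] <- s
    adj <- adj | (fl & shift3(reg, dv, FALSE))
  }
  if (!any(adj)) stop("max_surface_shear(): no medium faces adjacent to region")
  uc <- cell_center_velocity(flow)
  co <- grid_coord_arrays(grid)
  pts0 <- cbind(co$x[adj], co$y[adj], co$z[adj])

  use_sdf <- (lab == REGION_LABELS[["TISSUE"]]) && !is.null(grid$sdf)
  if (use_sdf) {
    # outward normal from central differences of the signed distance
    gx <- (shift3(grid$sdf, c(1L, 0L, 0L), NA) - shift3(grid$sdf, c(-1L, 0L, 0L), NA)) / (2 * h)
    gy <- (shift3(grid$sdf, c(0L, 1L, 0L), NA) - shift3(grid$sdf, c(0L, -1L, 0L), NA)) / (2 * h)
    gz <- (shift3(grid$sdf, c(0L, 0L, 1L), NA) - shift3(grid$sdf, c(0L, 0L, -1L), NA)) / (2 * h)
    nrm <- cbind(gx[adj], gy[adj], gz[adj])
    nrm[is.na(nrm)] <- 0
    nn <- sqrt(rowSums(nrm^2))
    nn[nn == 0] <- 1
    nrm <- nrm / nn
    dist <- grid$sdf[adj]           # distance from cell centre to surface
    surf <- pts0 - nrm * dist
  } else {
    # voxel-face normals: one record per adjacent (cell, direction) pair
    surf_list <- list(); nrm_list <- list()
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      dv <- c(0L, 0L, 0L); dv[ax] <- s
      m <- fl & shift3(reg, dv, FALSE)
      if (!any(m)) next
      p <- cbind(co$x[m], co$y[m], co$z[m])
      nvec <- -dv                    # outward from the region into the fluid
      p[, ax] <- p[, ax] + s * h / 2 # face position
      surf_list[[length(surf_list) + 1L]] <- p
      nrm_list[[length(nrm_list) + 1L]] <-
        matrix(rep(nvec, nrow(p)), ncol = 3, byrow = TRUE)
    }
    surf <- do.call(rbind, surf_list)
    nrm <- do.call(rbind, nrm_list)
  }

  probe <- function(dist) {
    p <- surf + nrm * dist
    cbind(trilinear(uc$u, grid, p), trilinear(uc$v, grid, p),
          trilinear(uc$w, grid, p))
  }
  # probes at 1.5h and 3h: clear of the one-cell stair-step contamination
  # layer, still inside the near-wall shear region; the quadratic fit through
  # the no-slip surface value stays exact for linear and parabolic profiles
  d1 <- 1.5 * h
  u1 <- probe(d1); u2 <- probe(2 * d1)
  tang <- function(u) u - nrm * rowSums(u * nrm)
  t1 <- tang(u1); t2 <- tang(u2)
  dudn <- (4 * t1 - t2) / (2 * d1)
  tau <- mu * sqrt(rowSums(dudn^2))
  max(tau)
}

#' Bundle scenario metrics
#'
#' @param fields named list of `concentration_field`s (by species).
#' @param flow a `flow_field` or NULL.
#' @param grid the `labeled_grid`.
#' @param mu viscosity used for the shear computation.
#' @return object of class `summary_metrics`.
#' @export
summarize_scenario <- function(fields, flow, grid,
                               mu = default_physical_params()$mu) {
  met <- list()
  for (nm in names(fields)) {
    met[[paste0("c_ave_", nm)]] <- region_average(fields[[nm]], grid)
    met[[paste0("c_min_", nm)]] <- region_min(fields[[nm]], grid)
  }
  if ("oxygen" %in% names(fields)) {
    met$hypoxic_fraction <- hypoxic_fraction(fields$oxygen, grid)
  }
  met$tau_max <- if (!is.null(flow)) {
    max_surface_shear(flow, grid, mu = mu)
  } else NA_real_
  vols <- domain_volumes(grid)
  for (nm in names(vols)) met[[paste0("vol_", tolower(nm))]] <- vols[[nm]]
  if (!is.null(flow)) {
    met$mass_balance <- flow$diagnostics$mass_balance
    met$max_divergence <- flow$diagnostics$max_divergence
  }
  structure(met, class = "summary_metrics")
}

#' @export
print.summary_metrics <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("  %-20s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Write a labelled grid and fields as legacy VTK
#'
#' Plain-text VTK STRUCTURED_POINTS with CELL_DATA arrays: region label,
#' per-species concentration and cell-centred velocity.
#'
#' @param path output file path (`.vtk`).
#' @param grid a `labeled_grid`.
#' @param fields named list of `concentration_field`s (optional).
#' @param flow a `flow_field` (optional).
#' @return the path, invisibly.
#' @export
write_vtk <- function(path, grid, fields = list(), flow = NULL) {
  d <- grid$dims
  h <- grid$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aggtrap scenario output", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("CELL_DATA %d", prod(d))), con)
  writeLines(c("SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(grid$label)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS c_%s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    v <- as.vector(fields[[nm]]$c)
    v[is.na(v)] <- -1
    writeLines(format(v, digits = 8, trim = TRUE, scientific = TRUE), con)
  }
  if (!is.null(flow)) {
    uc <- cell_center_velocity(flow)
    writeLines("VECTORS velocity double", con)
    m <- cbind(as.vector(uc$u), as.vector(uc$v), as.vector(uc$w))
    writeLines(paste(format(m[, 1], digits = 8, trim = TRUE),
                     format(m[, 2], digits = 8, trim = TRUE),
                     format(m[, 3], digits = 8, trim = TRUE)), con)
  }
  invisible(path)
}

#' Write scenario outputs
#'
#' Writes the VTK field dump, a one-row CSV of the summary metrics, and a
#' JSON provenance record containing the fully resolved configuration, grid
#' statistics and package version.
#'
#' @param fields named list of `concentration_field`s.
#' @param flow a `flow_field` or NULL.
#' @param grid a `labeled_grid`.
#' @param metrics a `summary_metrics`.
#' @param scenario the resolved scenario (see [scenario()]), for provenance.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return named list of written paths.
#' @export
write_outputs <- function(fields, flow, grid, metrics, scenario, dir,
                          stem = "scenario") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vtk = file.path(dir, paste0(stem, ".vtk")),
                csv = file.path(dir, paste0(stem, "_metrics.csv")),
                json = file.path(dir, paste0(stem, "_provenance.json")))
  write_vtk(paths$vtk, grid, fields, flow)
  utils::write.csv(as.data.frame(unclass(metrics)), paths$csv,
                   row.names = FALSE)
  prov <- list(
    package = "aggtrap",
    version = as.character(utils::packageVersion("aggtrap")),
    config = scenario_to_list(scenario),
    grid = list(dims = grid$dims, spacing = grid$spacing,
                cells = prod(grid$dims)),
    metrics = unclass(metrics))
  jsonlite::write_json(prov, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

#' Validate a provenance record against the shipped schema
#'
#' Minimal structural validation: all required keys of the shipped schema
#' must be present with the right JSON types.
#'
#' @param path path to a provenance JSON file.
#' @return TRUE (invisibly) or an error describing the missing key.
#' @export
validate_provenance <- function(path) {
  schema_path <- system.file("extdata", "provenance-schema.json",
                             package = "aggtrap")
  schema <- jsonlite::read_json(schema_path)
  doc <- jsonlite::read_json(path)
  check <- function(sch, node, where) {
    for (key in names(sch$required)) {
      if (is.null(node[[key]])) {
        stop("provenance record missing required key '", where, key, "'")
      }
      sub <- sch$required[[key]]
      if (is.list(sub) && !is.null(sub$required)) {
        check(sub, node[[key]], paste0(where, key, "."))
      }
    }
  }
  check(schema, doc, "")
  invisible(TRUE)
}
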