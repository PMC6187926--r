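# Scenario orchestration: configuration <-> JSON, end-to-end runs
# (geometry -> flow -> transport per species -> metrics), parameter sweeps,
# and the command-line entry point.

#' Scenario description
#'
#' Bundles everything needed for one end-to-end run.  Solvers are
#' deterministic; `seed` exists only for stochastic test utilities.
#'
#' @param geometry a [geometry_spec].
#' @param physical a [physical_params].
#' @param species list of [species_spec] objects (solved independently).
#' @param settings a [solver_settings].
#' @param spacing voxel spacing, m.
#' @param coarse_ok permit under-resolved aggregates.
#' @param output_dir if not `NULL`, [run_scenario()] writes VTK/CSV/JSON here.
#' @param stem output file-name stem.
#' @param seed optional integer seed recorded in provenance.
#' @return an object of class `scenario`.
#' @export
scenario <- function(geometry = geometry_spec(),
                     physical = default_physical_params(),
                     species = list(default_species("oxygen"),
                                    default_species("glucose")),
                     settings = solver_settings(),
                     spacing = 10e-6,
                     coarse_ok = FALSE,
                     output_dir = NULL,
                     stem = "scenario",
                     seed = NULL) {
  stopifnot(inherits(geometry, "geometry_spec"),
            inherits(physical, "physical_params"),
            inherits(settings, "solver_settings"),
            spacing > 0)
  species <- if (inherits(species, "species_spec")) list(species) else species
  for (sp in species) stopifnot(inherits(sp, "species_spec"))
  names(species) <- vapply(species, `[[`, "", "name")
  structure(list(geometry = geometry, physical = physical, species = species,
                 settings = settings, spacing = spacing, coarse_ok = coarse_ok,
                 output_dir = output_dir, stem = stem, seed = seed),
            class = "scenario")
}

## --- config serialization (micrometre / mM units at the file boundary) ------

.geom_um_fields <- c("trap_height", "trap_length", "barrier_wall_thickness",
                     "minor_radius", "margin", "channel_width",
                     "channel_height", "channel_length", "lid_thickness",
                     "well_base_thickness")

#' Serialize a scenario to a plain list (config units)
#'
#' Lengths are written in micrometres, the footprint in mm^2 and the flow
#' rate in uL/min; everything else is SI / mM.  The output round-trips
#' losslessly through [scenario_from_list()].
#'
#' @param sc a `scenario`.
#' @return a nested list suitable for `jsonlite::write_json`.
#' @export
scenario_to_list <- function(sc) {
  g <- unclass(sc$geometry)
  for (f in .geom_um_fields) g[[f]] <- m_to_um(g[[f]])
  g$trap_footprint_area <- sc$geometry$trap_footprint_area * 1e6  # mm^2
  p <- unclass(sc$physical)
  p$Q <- p$Q / ul_per_min_to_m3_per_s(1)                          # uL/min
  list(geometry = g, physical = p,
       species = lapply(sc$species, function(s) unclass(s)),
       solver = unclass(sc$settings),
       spacing = m_to_um(sc$spacing), coarse_ok = sc$coarse_ok,
       stem = sc$stem, seed = sc$seed)
}

#' Rebuild a scenario from its config list
#'
#' Unknown keys anywhere in the config are an error (typo protection).
#'
#' @param lst list as produced by [scenario_to_list()] or read from JSON.
#' @return a `scenario`.
#' @export
scenario_from_list <- function(lst) {
  known_top <- c("geometry", "physical", "species", "solver", "spacing",
                 "coarse_ok", "stem", "seed", "output_dir")
  unknown <- setdiff(names(lst), known_top)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  g <- lst$geometry
  if (!is.null(g)) {
    known_g <- c(.geom_um_fields, "trap_kind", "trap_footprint_area",
                 "aggregate_kind", "aspect_ratio", "well_substrate_is_pdms",
                 "half_width", "toroid_axis", "spheroid_mode")
    unknown <- setdiff(names(g), known_g)
    if (length(unknown)) stop("unknown geometry key(s): ",
                              paste(unknown, collapse = ", "))
    for (f in intersect(names(g), .geom_um_fields)) g[[f]] <- um_to_m(g[[f]])
    if (!is.null(g$trap_footprint_area)) {
      g$trap_footprint_area <- g$trap_footprint_area * 1e-6
    }
    geometry <- do.call(geometry_spec, g)
  } else geometry <- geometry_spec()
  physical <- if (!is.null(lst$physical)) {
    p <- lst$physical
    if (!is.null(p$Q)) p$Q <- ul_per_min_to_m3_per_s(p$Q)
    physical_params_from_list(p)
  } else default_physical_params()
  species <- if (!is.null(lst$species)) {
    lapply(lst$species, species_from_list)
  } else list(default_species("oxygen"), default_species("glucose"))
  settings <- if (!is.null(lst$solver)) {
    known_s <- names(formals(solver_settings))
    unknown <- setdiff(names(lst$solver), known_s)
    if (length(unknown)) stop("unknown solver key(s): ",
                              paste(unknown, collapse = ", "))
    do.call(solver_settings, lst$solver)
  } else solver_settings()
  scenario(geometry = geometry, physical = physical, species = species,
           settings = settings,
           spacing = um_to_m(lst$spacing %||% 10),
           coarse_ok = isTRUE(lst$coarse_ok),
           output_dir = lst$output_dir,
           stem = lst$stem %||% "scenario",
           seed = lst$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario configuration file (JSON)
#'
#' @param path path to a JSON config.
#' @return a `scenario`.
#' @export
read_scenario_config <- function(path) {
  scenario_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                         simplifyDataFrame = FALSE,
                                         simplifyMatrix = FALSE))
}

#' Write a scenario configuration file (JSON)
#'
#' @param sc a `scenario`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scenario_config <- function(sc, path) {
  jsonlite::write_json(scenario_to_list(sc), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Run one scenario end to end
#'
#' Builds the labelled grid, solves the flow once, solves each species
#' (reusing the flow field; species do not feed back into the flow), and
#' computes the summary metrics.  Deterministic for a fixed configuration.
#'
#' @param sc a `scenario`.
#' @param write logical; write outputs when `sc$output_dir` is set.
#' @return list with `grid`, `flow`, `fields`, `metrics`, `scenario`.
#' @export
run_scenario <- function(sc, write = !is.null(sc$output_dir)) {
  stopifnot(inherits(sc, "scenario"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_scenario() [stage %s]: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  grid <- stage("geometry", build_domain(sc$geometry, sc$spacing,
                                         coarse_ok = sc$coarse_ok))
  flow <- stage("flow", solve_flow(grid, sc$physical, sc$settings))
  fields <- list()
  for (sp in sc$species) {
    fields[[sp$name]] <- stage(paste0("transport:", sp$name),
                               solve_species(grid, sp, flow, sc$settings))
  }
  metrics <- stage("postprocess",
                   summarize_scenario(fields, flow, grid, mu = sc$physical$mu))
  out <- list(grid = grid, flow = flow, fields = fields, metrics = metrics,
              scenario = sc)
  if (write) {
    out$paths <- stage("write", write_outputs(fields, flow, grid, metrics, sc,
                                              sc$output_dir, sc$stem))
  }
  out
}

#' Parameter sweep
#'
#' Runs the base scenario across one swept axis for each aggregate kind,
#' isolating failures per row.  Swept values for geometric axes are in SI
#' metres (`minor_radius`) or dimensionless (`aspect_ratio`, `h_over_r`).
#'
#' @param base a `scenario`.
#' @param axis one of `"trap_kind"`, `"h_over_r"`, `"aspect_ratio"`,
#'   `"minor_radius"`.
#' @param values swept values; defaults per axis are
#'   `h_over_r = c(5, 6, 7.5, 9)`, `aspect_ratio = c(1.5, 2, 2.5, 3)`,
#'   `minor_radius = c(40, 60, 80, 100) um`,
#'   `trap_kind = c("u_barrier", "microwell")`.
#' @param aggregate_kinds aggregate kinds enumerated per value.
#' @return data frame (class `sweep_table`) with one row per combination,
#'   metrics columns, and a `status` column (`"ok"` or the error message).
#' @export
run_sweep <- function(base, axis = c("trap_kind", "h_over_r", "aspect_ratio",
                                     "minor_radius"),
                      values = NULL,
                      aggregate_kinds = c("toroid_horizontal",
                                          "toroid_vertical", "spheroid")) {
  stopifnot(inherits(base, "scenario"))
  axis <- match.arg(axis)
  if (is.null(values)) {
    values <- switch(axis,
                     trap_kind = c("u_barrier", "microwell"),
                     h_over_r = c(5, 6, 7.5, 9),
                     aspect_ratio = c(1.5, 2, 2.5, 3),
                     minor_radius = c(40, 60, 80, 100) * 1e-6)
  }
  if (length(values) == 0) stop("run_sweep(): empty sweep axis")
  rows <- list()
  for (v in values) {
    for (agg in aggregate_kinds) {
      g <- unclass(base$geometry)
      g$aggregate_kind <- agg
      switch(axis,
             trap_kind = { g$trap_kind <- v },
             h_over_r = { g$trap_height <- v * g$minor_radius },
             aspect_ratio = { g$aspect_ratio <- v },
             minor_radius = { g$minor_radius <- v })
      row <- data.frame(axis = axis, value = if (is.numeric(v)) v else NA,
                        value_chr = as.character(v), aggregate_kind = agg,
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        sc <- base
        sc$geometry <- do.call(geometry_spec, g)
        sc$output_dir <- NULL
        out <- run_scenario(sc)
        met <- unclass(out$metrics)
        cbind(row, as.data.frame(met), status = "ok",
              stringsAsFactors = FALSE)
      }, error = function(e) {
        cbind(row, status = paste0("failed: ", conditionMessage(e)),
              stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Grid-independence study
#'
#' Runs the same scenario at a sequence of spacings and reports the tissue
#' average of each species per spacing, with relative changes between
#' successive grids.
#'
#' @param sc a `scenario`.
#' @param spacings decreasing voxel spacings, m (at least 3).
#' @return data frame with one row per spacing and per-species columns
#'   `c_ave_*` plus `rel_change_*` vs the previous (coarser) grid.
#' @export
run_grid_independence <- function(sc, spacings) {
  if (length(spacings) < 3) {
    stop("run_grid_independence(): need at least 3 spacings")
  }
  if (any(diff(spacings) >= 0)) {
    stop("run_grid_independence(): spacings must be strictly decreasing")
  }
  rows <- list()
  prev <- NULL
  for (hh in spacings) {
    sci <- sc
    sci$spacing <- hh
    sci$output_dir <- NULL
    out <- run_scenario(sci)
    met <- unclass(out$metrics)
    avg <- met[grep("^c_ave_", names(met))]
    row <- data.frame(spacing = hh, cells = prod(out$grid$dims))
    for (nm in names(avg)) row[[nm]] <- avg[[nm]]
    if (!is.null(prev)) {
      for (nm in names(avg)) {
        row[[sub("^c_ave_", "rel_change_", nm)]] <-
          abs(avg[[nm]] - prev[[nm]]) / abs(avg[[nm]])
      }
    } else {
      for (nm in names(avg)) {
        row[[sub("^c_ave_", "rel_change_", nm)]] <- NA_real_
      }
    }
    prev <- avg
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

## --- command-line interface --------------------------------------------------

cli_opt <- function(args, name, default = NULL) {
  hit <- which(args == paste0("--", name))
  if (length(hit) == 0) return(default)
  if (hit[1] == length(args)) stop("missing value for --", name)
  args[hit[1] + 1L]
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{`run <config.json> [--out DIR]`}{run one scenario end to end.}
#'   \item{`sweep <config.json> --axis AXIS [--values a,b,c] [--out CSV]`}{
#'     run a parameter sweep.}
#'   \item{`dump-grid <config.json> [--out FILE.vtk]`}{voxelize and write the
#'     labelled grid.}
#'   \item{`fixtures <name> [--out DIR]`}{emit a synthetic fixture's scenario
#'     config and expected values.}
#'   \item{`validate`}{run the coarse-scale verification suite.}
#' }
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
aggtrap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: aggtrap <run|sweep|dump-grid|fixtures|validate> ...")
    cmd <- args[1]
    rest <- args[-1]
    switch(cmd,
      run = {
        cfg <- rest[!startsWith(rest, "--")][1]
        if (is.na(cfg)) stop("run: missing config path")
        sc <- read_scenario_config(cfg)
        out_dir <- cli_opt(rest, "out", sc$output_dir %||% ".")
        sc$output_dir <- out_dir
        res <- run_scenario(sc)
        message("metrics:")
        print(res$metrics)
        0L
      },
      sweep = {
        cfg <- rest[!startsWith(rest, "--")][1]
        if (is.na(cfg)) stop("sweep: missing config path")
        sc <- read_scenario_config(cfg)
        axis <- cli_opt(rest, "axis")
        if (is.null(axis)) stop("sweep: missing --axis")
        vals <- cli_opt(rest, "values")
        values <- if (!is.null(vals)) {
          if (axis == "trap_kind") strsplit(vals, ",")[[1]] else
            as.numeric(strsplit(vals, ",")[[1]]) *
              (if (axis == "minor_radius") 1e-6 else 1)
        } else NULL
        tab <- run_sweep(sc, axis = axis, values = values)
        out <- cli_opt(rest, "out")
        if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
        print(tab[, intersect(c("axis", "value", "value_chr",
                                "aggregate_kind", "c_ave_oxygen",
                                "c_ave_glucose", "tau_max", "status"),
                              names(tab))])
        if (any(tab$status != "ok")) 1L else 0L
      },
      `dump-grid` = {
        cfg <- rest[!startsWith(rest, "--")][1]
        if (is.na(cfg)) stop("dump-grid: missing config path")
        sc <- read_scenario_config(cfg)
        grid <- build_domain(sc$geometry, sc$spacing, coarse_ok = sc$coarse_ok)
        out <- cli_opt(rest, "out", paste0(sc$stem, "_grid.vtk"))
        write_vtk(out, grid)
        message("wrote ", out)
        0L
      },
      fixtures = {
        nm <- rest[!startsWith(rest, "--")][1]
        if (is.na(nm)) stop("fixtures: missing fixture name")
        out_dir <- cli_opt(rest, "out", ".")
        emit_fixture(nm, out_dir)
        0L
      },
      validate = {
        ok <- run_validation_suite()
        if (ok) 0L else 1L
      },
      stop("unknown subcommand '", cmd, "'")
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# Coarse-scale verification executed by `aggtrap validate`.
run_validation_suite <- function() {
  ok <- TRUE
  note <- function(name, pass, detail = "") {
    message(sprintf("%-40s %s %s", name, if (pass) "PASS" else "FAIL", detail))
    ok <<- ok && pass
  }
  kn <- knudsen_number(0.25e-9, 80e-6)
  note("knudsen number 0.25nm / 80um", isTRUE(all.equal(kn, 3.125e-6)))
  fx <- make_validation_sphere("ci")
  res <- run_validation_sphere(fx)
  note("constant-rate sphere vs closed form",
       res$max_rel_error <= fx$tolerance,
       sprintf("(max rel err %.3g)", res$max_rel_error))
  mini <- make_mini_chip("ci", "spheroid", "u_barrier")
  out <- run_scenario(mini$scenario)
  note("mini chip mass balance",
       out$flow$diagnostics$mass_balance <= 1e-8,
       sprintf("(%.3g)", out$flow$diagnostics$mass_balance))
  ok
}
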