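# Config parsing/validation, unit conversion, seeding and all file writers.

#' Seeding plan for the initial agent layout
#'
#' @param counts named integer vector: number of agents per functional
#'   group (ratios such as 1:1 or 1:1:1 are expressed through the counts).
#' @param layout `"layered"` (evenly distributed in `n_layers` lattice
#'   layers at the bottom of the domain, groups interleaved so every agent
#'   sits next to its partners) or `"monolayer"` (random positions on the
#'   substratum).
#' @param n_layers number of layers for the layered layout.
#' @param jitter lateral position jitter, um.
#' @param mass_range initial agent mass as a fraction of the group's
#'   division mass, drawn uniformly from this range.
#' @return a `seeding_plan`.
#' @export
seeding_plan <- function(counts, layout = c("layered", "monolayer"),
                         n_layers = 8, jitter = 0.1,
                         mass_range = c(0.5, 0.9)) {
  layout <- match.arg(layout)
  stopifnot(all(counts >= 0), n_layers >= 1, jitter >= 0,
            length(mass_range) == 2, all(mass_range > 0.1), all(mass_range < 1))
  structure(list(counts = counts, layout = layout, n_layers = n_layers,
                 jitter = jitter, mass_range = mass_range),
            class = "seeding_plan")
}

#' Generate the initial agent layout
#'
#' Deterministic given the RNG state (the engine seeds R's RNG from the
#' scenario seed before calling this). Groups are assigned round-robin
#' along the lattice so that the requested ratios are exact to rounding and
#' members of different guilds are adjacent.
#'
#' @param plan a [seeding_plan()].
#' @param spec a [grid_spec()].
#' @param groups named list of [functional_group]s covering `names(plan$counts)`.
#' @return agent data.frame.
#' @export
generate_seeding <- function(plan, spec, groups) {
  total <- sum(plan$counts)
  if (total == 0L)
    return(agents_df(character(0), numeric(0), numeric(0), numeric(0), numeric(0)))
  gnames <- names(plan$counts)[plan$counts > 0]
  dd <- vapply(groups[gnames], function(g) g$division_diameter, numeric(1))
  pitch <- max(dd) * 0.95
  npl <- if (plan$layout == "layered") ceiling(total / plan$n_layers) else total
  nxs <- max(1L, floor(spec$Lx / pitch))
  nys <- max(1L, ceiling(npl / nxs))
  if (nys * pitch > spec$Ly + 1e-9)
    stop("requested seeding density does not fit the domain footprint")
  # lattice positions, layer by layer
  k <- 0L
  pos <- matrix(0, total, 3)
  layer_h <- max(dd)
  for (i in seq_len(total) - 1L) {
    layer <- if (plan$layout == "layered") i %/% npl else 0L
    j <- i %% npl
    pos[i + 1L, ] <- c((j %% nxs + 0.5) * spec$Lx / nxs,
                       (j %/% nxs + 0.5) * spec$Ly / nys,
                       (layer + 0.5) * layer_h)
    k <- k + 1L
  }
  # round-robin group assignment honouring the exact counts
  quota <- plan$counts[gnames]
  grp <- character(total)
  gi <- 1L
  for (i in seq_len(total)) {
    while (quota[gnames[gi]] == 0L) gi <- gi %% length(gnames) + 1L
    grp[i] <- gnames[gi]
    quota[gnames[gi]] <- quota[gnames[gi]] - 1L
    gi <- gi %% length(gnames) + 1L
  }
  jit <- matrix(runif(2 * total, -plan$jitter, plan$jitter), total, 2)
  x <- (pos[, 1] + jit[, 1]) %% spec$Lx
  y <- (pos[, 2] + jit[, 2]) %% spec$Ly
  mdiv <- vapply(groups[grp], division_mass, numeric(1))
  dens <- vapply(groups[grp], function(g) g$density, numeric(1))
  mass <- mdiv * runif(total, plan$mass_range[1], plan$mass_range[2])
  ag <- agents_df(grp, x, y, pos[, 3], mass, density = dens)
  ag$z <- pmax(ag$z, ag$diameter / 2)
  ag
}

# ---- configuration I/O -----------------------------------------------------

#' Load a scenario configuration from YAML
#'
#' Concentrations may be given in mg/L (converted through the species'
#' reference-form molar mass: total ammonia as mg NH3, total inorganic
#' carbon as mg CO2, and so on) or directly in mol/L via
#' `concentration_unit: molL`.
#'
#' @param path YAML file.
#' @param db thermodynamic database.
#' @return a validated `scenario_config` (see [scenario_config()]).
#' @export
load_config <- function(path, db = default_thermo_db()) {
  y <- yaml::read_yaml(path)
  unit <- y$concentration_unit %||% "mgL"
  conv <- function(v) {
    v <- unlist(v)
    if (identical(unit, "mgL")) mgL_to_molL(names(v), v, db) else v
  }
  args <- y
  args$concentration_unit <- NULL
  args$bulk <- conv(y$bulk)
  if (!is.null(y$inlet)) args$inlet <- conv(y$inlet)
  if (!is.null(y$seeding))
    args$seeding <- do.call(seeding_plan, c(list(counts = unlist(y$seeding$counts)),
                                            y$seeding[setdiff(names(y$seeding), "counts")]))
  if (!is.null(y$grid)) args$grid <- do.call(grid_spec, y$grid)
  do.call(scenario_config, args)
}

#' Write a scenario configuration to YAML
#'
#' Inverse of [load_config()] (concentrations written in mol/L so the
#' round trip is exact).
#'
#' @param config a `scenario_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  y <- unclass(config)
  y$concentration_unit <- "molL"
  y$bulk <- as.list(y$bulk)
  y$inlet <- as.list(y$inlet)
  y$groups <- names(config$groups)   # packaged groups are stored by name
  y$grid <- y$grid[c("nx", "ny", "nz", "h")]
  y$seeding <- list(counts = as.list(plan_counts <- y$seeding$counts),
                    layout = y$seeding$layout, n_layers = y$seeding$n_layers,
                    jitter = y$seeding$jitter, mass_range = y$seeding$mass_range)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- writers ---------------------------------------------------------------

#' Write all trajectory outputs
#'
#' Produces `bulk_timeseries.csv`, `biomass_timeseries.csv`, one
#' `agents_t<k>.csv` and `grid_t<k>.vtk` per stored snapshot, and a
#' `run_manifest.json` with the scenario name, seed and package version.
#'
#' @param trajectory a `simulation_trajectory` from [run_scenario()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(trajectory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- trajectory$timeseries
  bulk_cols <- c("time_h", grep("^C_|^pH_bulk$|^p_", names(ts), value = TRUE))
  bio_cols <- c("time_h", grep("^B_|^inert_mass$|^n_agents$|^height_um$",
                               names(ts), value = TRUE))
  files <- character(0)
  f <- file.path(dir, "bulk_timeseries.csv")
  write.csv(ts[, bulk_cols, drop = FALSE], f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "biomass_timeseries.csv")
  write.csv(ts[, bio_cols, drop = FALSE], f, row.names = FALSE)
  files <- c(files, f)
  for (i in seq_along(trajectory$snapshots)) {
    sn <- trajectory$snapshots[[i]]
    f <- file.path(dir, sprintf("agents_t%d.csv", i))
    write.csv(agent_snapshot(sn$agents), f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(sn$grid)) {
      f <- file.path(dir, sprintf("grid_t%d.vtk", i))
      write_vtk(sn$grid, f)
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(list(
    scenario = trajectory$config$name,
    seed = trajectory$config$seed,
    package = "biofilmsim",
    version = as.character(utils::packageVersion("biofilmsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_steps = nrow(ts), t_end_h = max(ts$time_h)
  ), f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Agent table in the documented snapshot schema
#'
#' @param agents agent data.frame.
#' @return data.frame with columns `id`, `group`, `state`, `x_um`, `y_um`,
#'   `z_um`, `mass_Cmol`, `diameter_um`.
#' @export
agent_snapshot <- function(agents) {
  data.frame(id = agents$id, group = agents$group, state = agents$state,
             x_um = agents$x, y_um = agents$y, z_um = agents$z,
             mass_Cmol = agents$mass, diameter_um = agents$diameter,
             stringsAsFactors = FALSE)
}

#' Write a grid state as legacy ASCII VTK (structured points)
#'
#' One scalar field per species (total concentration, mol/L), plus the pH
#' field and the region labels.
#'
#' @param grid a `grid_state`.
#' @param path output file.
#' @export
write_vtk <- function(grid, path) {
  spec <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "biofilmsim grid snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", spec$nx, spec$ny, spec$nz),
               sprintf("ORIGIN %g %g %g", spec$h / 2, spec$h / 2, spec$h / 2),
               sprintf("SPACING %g %g %g", spec$h, spec$h, spec$h),
               sprintf("POINT_DATA %d", spec$nx * spec$ny * spec$nz)), con)
  for (s in grid$species) {
    writeLines(c(sprintf("SCALARS %s double 1", s), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(grid$conc[[s]]), digits = 8, trim = TRUE,
                      scientific = TRUE), con)
  }
  writeLines(c("SCALARS pH double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(grid$pH), digits = 6, trim = TRUE), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.vector(grid$region)), con)
  invisible(path)
}

#' Read back the header and one field of a legacy VTK file
#'
#' Minimal structured-points reader used for round-trip validation of
#' [write_vtk()] output.
#'
#' @param path VTK file.
#' @param field scalar field name to extract (`NULL`: header only).
#' @return list with `dims`, `spacing` and (optionally) `values`.
#' @export
read_vtk_header <- function(path, field = NULL) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE), " ")[[1]][-1])
  spacing <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE), " ")[[1]][-1])
  out <- list(dims = dims, spacing = spacing)
  if (!is.null(field)) {
    i <- grep(paste0("^SCALARS ", field, " "), lines)
    if (!length(i)) stop("field not found: ", field)
    n <- prod(dims)
    vals <- as.numeric(lines[(i + 2):(i + 1 + n)])
    out$values <- array(vals, dims)
  }
  out
}
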