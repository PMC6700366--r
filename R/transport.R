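# Grid-based diffusion-reaction of total species concentrations with a
# moving boundary layer and biofilm/boundary-layer/bulk region labels.

#' Regular grid specification
#'
#' @param nx,ny,nz number of cells in each direction.
#' @param h grid spacing, um (cells are cubes).
#' @return a `grid_spec` with derived domain lengths `Lx`, `Ly`, `Lz` (um)
#'   and cell volume `cell_L` (litres).
#' @export
grid_spec <- function(nx = 50, ny = 10, nz = 150, h = 2) {
  stopifnot(nx >= 1, ny >= 1, nz >= 2, h > 0)
  structure(list(nx = nx, ny = ny, nz = nz, h = h,
                 Lx = nx * h, Ly = ny * h, Lz = nz * h,
                 cell_L = h^3 * 1e-15), class = "grid_spec")
}

.REGION <- c(biofilm = 0L, boundary_layer = 1L, bulk = 2L)

#' Initialize a grid state
#'
#' Concentration fields start uniform at the bulk values; regions are
#' labelled for an empty domain (boundary layer on the bottom planes).
#'
#' @param spec a [grid_spec].
#' @param bulk named vector of bulk total concentrations, mol/L (names are
#'   database species).
#' @param db thermodynamic database.
#' @param pH initial pH assigned to the whole field.
#' @param biofilm_factor ratio of biofilm to water diffusivity.
#' @param bl_um boundary-layer thickness, um.
#' @return a `grid_state`.
#' @export
grid_state <- function(spec, bulk, db = default_thermo_db(), pH = 7,
                       biofilm_factor = 0.8, bl_um = 40) {
  sp <- names(bulk)
  D <- vapply(sp, function(s) db$species[[s]]$D_water, numeric(1)) * 1e12  # um^2/h
  if (any(!is.finite(D)))
    stop("species without diffusion coefficient: ",
         paste(sp[!is.finite(D)], collapse = ", "))
  dims <- c(spec$nx, spec$ny, spec$nz)
  g <- structure(list(
    spec = spec, species = sp, bulk = bulk,
    conc = lapply(bulk, function(v) array(v, dims)),
    rates = setNames(lapply(sp, function(s) array(0, dims)), sp),
    region = array(.REGION[["bulk"]], dims),
    pH = array(pH, dims),
    D_um2_h = setNames(D, sp),
    biofilm_factor = biofilm_factor, bl_um = bl_um,
    front_plane = 0L, deficit = setNames(numeric(length(sp)), sp)
  ), class = "grid_state")
  update_regions(g, NULL)
}

#' Effective diffusivity of a species by region
#'
#' Biofilm: `0.8 * D_water` (relative diffusivity configurable); boundary
#' layer: `D_water`; bulk cells are not diffused (they are held at the
#' Dirichlet bulk value), so `NA` is returned for them.
#'
#' @param species species name.
#' @param region `"biofilm"`, `"boundary_layer"` or `"bulk"`.
#' @param db thermodynamic database.
#' @param biofilm_factor biofilm/water diffusivity ratio.
#' @return effective diffusivity, m^2/h.
#' @export
effective_diffusivity <- function(species, region, db = default_thermo_db(),
                                  biofilm_factor = 0.8) {
  region <- match.arg(region, names(.REGION))
  D <- db$species[[species]]$D_water
  switch(region, biofilm = biofilm_factor * D, boundary_layer = D, bulk = NA_real_)
}

#' Relabel grid regions from the current biofilm front
#'
#' The biofilm front is the highest agent top (`z + radius`), rounded up to
#' a grid plane; the next `ceiling(bl_um / h)` planes are the boundary
#' layer; everything above is bulk, held at the current bulk concentrations.
#'
#' @param grid a `grid_state`.
#' @param agents agent data.frame (or `NULL` for an empty domain).
#' @return the relabelled `grid_state`.
#' @export
update_regions <- function(grid, agents) {
  spec <- grid$spec
  front <- if (is.null(agents) || nrow(agents) == 0L) 0
           else max(agents$z + agents$diameter / 2)
  fp <- as.integer(ceiling(front / spec$h - 1e-9))
  blp <- as.integer(ceiling(grid$bl_um / spec$h))
  if (fp + blp >= spec$nz)
    stop("biofilm front + boundary layer reach the domain top (plane ",
         fp + blp, " of ", spec$nz, "): increase nz")
  plane <- rep(rep(seq_len(spec$nz), each = spec$nx * spec$ny), 1L)
  lab <- ifelse(plane <= fp, .REGION[["biofilm"]],
                ifelse(plane <= fp + blp, .REGION[["boundary_layer"]],
                       .REGION[["bulk"]]))
  grid$region <- array(as.integer(lab), c(spec$nx, spec$ny, spec$nz))
  grid$front_plane <- fp
  # newly-bulk cells (front receded or initialisation) take the bulk value
  for (s in grid$species) {
    a <- grid$conc[[s]]
    a[grid$region == .REGION[["bulk"]]] <- grid$bulk[[s]]
    grid$conc[[s]] <- a
  }
  grid
}

#' Map agent centre positions to grid cells
#'
#' Cells are addressed 0-based per axis (`floor(position / h)`); agents
#' outside the domain raise an error.
#'
#' @param spec a [grid_spec].
#' @param x,y,z agent positions, um.
#' @return list with 0-based `ix`, `iy`, `iz` and the 1-based linear array
#'   index `lin`.
#' @export
cell_index <- function(spec, x, y, z) {
  ix <- floor(x / spec$h); iy <- floor(y / spec$h); iz <- floor(z / spec$h)
  ix <- pmin(ix, spec$nx - 1L)  # agents exactly on the upper face belong to the last cell
  iy <- pmin(iy, spec$ny - 1L)
  iz <- pmin(iz, spec$nz - 1L)
  if (any(ix < 0 | iy < 0 | iz < 0 | x > spec$Lx | y > spec$Ly | z > spec$Lz))
    stop("agent position outside the grid domain")
  list(ix = ix, iy = iy, iz = iz,
       lin = 1L + ix + spec$nx * (iy + spec$ny * iz))
}

#' Accumulate per-agent reaction rates into per-cell rate fields
#'
#' Each agent's molar rates (mol/h) are deposited in the cell containing
#' its centre and converted to volumetric rates (mol/L/h) by the cell
#' volume; contributions are additive, and the field total equals the agent
#' total exactly.
#'
#' @param grid a `grid_state`.
#' @param agents agent data.frame.
#' @param agent_rates matrix (agents x species, mol/h) with columns named
#'   by grid species; missing species get zero fields.
#' @return the `grid_state` with updated `rates`.
#' @export
assemble_reactions <- function(grid, agents, agent_rates) {
  spec <- grid$spec
  dims <- c(spec$nx, spec$ny, spec$nz)
  for (s in grid$species) grid$rates[[s]] <- array(0, dims)
  if (is.null(agents) || nrow(agents) == 0L) return(grid)
  ci <- cell_index(spec, agents$x, agents$y, agents$z)
  for (s in intersect(colnames(agent_rates), grid$species)) {
    v <- agent_rates[, s]
    nz <- which(v != 0)
    if (!length(nz)) next
    a <- grid$rates[[s]]
    sums <- rowsum(v[nz], ci$lin[nz])
    idx <- as.integer(rownames(sums))
    a[idx] <- a[idx] + sums[, 1] / spec$cell_L
    grid$rates[[s]] <- a
  }
  grid
}

# largest stable explicit time step, h (per species)
.dt_stability <- function(grid) {
  grid$spec$h^2 / (6 * grid$D_um2_h)
}

#' One explicit diffusion-reaction step
#'
#' Fully explicit 7-point-stencil update of all species fields over `dt_h`
#' hours, with Dirichlet bulk cells, zero-flux bottom boundary and periodic
#' lateral faces. `dt_h` must respect the stability bound `h^2 / (6 D)`.
#'
#' @param grid a `grid_state` with assembled `rates`.
#' @param dt_h time step, hours.
#' @return updated `grid_state`.
#' @export
diffusion_step <- function(grid, dt_h) {
  bound <- min(.dt_stability(grid))
  if (dt_h > bound)
    stop("dt_h = ", dt_h, " h violates the stability bound ", signif(bound, 4), " h")
  out <- cpp_diffuse_chunk(grid$conc, grid$rates, grid$region, grid$D_um2_h,
                           grid$biofilm_factor, grid$spec$h, 1L, dt_h)
  grid$conc <- setNames(out$conc, grid$species)
  grid$deficit <- grid$deficit + setNames(out$deficit, grid$species)
  attr(grid, "delta") <- setNames(out$delta, grid$species)
  grid
}

#' March the diffusion-reaction system to steady state
#'
#' Explicit pseudo-time marching at the per-species stability-bound step
#' until the maximum relative field change per step falls below `tol`.
#' When a `refresh` callback is given it is invoked before every chunk of
#' steps to re-evaluate pH, thermodynamics and the per-cell reaction-rate
#' fields from the current concentration fields (quasi-steady coupling);
#' convergence then additionally requires the refreshed rates to have
#' stopped moving the fields.
#'
#' @param grid a `grid_state`.
#' @param refresh optional `function(grid) -> grid` updating `grid$rates`
#'   (and possibly `grid$pH`).
#' @param tol relative per-step field change for convergence.
#' @param max_steps cap on total inner steps.
#' @param chunk inner steps between refreshes.
#' @return the converged `grid_state`; diagnostics in attributes
#'   `iterations`, `converged`, `delta`.
#' @export
solve_to_steady_state <- function(grid, refresh = NULL, tol = 1e-6,
                                  max_steps = 200000L, chunk = 400L) {
  total <- 0L
  repeat {
    if (!is.null(refresh)) grid <- refresh(grid)
    nst <- as.integer(min(chunk, max_steps - total))
    if (nst <= 0L) break
    out <- cpp_diffuse_chunk(grid$conc, grid$rates, grid$region, grid$D_um2_h,
                             grid$biofilm_factor, grid$spec$h, nst, -1)
    grid$conc <- setNames(out$conc, grid$species)
    grid$deficit <- grid$deficit + setNames(out$deficit, grid$species)
    total <- total + nst
    if (all(out$delta <= tol)) {
      attr(grid, "converged") <- TRUE
      break
    }
    if (total >= max_steps) {
      if (max(out$delta) > 100 * tol)
        warning("diffusion-reaction not converged after ", total,
                " steps; max relative per-step change = ", signif(max(out$delta), 3))
      attr(grid, "converged") <- FALSE
      break
    }
  }
  attr(grid, "iterations") <- total
  attr(grid, "delta") <- setNames(out$delta, grid$species)
  grid
}
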