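# Bulk-liquid CSTR mass balance coupled to the biofilm domain, and gas
# headspace balance via two-film transfer.

#' Reactor and headspace state
#'
#' @param C named bulk concentrations, mol/L.
#' @param C_in named inlet concentrations, mol/L (defaults to `C`).
#' @param Q liquid flow rate, L/h.
#' @param V liquid volume, L.
#' @param A_F biofilm surface area in the reactor, m^2.
#' @param p named headspace partial pressures, bar (defaults to zero for
#'   every gas-capable species).
#' @param V_gas headspace volume, L (defaults to the liquid volume).
#' @param Q_gas gas outflow rate, L/h.
#' @param kLa gas-liquid mass-transfer coefficient, 1/h.
#' @param T temperature, K.
#' @param inert an [inert_pool()] carried by the bulk liquid.
#' @param pH current bulk pH.
#' @return a `reactor_state`.
#' @export
reactor_state <- function(C, C_in = C, Q, V, A_F, p = NULL, V_gas = V,
                          Q_gas = V, kLa = 0, T = 298.15,
                          inert = inert_pool(), pH = 7) {
  stopifnot(Q >= 0, V > 0, V_gas > 0, Q_gas >= 0, kLa >= 0, A_F >= 0)
  if (is.null(p)) p <- setNames(numeric(length(C)), names(C))
  if (any(p < 0)) stop("partial pressures must be >= 0")
  if (any(C < 0) || any(C_in < 0)) stop("concentrations must be >= 0")
  structure(list(C = C, C_in = C_in, Q = Q, V = V, A_F = A_F, p = p,
                 V_gas = V_gas, Q_gas = Q_gas, kLa = kLa, T = T,
                 inert = inert, pH = pH), class = "reactor_state")
}

#' Biofilm reaction flux seen by the bulk liquid
#'
#' Volume integral of the per-cell reaction rates over the computational
#' domain, scaled to the reactor by the ratio of the biofilm area in the
#' reactor to the domain footprint, and normalised by the reactor volume:
#' `flux_S = (A_F / (Lx Ly)) * (1/V) * sum_cells r_S * V_cell`.
#'
#' @param grid a `grid_state` with converged rate fields.
#' @param A_F biofilm area in the reactor, m^2.
#' @param V reactor liquid volume, L.
#' @return named vector, mol/L/h per species (sign of the rates).
#' @export
biofilm_flux <- function(grid, A_F, V) {
  spec <- grid$spec
  footprint_m2 <- spec$Lx * spec$Ly * 1e-12
  if (footprint_m2 <= 0) stop("zero domain footprint area")
  scale <- A_F / footprint_m2 / V
  vapply(grid$species, function(s) sum(grid$rates[[s]]) * spec$cell_L * scale,
         numeric(1))
}

#' One bulk-liquid CSTR step (backward Euler)
#'
#' `dC/dt = (Q/V) (C_in - C) + flux + transfer`, with the dilution term
#' implicit and the biofilm flux and gas-transfer source explicit (they are
#' evaluated from the just-converged diffusion-reaction fields).
#'
#' @param reactor a `reactor_state`.
#' @param flux biofilm flux from [biofilm_flux()], mol/L/h (named; missing
#'   species contribute zero).
#' @param transfer named gas-transfer source into the liquid, mol/L/h
#'   (negative = stripping).
#' @param dt_h time step, h.
#' @return updated `reactor_state`.
#' @export
bulk_step <- function(reactor, flux = NULL, transfer = NULL, dt_h) {
  stopifnot(dt_h > 0)
  C <- reactor$C
  src <- setNames(numeric(length(C)), names(C))
  for (extra in list(flux, transfer)) {
    if (!is.null(extra)) {
      hit <- intersect(names(extra), names(C))
      src[hit] <- src[hit] + extra[hit]
    }
  }
  D <- reactor$Q / reactor$V
  Cn <- (C + dt_h * (D * reactor$C_in + src)) / (1 + dt_h * D)
  if (any(Cn < 0)) {
    warning("bulk concentration(s) clipped to zero: ",
            paste(names(Cn)[Cn < 0], collapse = ", "))
    Cn <- pmax(Cn, 0)
  }
  reactor$C <- Cn
  reactor
}

#' Two-film gas-liquid transfer rate
#'
#' Transfer rate `kLa * (C_L - C_sat)` with `C_sat = Henry * p`; positive
#' values strip gas out of the liquid. Vectorises over grid cells.
#'
#' @param C_L dissolved concentration(s), mol/L.
#' @param p partial pressure in the headspace, bar.
#' @param kLa transfer coefficient, 1/h.
#' @param henry Henry constant, mol/(L bar).
#' @return transfer rate(s), mol/L/h (liquid loses at this rate).
#' @export
gas_transfer_rate <- function(C_L, p, kLa, henry) {
  if (!is.finite(henry)) stop("species has no Henry constant")
  kLa * (C_L - henry * p)
}

#' One headspace step (backward Euler)
#'
#' `dp/dt = r_ave (V/V_gas) R T - (Q_gas/V_gas) p`, where `r_ave` is the
#' domain-averaged stripping rate (mol per litre of liquid per hour),
#' converted to bar/h by the ideal-gas law at the reactor temperature.
#'
#' @param reactor a `reactor_state`.
#' @param transfer_ave named average stripping rate, mol/L/h (positive =
#'   into the headspace).
#' @param dt_h time step, h.
#' @return updated `reactor_state`.
#' @export
headspace_step <- function(reactor, transfer_ave, dt_h) {
  stopifnot(dt_h > 0)
  p <- reactor$p
  src <- setNames(numeric(length(p)), names(p))
  hit <- intersect(names(transfer_ave), names(p))
  src[hit] <- transfer_ave[hit] * (reactor$V / reactor$V_gas) * .RBAR * reactor$T
  Dg <- reactor$Q_gas / reactor$V_gas
  pn <- (p + dt_h * src) / (1 + dt_h * Dg)
  if (any(pn < 0)) {
    warning("headspace partial pressure(s) clipped to zero")
    pn <- pmax(pn, 0)
  }
  reactor$p <- pn
  reactor
}
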