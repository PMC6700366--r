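# Agent life cycle: growth-regime classification, mass update, division,
# inert transition, decay and per-agent reaction contributions.

#' Diameter of a spherical agent from its dry mass
#'
#' `diameter = (6 m_g / (pi rho))^(1/3)` with the dry mass from the C-mol
#' mass via the biomass molar mass (24.626 g/C-mol for CH1.8O0.5N0.2).
#'
#' @param mass agent mass, C-mol.
#' @param density dry biomass density, fg/um^3.
#' @return diameter, um.
#' @export
agent_diameter <- function(mass, density = 290) {
  mass_fg <- mass * .BIOMASS_MOLAR_MASS * 1e15
  (6 * mass_fg / (pi * density))^(1 / 3)
}

#' Mass of an agent of given diameter
#' @param diameter diameter, um.
#' @inheritParams agent_diameter
#' @return mass, C-mol.
#' @export
agent_mass_from_diameter <- function(diameter, density = 290) {
  (pi / 6) * diameter^3 * density / (.BIOMASS_MOLAR_MASS * 1e15)
}

#' Mass at which an agent of a group divides
#' @param group a [functional_group].
#' @return division mass, C-mol.
#' @export
division_mass <- function(group) {
  agent_mass_from_diameter(group$division_diameter, group$density)
}

#' Create an agent table
#'
#' Agents are rows of a plain data.frame: `id`, `group`, `state`
#' (`"active"`/`"inert"`), position `x`, `y`, `z` (um), `mass` (C-mol),
#' `diameter` (um), velocity `vx`, `vy`, `vz` (um/s) and current specific
#' growth rate `mu` (1/h).
#'
#' @param group character vector of group names.
#' @param x,y,z positions, um.
#' @param mass masses, C-mol.
#' @param density dry density used for diameters, fg/um^3.
#' @param state agent states.
#' @return data.frame of agents.
#' @export
agents_df <- function(group, x, y, z, mass, density = 290, state = "active") {
  n <- length(x)
  data.frame(id = seq_len(n), group = rep_len(group, n), state = rep_len(state, n),
             x = x, y = y, z = z, mass = mass,
             diameter = agent_diameter(mass, density),
             vx = rep(0, n), vy = rep(0, n), vz = rep(0, n), mu = rep(0, n),
             stringsAsFactors = FALSE)
}

#' Multiplicative Monod limitation of a group at local conditions
#'
#' `prod_i C_i / (K_i + C_i)` over the group's limiting substrates, where
#' each `C_i` is the concentration of the specific uptake form named by
#' `K_S` (not the species total).
#'
#' @param group a [functional_group].
#' @param forms named concentrations of protonation forms, mol/L; may be a
#'   matrix (systems x forms) for many locations at once.
#' @return limitation factor(s) in `[0, 1]`.
#' @export
monod_limitation <- function(group, forms) {
  K <- group$K_S
  if (is.matrix(forms)) {
    p <- rep(1, nrow(forms))
    for (f in names(K)) {
      C <- pmax(forms[, f], 0)
      p <- p * C / (K[[f]] + C)
    }
    p
  } else {
    p <- 1
    for (f in names(K)) {
      C <- max(forms[[f]], 0)
      p <- p * C / (K[[f]] + C)
    }
    p
  }
}

#' Classify the growth regime of an agent
#'
#' Compares the uptake-linked energy flux `q_max * Y_XS * limitation`
#' against the maintenance demand `m_bac` with relaxation band
#' `(beta, alpha)`: above `alpha * m_bac` the agent grows, below
#' `beta * m_bac` it decays, in between it maintains (mass constant).
#'
#' @param group a [functional_group].
#' @param energy energetic state from [group_energetics()].
#' @param limitation Monod limitation factor(s).
#' @param alpha,beta relaxation parameters, `alpha > 1 > beta > 0`.
#' @return character vector: `"grow"`, `"maintain"` or `"decay"`.
#' @export
classify_regime <- function(group, energy, limitation, alpha = 1.2, beta = 0.8) {
  stopifnot(alpha > 1, beta < 1, beta > 0)
  flux <- group$q_max * energy$Y_XS * limitation
  m <- energy$m_bac
  ifelse(flux > alpha * m, "grow", ifelse(flux < beta * m, "decay", "maintain"))
}

#' Update agent mass over a biological time step
#'
#' Exponential integration of the agent mass balance: growth
#' `X <- X exp(mu dt)`, maintenance leaves `X` unchanged, decay
#' `X <- X exp(-k_decay dt)`.
#'
#' @param mass masses, C-mol.
#' @param regime regimes from [classify_regime()].
#' @param mu specific growth rates (used where `regime == "grow"`), 1/h.
#' @param k_decay decay constants (used where `regime == "decay"`), 1/h.
#' @param dt biological time step, h.
#' @return updated masses.
#' @export
update_mass <- function(mass, regime, mu, k_decay, dt) {
  stopifnot(dt > 0)
  rate <- ifelse(regime == "grow", mu, ifelse(regime == "decay", -k_decay, 0))
  out <- mass * exp(rate * dt)
  if (any(out <= 0)) stop("non-positive mass after update")
  out
}

# uniform random unit vectors, n x 3
.runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Divide agents that reached their division diameter
#'
#' Each dividing parent is split at a mass fraction drawn uniformly from
#' 0.4-0.6 (50 +/- 10%). One daughter keeps the parent position; the
#' other is placed on a random direction at a centre distance equal to the
#' sum of the daughter radii. Daughters inherit group and state, velocities
#' reset to zero; lateral positions wrap periodically and positions below
#' the substratum are reflected. Randomness flows from R's global RNG
#' (seeded once per simulation).
#'
#' @param agents agent data.frame.
#' @param groups named list of [functional_group]s.
#' @param Lx,Ly lateral domain size, um (for periodic wrapping).
#' @return list `agents` (updated table) and `n_divided`.
#' @export
divide <- function(agents, groups, Lx = Inf, Ly = Inf) {
  ddiv <- vapply(groups, function(g) g$division_diameter, numeric(1))[agents$group]
  sel <- which(agents$state == "active" & agents$diameter >= ddiv)
  if (!length(sel)) return(list(agents = agents, n_divided = 0L))
  par <- agents[sel, ]
  dens <- vapply(groups, function(g) g$density, numeric(1))[par$group]
  f <- runif(length(sel), 0.4, 0.6)
  m1 <- f * par$mass
  m2 <- (1 - f) * par$mass
  d1 <- agent_diameter(m1, dens)
  d2 <- agent_diameter(m2, dens)
  dir <- .runif_sphere(length(sel))
  dist <- (d1 + d2) / 2
  # first daughter replaces the parent in place
  agents$mass[sel] <- m1
  agents$diameter[sel] <- d1
  agents$vx[sel] <- 0; agents$vy[sel] <- 0; agents$vz[sel] <- 0
  x2 <- par$x + dir[, 1] * dist
  y2 <- par$y + dir[, 2] * dist
  z2 <- par$z + dir[, 3] * dist
  if (is.finite(Lx)) x2 <- x2 %% Lx
  if (is.finite(Ly)) y2 <- y2 %% Ly
  z2 <- pmax(z2, d2 / 2)          # reflect below the substratum
  sib <- data.frame(id = max(agents$id) + seq_along(sel), group = par$group,
                    state = par$state, x = x2, y = y2, z = z2,
                    mass = m2, diameter = d2, vx = 0, vy = 0, vz = 0, mu = 0,
                    stringsAsFactors = FALSE)
  list(agents = rbind(agents, sib), n_divided = length(sel))
}

#' Flag starved agents as inert
#'
#' An active agent whose mass has fallen to 10% of its group's division
#' mass (boundary included) becomes inert, irreversibly: it stops reacting
#' and growing but keeps participating in mechanics.
#'
#' @param agents agent data.frame.
#' @param groups named list of [functional_group]s.
#' @param fraction inert threshold as a fraction of division mass.
#' @return updated agent data.frame.
#' @export
check_inert <- function(agents, groups, fraction = 0.1) {
  mdiv <- vapply(groups, division_mass, numeric(1))[agents$group]
  sel <- agents$state == "active" & agents$mass <= fraction * mdiv
  if (any(sel)) {
    agents$state[sel] <- "inert"
    agents$mu[sel] <- 0
  }
  agents
}

#' Species released by cellular decay
#'
#' Decayed biomass is returned as the carbon and nitrogen sources of the
#' group's anabolic reaction: 1 C-mol of carbon (scaled by the carbon count
#' of the source form) and 0.2 mol N (the biomass nitrogen content) per
#' C-mol of biomass lost. Carbon and nitrogen are conserved exactly.
#'
#' @param dmass biomass lost, C-mol (>= 0).
#' @param group a [functional_group].
#' @param db thermodynamic database.
#' @return named vector of mol released per form label.
#' @export
decay_products <- function(dmass, group, db = default_thermo_db()) {
  stopifnot(all(dmass >= 0))
  el_c <- .elements_form(db, group$c_source)
  el_n <- .elements_form(db, group$n_source)
  out <- c(dmass / el_c["C", 1], 0.2 * dmass / el_n["N", 1])
  names(out) <- c(group$c_source, group$n_source)
  out
}

#' Reaction rates contributed by one agent
#'
#' Growing agents run the overall growth reaction at `mu * X` (C-mol/h)
#' plus the catabolic reaction at the maintenance flux `m_bac * X / Y_XS`
#' (mol donor/h); maintaining agents run the maintenance flux only;
#' decaying agents release decay products at `k_decay * X`. Inert agents
#' contribute nothing.
#'
#' @param group a [functional_group].
#' @param energy energetic state from [group_energetics()].
#' @param regime `"grow"`, `"maintain"` or `"decay"`.
#' @param mass agent mass, C-mol.
#' @param mu specific growth rate (grow regime), 1/h.
#' @param state agent state.
#' @param db thermodynamic database.
#' @return named vector, mol/h per form label (negative = consumed).
#' @export
agent_reaction_rates <- function(group, energy, regime, mass, mu = NULL,
                                 state = "active", db = default_thermo_db()) {
  if (state != "active") return(numeric(0))
  if (regime == "grow") {
    if (is.null(mu)) mu <- group$q_max * energy$Y_XS - energy$m_bac
    ov <- overall_reaction(group$ana, group$cat, energy$Y_XS, group$donor, db)
    r <- ov$stoich * (mu * mass)
    mnt <- group$cat$stoich * (energy$m_bac * mass / energy$Y_XS)
    labs <- union(names(r), names(mnt))
    out <- setNames(numeric(length(labs)), labs)
    out[names(r)] <- out[names(r)] + r
    out[names(mnt)] <- out[names(mnt)] + mnt
    out
  } else if (regime == "maintain") {
    group$cat$stoich * (energy$m_bac * mass / energy$Y_XS)
  } else {
    decay_products(group$k_decay * mass, group, db)
  }
}

# map a named form-rate vector to species-total rates, dropping H+, OH-,
# H2O and Biomass (protons are implicit in the charge balance; water is at
# activity 1; biomass lives on the agents).
.rates_to_species <- function(rates, db) {
  drop_labs <- c("H+", "OH-", "H2O", "Biomass")
  keep <- setdiff(names(rates), drop_labs)
  if (!length(keep)) return(numeric(0))
  sp <- db$forms$species[match(keep, db$forms$form)]
  tapply(rates[keep], sp, sum)
}
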