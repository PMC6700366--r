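# Soft-sphere mechanics: force laws (reference R implementations), the
# compiled relaxation loop, and height-cap shaving.

#' Mechanical parameters
#'
#' Defaults give strongly overdamped, quasi-static relaxation: the Stokes
#' drag of a ~1 um cell in water dominates inertia, and the normal spring is
#' soft enough that `k_n * dt / (6 pi mu r)` is well below 1.
#'
#' @param k_n normal spring stiffness, N/m.
#' @param gamma_n normal dashpot, N s/m.
#' @param k_t tangential spring stiffness (kept for completeness; the
#'   quasi-static relaxation uses a tangential dashpot), N/m.
#' @param gamma_t tangential dashpot, N s/m.
#' @param mu_f Coulomb friction coefficient capping the tangential force.
#' @param k_adh adhesion force scale at contact for two reference-mass
#'   agents, N.
#' @param m_ref reference agent mass (1 um wet cell), kg.
#' @param cutoff_um adhesion cutoff distance beyond touching, um.
#' @param dt_s relaxation time step, s.
#' @param max_steps relaxation step cap.
#' @param tol_overlap residual overlap tolerance, fraction of mean diameter.
#' @param tol_speed residual speed tolerance, m/s.
#' @param viscosity fluid dynamic viscosity, Pa s.
#' @param flow uniform fluid velocity (one-way drag coupling), m/s.
#' @return a `mech_params` list.
#' @export
mech_params <- function(k_n = 5e-6, gamma_n = 1e-9, k_t = 0, gamma_t = 1e-9,
                        mu_f = 0.5, k_adh = 1e-16, m_ref = 5.76e-16,
                        cutoff_um = 0.2, dt_s = 1e-3, max_steps = 20000L,
                        tol_overlap = 0.01, tol_speed = 1e-6,
                        viscosity = 1e-3, flow = c(0, 0, 0)) {
  p <- list(k_n = k_n, gamma_n = gamma_n, k_t = k_t, gamma_t = gamma_t,
            mu_f = mu_f, k_adh = k_adh, m_ref = m_ref, cutoff_um = cutoff_um,
            dt_s = dt_s, max_steps = as.integer(max_steps),
            tol_overlap = tol_overlap, tol_speed = tol_speed,
            viscosity = viscosity, flow = as.numeric(flow))
  if (any(unlist(p[c("k_n", "gamma_n", "k_t", "gamma_t", "mu_f", "k_adh",
                     "cutoff_um", "dt_s", "tol_overlap", "tol_speed")]) < 0))
    stop("mechanical parameters must be >= 0")
  structure(p, class = "mech_params")
}

# wet (buoyant-relevant) mass used for mechanics, kg; diameter um
.wet_mass_kg <- function(diameter, wet_density = 1100) {
  (pi / 6) * (diameter * 1e-6)^3 * wet_density
}

#' Pairwise contact force (reference implementation)
#'
#' Kelvin-Voigt normal spring-dashpot plus a tangential dashpot capped by
#' the Coulomb criterion. Zero unless the spheres overlap. The forces on
#' the two agents are equal and opposite.
#'
#' @param a,b agents: lists with `pos` (um, length 3), `radius` (um),
#'   `vel` (um/s, length 3), `mass` (kg).
#' @param params a [mech_params()].
#' @return list `on_a`, `on_b` (N, length-3 vectors) and `overlap_um`.
#' @export
contact_force <- function(a, b, params = mech_params()) {
  d <- (a$pos - b$pos) * 1e-6
  dist <- sqrt(sum(d^2))
  sumr <- (a$radius + b$radius) * 1e-6
  if (dist >= sumr || dist == 0)
    return(list(on_a = c(0, 0, 0), on_b = c(0, 0, 0),
                overlap_um = max(0, (sumr - dist)) * 1e6))
  n <- d / dist
  ov <- sumr - dist
  vrel <- (a$vel - b$vel) * 1e-6
  vn <- sum(vrel * n)
  Fn <- params$k_n * ov - params$gamma_n * vn
  vt <- vrel - vn * n
  Ft <- -params$gamma_t * vt
  cap <- params$mu_f * abs(Fn)
  ftm <- sqrt(sum(Ft^2))
  if (ftm > cap && ftm > 0) Ft <- Ft * cap / ftm
  F <- Fn * n + Ft
  list(on_a = F, on_b = -F, overlap_um = ov * 1e6)
}

#' Pairwise adhesion force (reference implementation)
#'
#' Attractive spring along the centre line whose strength scales with the
#' product of the two agent masses (relative to `m_ref^2`) and ramps
#' linearly to zero at the cutoff gap; full strength once in contact.
#'
#' @inheritParams contact_force
#' @return list `on_a`, `on_b` (N).
#' @export
adhesion_force <- function(a, b, params = mech_params()) {
  d <- (a$pos - b$pos) * 1e-6
  dist <- sqrt(sum(d^2))
  sumr <- (a$radius + b$radius) * 1e-6
  gap <- dist - sumr
  cutoff <- params$cutoff_um * 1e-6
  if (gap >= cutoff || dist == 0)
    return(list(on_a = c(0, 0, 0), on_b = c(0, 0, 0)))
  n <- d / dist
  ramp <- min(1, 1 - gap / cutoff)
  Fad <- params$k_adh * (a$mass * b$mass) / params$m_ref^2 * ramp
  list(on_a = -Fad * n, on_b = Fad * n)
}

#' Stokes drag force on an agent (one-way fluid coupling)
#'
#' `F = 6 pi mu r (u_fluid - v)`; the fluid is not affected by the cells.
#'
#' @param agent list with `radius` (um) and `vel` (um/s).
#' @param fluid_velocity local fluid velocity, m/s.
#' @param params a [mech_params()].
#' @return force, N (length 3).
#' @export
drag_force <- function(agent, fluid_velocity = c(0, 0, 0), params = mech_params()) {
  6 * pi * params$viscosity * (agent$radius * 1e-6) *
    (fluid_velocity - agent$vel * 1e-6)
}

#' Force breakdown for a set of agents (compiled path)
#'
#' @param agents agent data.frame.
#' @param params a [mech_params()].
#' @param Lx,Ly periodic lateral domain size, um (`<= 0` disables wrapping).
#' @return list of 3 x n matrices `contact`, `adhesion`, `drag` (N) plus
#'   `max_overlap_m`.
#' @export
mech_forces <- function(agents, params = mech_params(), Lx = -1, Ly = -1) {
  cpp_mech_forces(agents$x, agents$y, agents$z, agents$diameter / 2,
                  agents$vx, agents$vy, agents$vz,
                  .wet_mass_kg(agents$diameter), params, Lx, Ly)
}

#' Relax agent overlaps by damped discrete-element integration
#'
#' Integrates `m dv/dt = F_contact + F_adhesion + F_drag` with a
#' semi-implicit Euler scheme (drag implicit, hence stable in the
#' overdamped regime) until the maximum overlap falls below 1% of the mean
#' diameter and motion has died down, or `max_steps` is reached. The
#' substratum is a rigid plane; lateral faces are periodic.
#'
#' @param agents agent data.frame.
#' @param params a [mech_params()].
#' @param Lx,Ly lateral domain size, um.
#' @return list with updated `agents`, `steps`, `converged`,
#'   `max_overlap_frac`, `max_speed_m_s`, `ke_trace`.
#' @export
relax <- function(agents, params = mech_params(), Lx, Ly) {
  if (nrow(agents) == 0L)
    return(list(agents = agents, steps = 0L, converged = TRUE,
                max_overlap_frac = 0, max_speed_m_s = 0, ke_trace = numeric(0)))
  out <- cpp_relax(agents$x, agents$y, agents$z, agents$diameter / 2,
                   .wet_mass_kg(agents$diameter), params, Lx, Ly,
                   params$dt_s, params$max_steps, params$tol_overlap,
                   params$tol_speed)
  if (!out$converged && out$max_overlap_frac > 2 * params$tol_overlap)
    warning("mechanical relaxation stopped at overlap fraction ",
            signif(out$max_overlap_frac, 3), " after ", out$steps, " steps")
  agents$x <- out$x; agents$y <- out$y; agents$z <- out$z
  agents$vx <- 0; agents$vy <- 0; agents$vz <- 0
  c(list(agents = agents), out[c("steps", "converged", "max_overlap_frac",
                                 "max_speed_m_s", "ke_trace")])
}

#' Shave agents above the height cap
#'
#' Agents whose centre lies above `z_max` are removed from the domain
#' (mimicking detachment at a steady biofilm thickness). The removed mass
#' is reported for the audit ledger, not returned to the bulk.
#'
#' @param agents agent data.frame.
#' @param z_max height cap, um.
#' @return list `agents` (kept), `removed` (data.frame),
#'   `removed_mass` (C-mol).
#' @export
shave <- function(agents, z_max) {
  stopifnot(z_max > 0)
  sel <- agents$z > z_max
  list(agents = agents[!sel, , drop = FALSE],
       removed = agents[sel, , drop = FALSE],
       removed_mass = sum(agents$mass[sel]))
}
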