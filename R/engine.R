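# Orchestration of the simulation loop across the three time scales and
# the scenario modes (boundary conditions, pH control, thermodynamic
# coupling).

# mode combinations used by the packaged scenarios (boundary, pH, thermo)
.ALLOWED_MODES <- rbind(
  c("fixed",   "constant", "coupled"),    # nitrification 1a
  c("dynamic", "constant", "coupled"),    # 2a
  c("fixed",   "free",     "coupled"),    # 3a, 1b
  c("dynamic", "free",     "coupled"),    # 4a, 2b
  c("dynamic", "buffered", "coupled"),    # 5a, 5b
  c("dynamic", "buffered", "decoupled")   # 4b
)

#' Build a validated scenario configuration
#'
#' @param name scenario label.
#' @param grid a [grid_spec()].
#' @param bulk named initial bulk totals, mol/L.
#' @param inlet named inlet totals, mol/L (defaults to `bulk`).
#' @param groups character vector of packaged group names (see
#'   [functional_group_library()]) or a named list of [functional_group]s.
#' @param seeding a [seeding_plan()].
#' @param boundary_mode `"fixed"` (Dirichlet values frozen, reactor
#'   decoupled) or `"dynamic"` (Dirichlet values follow the reactor mass
#'   balance every biological step).
#' @param pH_mode `"constant"`, `"free"` or `"buffered"` (free pH plus
#'   strong-ion titration of the bulk back to `buffer_setpoint` whenever it
#'   drops below `buffer_trigger`).
#' @param thermo_mode `"coupled"` (yields recomputed per agent per refresh
#'   from local concentrations) or `"decoupled"` (yields frozen at t = 0
#'   from the initial bulk).
#' @param pH_init initial (and constant-mode) pH.
#' @param buffer_trigger,buffer_setpoint buffered-mode trigger and target pH.
#' @param fixed_species species whose top boundary value stays at the
#'   initial bulk value even in dynamic mode (e.g. aerated O2 and CO2).
#' @param z_max height cap, um: agents above it are shaved off.
#' @param dt_bio biological time step, h (adaptively reduced so no agent
#'   changes mass by more than ~10% per step).
#' @param dt_diff diffusion pseudo-time step, s (`NULL`: the per-species
#'   stability bound `h^2/(6 D)` with a 0.9 safety factor).
#' @param dt_mech mechanical relaxation step, s.
#' @param alpha,beta growth/decay relaxation band around maintenance.
#' @param T temperature, K.
#' @param seed RNG seed (all stochastic draws flow from it).
#' @param t_end simulated time horizon, h.
#' @param output_every snapshot cadence, h.
#' @param reactor list with `Q`, `V`, `A_F`, `V_gas`, `Q_gas`, `kLa`.
#' @param stationarity list with `window_h` and `rel_tol`: the run is
#'   declared stationary when every group's biomass changes by less than
#'   `rel_tol` (relative) over the trailing window.
#' @param stop_at_stationarity stop once the height cap has been reached
#'   and the community is stationary.
#' @param diff_tol steady-state tolerance (max relative field change per
#'   pseudo-time step).
#' @param diff_chunk inner diffusion steps between pH/thermodynamics/rate
#'   refreshes.
#' @param diff_max_steps cap on inner steps per biological step.
#' @param bl_um boundary-layer thickness, um.
#' @param biofilm_factor biofilm/water diffusivity ratio.
#' @param mech a [mech_params()].
#' @param allow_custom allow mode combinations outside the packaged
#'   scenario tables.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(name, grid, bulk, inlet = bulk, groups, seeding,
                            boundary_mode = c("fixed", "dynamic"),
                            pH_mode = c("constant", "free", "buffered"),
                            thermo_mode = c("coupled", "decoupled"),
                            pH_init = 7.5, buffer_trigger = 6.5,
                            buffer_setpoint = pH_init,
                            fixed_species = character(0), z_max,
                            dt_bio = 1, dt_diff = NULL, dt_mech = 1e-3,
                            alpha = 1.2, beta = 0.8, T = 298.15, seed = 1L,
                            t_end = 1000, output_every = 100,
                            reactor = list(Q = 0.02, V = 0.1, A_F = 0.05,
                                           V_gas = 0.1, Q_gas = 0.1, kLa = 0),
                            stationarity = list(window_h = 48, rel_tol = 0.01),
                            stop_at_stationarity = TRUE,
                            diff_tol = 1e-6, diff_chunk = 600L,
                            diff_max_steps = 200000L, bl_um = 40,
                            biofilm_factor = 0.8, mech = mech_params(),
                            allow_custom = FALSE) {
  boundary_mode <- match.arg(boundary_mode)
  pH_mode <- match.arg(pH_mode)
  thermo_mode <- match.arg(thermo_mode)
  stopifnot(inherits(grid, "grid_spec"), inherits(seeding, "seeding_plan"),
            alpha > 1, beta > 0, beta < 1, dt_bio > 0, dt_bio <= 1,
            dt_mech > 0, T > 0, t_end > 0, z_max > 0)
  if (!is.null(dt_diff) && dt_diff / 3600 >= dt_mech / 3600 * 1000)
    stop("expected dt_diff (s) < dt_mech (s) < dt_bio (h)")
  if (z_max + bl_um >= grid$Lz)
    stop("z_max + boundary layer (", z_max + bl_um,
         " um) must leave room for bulk cells below the domain top (Lz = ",
         grid$Lz, " um)")
  if (is.null(names(bulk)) || is.null(names(inlet)))
    stop("bulk and inlet must be named by species")
  if (!allow_custom) {
    combo <- c(boundary_mode, pH_mode, thermo_mode)
    ok <- any(apply(.ALLOWED_MODES, 1, function(r) all(r == combo)))
    if (!ok)
      stop("mode combination (", paste(combo, collapse = ", "),
           ") is not one of the packaged scenario modes; ",
           "set allow_custom = TRUE to override")
  }
  if (is.character(groups)) {
    lib <- functional_group_library()
    missing <- setdiff(groups, names(lib))
    if (length(missing)) stop("unknown group(s): ", paste(missing, collapse = ", "))
    groups <- lib[groups]
  }
  if (!all(names(seeding$counts) %in% names(groups)))
    stop("seeding refers to groups not in the configuration")
  need <- c("Q", "V", "A_F", "V_gas", "Q_gas", "kLa")
  if (!all(need %in% names(reactor))) stop("reactor needs fields: ",
                                           paste(need, collapse = ", "))
  structure(list(name = name, grid = grid, bulk = bulk, inlet = inlet,
                 groups = groups, seeding = seeding,
                 boundary_mode = boundary_mode, pH_mode = pH_mode,
                 thermo_mode = thermo_mode, pH_init = pH_init,
                 buffer_trigger = buffer_trigger,
                 buffer_setpoint = buffer_setpoint,
                 fixed_species = fixed_species, z_max = z_max,
                 dt_bio = dt_bio, dt_diff = dt_diff, dt_mech = dt_mech,
                 alpha = alpha, beta = beta, T = T, seed = as.integer(seed),
                 t_end = t_end, output_every = output_every,
                 reactor = reactor, stationarity = stationarity,
                 stop_at_stationarity = stop_at_stationarity,
                 diff_tol = diff_tol, diff_chunk = as.integer(diff_chunk),
                 diff_max_steps = as.integer(diff_max_steps), bl_um = bl_um,
                 biofilm_factor = biofilm_factor, mech = mech,
                 allow_custom = allow_custom),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$name, "\n",
      " grid", x$grid$nx, "x", x$grid$ny, "x", x$grid$nz, "@", x$grid$h, "um;",
      "BC", x$boundary_mode, "| pH", x$pH_mode, "| thermo", x$thermo_mode, "\n",
      " groups:", paste(names(x$groups), collapse = ", "),
      "| seed", x$seed, "| t_end", x$t_end, "h\n")
  invisible(x)
}

# Gibbs energy of a reaction evaluated per grid cell (vectorized):
# forms_mat: cells x form-labels, H: per-cell proton concentration.
.reaction_gibbs_cells <- function(stoich, dG0, forms_mat, H, T, floor = 1e-12) {
  out <- rep(dG0, length(H))
  lnq <- numeric(length(H))
  for (lab in names(stoich)) {
    if (lab == "H2O" || lab == "Biomass") next
    a <- if (lab == "H+") H
         else if (lab %in% colnames(forms_mat)) forms_mat[, lab]
         else 1
    lnq <- lnq + stoich[[lab]] * log(pmax(a, floor))
  }
  out + .RGAS * T * lnq
}

# Per-group precomputation reused every refresh.
.group_meta <- function(groups, db) {
  lapply(groups, function(g) {
    donor_species <- db$forms$species[match(g$donor, db$forms$form)]
    donor_forms <- db$forms$form[db$forms$species == donor_species]
    in_ana <- intersect(donor_forms, names(g$ana$stoich))
    d_ana <- if (length(in_ana)) -sum(pmin(g$ana$stoich[in_ana], 0)) else 0
    list(ana_sp = .rates_to_species(g$ana$stoich, db),
         cat_sp = .rates_to_species(g$cat$stoich, db),
         dec_sp = .rates_to_species(decay_products(1, g, db), db),
         d_ana = d_ana,
         dG0_cat = sum(g$cat$stoich * .dG_form(db, names(g$cat$stoich))),
         dG0_ana = sum(g$ana$stoich * .dG_form(db, names(g$ana$stoich))))
  })
}

# Rate-refresh closure for the quasi-steady diffusion-reaction solve.
# Recomputes per-cell pH/speciation, (coupled) thermodynamics, growth
# regimes and per-agent rates from the current fields; deposits volumetric
# rate fields and writes the biological state (mu, regime, Y) plus the
# gas-transfer average into `env`.
.make_refresh <- function(agents, groups, meta, config, inert, reactor, db, env) {
  spec <- config$grid
  act <- which(agents$state == "active")
  env$mu <- rep(0, nrow(agents))
  env$regime <- rep(NA_character_, nrow(agents))
  env$Y <- rep(NA_real_, nrow(agents))
  env$transfer_ave <- NULL
  gas_sp <- if (reactor$kLa > 0)
    names(config$bulk)[vapply(names(config$bulk),
                              function(s) is.finite(db$species[[s]]$henry), TRUE)]
  else character(0)
  if (length(act)) {
    ci <- cell_index(spec, agents$x[act], agents$y[act], agents$z[act])
    ucl <- sort(unique(ci$lin))
    rmap <- match(ci$lin, ucl)
  }
  grp_rows <- if (length(act)) split(seq_along(act), agents$group[act]) else list()

  function(grid) {
    if (length(act)) {
      tot <- vapply(grid$species, function(s) grid$conc[[s]][ucl],
                    numeric(length(ucl)))
      if (!is.matrix(tot)) tot <- matrix(tot, nrow = length(ucl),
                                         dimnames = list(NULL, grid$species))
      if (config$pH_mode == "constant") {
        H <- rep(10^(-config$pH_init), length(ucl))
        pHu <- rep(config$pH_init, length(ucl))
      } else {
        sol <- .solve_pH_vec(tot, inert$Na - inert$Cl, guess = grid$pH[ucl],
                             tol = 1e-12, db = db, T = config$T)
        H <- sol$H
        pHu <- sol$pH
      }
      grid$pH[ucl] <- pHu
      forms <- speciate(tot, H, db, config$T)
      arate <- matrix(0, length(act), length(grid$species),
                      dimnames = list(NULL, grid$species))
      for (gname in names(grp_rows)) {
        g <- groups[[gname]]
        mt <- meta[[gname]]
        rows <- grp_rows[[gname]]
        r <- rmap[rows]
        Pi <- monod_limitation(g, forms[r, , drop = FALSE])
        if (config$thermo_mode == "decoupled") {
          en <- env$frozen[[gname]]
          dgc <- rep(en$dG_cat, length(rows))
          Y <- rep(en$Y_XS, length(rows))
          m <- rep(en$m_bac, length(rows))
        } else {
          dgc <- .reaction_gibbs_cells(g$cat$stoich, mt$dG0_cat, forms[r, , drop = FALSE],
                                       H[r], config$T)
          dga <- .reaction_gibbs_cells(g$ana$stoich, mt$dG0_ana, forms[r, , drop = FALSE],
                                       H[r], config$T)
          feasible <- dgc < 0 & (dga + g$dG_dis) > 0
          Y <- ifelse(feasible, abs(dgc) / (dga + g$dG_dis), NA_real_)
          m <- ifelse(feasible,
                      if (!is.null(g$m_bac_direct)) g$m_bac_direct
                      else Y * g$dG_dis_m / abs(dgc), NA_real_)
        }
        flux <- g$q_max * Y * Pi
        regime <- ifelse(!is.finite(flux), "decay",
                         ifelse(flux > config$alpha * m, "grow",
                                ifelse(flux < config$beta * m, "decay", "maintain")))
        mu <- ifelse(regime == "grow", flux - m, 0)
        X <- agents$mass[act][rows]
        aflux <- ifelse(regime == "grow", mu * X, 0)
        cflux <- ifelse(regime == "grow", (1 / Y - mt$d_ana) * mu * X + m * X / Y,
                        ifelse(regime == "maintain", m * X / Y, 0))
        cflux[!is.finite(cflux)] <- 0
        dflux <- ifelse(regime == "decay", g$k_decay * X, 0)
        for (s in names(mt$ana_sp))
          if (s %in% grid$species)
            arate[rows, s] <- arate[rows, s] + aflux * mt$ana_sp[[s]]
        for (s in names(mt$cat_sp))
          if (s %in% grid$species)
            arate[rows, s] <- arate[rows, s] + cflux * mt$cat_sp[[s]]
        for (s in names(mt$dec_sp))
          if (s %in% grid$species)
            arate[rows, s] <- arate[rows, s] + dflux * mt$dec_sp[[s]]
        env$mu[act[rows]] <- mu
        env$regime[act[rows]] <- regime
        env$Y[act[rows]] <- Y
      }
      grid <- assemble_reactions(grid, agents[act, , drop = FALSE], arate)
    } else {
      grid <- assemble_reactions(grid, NULL, NULL)
    }
    if (length(gas_sp)) {
      liquid <- grid$region != .REGION[["bulk"]]
      tr <- setNames(numeric(length(gas_sp)), gas_sp)
      for (s in gas_sp) {
        r_cell <- gas_transfer_rate(grid$conc[[s]], reactor$p[[s]],
                                    reactor$kLa, db$species[[s]]$henry)
        a <- grid$rates[[s]]
        a[liquid] <- a[liquid] - r_cell[liquid]
        grid$rates[[s]] <- a
        tr[[s]] <- mean(r_cell[liquid])
      }
      env$transfer_ave <- tr
    }
    # under-relax the rate fields between refreshes: agents sitting on a
    # regime boundary would otherwise flip their rates every refresh and
    # keep the fields oscillating; the damped fixed point is the duty-cycled
    # average rate
    if (!is.null(env$prev_rates)) {
      for (s in grid$species)
        grid$rates[[s]] <- 0.5 * (grid$rates[[s]] + env$prev_rates[[s]])
    }
    env$prev_rates <- grid$rates
    grid
  }
}

#' Run a scenario
#'
#' Executes the simulation loop. Per biological step, in order: (1)
#' speciation/pH refresh; (2) diffusion-reaction to steady state with pH
#' and (coupled) thermodynamics refreshed between chunks; (3) agent mass
#' balances over the (adaptively limited) biological step; (4) reactor and
#' headspace balances with Dirichlet update (dynamic mode); (5) pH
#' buffering check (buffered mode); (6) division and inert/decay checks;
#' (7) shaving at the height cap; (8) mechanical relaxation. The loop stops
#' at `t_end`, or earlier once the height cap has been reached and every
#' group's biomass is stationary.
#'
#' @param config a [scenario_config()].
#' @param verbose print one line per biological step.
#' @param agents optional initial agent table overriding the seeding plan
#'   (e.g. to continue from a snapshot).
#' @return a `simulation_trajectory`: list with `timeseries` (data.frame),
#'   `snapshots` (agent tables and final grid), `agents`, `grid`,
#'   `reactor`, `config`, `diagnostics`.
#' @export
run_scenario <- function(config, verbose = FALSE, agents = NULL) {
  db <- default_thermo_db()
  set.seed(config$seed)
  spec <- config$grid
  groups <- config$groups
  meta <- .group_meta(groups, db)

  if (is.null(agents)) agents <- generate_seeding(config$seeding, spec, groups)
  if (nrow(agents)) agents <- relax(agents, config$mech, spec$Lx, spec$Ly)$agents

  tt <- titrate_to_setpoint(config$bulk, inert_pool(), config$pH_init, db, config$T)
  inert <- tt$inert
  grid <- grid_state(spec, config$bulk, db, pH = config$pH_init,
                     biofilm_factor = config$biofilm_factor, bl_um = config$bl_um)
  grid <- update_regions(grid, agents)
  reactor <- reactor_state(C = config$bulk, C_in = config$inlet,
                           Q = config$reactor$Q, V = config$reactor$V,
                           A_F = config$reactor$A_F, V_gas = config$reactor$V_gas,
                           Q_gas = config$reactor$Q_gas, kLa = config$reactor$kLa,
                           T = config$T, inert = inert, pH = config$pH_init)

  env <- new.env(parent = emptyenv())
  # frozen yields for decoupled mode: from the initial bulk composition
  bulk_forms0 <- speciate(config$bulk, 10^(-config$pH_init), db, config$T)$concentrations
  env$frozen <- lapply(groups, function(g)
    group_energetics(g, conc = bulk_forms0, T = config$T, db = db))

  gnames <- names(groups)
  record <- function(t, diag = list()) {
    active <- agents$state == "active"
    B <- vapply(gnames, function(g) sum(agents$mass[active & agents$group == g]),
                numeric(1))
    row <- c(list(time_h = t,
                  height_um = if (nrow(agents)) max(agents$z + agents$diameter / 2) else 0,
                  n_agents = nrow(agents), n_active = sum(active),
                  inert_mass = sum(agents$mass[!active])),
             setNames(as.list(B), paste0("B_", gnames)),
             setNames(as.list(reactor$C), paste0("C_", names(reactor$C))),
             list(pH_bulk = reactor$pH),
             setNames(as.list(reactor$p), paste0("p_", names(reactor$p))),
             diag)
    row
  }
  rows <- list(record(0, list(diff_iters = 0, relax_steps = 0, n_divided = 0,
                              n_shaved = 0, dt_h = 0)))
  snapshots <- list(list(time = 0, agents = agents, grid = NULL))
  next_snap <- config$output_every

  t <- 0; step <- 0L
  cap_reached <- FALSE
  shaved_mass <- 0
  stat <- FALSE
  btimes <- numeric(0)
  bhist <- matrix(numeric(0), 0, length(gnames))

  while (t < config$t_end) {
    step <- step + 1L
    env$prev_rates <- NULL
    refresh <- .make_refresh(agents, groups, meta, config, reactor$inert,
                             reactor, db, env)
    grid <- solve_to_steady_state(grid, refresh, tol = config$diff_tol,
                                  max_steps = config$diff_max_steps,
                                  chunk = config$diff_chunk)
    diff_iters <- attr(grid, "iterations")

    # (3) biology over an adaptively limited step
    dt <- config$dt_bio
    if (nrow(agents)) {
      act <- agents$state == "active"
      kdec <- vapply(groups, function(g) g$k_decay, numeric(1))[agents$group]
      rate <- ifelse(env$regime == "grow", env$mu,
                     ifelse(env$regime == "decay", -kdec, 0))
      rate[!act | is.na(rate)] <- 0
      mx <- max(abs(rate))
      if (mx * dt > 0.105) dt <- max(0.105 / mx, config$dt_bio / 64)
      agents$mass[act] <- update_mass(agents$mass[act], env$regime[act],
                                      env$mu[act], kdec[act], dt)
      agents$mu <- ifelse(act, ifelse(env$regime == "grow", env$mu, 0), 0)
      dens <- vapply(groups, function(g) g$density, numeric(1))[agents$group]
      agents$diameter <- agent_diameter(agents$mass, dens)
    }

    # (4) reactor coupling and Dirichlet update (dynamic mode only)
    if (config$boundary_mode == "dynamic") {
      flux <- biofilm_flux(grid, reactor$A_F, reactor$V)
      # aerated/pinned species are not balanced in the bulk
      flux[intersect(config$fixed_species, names(flux))] <- 0
      reactor <- bulk_step(reactor, flux, transfer = if (!is.null(env$transfer_ave))
        -env$transfer_ave else NULL, dt_h = dt)
      if (!is.null(env$transfer_ave))
        reactor <- headspace_step(reactor, env$transfer_ave, dt)
      if (length(config$fixed_species))
        reactor$C[config$fixed_species] <- config$bulk[config$fixed_species]
      grid$bulk <- reactor$C
    }

    # (5) bulk pH bookkeeping and buffering
    if (config$pH_mode == "constant") {
      reactor$pH <- config$pH_init
    } else {
      sol <- solve_pH(reactor$C, reactor$inert, guess = reactor$pH, db = db,
                      T = config$T)
      reactor$pH <- sol$pH
      if (config$pH_mode == "buffered" && sol$pH < config$buffer_trigger) {
        tt <- titrate_to_setpoint(reactor$C, reactor$inert,
                                  config$buffer_setpoint, db, config$T)
        reactor$inert <- tt$inert
        reactor$pH <- config$buffer_setpoint
      }
    }

    # (6) division and inert checks
    ndiv <- 0L
    if (nrow(agents)) {
      dv <- divide(agents, groups, spec$Lx, spec$Ly)
      agents <- dv$agents
      ndiv <- dv$n_divided
      agents <- check_inert(agents, groups)
    }

    # (7) shaving at the height cap
    nshaved <- 0L
    if (nrow(agents)) {
      sh <- shave(agents, config$z_max)
      nshaved <- nrow(sh$removed)
      shaved_mass <- shaved_mass + sh$removed_mass
      agents <- sh$agents
    }

    # (8) mechanical relaxation
    relax_steps <- 0L
    if (nrow(agents) && (ndiv > 0L || nshaved > 0L || step == 1L)) {
      rl <- relax(agents, config$mech, spec$Lx, spec$Ly)
      agents <- rl$agents
      relax_steps <- rl$steps
    }

    grid <- update_regions(grid, agents)
    t <- t + dt
    if (nrow(agents) && max(agents$z + agents$diameter / 2) >= config$z_max - spec$h)
      cap_reached <- TRUE

    rows[[length(rows) + 1L]] <- record(t, list(diff_iters = diff_iters,
                                                relax_steps = relax_steps,
                                                n_divided = ndiv,
                                                n_shaved = nshaved, dt_h = dt))
    if (t >= next_snap - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- list(time = t, agents = agents,
                                                  grid = NULL)
      next_snap <- next_snap + config$output_every
    }
    if (verbose)
      message(sprintf("t=%7.1f h  agents=%5d  height=%5.1f um  div=%d shav=%d diff=%d",
                      t, nrow(agents),
                      if (nrow(agents)) max(agents$z + agents$diameter / 2) else 0,
                      ndiv, nshaved, diff_iters))

    # stationarity: every group's biomass moved < rel_tol over the window
    active <- agents$state == "active"
    btimes <- c(btimes, t)
    bhist <- rbind(bhist, vapply(gnames, function(g)
      sum(agents$mass[active & agents$group == g]), numeric(1)))
    if (config$stop_at_stationarity && cap_reached &&
        t >= config$stationarity$window_h) {
      past <- which(btimes <= t - config$stationarity$window_h)
      if (length(past)) {
        b0 <- bhist[max(past), ]
        b1 <- bhist[nrow(bhist), ]
        rel <- ifelse(pmax(b0, b1) <= 0, 0, abs(b1 - b0) / pmax(b0, b1))
        if (all(rel < config$stationarity$rel_tol)) {
          stat <- TRUE
          break
        }
      }
    }
  }

  snapshots[[length(snapshots) + 1L]] <- list(time = t, agents = agents,
                                              grid = grid)
  structure(list(
    timeseries = as.data.frame(do.call(rbind, lapply(rows, unlist))),
    snapshots = snapshots, agents = agents, grid = grid, reactor = reactor,
    config = config,
    diagnostics = list(steps = step, cap_reached = cap_reached,
                       stationary = stat, shaved_mass = shaved_mass,
                       diffusion_deficit = grid$deficit)
  ), class = "simulation_trajectory")
}

#' @export
print.simulation_trajectory <- function(x, ...) {
  ts <- x$timeseries
  cat("<simulation_trajectory>", x$config$name, "-", nrow(ts) - 1, "steps to t =",
      round(max(ts$time_h), 1), "h;", nrow(x$agents), "agents, height",
      round(max(c(0, x$agents$z + x$agents$diameter / 2)), 1), "um\n")
  invisible(x)
}

#' Total biomass per group of a trajectory's final state
#'
#' @param trajectory a `simulation_trajectory`.
#' @param state `"active"`, `"inert"` or `"all"`.
#' @return named vector of C-mol biomass per group.
#' @export
biomass_by_group <- function(trajectory, state = "active") {
  a <- trajectory$agents
  keep <- if (state == "all") rep(TRUE, nrow(a)) else a$state == state
  vapply(names(trajectory$config$groups),
         function(g) sum(a$mass[keep & a$group == g]), numeric(1))
}
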