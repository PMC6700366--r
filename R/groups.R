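# Microbial functional groups: kinetics + metabolic reactions + energetics.

# molar mass of CH1.8O0.5N0.2 biomass, g per C-mol
.BIOMASS_MOLAR_MASS <- 24.626

#' Define a microbial functional group
#'
#' Bundles the Monod kinetics, decay, the anabolic/catabolic reaction pair
#' and the energetic parameters of one guild. Uptake (Monod) limitation acts
#' on specific protonation forms only — the names of `K_S` are form labels
#' (e.g. ammonia oxidizers are limited by free NH3, nitrite oxidizers by
#' nitrous acid, acetoclastic methanogens by undissociated acetic acid).
#'
#' @param name group name.
#' @param q_max maximum specific substrate uptake rate, mol donor (C-mol X)^-1 h^-1.
#' @param K_S named vector of half-saturation constants (mol/L), names are
#'   the uptake form labels of the limiting substrates.
#' @param k_decay first-order decay constant, 1/h.
#' @param dG_dis growth dissipation energy, kJ per C-mol X.
#' @param ana,cat anabolic / catabolic [reaction]s.
#' @param donor form label of the catabolic electron donor.
#' @param c_source,n_source form labels of the anabolic carbon and nitrogen
#'   sources (released again on decay).
#' @param dG_dis_m maintenance energy rate, kJ (C-mol X)^-1 h^-1.
#' @param m_bac_direct optional direct maintenance rate (1/h) overriding the
#'   energetic computation.
#' @param division_diameter diameter at which an agent divides, um.
#' @param density dry biomass density, fg/um^3.
#' @param db thermodynamic database.
#' @return a `functional_group`.
#' @export
functional_group <- function(name, q_max, K_S, k_decay, dG_dis, ana, cat, donor,
                             c_source, n_source, dG_dis_m = 4.5,
                             m_bac_direct = NULL, division_diameter = 1.36,
                             density = 290, db = default_thermo_db()) {
  stopifnot(q_max > 0, all(K_S > 0), k_decay > 0, dG_dis > 0,
            inherits(ana, "reaction"), inherits(cat, "reaction"))
  known <- db$forms$form
  bad <- setdiff(c(names(K_S), donor, c_source, n_source), known)
  if (length(bad)) stop("unknown form label(s) in group '", name, "': ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, q_max = q_max, K_S = K_S, k_decay = k_decay,
                 dG_dis = dG_dis, dG_dis_m = dG_dis_m, m_bac_direct = m_bac_direct,
                 ana = ana, cat = cat, donor = donor,
                 c_source = c_source, n_source = n_source,
                 division_diameter = division_diameter, density = density),
            class = "functional_group")
}

#' @export
print.functional_group <- function(x, ...) {
  cat("<functional_group>", x$name, " q_max =", x$q_max,
      " donor =", x$donor, " dG_dis =", x$dG_dis, "\n")
  invisible(x)
}

#' Energetic state of a functional group
#'
#' Computes the catabolic and anabolic Gibbs energies (at biochemical
#' standard conditions, or at supplied local activities in coupled-
#' thermodynamics mode), the Eq-1 growth yield and the maintenance rate.
#'
#' @param group a [functional_group].
#' @param conc optional named activities (mol/L) for local correction of
#'   both reactions; `NULL` evaluates the biochemical standard state
#'   (solutes 1 mol/L, pH 7).
#' @param T temperature, K.
#' @param db thermodynamic database.
#' @return list with `dG_cat`, `dG_ana`, `Y_XS`, `m_bac`.
#' @export
group_energetics <- function(group, conc = NULL, T = .T_REF,
                             db = default_thermo_db()) {
  dG_cat <- reaction_gibbs(group$cat, conc, T, db)
  dG_ana <- reaction_gibbs(group$ana, conc, T, db)
  Y <- growth_yield(dG_cat, dG_ana, group$dG_dis)
  m <- if (!is.null(group$m_bac_direct)) group$m_bac_direct
       else maintenance_rate(Y, group$dG_dis_m, dG_cat)
  list(dG_cat = dG_cat, dG_ana = dG_ana, Y_XS = Y, m_bac = m)
}

#' The packaged functional groups
#'
#' Two nitrifying guilds (ammonia and nitrite oxidizers) and three anaerobic
#' guilds (glucose fermenter, hydrogenotrophic and acetoclastic methanogen)
#' with their published kinetic constants, dissipation energies and
#' anabolic/catabolic reactions. Maintenance energy rates default to a
#' Tijhuis-type 4.5 kJ (C-mol X)^-1 h^-1 for the aerobes and
#' 0.5 kJ (C-mol X)^-1 h^-1 for the anaerobes.
#'
#' @param db thermodynamic database.
#' @return named list of [functional_group]s: `AOB`, `NOB`, `fermenter`,
#'   `h2_methanogen`, `ac_methanogen`.
#' @export
functional_group_library <- function(db = default_thermo_db()) {
  rx <- function(s, role) reaction(s, role, db = db)
  list(
    AOB = functional_group(
      "AOB", q_max = 0.032,
      K_S = c("NH3" = 2.11e-6, "O2" = 9.38e-7), k_decay = 0.01, dG_dis = 3500,
      ana = rx(c("NH3" = -0.9, "HCO3-" = -1, "H+" = -1,
                 "Biomass" = 1, "HNO2" = 0.7, "H2O" = 1.1), "anabolic"),
      cat = rx(c("NH3" = -1, "O2" = -1.5, "NO2-" = 1, "H+" = 1, "H2O" = 1), "catabolic"),
      donor = "NH3", c_source = "HCO3-", n_source = "NH3",
      dG_dis_m = 4.5, db = db),
    NOB = functional_group(
      "NOB", q_max = 0.031,
      K_S = c("HNO2" = 3.94e-9, "O2" = 1.88e-6), k_decay = 0.088, dG_dis = 3500,
      ana = rx(c("HNO2" = -2.9, "HCO3-" = -1, "H+" = -1,
                 "Biomass" = 1, "HNO3" = 2.7, "H2O" = 0.2), "anabolic"),
      cat = rx(c("NO2-" = -1, "O2" = -0.5, "NO3-" = 1), "catabolic"),
      donor = "NO2-", c_source = "HCO3-", n_source = "HNO2",
      dG_dis_m = 4.5, db = db),
    fermenter = functional_group(
      "fermenter", q_max = 0.208,
      K_S = c("C6H12O6" = 1.44e-3), k_decay = 0.033, dG_dis = 236,
      ana = rx(c("C6H12O6" = -0.175, "NH3" = -0.2,
                 "Biomass" = 1, "HCO3-" = 0.05, "H2O" = 0.4, "H+" = 0.05), "anabolic"),
      cat = rx(c("C6H12O6" = -1, "H2O" = -4,
                 "CH3COO-" = 2, "HCO3-" = 2, "H2" = 4, "H+" = 4), "catabolic"),
      donor = "C6H12O6", c_source = "C6H12O6", n_source = "NH3",
      dG_dis_m = 0.5, db = db),
    h2_methanogen = functional_group(
      "h2_methanogen", q_max = 0.063,
      K_S = c("H2" = 8.65e-4), k_decay = 0.0125, dG_dis = 700,
      ana = rx(c("HCO3-" = -1, "NH3" = -0.2, "H2" = -2.1, "H+" = -1,
                 "Biomass" = 1, "H2O" = 2.5), "anabolic"),
      cat = rx(c("HCO3-" = -0.25, "H2" = -1, "H+" = -0.25,
                 "CH4" = 0.25, "H2O" = 0.75), "catabolic"),
      donor = "H2", c_source = "HCO3-", n_source = "NH3",
      dG_dis_m = 0.5, db = db),
    ac_methanogen = functional_group(
      "ac_methanogen", q_max = 0.100,
      K_S = c("CH3COOH" = 5e-5), k_decay = 0.0021, dG_dis = 500,
      ana = rx(c("CH3COO-" = -0.525, "NH3" = -0.2, "H+" = -0.475,
                 "Biomass" = 1, "H2O" = 0.4, "HCO3-" = 0.05), "anabolic"),
      cat = rx(c("CH3COO-" = -1, "H2O" = -1, "CH4" = 1, "HCO3-" = 1), "catabolic"),
      donor = "CH3COO-", c_source = "CH3COO-", n_source = "NH3",
      dG_dis_m = 0.5, db = db)
  )
}
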