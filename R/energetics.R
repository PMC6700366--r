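# Reaction Gibbs energies, thermodynamic growth yields and the overall
# metabolic stoichiometry built from one catabolic and one anabolic reaction.

#' Define a metabolic half-reaction
#'
#' Stoichiometry is a named numeric vector over protonation-form labels of
#' the database (negative = consumed). Catabolic reactions are written per
#' mol of electron donor, anabolic reactions per C-mol of biomass formed
#' (biomass formula CH1.8O0.5N0.2, label `"Biomass"`).
#'
#' @param stoich named numeric vector of coefficients.
#' @param role `"catabolic"` or `"anabolic"`.
#' @param db thermodynamic database (for the balance check).
#' @param check if `TRUE`, element (C,H,N,O,P) and charge balance are
#'   verified to `tol`.
#' @param tol balance tolerance.
#' @return a `reaction` object.
#' @export
reaction <- function(stoich, role = c("catabolic", "anabolic"),
                     db = default_thermo_db(), check = TRUE, tol = 1e-6) {
  role <- match.arg(role)
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  if (check) {
    imb <- reaction_imbalance(stoich, db)
    if (max(abs(imb)) > tol)
      stop("reaction not balanced (max |imbalance| = ", signif(max(abs(imb)), 3),
           " in ", names(which.max(abs(imb))), ")")
  }
  structure(list(stoich = stoich, role = role), class = "reaction")
}

#' Element and charge imbalance of a stoichiometry
#'
#' @inheritParams reaction
#' @return named vector of net C, H, N, O, P and charge per reaction unit
#'   (all ~0 for a balanced reaction).
#' @export
reaction_imbalance <- function(stoich, db = default_thermo_db()) {
  if (inherits(stoich, "reaction")) stoich <- stoich$stoich
  el <- .elements_form(db, names(stoich))
  drop(el %*% stoich)
}

#' @export
print.reaction <- function(x, ...) {
  s <- x$stoich
  lhs <- s[s < 0]; rhs <- s[s > 0]
  fmt <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  cat("<reaction:", x$role, "> ", fmt(lhs), " -> ", fmt(rhs), "\n", sep = "")
  invisible(x)
}

#' Gibbs energy of a reaction at given activities
#'
#' `dG = dG0 + R T ln(Q)` with `dG0` from the formation energies of the
#' participating forms and `Q` the activity-based reaction quotient. Water
#' has activity 1; everything else uses the supplied activity (mol/L for
#' solutes, bar for gas-phase entries), defaulting to 1 mol/L except the
#' proton which defaults to 1e-7 (biochemical standard state). Activities
#' are floored at `floor` to avoid singular logarithms in depleted cells.
#'
#' @param rxn a [reaction] (or bare named stoichiometry).
#' @param conc named activities; missing entries use the defaults above.
#' @param T temperature, K.
#' @param db thermodynamic database.
#' @param floor lower bound applied inside the logarithm, mol/L.
#' @return Gibbs energy change, kJ per reaction unit.
#' @export
reaction_gibbs <- function(rxn, conc = NULL, T = .T_REF, db = default_thermo_db(),
                           floor = 1e-12) {
  st <- if (inherits(rxn, "reaction")) rxn$stoich else rxn
  labs <- names(st)
  dG0 <- sum(st * .dG_form(db, labs))
  act <- rep(1, length(st))
  names(act) <- labs
  if ("H+" %in% labs) act[["H+"]] <- 1e-7
  if (!is.null(conc)) {
    hit <- intersect(names(conc), labs)
    act[hit] <- conc[hit]
  }
  if ("H2O" %in% labs) act[["H2O"]] <- 1
  act <- pmax(act, floor)
  dG0 + .RGAS * T * sum(st * log(act))
}

#' Thermodynamic growth yield
#'
#' `Y_XS = |dG_cat| / (dG_ana + dG_dis)` — C-mol biomass formed per mol of
#' electron donor catabolized: the energy harvested by running catabolism
#' once, divided by the energy needed to build and pay the dissipation of
#' one C-mol of biomass.
#'
#' @param dG_cat catabolic Gibbs energy, kJ per mol donor (must be < 0).
#' @param dG_ana anabolic Gibbs energy, kJ per C-mol biomass.
#' @param dG_dis growth dissipation energy, kJ per C-mol biomass
#'   (`dG_ana + dG_dis` must be > 0).
#' @return yield, C-mol X per mol electron donor.
#' @export
growth_yield <- function(dG_cat, dG_ana, dG_dis) {
  if (any(dG_cat >= 0))
    stop("no catabolic energy available (dG_cat >= 0): growth is impossible",
         call. = FALSE)
  den <- dG_ana + dG_dis
  if (any(den <= 0))
    stop("dG_ana + dG_dis must be positive (dissipation smaller than anabolic energy gain)")
  abs(dG_cat) / den
}

#' Maintenance-driven specific decay threshold
#'
#' Maintenance rate `m_bac = Y_XS * dG_dis_m / |dG_cat|` (1/h): the specific
#' rate of biomass-equivalent energy expenditure needed to keep a cell
#' alive, expressed on the growth scale via the yield. `dG_dis_m` is the
#' maintenance energy rate in kJ per C-mol X per hour (Tijhuis-type
#' correlation value or user supplied).
#'
#' @param Y_XS growth yield, C-mol X per mol donor.
#' @param dG_dis_m maintenance energy rate, kJ C-mol^-1 h^-1.
#' @param dG_cat catabolic Gibbs energy, kJ per mol donor (< 0).
#' @return maintenance rate, 1/h.
#' @export
maintenance_rate <- function(Y_XS, dG_dis_m, dG_cat) {
  if (any(dG_cat >= 0)) stop("dG_cat must be negative", call. = FALSE)
  Y_XS * dG_dis_m / abs(dG_cat)
}

#' Overall growth reaction at a given yield
#'
#' Combines anabolism and catabolism into the net growth stoichiometry per
#' C-mol of biomass formed: `overall = ana + (1/Y - d_ana) * cat`, where
#' `d_ana` is the electron-donor species consumption already contained in
#' the anabolic reaction. By construction the net donor-species consumption
#' is exactly `1/Y` mol per C-mol X.
#'
#' @param ana anabolic [reaction] (per C-mol biomass).
#' @param cat catabolic [reaction] (per mol donor).
#' @param Y_XS growth yield.
#' @param donor form label of the electron donor in the catabolic reaction.
#' @param db thermodynamic database.
#' @return a `reaction` (role `"anabolic"` basis: per C-mol biomass) with an
#'   attribute `cat_multiplier`.
#' @export
overall_reaction <- function(ana, cat, Y_XS, donor, db = default_thermo_db()) {
  sa <- ana$stoich; sc <- cat$stoich
  if (!(donor %in% names(sc)) || sc[[donor]] >= 0)
    stop("donor '", donor, "' is not consumed by the catabolic reaction")
  donor_species <- db$forms$species[match(donor, db$forms$form)]
  donor_forms <- db$forms$form[db$forms$species == donor_species]
  in_ana <- intersect(donor_forms, names(sa))
  d_ana <- if (length(in_ana)) -sum(pmin(sa[in_ana], 0)) else 0
  mult <- 1 / Y_XS - d_ana
  if (mult < 0)
    stop("anabolic donor use exceeds total donor demand at this yield")
  labs <- union(names(sa), names(sc))
  st <- setNames(numeric(length(labs)), labs)
  st[names(sa)] <- st[names(sa)] + sa
  st[names(sc)] <- st[names(sc)] + mult * sc
  st <- st[abs(st) > 1e-15]
  out <- reaction(st, role = "anabolic", db = db, tol = 1e-6)
  attr(out, "cat_multiplier") <- mult
  attr(out, "donor") <- donor
  out
}
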