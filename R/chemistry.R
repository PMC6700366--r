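# Acid-base speciation and charge-balance pH, per system or vectorized over
# many systems (grid cells). All concentrations mol/L, temperatures K.

.KW <- 1e-14       # water autoionization at 298.15 K
.LN10 <- log(10)

#' Dissociation constants of a species' protonation chain
#'
#' One equilibrium constant per deprotonation step, computed from the
#' formation Gibbs energies of successive forms:
#' `K_k = exp(-dG_rxn_k / (R T))` with
#' `dG_rxn_k = dG_f(deprotonated) + dG_f(H+) - dG_f(protonated)`
#' (minus `dG_f(H2O)` on the first step for species whose first step lumps a
#' hydration equilibrium, e.g. CO2). No enthalpies are shipped with the
#' default table, so constants are temperature-independent; supplying a
#' `dH_rxn` attribute on the species enables a van't Hoff adjustment.
#'
#' @param species a [species_def] (or species name, resolved in `db`).
#' @param T temperature, K.
#' @param db thermodynamic database used to resolve names.
#' @return numeric vector of length `nforms - 1` (empty for single-form species).
#' @export
dissociation_constants <- function(species, T = .T_REF, db = default_thermo_db()) {
  if (is.character(species)) species <- db$species[[species]]
  stopifnot(inherits(species, "species_def"))
  if (T <= 0) stop("temperature must be > 0")
  nf <- nrow(species$forms)
  if (nf == 1L) return(numeric(0))
  dG <- species$forms$dG_f
  if (any(!is.finite(dG))) stop("non-finite formation energy in species ", species$name)
  dg_rxn <- dG[-1L] - dG[-nf]                      # + dG_f(H+) = 0
  if (species$has_hydration) dg_rxn[1L] <- dg_rxn[1L] - (-237.18)  # - dG_f(H2O)
  K <- exp(-dg_rxn / (.RGAS * .T_REF))
  dH <- attr(species, "dH_rxn")
  if (!is.null(dH) && T != .T_REF)
    K <- K * exp(-dH / .RGAS * (1 / T - 1 / .T_REF))
  K
}

# per-form weights w_j for one species at proton concentrations H (vector):
# w_1 = 1, w_j = w_{j-1} * K_{j-1} / H. Returns matrix length(H) x nforms.
.spec_weights <- function(K, H) {
  nf <- length(K) + 1L
  w <- matrix(1, length(H), nf)
  if (nf > 1L) for (j in 2:nf) w[, j] <- w[, j - 1L] * (K[j - 1L] / H)
  w
}

#' Partition total concentrations over protonation forms
#'
#' Closed-form equilibrium partition of each species' total concentration
#' over its forms at a given proton concentration. The partition conserves
#' mass exactly (the form concentrations of a species sum to its total).
#'
#' @param totals named numeric vector of total concentrations (mol/L), names
#'   being species of `db`; or a matrix with one column per species for many
#'   systems at once.
#' @param H proton concentration(s), mol/L (> 0); recycled to the number of
#'   systems.
#' @param db thermodynamic database.
#' @param T temperature, K.
#' @return for vector input, a `speciation_result`: list with `concentrations`
#'   (named over form labels), `H`, `pH` and `residual` (`NA` here; filled by
#'   [solve_pH()]). For matrix input, a matrix over form labels.
#' @export
speciate <- function(totals, H, db = default_thermo_db(), T = .T_REF) {
  single <- !is.matrix(totals)
  tot <- if (single) matrix(totals, 1L, dimnames = list(NULL, names(totals))) else totals
  if (any(tot < 0, na.rm = TRUE)) stop("negative total concentration")
  if (any(H <= 0)) stop("proton concentration must be > 0")
  H <- rep_len(H, nrow(tot))
  out <- list()
  for (s in colnames(tot)) {
    sp <- db$species[[s]]
    if (is.null(sp)) stop("unknown species: ", s)
    K <- dissociation_constants(sp, T)
    w <- .spec_weights(K, H)
    fr <- w / rowSums(w)
    cs <- fr * tot[, s]
    colnames(cs) <- sp$forms$form
    out[[s]] <- cs
  }
  conc <- do.call(cbind, out)
  if (!single) return(conc)
  structure(list(concentrations = conc[1L, ], H = H, pH = -log10(H),
                 residual = NA_real_), class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("<speciation_result> pH =", format(x$pH, digits = 8), "\n")
  print(x$concentrations)
  invisible(x)
}

#' Non-reactive strong-ion pool used for buffering
#'
#' @param Na sodium concentration, mol/L.
#' @param Cl chloride concentration, mol/L.
#' @return an `inert_pool` object.
#' @export
inert_pool <- function(Na = 0, Cl = 0) {
  stopifnot(Na >= 0, Cl >= 0)
  structure(list(Na = Na, Cl = Cl), class = "inert_pool")
}

# vectorized signed charge-balance residual and its dH derivative.
# tot: matrix systems x species; H: vector; znet: Na - Cl (+ fixed offset).
.charge_residual <- function(tot, H, znet, db, T, deriv = FALSE) {
  res <- H - .KW / H + znet
  dres <- if (deriv) 1 + .KW / H^2 else NULL
  for (s in colnames(tot)) {
    sp <- db$species[[s]]
    K <- dissociation_constants(sp, T)
    z <- sp$forms$charge
    m <- seq_along(z) - 1L
    w <- .spec_weights(K, H)
    S0 <- rowSums(w)
    Sz <- drop(w %*% z)
    res <- res + tot[, s] * Sz / S0
    if (deriv) {
      S1  <- drop(w %*% m)
      Sz1 <- drop(w %*% (z * m))
      dres <- dres + tot[, s] * (Sz * S1 - Sz1 * S0) / (H * S0^2)
    }
  }
  if (deriv) list(res = unname(res), dres = unname(dres)) else unname(res)
}

#' Signed charge-balance residual
#'
#' `residual = sum(charge * form concentration) + [H+] - [OH-] + [Na+] - [Cl-]`
#' with `[OH-] = Kw / [H+]`. The residual is strictly decreasing in pH for
#' fixed totals, which guarantees a unique root.
#'
#' @inheritParams speciate
#' @param inert an [inert_pool()].
#' @return signed residual(s), mol/L.
#' @export
charge_balance <- function(totals, H, inert = inert_pool(), db = default_thermo_db(),
                           T = .T_REF) {
  single <- !is.matrix(totals)
  tot <- if (single) matrix(totals, 1L, dimnames = list(NULL, names(totals))) else totals
  if (any(tot < 0, na.rm = TRUE)) stop("negative total concentration")
  H <- rep_len(H, nrow(tot))
  r <- .charge_residual(tot, H, inert$Na - inert$Cl, db, T)
  if (single) r[1L] else r
}

# damped Newton in log10[H+] with step clamping and bisection fallback.
# tot: matrix systems x species; znet: vector. Returns list(H, residual, iter).
.solve_pH_vec <- function(tot, znet, guess = 7, tol = 1e-12, db = default_thermo_db(),
                          T = .T_REF, pH_range = c(1, 14), maxit = 100L) {
  n <- nrow(tot)
  znet <- rep_len(znet, n)
  lo <- pH_range[1]; hi <- pH_range[2]
  f_lo <- .charge_residual(tot, 10^(-lo), znet, db, T)  # most acidic end: residual max
  f_hi <- .charge_residual(tot, 10^(-hi), znet, db, T)
  bad <- f_lo < 0 | f_hi > 0
  if (any(bad))
    stop("no charge-balance sign change in pH range [", lo, ", ", hi, "] for ",
         sum(bad), " system(s): infeasible chemistry")
  pH <- rep_len(guess, n)
  pH <- pmin(pmax(pH, lo), hi)
  blo <- rep(lo, n); bhi <- rep(hi, n)   # maintained bisection bracket
  iter <- 0L
  repeat {
    iter <- iter + 1L
    H <- 10^(-pH)
    rd <- .charge_residual(tot, H, znet, db, T, deriv = TRUE)
    conv <- abs(rd$res) <= tol
    if (all(conv) || iter >= maxit) break
    # residual > 0 means too acidic -> root is at higher pH
    blo <- ifelse(rd$res > 0, pmax(blo, pH), blo)
    bhi <- ifelse(rd$res < 0, pmin(bhi, pH), bhi)
    # Newton in x = log10 H = -pH: df/dx = dres/dH * H * ln10
    dfdx <- rd$dres * H * .LN10
    step_x <- -rd$res / dfdx
    step_x <- pmin(pmax(step_x, -1), 1)          # clamp to 1 pH unit
    pH_new <- pH - step_x                        # pH = -x
    # fall back to bisection where Newton leaves the bracket or stalls
    outside <- !conv & (pH_new <= blo | pH_new >= bhi | !is.finite(pH_new))
    pH_new[outside] <- (blo[outside] + bhi[outside]) / 2
    pH_new[conv] <- pH[conv]
    pH <- pH_new
  }
  H <- 10^(-pH)
  res <- .charge_residual(tot, H, znet, db, T)
  if (any(abs(res) > tol))
    warning(sum(abs(res) > tol), " system(s) not converged to tol after ",
            maxit, " iterations; max |residual| = ", max(abs(res)))
  list(H = H, pH = pH, residual = res, iterations = iter)
}

#' Solve the charge balance for pH
#'
#' Finds the proton concentration at which the solution is electroneutral,
#' using a damped Newton iteration in log10([H+]) (steps clamped to one pH
#' unit) with a maintained bracket and bisection fallback. A sign change of
#' the residual must exist in `pH_range`.
#'
#' @inheritParams charge_balance
#' @param guess starting pH.
#' @param tol convergence tolerance on the residual, mol/L.
#' @param pH_range admissible pH interval.
#' @return a `speciation_result` with fields `concentrations`, `H`, `pH`,
#'   `residual`, `iterations`.
#' @export
solve_pH <- function(totals, inert = inert_pool(), guess = 7, tol = 1e-12,
                     db = default_thermo_db(), T = .T_REF, pH_range = c(1, 14)) {
  single <- !is.matrix(totals)
  tot <- if (single) matrix(totals, 1L, dimnames = list(NULL, names(totals))) else totals
  if (any(tot < 0, na.rm = TRUE)) stop("negative total concentration")
  ans <- .solve_pH_vec(tot, inert$Na - inert$Cl, guess, tol, db, T, pH_range)
  conc <- speciate(tot, ans$H, db, T)
  if (single)
    structure(list(concentrations = conc[1L, ], H = ans$H[1L], pH = ans$pH[1L],
                   residual = ans$residual[1L], iterations = ans$iterations),
              class = "speciation_result")
  else c(ans, list(concentrations = conc))
}

#' Strong-ion addition needed to buffer the bulk to a pH setpoint
#'
#' The charge-balance residual is linear in the inert ions, so the sodium
#' (upward titration) or chloride (downward titration) addition that moves
#' the solved pH exactly to the setpoint is obtained in closed form from the
#' residual evaluated at the setpoint.
#'
#' @inheritParams charge_balance
#' @param setpoint target pH, in (1, 14).
#' @return list with the updated `inert_pool` and the additions `Na_added`,
#'   `Cl_added` (>= 0, at most one positive).
#' @export
titrate_to_setpoint <- function(totals, inert = inert_pool(), setpoint,
                                db = default_thermo_db(), T = .T_REF) {
  stopifnot(setpoint > 1, setpoint < 14)
  r <- charge_balance(totals, 10^(-setpoint), inert, db, T)
  na_add <- max(0, -r)
  cl_add <- max(0, r)
  list(inert = inert_pool(inert$Na + na_add, inert$Cl + cl_add),
       Na_added = na_add, Cl_added = cl_add)
}
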