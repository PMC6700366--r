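#' @useDynLib biofilmsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames uniroot ks.test
#' @importFrom utils read.csv write.csv head tail
NULL

# gas constant, kJ mol^-1 K^-1, and L bar mol^-1 K^-1
.RGAS  <- 8.314e-3
.RBAR  <- 0.0831446
.T_REF <- 298.15

#' Define a chemical species with its protonation chain
#'
#' A species is a total (analytical) concentration that partitions over an
#' ordered chain of 1-4 protonation forms (i.e. up to three deprotonations),
#' each with a charge and a formation Gibbs energy at 298.15 K. The first
#' form is the most protonated. Successive charges must differ by exactly -1.
#'
#' @param name species identifier (e.g. `"carbonate"`).
#' @param forms data.frame with columns `form` (label), `charge` (integer)
#'   and `dG_f` (kJ/mol); optionally element-count columns `n_C`, `n_H`,
#'   `n_N`, `n_O`, `n_P` used for reaction balance checks.
#' @param has_hydration logical; if `TRUE` the first deprotonation step also
#'   consumes one water (e.g. CO2 + H2O -> HCO3- + H+), so the hydration
#'   equilibrium is lumped into the first apparent dissociation constant.
#' @param D_water diffusion coefficient in water, m^2/h (`NA` for species
#'   that are never transported).
#' @param molar_mass molar mass (g/mol) of the reference form used when
#'   concentrations are configured in mg/L.
#' @param henry optional Henry constant, mol L^-1 bar^-1, for species with a
#'   gas-phase counterpart.
#' @return an object of class `species_def`.
#' @export
species_def <- function(name, forms, has_hydration = FALSE, D_water = NA_real_,
                        molar_mass = NA_real_, henry = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(forms))
  n <- nrow(forms)
  if (n < 1L || n > 4L)
    stop("species '", name, "': must have 1-4 protonation forms (<= 3 deprotonations)")
  if (!all(c("form", "charge", "dG_f") %in% names(forms)))
    stop("forms needs columns form, charge, dG_f")
  if (any(!is.finite(forms$dG_f)))
    stop("species '", name, "': non-finite formation energy")
  if (n > 1L && any(diff(forms$charge) != -1L))
    stop("species '", name, "': successive form charges must differ by exactly -1")
  if (!is.na(D_water) && D_water <= 0) stop("D_water must be > 0")
  if (!is.na(molar_mass) && molar_mass <= 0) stop("molar_mass must be > 0")
  structure(list(name = name, forms = forms, has_hydration = isTRUE(has_hydration),
                 D_water = D_water, molar_mass = molar_mass, henry = henry),
            class = "species_def")
}

#' @export
print.species_def <- function(x, ...) {
  cat("<species_def>", x$name, "-", nrow(x$forms), "form(s):",
      paste(x$forms$form, collapse = " -> "), "\n")
  invisible(x)
}

#' Load a thermodynamic species database
#'
#' Reads the shipped (or a user-supplied) constant table and species property
#' table into the database object used by all chemistry, energetics and
#' transport functions. The shipped table carries, for every protonation
#' form, an effective formation Gibbs energy calibrated so that the packaged
#' functional groups reproduce their published growth yields, alongside the
#' uncalibrated standard value (`dG_f_standard_kJ_mol`) and a `source` tag.
#'
#' @param constants path to the constants CSV (columns `species`, `form`,
#'   `charge`, `dG_f_kJ_mol`, element counts, `source`).
#' @param properties path to the species property CSV (diffusivities, molar
#'   masses, Henry constants, hydration flags).
#' @return an object of class `thermo_db`: list with elements `species`
#'   (named list of [species_def]) and `forms` (flat data.frame over forms).
#' @export
load_thermo_db <- function(constants = system.file("extdata", "thermo_constants.csv",
                                                   package = "biofilmsim"),
                           properties = system.file("extdata", "species_properties.csv",
                                                    package = "biofilmsim")) {
  con <- read.csv(constants, stringsAsFactors = FALSE)
  prp <- read.csv(properties, stringsAsFactors = FALSE)
  sp <- lapply(unique(con$species), function(s) {
    rows <- con[con$species == s, , drop = FALSE]
    p <- prp[match(s, prp$species), ]
    species_def(
      name = s,
      forms = data.frame(form = rows$form, charge = rows$charge,
                         dG_f = rows$dG_f_kJ_mol,
                         n_C = rows$n_C, n_H = rows$n_H, n_N = rows$n_N,
                         n_O = rows$n_O, n_P = rows$n_P,
                         stringsAsFactors = FALSE),
      has_hydration = isTRUE(p$has_hydration),
      D_water = p$D_water_m2_h, molar_mass = p$molar_mass_g_mol,
      henry = p$henry_mol_L_bar)
  })
  names(sp) <- unique(con$species)
  forms <- con
  forms$species_of_form <- forms$species
  rownames(forms) <- forms$form
  structure(list(species = sp, forms = forms), class = "thermo_db")
}

.db_cache <- new.env(parent = emptyenv())

#' The packaged thermodynamic database
#'
#' Cached accessor for [load_thermo_db()] on the shipped tables.
#' @return a `thermo_db`.
#' @export
default_thermo_db <- function() {
  if (is.null(.db_cache$db)) .db_cache$db <- load_thermo_db()
  .db_cache$db
}

# formation energy of a form label (kJ/mol); errors on unknown labels
.dG_form <- function(db, labels) {
  i <- match(labels, db$forms$form)
  if (anyNA(i)) stop("unknown form label(s): ", paste(labels[is.na(i)], collapse = ", "))
  db$forms$dG_f_kJ_mol[i]
}

# charge of a form label
.charge_form <- function(db, labels) {
  i <- match(labels, db$forms$form)
  if (anyNA(i)) stop("unknown form label(s): ", paste(labels[is.na(i)], collapse = ", "))
  db$forms$charge[i]
}

# element-count matrix (C,H,N,O,P + charge row) for form labels
.elements_form <- function(db, labels) {
  i <- match(labels, db$forms$form)
  if (anyNA(i)) stop("unknown form label(s): ", paste(labels[is.na(i)], collapse = ", "))
  m <- t(as.matrix(db$forms[i, c("n_C", "n_H", "n_N", "n_O", "n_P", "charge")]))
  colnames(m) <- labels
  rownames(m) <- c("C", "H", "N", "O", "P", "z")
  m
}

#' Convert mg/L to mol/L (and back) for a database species
#'
#' Conversion uses the molar mass of the species' reference form (e.g. total
#' "CO2" configured as mg CO2 per litre, total ammonia as mg NH3 per litre).
#'
#' @param species species name(s).
#' @param x concentration values.
#' @param db thermodynamic database.
#' @return converted values.
#' @export
mgL_to_molL <- function(species, x, db = default_thermo_db()) {
  mm <- vapply(species, function(s) db$species[[s]]$molar_mass, numeric(1))
  x / 1000 / mm
}

#' @rdname mgL_to_molL
#' @export
molL_to_mgL <- function(species, x, db = default_thermo_db()) {
  mm <- vapply(species, function(s) db$species[[s]]$molar_mass, numeric(1))
  x * 1000 * mm
}
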