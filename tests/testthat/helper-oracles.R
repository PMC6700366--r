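# Independent oracles used across the suite. These deliberately re-derive
# quantities from the raw shipped tables (or closed forms) by a different
# algebraic route than the package implementation.

.oracle_env <- new.env()

oracle_constants <- function() {
  if (is.null(.oracle_env$con))
    .oracle_env$con <- read.csv(system.file("extdata", "thermo_constants.csv",
                                            package = "biofilmsim"))
  .oracle_env$con
}

# brute-force charge-balance residual: alpha fractions built directly from
# the CSV formation energies (hydration handled for carbonate)
oracle_residual <- function(totals, H, Na = 0, Cl = 0) {
  con <- oracle_constants()
  RT <- 8.314e-3 * 298.15
  res <- H - 1e-14 / H + Na - Cl
  for (s in names(totals)) {
    rows <- con[con$species == s, ]
    if (nrow(rows) > 1) {
      dg <- diff(rows$dG_f_kJ_mol)
      if (s == "carbonate") dg[1] <- dg[1] + 237.18   # hydration consumes water
      K <- exp(-dg / RT)
      terms <- c(1, cumprod(K) / H^seq_along(K))
    } else {
      terms <- 1
    }
    res <- res + totals[[s]] * sum(terms * rows$charge) / sum(terms)
  }
  res
}

# bisection (uniroot) pH oracle on the brute-force residual
oracle_pH <- function(totals, Na = 0, Cl = 0) {
  uniroot(function(p) oracle_residual(totals, 10^(-p), Na, Cl),
          c(1, 14), tol = 1e-11)$root
}

# random feasible speciation systems (log-uniform totals, random inerts)
random_system <- function() {
  sp <- c("ammonia", "carbonate", "nitrite", "nitrate", "acetate", "phosphate")
  pick <- sample(sp, sample(2:5, 1))
  totals <- setNames(10^runif(length(pick), -6, -2), pick)
  list(totals = totals,
       inert = inert_pool(Na = runif(1, 0, 5e-3), Cl = runif(1, 0, 5e-3)))
}

# independent 1-D explicit diffusion stepper (bottom Neumann, top cell
# pinned, frozen volumetric rates)
oracle_diffuse_1d <- function(C, D_um2_h, h_um, dt_h, nsteps, rates) {
  nz <- length(C)
  for (s in seq_len(nsteps)) {
    lap <- numeric(nz)
    for (i in seq_len(nz - 1)) {
      up <- if (i < nz) C[i + 1] else C[i]
      dn <- if (i > 1) C[i - 1] else C[i]
      lap[i] <- (up - 2 * C[i] + dn) / h_um^2
    }
    C[seq_len(nz - 1)] <- C[seq_len(nz - 1)] +
      dt_h * (D_um2_h * lap[seq_len(nz - 1)] + rates[seq_len(nz - 1)])
  }
  C
}

# build a 1-column grid whose every cell except the top plane is biofilm
column_grid <- function(nz, h, species, bulk_value, biofilm_factor = 1) {
  spec <- grid_spec(1, 1, nz, h)
  g <- grid_state(spec, setNames(bulk_value, species),
                  biofilm_factor = biofilm_factor, bl_um = h)
  g$region <- array(c(rep(0L, nz - 1), 2L), c(1, 1, nz))
  g$front_plane <- nz - 1L
  g
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.xmin)), tol)
}
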