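# Agent life cycle: limitation, regimes, mass update, division, inert
# transition, decay products, reaction contributions.

db <- default_thermo_db()
lib <- functional_group_library(db)

test_that("Monod limitation multiplies uptake-form saturations", {
  aob <- lib$AOB
  expect_equal(monod_limitation(aob, c("NH3" = 0, "O2" = 1e-3)), 0)
  # both substrates at half saturation -> 0.25 (Table values by construction)
  expect_equal(monod_limitation(aob, c("NH3" = 2.11e-6, "O2" = 9.38e-7)), 0.25)
  # saturates to 1
  expect_gt(monod_limitation(aob, c("NH3" = 1, "O2" = 1)), 0.999)
  # matrix form agrees with scalar form
  m <- rbind(c("NH3" = 1e-6, "O2" = 1e-6), c("NH3" = 1e-5, "O2" = 1e-7))
  expect_equal(monod_limitation(aob, m),
               c(monod_limitation(aob, m[1, ]), monod_limitation(aob, m[2, ])))
})

test_that("regime classification partitions around the maintenance band", {
  g <- lib$AOB
  en <- group_energetics(g, db = db)
  # no substrate -> decay; no maintenance -> grow
  expect_equal(classify_regime(g, en, 0), "decay")
  en0 <- en; en0$m_bac <- 0
  expect_equal(classify_regime(g, en0, 0.5), "grow")
  # flux exactly at m_bac sits inside the (beta, alpha) band -> maintain
  Pi_eq <- en$m_bac / (g$q_max * en$Y_XS)
  expect_equal(classify_regime(g, en, Pi_eq), "maintain")
  expect_equal(classify_regime(g, en, Pi_eq * 1.19), "maintain")
  expect_equal(classify_regime(g, en, Pi_eq * 1.21), "grow")
  expect_equal(classify_regime(g, en, Pi_eq * 0.81), "maintain")
  expect_equal(classify_regime(g, en, Pi_eq * 0.79), "decay")
  # exactly one regime per agent (partition property)
  set.seed(4)
  r <- classify_regime(g, en, runif(100))
  expect_true(all(r %in% c("grow", "maintain", "decay")))
})

test_that("mass update integrates the three regimes exactly", {
  expect_equal(update_mass(2e-15, "maintain", mu = 1, k_decay = 1, dt = 5), 2e-15)
  expect_equal(update_mass(1e-15, "grow", mu = log(2), k_decay = 0, dt = 1), 2e-15)
  expect_equal(update_mass(1e-15, "decay", mu = 0, k_decay = 0.01, dt = 10),
               1e-15 * exp(-0.1))
  expect_error(update_mass(1e-15, "grow", mu = 1, k_decay = 0, dt = -1))
})

test_that("division conserves mass, is reproducible and splits 40-60", {
  g <- lib["AOB"]
  m0 <- division_mass(g$AOB) * 1.05
  mk <- function() agents_df("AOB", x = 5, y = 5, z = 5, mass = m0)
  set.seed(99)
  d1 <- divide(mk(), g, Lx = 10, Ly = 10)
  expect_equal(d1$n_divided, 1L)
  expect_equal(sum(d1$agents$mass), m0, tolerance = 1e-15)
  # daughters touch: centre distance equals the sum of radii
  a <- d1$agents
  dist <- sqrt(sum((c(a$x[1], a$y[1], a$z[1]) - c(a$x[2], a$y[2], a$z[2]))^2))
  expect_equal(dist, sum(a$diameter) / 2, tolerance = 1e-9)
  # same seed -> identical outcome; different seed -> different direction
  set.seed(99); d2 <- divide(mk(), g, Lx = 10, Ly = 10)
  expect_identical(d1$agents, d2$agents)
  # split fractions are Uniform(0.4, 0.6) by a KS test on many divisions
  set.seed(7)
  many <- agents_df("AOB", x = runif(2000, 0, 50), y = runif(2000, 0, 50),
                    z = runif(2000, 2, 40), mass = rep(m0, 2000))
  dm <- divide(many, g, Lx = 50, Ly = 50)
  f <- dm$agents$mass[1:2000] / m0
  ks <- suppressWarnings(ks.test(f, "punif", 0.4, 0.6))
  expect_gt(ks$p.value, 0.01)
  # below threshold -> no-op
  small <- agents_df("AOB", 1, 1, 1, mass = 0.5 * division_mass(g$AOB))
  expect_equal(divide(small, g, 10, 10)$n_divided, 0L)
})

test_that("inert transition triggers at 10% of division mass, inclusive", {
  g <- lib["AOB"]
  mdiv <- division_mass(g$AOB)
  a <- agents_df("AOB", x = c(1, 2, 3), y = 1, z = 1,
                 mass = mdiv * c(0.09, 0.100000, 0.5))
  a <- check_inert(a, g)
  expect_equal(a$state, c("inert", "inert", "active"))
  # irreversible: inert agents stay inert and carry mu = 0
  expect_true(all(a$mu[a$state == "inert"] == 0))
})

test_that("decay products close the carbon and nitrogen balance", {
  con <- oracle_constants()
  expect_equal(decay_products(0, lib$AOB, db), c("HCO3-" = 0, "NH3" = 0))
  # 1 C-mol of AOB biomass -> 1 mol bicarbonate + 0.2 mol ammonia
  expect_equal(decay_products(1, lib$AOB, db), c("HCO3-" = 1, "NH3" = 0.2))
  # randomized element-balance property across all groups
  set.seed(3)
  for (g in lib) {
    dm <- runif(1, 1e-16, 1e-13)
    rel <- decay_products(dm, g, db)
    el <- t(as.matrix(con[match(names(rel), con$form),
                          c("n_C", "n_H", "n_N", "n_O")]))
    out <- drop(el %*% rel)
    expect_equal(unname(out["n_C"]), dm, tolerance = 1e-12 * dm)
    expect_equal(unname(out["n_N"]), 0.2 * dm, tolerance = 1e-12 * dm)
  }
})

test_that("agent reaction rates follow the metabolic stoichiometry", {
  g <- lib$AOB
  en <- group_energetics(g, db = db)
  X <- 5e-15
  # inert agents contribute nothing
  expect_length(agent_reaction_rates(g, en, "grow", X, state = "inert"), 0)
  # maintain: catabolic flux only, no biomass-linked N assimilation
  rm_ <- agent_reaction_rates(g, en, "maintain", X, db = db)
  expect_equal(unname(rm_[["NH3"]] / rm_[["O2"]]), 1 / 1.5, tolerance = 1e-12)
  expect_false("HCO3-" %in% names(rm_)[rm_ != 0] &&
                 rm_[["HCO3-"]] < 0)  # no carbon fixation during maintenance
  # grow: O2:NH3 consumption matches the overall-reaction ratio
  mu <- g$q_max * en$Y_XS * 0.9 - en$m_bac
  rg <- agent_reaction_rates(g, en, "grow", X, mu = mu, db = db)
  ov <- overall_reaction(g$ana, g$cat, en$Y_XS, g$donor, db = db)
  o2_per_nh3 <- (ov$stoich[["O2"]] * mu * X + g$cat$stoich[["O2"]] * en$m_bac * X / en$Y_XS) /
    ((ov$stoich[["NH3"]] + 0) * mu * X + g$cat$stoich[["NH3"]] * en$m_bac * X / en$Y_XS)
  expect_equal(unname(rg[["O2"]] / rg[["NH3"]]), unname(o2_per_nh3),
               tolerance = 1e-12)
  # decay: releases the anabolic C and N sources at k_decay * X
  rd <- agent_reaction_rates(g, en, "decay", X, db = db)
  expect_equal(rd, c("HCO3-" = 1, "NH3" = 0.2) * g$k_decay * X)
})

test_that("a biological step conserves C and N between agents and fields", {
  # closed stoichiometric check: rates * dt vs biomass change, tiny step so
  # the exponential and linear updates agree to high order
  g <- lib$AOB
  en <- group_energetics(g, db = db)
  X <- 6e-15
  mu <- g$q_max * en$Y_XS * 0.8 - en$m_bac
  dt <- 2e-8 / mu
  r <- agent_reaction_rates(g, en, "grow", X, mu = mu, db = db)
  r <- r[names(r) != "Biomass"]          # dissolved pools only
  con <- oracle_constants()
  el <- t(as.matrix(con[match(names(r), con$form), c("n_C", "n_N")]))
  dX <- X * (exp(mu * dt) - 1)
  # carbon: biomass gain + net dissolved carbon change = 0
  expect_equal(unname(drop(el %*% r)["n_C"] * dt) + dX, 0,
               tolerance = 1e-8 * dX)
  expect_equal(unname(drop(el %*% r)["n_N"] * dt) + 0.2 * dX, 0,
               tolerance = 1e-8 * dX)
})
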