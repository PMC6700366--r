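# Acid-base speciation and charge-balance pH solving.

db <- default_thermo_db()

test_that("dissociation constants follow exp(-dG/RT)", {
  RT <- 8.314e-3 * 298.15
  mk <- function(dg2) species_def("toy", data.frame(
    form = c("HA", "A-"), charge = c(0, -1), dG_f = c(0, dg2)))
  # dG_rxn = 0 -> K = 1; dG_rxn = -RT ln 10 -> K = 10
  expect_equal(dissociation_constants(mk(0)), 1)
  expect_equal(dissociation_constants(mk(-RT * log(10))), 10)
  # acetate step against a scalar hand computation from the shipped table
  con <- oracle_constants()
  dgs <- con$dG_f_kJ_mol[match(c("CH3COOH", "CH3COO-"), con$form)]
  expect_equal(dissociation_constants("acetate", db = db),
               exp(-(dgs[2] - dgs[1]) / RT))
  # chain validation
  expect_error(species_def("bad", data.frame(form = c("A", "B"),
                                             charge = c(0, -2), dG_f = c(0, 0))),
               "differ by exactly -1")
  expect_error(dissociation_constants("acetate", T = -1, db = db), "> 0")
})

test_that("speciation partitions totals exactly and monotonically", {
  # zero totals -> zero forms
  s0 <- speciate(c(carbonate = 0, ammonia = 0), H = 1e-7, db = db)
  expect_true(all(s0$concentrations == 0))
  # monoprotic species at [H+] = K -> 50/50 split
  K <- dissociation_constants("acetate", db = db)
  s <- speciate(c(acetate = 2e-3), H = K, db = db)
  expect_equal(unname(s$concentrations[["CH3COOH"]]), 1e-3, tolerance = 1e-12)
  expect_equal(unname(s$concentrations[["CH3COO-"]]), 1e-3, tolerance = 1e-12)
  # diprotic-level partition against a Henderson-Hasselbalch hand solution
  Kc <- dissociation_constants("carbonate", db = db)
  H <- 10^(-7.2)
  tot <- 3.3e-3
  s <- speciate(c(carbonate = tot), H = H, db = db)
  w <- c(1, Kc[1] / H, Kc[1] * Kc[2] / H^2)
  expect_equal(unname(s$concentrations[c("CO2", "HCO3-", "CO3-2")]),
               tot * w / sum(w), tolerance = 1e-12, ignore_attr = TRUE)
  # mass conservation over forms, many random systems
  set.seed(11)
  for (i in 1:20) {
    sys <- random_system()
    sp <- speciate(sys$totals, H = 10^runif(1, -11, -3), db = db)
    con <- oracle_constants()
    for (s2 in names(sys$totals)) {
      labs <- con$form[con$species == s2]
      expect_equal(sum(sp$concentrations[labs]), unname(sys$totals[[s2]]),
                   tolerance = 1e-12)
    }
  }
  # raising H never increases a deprotonated-form fraction
  H_grid <- 10^seq(-10, -4, length.out = 25)
  frac <- vapply(H_grid, function(h)
    speciate(c(ammonia = 1e-3), h, db = db)$concentrations[["NH3"]] / 1e-3,
    numeric(1))
  expect_true(all(diff(frac) <= 1e-15))
  expect_error(speciate(c(ammonia = -1e-3), 1e-7, db = db), "negative")
})

test_that("charge balance matches a brute-force summation and is monotone", {
  # pure water at [H+] = 1e-7 is neutral
  expect_equal(charge_balance(c(oxygen = 0), 1e-7, db = db), 0, tolerance = 1e-20)
  # strong-acid analytic: 1e-3 Cl- at [H+] = 1e-3 (OH- negligible at 1e-11)
  r <- charge_balance(c(oxygen = 0), 1e-3, inert_pool(Cl = 1e-3), db = db)
  expect_equal(r, -1e-11, tolerance = 1e-6)
  # nitrification-style bulk mixture vs independent summation at candidate pH
  totals <- mgL_to_molL(c("ammonia", "carbonate", "nitrite", "nitrate"),
                        c(30, 88, 0.5, 0.2), db)
  for (pH in c(5, 6.5, 7.5, 9)) {
    expect_equal(charge_balance(totals, 10^(-pH), inert_pool(1e-4, 2e-4), db = db),
                 oracle_residual(totals, 10^(-pH), 1e-4, 2e-4),
                 tolerance = 1e-15)
  }
  # strictly decreasing in pH
  pHs <- seq(2, 12, by = 0.25)
  rs <- vapply(pHs, function(p) charge_balance(totals, 10^(-p), db = db),
               numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("solve_pH reaches electroneutrality and agrees with bisection", {
  # pure water -> pH 7, strong acid -> pH 3
  expect_equal(solve_pH(c(oxygen = 0), db = db)$pH, 7, tolerance = 1e-6)
  expect_equal(solve_pH(c(oxygen = 0), inert_pool(Cl = 1e-3), db = db)$pH, 3,
               tolerance = 1e-6)
  # initial nitrification bulk vs the uniroot oracle
  totals <- mgL_to_molL(c("ammonia", "carbonate", "nitrite", "nitrate"),
                        c(30, 88, 0, 0), db)
  sol <- solve_pH(totals, db = db)
  expect_lt(abs(sol$residual), 1e-12)
  expect_equal(sol$pH, oracle_pH(totals), tolerance = 1e-6)
  # guess independence
  expect_equal(solve_pH(totals, guess = 3, db = db)$pH,
               solve_pH(totals, guess = 11, db = db)$pH, tolerance = 1e-9)
  # adding strong base never decreases the solved pH
  na <- seq(0, 2e-3, length.out = 9)
  ph <- vapply(na, function(x) solve_pH(totals, inert_pool(Na = x), db = db)$pH,
               numeric(1))
  expect_true(all(diff(ph) > -1e-9))
})

test_that("titration to a setpoint is exact, idempotent and non-negative", {
  totals <- mgL_to_molL(c("ammonia", "carbonate"), c(10, 50), db)
  # acidified bulk titrated upward
  acid <- inert_pool(Cl = 2e-3)
  tt <- titrate_to_setpoint(totals, acid, setpoint = 7.5, db = db)
  expect_gt(tt$Na_added, 0)
  expect_equal(tt$Cl_added, 0)
  expect_equal(solve_pH(totals, tt$inert, db = db)$pH, 7.5, tolerance = 1e-9)
  # already at setpoint -> zero addition (idempotent)
  cur <- solve_pH(totals, tt$inert, db = db)$pH
  tt2 <- titrate_to_setpoint(totals, tt$inert, cur, db = db)
  expect_equal(tt2$Na_added + tt2$Cl_added, 0, tolerance = 1e-12)
})
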