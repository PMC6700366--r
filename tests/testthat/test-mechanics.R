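# Soft-sphere forces and discrete-element relaxation.

p <- mech_params()

mk_agent <- function(pos, radius = 0.5, vel = c(0, 0, 0), mass = 5.76e-16)
  list(pos = pos, radius = radius, vel = vel, mass = mass)

test_that("contact force is zero without overlap, Hookean and antisymmetric", {
  a <- mk_agent(c(0, 0, 5)); b <- mk_agent(c(1.2, 0, 5))
  f0 <- contact_force(a, b, p)
  expect_equal(f0$on_a, c(0, 0, 0))
  # static head-on overlap delta with no damping: |F| = k_n * delta
  pz <- mech_params(gamma_n = 0, gamma_t = 0)
  b2 <- mk_agent(c(0.9, 0, 5))
  f <- contact_force(a, b2, pz)
  expect_equal(f$on_a, -f$on_b)
  expect_equal(sqrt(sum(f$on_a^2)), pz$k_n * 0.1e-6, tolerance = 1e-12)
  expect_equal(sign(f$on_a[1]), -1)      # repulsive, a pushed away from b
})

test_that("tangential force is capped exactly by the Coulomb criterion", {
  # sliding contact: large tangential relative velocity activates the cap
  a <- mk_agent(c(0, 0, 5), vel = c(0, 1e3, 0))
  b <- mk_agent(c(0.9, 0, 5))
  f <- contact_force(a, b, p)
  n <- c(-1, 0, 0)
  Fn <- sum(f$on_a * n) * n
  Ft <- f$on_a - Fn
  expect_equal(sqrt(sum(Ft^2)), p$mu_f * sqrt(sum(Fn^2)), tolerance = 1e-10)
})

test_that("adhesion vanishes at the cutoff, scales with masses, stays antisymmetric", {
  a <- mk_agent(c(0, 0, 5)); b <- mk_agent(c(1.3, 0, 5))   # gap 0.3 > cutoff 0.2
  expect_equal(adhesion_force(a, b, p)$on_a, c(0, 0, 0))
  b2 <- mk_agent(c(1.1, 0, 5))                              # gap 0.1
  f1 <- adhesion_force(a, b2, p)
  expect_equal(f1$on_a, -f1$on_b)
  expect_gt(f1$on_a[1], 0)                                  # attractive
  # doubling both masses quadruples the force (documented scaling law)
  a2 <- mk_agent(c(0, 0, 5), mass = 2 * 5.76e-16)
  b3 <- mk_agent(c(1.1, 0, 5), mass = 2 * 5.76e-16)
  f2 <- adhesion_force(a2, b3, p)
  expect_equal(f2$on_a, 4 * f1$on_a, tolerance = 1e-12)
  # continuity: force -> 0 approaching the cutoff
  gaps <- seq(0.19, 0.1999, length.out = 10)
  mags <- vapply(gaps, function(g)
    sqrt(sum(adhesion_force(a, mk_agent(c(1 + g, 0, 5)), p)$on_a^2)), numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_lt(mags[length(mags)], 1e-3 * p$k_adh)
})

test_that("Stokes drag is linear in radius and relative velocity", {
  still <- mk_agent(c(0, 0, 5))
  expect_equal(drag_force(still, c(0, 0, 0), p), c(0, 0, 0))
  u <- c(1e-6, 0, 0)
  f <- drag_force(still, u, p)
  expect_equal(f, 6 * pi * p$viscosity * 0.5e-6 * u)
  big <- mk_agent(c(0, 0, 5), radius = 1)
  expect_equal(drag_force(big, u, p), 2 * f)
})

test_that("compiled forces agree with the R reference and obey Newton's third law", {
  set.seed(31)
  n <- 40
  ag <- agents_df(rep("AOB", n), x = runif(n, 0, 10), y = runif(n, 0, 10),
                  z = runif(n, 1, 6), mass = runif(n, 3e-15, 1.6e-14))
  ag$vx <- rnorm(n, 0, 1); ag$vy <- rnorm(n, 0, 1); ag$vz <- rnorm(n, 0, 1)
  ff <- mech_forces(ag, p, Lx = -1, Ly = -1)   # no wrapping: compare all pairs
  # momentum: internal pairwise forces cancel
  expect_lt(max(abs(rowSums(ff$contact))), 1e-12)
  expect_lt(max(abs(rowSums(ff$adhesion))), 1e-12)
  # pairwise check against the R reference implementation
  wet <- (pi / 6) * (ag$diameter * 1e-6)^3 * 1100
  Fc <- matrix(0, 3, n); Fa <- matrix(0, 3, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A <- list(pos = c(ag$x[i], ag$y[i], ag$z[i]), radius = ag$diameter[i] / 2,
              vel = c(ag$vx[i], ag$vy[i], ag$vz[i]), mass = wet[i])
    B <- list(pos = c(ag$x[j], ag$y[j], ag$z[j]), radius = ag$diameter[j] / 2,
              vel = c(ag$vx[j], ag$vy[j], ag$vz[j]), mass = wet[j])
    fc <- contact_force(A, B, p); fa <- adhesion_force(A, B, p)
    Fc[, i] <- Fc[, i] + fc$on_a; Fc[, j] <- Fc[, j] + fc$on_b
    Fa[, i] <- Fa[, i] + fa$on_a; Fa[, j] <- Fa[, j] + fa$on_b
  }
  expect_equal(ff$contact, Fc, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ff$adhesion, Fa, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("binned neighbour search equals all-pairs on several hundred agents", {
  set.seed(77)
  n <- 400
  # all agents well inside the box, so periodic wrapping cannot change any
  # pair distance: the unwrapped all-pairs path and the wrapped binned path
  # must agree exactly
  ag <- agents_df(rep("AOB", n), x = runif(n, 8, 32), y = runif(n, 8, 32),
                  z = runif(n, 1, 1.8), mass = runif(n, 3e-15, 1.6e-14))
  binned <- mech_forces(ag, p, Lx = 40, Ly = 40)
  allpairs <- mech_forces(ag, p, Lx = -1, Ly = -1)  # 1x1x1 bins: direct loop
  expect_equal(binned$contact, allpairs$contact, tolerance = 1e-14)
  expect_equal(binned$adhesion, allpairs$adhesion, tolerance = 1e-14)
  expect_lt(max(abs(rowSums(binned$contact))), 1e-12)
  fb2 <- mech_forces(ag, p, Lx = 40, Ly = 40)
  expect_identical(binned$contact, fb2$contact)
})

test_that("relaxation removes a 20% overlap and preserves symmetry", {
  d <- agent_diameter(6e-15)
  a <- agents_df(c("A", "A"), x = c(10, 10 + 0.8 * d), y = c(10, 10),
                 z = c(5, 5), mass = rep(6e-15, 2))
  out <- relax(a, p, Lx = 20, Ly = 20)
  expect_true(out$converged)
  expect_lte(out$max_overlap_frac, 0.01)
  # non-overlapping static agents stay put
  b <- agents_df(c("A", "A"), x = c(5, 8), y = c(5, 5), z = c(5, 5),
                 mass = rep(6e-15, 2))
  out2 <- relax(b, p, Lx = 20, Ly = 20)
  expect_equal(out2$agents$x, b$x, tolerance = 1e-12)
  # symmetric 3-agent line stays symmetric
  tri <- agents_df(rep("A", 3), x = c(10 - 0.9 * d, 10, 10 + 0.9 * d),
                   y = rep(10, 3), z = rep(5, 3), mass = rep(6e-15, 3))
  out3 <- relax(tri, p, Lx = 20, Ly = 20)
  expect_equal(out3$agents$x[2], 10, tolerance = 1e-9)
  expect_equal(out3$agents$x[2] - out3$agents$x[1],
               out3$agents$x[3] - out3$agents$x[2], tolerance = 1e-9)
  # kinetic energy decays over the relaxation tail
  ke <- out$ke_trace
  if (length(ke) > 4) {
    tail_ke <- ke[ceiling(length(ke) / 2):length(ke)]
    expect_true(all(diff(tail_ke) <= 1e-30))
  }
  # substratum is rigid: an agent pushed down stays above z = r
  low <- agents_df(c("A", "A"), x = c(5, 5), y = c(5, 5),
                   z = c(d / 2, d / 2 + 0.7 * d), mass = rep(6e-15, 2))
  out4 <- relax(low, p, 20, 20)
  expect_gte(min(out4$agents$z), d / 2 - 1e-9)
})

test_that("relaxation is deterministic for identical inputs", {
  set.seed(55)
  n <- 120
  ag <- agents_df(rep("A", n), x = runif(n, 0, 15), y = runif(n, 0, 15),
                  z = runif(n, 0.6, 4), mass = runif(n, 3e-15, 1.6e-14))
  r1 <- relax(ag, p, 15, 15)
  r2 <- relax(ag, p, 15, 15)
  expect_identical(r1$agents, r2$agents)
  expect_identical(r1$steps, r2$steps)
})

test_that("shaving removes exactly the agents above the cap", {
  a <- agents_df(rep("A", 3), x = 1:3, y = 1, z = c(100, 260, 250),
                 mass = rep(6e-15, 3))
  s <- shave(a, 250)
  expect_equal(nrow(s$removed), 1L)
  expect_equal(s$removed$z, 260)
  expect_equal(s$removed_mass, 6e-15)
  # idempotent between growth steps
  s2 <- shave(s$agents, 250)
  expect_equal(nrow(s2$removed), 0L)
})
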