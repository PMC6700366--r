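# Diffusion-reaction on the grid: regions, rate assembly, explicit
# stepping, steady-state solving.

db <- default_thermo_db()

test_that("effective diffusivity by region", {
  D <- db$species$oxygen$D_water
  expect_equal(effective_diffusivity("oxygen", "biofilm", db), 0.8 * D)
  expect_equal(effective_diffusivity("oxygen", "boundary_layer", db), D)
  expect_true(is.na(effective_diffusivity("oxygen", "bulk", db)))
})

test_that("region labels track the biofilm front and the 40 um layer", {
  spec <- grid_spec(4, 4, 60, 2)
  g <- grid_state(spec, c(oxygen = 2.8e-4))
  # empty domain: no biofilm, boundary layer on the first 20 planes
  expect_equal(g$front_plane, 0L)
  expect_equal(sum(g$region == 1L), 4 * 4 * 20)
  # a single agent: front at ceil((z + r)/h) planes
  a <- agents_df("AOB", 1, 1, 30, mass = 6e-15)
  g2 <- update_regions(g, a)
  expect_equal(g2$front_plane, as.integer(ceiling((30 + a$diameter / 2) / 2)))
  # shrinking front relabels consistently and restores bulk values
  g3 <- update_regions(g2, NULL)
  expect_equal(g3$front_plane, 0L)
  expect_true(all(g3$conc$oxygen[g3$region == 2L] == 2.8e-4))
  # overflow guard
  a_hi <- agents_df("AOB", 1, 1, 110, mass = 6e-15)
  expect_error(update_regions(g, a_hi), "increase nz")
})

test_that("reaction assembly is additive and conserves the agent totals", {
  spec <- grid_spec(4, 4, 20, 2)
  g <- grid_state(spec, c(oxygen = 2.8e-4), bl_um = 10)
  # no agents -> zero fields
  g0 <- assemble_reactions(g, NULL, NULL)
  expect_true(all(g0$rates$oxygen == 0))
  # one agent consuming 1e-15 mol/h in an 8 um^3 cell
  a <- agents_df("AOB", 3, 3, 3, mass = 6e-15)
  r <- matrix(-1e-15, 1, 1, dimnames = list(NULL, "oxygen"))
  g1 <- assemble_reactions(g, a, r)
  expect_equal(sum(g1$rates$oxygen != 0), 1)
  expect_equal(min(g1$rates$oxygen), -1e-15 / 8e-15)
  # two agents in one cell are additive; grid total equals agent total
  a2 <- agents_df(c("AOB", "AOB"), c(3, 3.5), c(3, 3), c(3, 3), rep(6e-15, 2))
  r2 <- matrix(c(-1e-15, -2e-15), 2, 1, dimnames = list(NULL, "oxygen"))
  g2 <- assemble_reactions(g, a2, r2)
  expect_equal(sum(g2$rates$oxygen) * spec$cell_L, -3e-15, tolerance = 1e-12)
  expect_error(cell_index(spec, -1, 1, 1), "outside")
})

test_that("explicit stepping respects stability and preserves uniform fields", {
  g <- column_grid(30, 2, "oxygen", 2.8e-4)
  expect_error(diffusion_step(g, dt_h = 1), "stability")
  dt <- 0.5 * 4 / (6 * g$D_um2_h[["oxygen"]])
  g1 <- diffusion_step(g, dt)
  expect_equal(g1$conc$oxygen, g$conc$oxygen, tolerance = 1e-15)
})

test_that("discrete conservation in a sealed reaction-free box", {
  # all-biofilm box (no pinned cells): periodic + Neumann faces conserve mass
  spec <- grid_spec(6, 5, 8, 2)
  g <- grid_state(spec, c(oxygen = 1e-4), bl_um = 4)
  g$region <- array(0L, c(6, 5, 8))
  set.seed(21)
  g$conc$oxygen <- array(runif(6 * 5 * 8, 0, 2e-4), c(6, 5, 8))
  tot0 <- sum(g$conc$oxygen)
  out <- biofilmsim:::cpp_diffuse_chunk(g$conc, g$rates, g$region, g$D_um2_h,
                           g$biofilm_factor, spec$h, 10000L, -1)
  expect_equal(sum(out$conc[[1]]) / tot0, 1, tolerance = 1e-12)
  # monotone decay of the residual in reaction-free relaxation
  d1 <- biofilmsim:::cpp_diffuse_chunk(g$conc, g$rates, g$region, g$D_um2_h, 0.8, 2, 100L, -1)
  d2 <- biofilmsim:::cpp_diffuse_chunk(d1$conc, g$rates, g$region, g$D_um2_h, 0.8, 2, 100L, -1)
  expect_lt(d2$delta[1], d1$delta[1])
})

test_that("1-D reduction agrees with an independently coded 1-D solver", {
  nz <- 25; h <- 2
  g <- column_grid(nz, h, "oxygen", 2e-4, biofilm_factor = 1)
  set.seed(5)
  prof <- c(sort(runif(nz - 1, 0, 2e-4)), 2e-4)
  g$conc$oxygen <- array(prof, c(1, 1, nz))
  rates <- c(runif(nz - 1, -2e-3, 2e-3), 0)
  g$rates$oxygen <- array(rates, c(1, 1, nz))
  D <- g$D_um2_h[["oxygen"]]
  dt <- 0.9 * h^2 / (6 * D)
  out <- biofilmsim:::cpp_diffuse_chunk(g$conc, g$rates, g$region, g$D_um2_h, 1, h, 200L, dt)
  oracle <- oracle_diffuse_1d(prof, D, h, dt, 200L, rates)
  oracle <- pmax(oracle, 0)
  expect_lt(max(abs(out$conc[[1]] - oracle)), 1e-9 * max(prof))
})

test_that("steady profiles match the linear, parabolic and cosh closed forms", {
  # linear: constant flux through a passive column (sink confined to the
  # bottom cell) -> uniform concentration steps of S h^2 / D per cell
  nz <- 40; h <- 2
  g <- column_grid(nz, h, "oxygen", 2.5e-4, biofilm_factor = 1)
  D <- g$D_um2_h[["oxygen"]]
  S <- 0.5
  g$rates$oxygen[1, 1, 1] <- -S
  g <- solve_to_steady_state(g, tol = 1e-10)
  prof <- g$conc$oxygen[1, 1, ]
  steps <- diff(prof[1:(nz - 1)])
  expect_lt(max(abs(steps - S * h^2 / D)) / (S * h^2 / D), 1e-3)

  # parabolic: uniform zeroth-order sink, zero-flux bottom, fixed top
  g2 <- column_grid(nz, h, "oxygen", 2.5e-4, biofilm_factor = 1)
  q <- 0.4
  g2$rates$oxygen[1, 1, 1:(nz - 1)] <- -q
  g2 <- solve_to_steady_state(g2, tol = 1e-10)
  zc <- (seq_len(nz) - 0.5) * h           # cell centres
  analytic <- 2.5e-4 - q / (2 * D) * (zc[nz]^2 - zc^2)
  expect_lt(max(abs(g2$conc$oxygen[1, 1, ] - analytic)) / 2.5e-4, 1e-3)

  # cosh: first-order sink r = -k C refreshed from the current field
  # (Thiele modulus phi * L ~ 1.3)
  g3 <- column_grid(nz, h, "oxygen", 2.5e-4, biofilm_factor = 1)
  k <- 2000
  refresh <- function(gr) {
    gr$rates$oxygen <- -k * gr$conc$oxygen
    gr
  }
  g3 <- solve_to_steady_state(g3, refresh, tol = 1e-10)
  phi <- sqrt(k / D)
  analytic3 <- 2.5e-4 * cosh(phi * zc) / cosh(phi * zc[nz])
  expect_lt(max(abs(g3$conc$oxygen[1, 1, ] - analytic3) / analytic3), 1e-3)
})

test_that("an already-steady field converges immediately", {
  g <- column_grid(20, 2, "oxygen", 1e-4)
  g <- solve_to_steady_state(g, tol = 1e-8)
  expect_true(attr(g, "converged"))
  it0 <- attr(g, "iterations")
  expect_lte(it0, 400)
})
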