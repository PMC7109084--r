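test_that("fine-lattice node count follows dim^3", {
  expect_equal(grid_node_count(solver_config()), 2146689)
  expect_equal(grid_node_count(solver_config(fine_dim = 65)), 274625)
  expect_equal(grid_node_count(solver_config(fine_dim = 3)), 27)
})

small_cfg <- function(...) {
  solver_config(fine_dim = 49, fine_spacing = 0.6, coarse_dim = 25, ...)
}

test_that("zero charges give an identically zero potential", {
  s <- point_charge(0)
  g <- solve_lpb(s, small_cfg(ionic_strength = 0, eps_protein = 78.54))
  expect_equal(max(abs(g$values)), 0)
})

test_that("homogeneous-medium solution matches the Coulomb closed form", {
  cfg <- small_cfg(eps_protein = 78.54, ionic_strength = 0)
  g <- solve_lpb(point_charge(1), cfg)
  r <- seq(5, 12, by = 0.5)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  lB <- groovescope:::.bjerrum_vac(cfg$temperature)
  for (i in seq_len(nrow(dirs))) {
    num <- groovescope:::interp_grid(g, outer(r, dirs[i, ]))
    exact <- lB / (78.54 * r)
    expect_lt(max(abs(num - exact) / exact), 0.05)
  }
})

test_that("screened solution matches the Debye-Hueckel closed form", {
  cfg <- small_cfg(eps_protein = 78.54, ionic_strength = 0.150,
                   ion_exclusion = 0)
  g <- solve_lpb(point_charge(1), cfg)
  r <- seq(5, 12, by = 0.5)
  lB <- groovescope:::.bjerrum_vac(cfg$temperature)
  kap <- sqrt(groovescope:::.kbar2(0.150, cfg$temperature) / 78.54)
  num <- groovescope:::interp_grid(g, cbind(r, 0, 0))
  exact <- lB * exp(-kap * r) / (78.54 * r)
  expect_lt(max(abs(num - exact) / exact), 0.05)
})

test_that("the linear operator obeys superposition and sign symmetry", {
  cfg <- solver_config(fine_dim = 33, fine_spacing = 0.8, coarse_dim = 17)
  a <- point_charge(1, at = c(-2, 0, 0))
  b <- point_charge(1, at = c(2, 1, 0))
  both <- dplyr::bind_rows(a, b)
  both$charge <- c(1, -0.5)
  a$charge <- 1; b$charge <- -0.5
  ctr <- c(0, 0.5, 0)
  # solve all three problems on the identical lattice (same atom set, so the
  # dielectric map is shared; only the source differs)
  za <- both; za$charge <- c(1, 0)
  zb <- both; zb$charge <- c(0, -0.5)
  g_ab <- solve_lpb(both, cfg, center = ctr)
  g_a <- solve_lpb(za, cfg, center = ctr)
  g_b <- solve_lpb(zb, cfg, center = ctr)
  scale <- max(abs(g_ab$values))
  expect_lt(max(abs(g_ab$values - g_a$values - g_b$values)) / scale, 1e-3)

  neg <- both; neg$charge <- -both$charge
  g_neg <- solve_lpb(neg, cfg, center = ctr)
  expect_lt(max(abs(g_ab$values + g_neg$values)) / scale, 1e-3)
})

test_that("mesh refinement reduces deviation from the Coulomb oracle", {
  err_at <- function(spacing, dim) {
    cfg <- solver_config(fine_dim = dim, fine_spacing = spacing,
                         coarse_dim = 25, eps_protein = 78.54,
                         ionic_strength = 0)
    g <- solve_lpb(point_charge(1), cfg)
    r <- seq(4, 8, by = 0.5)
    lB <- groovescope:::.bjerrum_vac(310)
    num <- groovescope:::interp_grid(g, cbind(r, 0, 0))
    max(abs(num - lB / (78.54 * r)) / (lB / (78.54 * r)))
  }
  expect_lt(err_at(0.5, 41), err_at(1.0, 21))
})

test_that("solver reports non-convergence instead of returning garbage", {
  cfg <- small_cfg(max_iter = 2, ionic_strength = 0)
  expect_error(solve_lpb(point_charge(1), cfg), "did not converge")
})

test_that("electric field is the negative central-difference gradient", {
  dims <- c(9, 9, 9)
  ax <- seq(0, 4, by = 0.5)
  # constant potential -> zero field
  gc <- groovescope:::new_scalar_grid(c(0, 0, 0), 0.5, array(3, dims))
  fc <- compute_field(gc)
  expect_equal(max(abs(fc$ex)), 0)
  expect_equal(max(abs(fc$ez)), 0)

  # linear ramp V = a*x -> field (-a, 0, 0) exactly at every node
  a <- 2.5
  ramp <- array(rep(a * ax, times = prod(dims[2:3])), dims)
  fr <- compute_field(groovescope:::new_scalar_grid(c(0, 0, 0), 0.5, ramp))
  expect_equal(max(abs(fr$ex + a)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fr$ey)), 0)

  # positive point charge -> field points radially outward
  cfg <- solver_config(fine_dim = 33, fine_spacing = 0.8, coarse_dim = 17,
                       eps_protein = 78.54, ionic_strength = 0)
  g <- solve_lpb(point_charge(1), cfg)
  f <- compute_field(g)
  axv <- groovescope:::grid_axes(g)
  for (p in list(c(25, 17, 17), c(17, 25, 17), c(9, 17, 9))) {
    rvec <- c(axv[[1]][p[1]], axv[[2]][p[2]], axv[[3]][p[3]])
    e <- c(f$ex[p[1], p[2], p[3]], f$ey[p[1], p[2], p[3]],
           f$ez[p[1], p[2], p[3]])
    expect_gt(sum(e * rvec) / sqrt(sum(e^2) * sum(rvec^2)), 0.99)
  }
})

test_that("surface sampling interpolates outward-displaced probe points", {
  dims <- c(11, 11, 11)
  g <- groovescope:::new_scalar_grid(c(-5, -5, -5), 1, array(7, dims))
  set.seed(8)
  s <- atoms_from_xyz(matrix(rnorm(15, sd = 0.5), ncol = 3))
  out <- sample_surface_potential(g, s, probe_offset = 0.3)
  expect_equal(out$surface_potential, rep(7, 5))

  # positive central charge: every surface sample positive; doubling the
  # charge doubles the samples (solver linearity)
  cfg <- solver_config(fine_dim = 33, fine_spacing = 0.8, coarse_dim = 17,
                       ionic_strength = 0)
  ring <- atoms_from_xyz(3 * groovescope:::.fib_sphere(12, 1))
  ring$charge <- 0; ring$radius <- 1.7
  chg <- dplyr::bind_rows(point_charge(1), ring)
  g1 <- solve_lpb(chg, cfg, center = c(0, 0, 0))
  s1 <- sample_surface_potential(g1, ring)
  expect_true(all(s1$surface_potential > 0))

  chg2 <- chg; chg2$charge <- 2 * chg$charge
  g2 <- solve_lpb(chg2, cfg, center = c(0, 0, 0))
  s2 <- sample_surface_potential(g2, ring)
  expect_equal(s2$surface_potential, 2 * s1$surface_potential,
               tolerance = 1e-3)

  # points outside the lattice flag as missing
  far <- atoms_from_xyz(matrix(c(500, 0, 0), ncol = 3))
  expect_true(is.na(sample_surface_potential(g, far)$surface_potential))
})

test_that("OpenDX grids round-trip through write_dx/read_dx", {
  vals <- array(rnorm(27), c(3, 3, 3))
  g <- groovescope:::new_scalar_grid(c(-1, 0, 2), c(0.5, 0.5, 0.5), vals)
  back <- read_dx(write_dx(g))
  expect_equal(back$dims, g$dims)
  expect_equal(back$origin, g$origin)
  expect_equal(back$values, g$values, tolerance = 1e-6)

  # non-cubic dims exercise the z-fastest ordering
  g2 <- groovescope:::new_scalar_grid(c(0, 0, 0), c(1, 1, 1),
                                      array(seq_len(24), c(2, 3, 4)))
  lines <- write_dx(g2)
  expect_true(any(grepl("counts 2 3 4", lines)))
  back2 <- read_dx(lines)
  expect_equal(back2$values, g2$values, tolerance = 1e-6)

  expect_error(read_dx("object 1 class something else"), "malformed DX")
})

test_that("focused fine solution matches the coarse solution at its boundary", {
  cfg <- solver_config(fine_dim = 33, fine_spacing = 0.8, coarse_dim = 25,
                       eps_protein = 78.54, ionic_strength = 0)
  g <- solve_lpb(point_charge(1), cfg)
  coarse <- attr(g, "coarse")
  axv <- groovescope:::grid_axes(g)
  pts <- as.matrix(expand.grid(axv[[1]][c(1, 33)], axv[[2]], axv[[3]][17]))
  fine_b <- groovescope:::interp_grid(g, pts)
  coarse_b <- groovescope:::interp_grid(coarse, pts)
  expect_equal(fine_b, coarse_b, tolerance = 1e-6)
})
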