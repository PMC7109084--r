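test_that("hollow-shell cavity volume matches the analytic sphere", {
  s <- make_cavity_probe(5, 7)
  ps <- detect_pockets(s)
  expect_equal(nrow(ps$pockets), 1)
  expect_lt(abs(sum(ps$pockets$volume) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.15)
  # centroid at the cavity center
  expect_lt(sqrt(sum(c(ps$pockets$x, ps$pockets$y, ps$pockets$z)^2)), 1)
})

test_that("a convex body encloses nothing", {
  one <- atoms_from_xyz(matrix(c(0, 0, 0), ncol = 3))
  expect_equal(nrow(detect_pockets(one)$pockets), 0)
  blob <- atoms_from_xyz(matrix(rnorm(30, sd = 1.0), ncol = 3))
  expect_equal(nrow(detect_pockets(blob)$pockets), 0)
})

test_that("slab-gap pocket voxels match an independent scan oracle", {
  grid2d <- as.matrix(expand.grid(x = seq(0, 12, 2), y = seq(0, 12, 2)))
  slabs <- atoms_from_xyz(rbind(cbind(grid2d, 0), cbind(grid2d, 12.2)))
  cfg <- pocket_config(min_pocket_voxels = 1)
  ps <- detect_pockets(slabs, cfg)
  lattice <- ps$lattice
  protein <- array(groovescope:::.protein_mask(slabs, cfg, lattice),
                   lattice$dims)
  want <- psp_oracle(protein, cfg$scan_threshold)
  got <- array(FALSE, lattice$dims)
  for (v in ps$voxels) got[v] <- TRUE
  expect_identical(got, want)
  expect_gt(sum(ps$pockets$volume), 0)
})

test_that("pocket volume is invariant under rotation within lattice error", {
  s <- make_cavity_probe(5, 7)
  v0 <- sum(detect_pockets(s)$pockets$volume)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sr <- s
  xyz <- coords(s) %*% R
  sr$x <- xyz[, 1]; sr$y <- xyz[, 2]; sr$z <- xyz[, 3]
  v1 <- sum(detect_pockets(sr)$pockets$volume)
  expect_lt(abs(v1 - v0) / v0, 0.10)
})

test_that("stricter scan thresholds select a subset of voxels", {
  s <- make_cavity_probe(4, 6)
  lax <- detect_pockets(s, pocket_config(scan_threshold = 3,
                                         min_pocket_voxels = 1))
  strict <- detect_pockets(s, pocket_config(scan_threshold = 7,
                                            min_pocket_voxels = 1))
  vox_lax <- unlist(lax$voxels)
  vox_strict <- unlist(strict$voxels)
  expect_true(all(vox_strict %in% vox_lax))
})

test_that("the difference-of-Gaussians method finds the calibrated cavity", {
  s <- make_cavity_probe(5, 7)
  ps <- detect_pockets(s, pocket_config(method = "dog"))
  expect_gte(nrow(ps$pockets), 1)
  expect_lt(sqrt(sum(c(ps$pockets$x[1], ps$pockets$y[1], ps$pockets$z[1])^2)),
            2.5)
})

test_that("volume traces are constant for static and decreasing for shrinking cavities", {
  s <- make_cavity_probe(5, 7)
  xyz <- coords(s)
  static <- groovescope:::new_traj(s, list(xyz, xyz, xyz))
  attr(static, "aligned") <- TRUE
  vt <- volume_trace(static)
  expect_equal(length(unique(vt$volume)), 1)
  expect_equal(vt$time_ns, c(0, 0.04, 0.08))

  # radial shrinkage of the shell shrinks the cavity monotonically
  shrink <- groovescope:::new_traj(s, lapply(c(1, 0.9, 0.8, 0.7),
                                             function(f) xyz * f))
  attr(shrink, "aligned") <- TRUE
  vs <- volume_trace(shrink)
  expect_true(all(diff(vs$volume) < 0))

  # frames with no enclosure give zero
  lone <- atoms_from_xyz(matrix(c(0, 0, 0), ncol = 3))
  t0 <- groovescope:::new_traj(lone, list(coords(lone), coords(lone)))
  attr(t0, "aligned") <- TRUE
  expect_true(all(volume_trace(t0)$volume == 0))
})

test_that("unaligned multi-frame trajectories trigger a warning", {
  s <- make_cavity_probe(4, 6)
  tr <- groovescope:::new_traj(s, list(coords(s), coords(s)))
  expect_warning(volume_trace(tr), "aligned")
})

test_that("occupancy is the per-voxel pocket frequency", {
  s <- make_cavity_probe(5, 7)
  xyz <- coords(s)
  same <- groovescope:::new_traj(s, list(xyz, xyz))
  attr(same, "aligned") <- TRUE
  g <- occupancy_grid(same)
  expect_true(all(g$values %in% c(0, 1)))
  # 1-frame occupancy equals the pocket indicator of that frame
  one <- groovescope:::new_traj(s, list(xyz))
  attr(one, "aligned") <- TRUE
  g1 <- occupancy_grid(one)
  ps <- detect_pockets(s, lattice = list(origin = g1$origin,
                                         spacing = g1$spacing,
                                         dims = g1$dims))
  expect_equal(g1$values > 0, ps$labels > 0)

  # pocket present in exactly half the frames -> occupancy 0.5 exactly
  gone <- xyz; gone[, 1] <- gone[, 1] + 500
  alt <- groovescope:::new_traj(s, list(xyz, gone, xyz, gone))
  attr(alt, "aligned") <- TRUE
  ga <- occupancy_grid(alt)
  expect_true(all(ga$values %in% c(0, 0.5)))
  expect_gt(sum(ga$values == 0.5), 0)

  # shells partition the nonzero-occupancy voxels
  sh1 <- occupancy_shell(ga, 0, 0.6)
  sh2 <- occupancy_shell(ga, 0.6, 0.8)
  sh3 <- occupancy_shell(ga, 0.8, 1.0)
  expect_equal(length(sh1$voxels) + length(sh2$voxels) + length(sh3$voxels),
               sum(ga$values > 0))
  expect_true(all(ga$values[occupancy_shell(ga, 0.4, 0.6)$voxels] == 0.5))
  # hi = 1 includes permanently-pocket voxels
  expect_equal(length(occupancy_shell(g1, 0.8, 1)$voxels),
               sum(g1$values == 1))
  # histogram over all occupancy values covers every voxel
  expect_equal(length(occupancy_shell(ga, 0, 1)$voxels) +
                 sum(ga$values == 0), prod(ga$dims))
})

test_that("Savitzky-Golay smoothing is exact on polynomials and damps noise", {
  x <- seq_len(101)
  const <- tibble::tibble(frame = x, time_ns = x * 0.04, value = rep(3, 101))
  expect_equal(savitzky_golay(const, 11, 3)$smoothed, const$value)

  cubic <- 2 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3
  sm <- savitzky_golay(cubic, 11, 3)
  interior <- 6:96
  expect_equal(sm[interior], cubic[interior], tolerance = 1e-8)

  set.seed(31)
  noise <- rnorm(500)
  expect_lt(var(savitzky_golay(noise, 51, 3)), var(noise))

  expect_error(savitzky_golay(noise[1:10], 11, 3), "window")
  expect_error(savitzky_golay(noise, 10, 3), "window")
})
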