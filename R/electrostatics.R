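# physical constants (SI); lB_vac(T) = e^2/(4 pi eps0 kB T) in Angstrom is the
# vacuum Bjerrum length that converts charge/distance to potential in kT/e
.e_charge <- 1.602176634e-19
.eps0 <- 8.8541878128e-12
.kB <- 1.380649e-23
.NA_mol <- 6.02214076e23

.bjerrum_vac <- function(temperature) {
  .e_charge^2 / (4 * pi * .eps0 * .kB * temperature) * 1e10
}

# screening coefficient eps_solvent * kappa^2 in 1/A^2 for a monovalent salt:
# kappa^2 = 8 pi (lB_vac/eps_s) n, with n the per-species number density, so
# eps_s * kappa^2 = 8 pi lB_vac n is independent of the solvent permittivity
.kbar2 <- function(ionic_strength, temperature) {
  n <- ionic_strength * .NA_mol * 1e3 / 1e30  # ions per A^3 per species
  8 * pi * .bjerrum_vac(temperature) * n
}

#' Finite-difference Poisson-Boltzmann solver configuration
#'
#' @param eps_protein Relative permittivity inside the molecule (default 4).
#' @param eps_solvent Relative permittivity of the solvent (default 78.54).
#' @param ionic_strength Monovalent salt concentration, mol/L (default 0.150).
#' @param temperature Absolute temperature in K (default 310); sets the kT/e
#'   scale of the output potential.
#' @param fine_dim Nodes per axis of the focused fine lattice (odd; default
#'   129, i.e. 129^3 = 2,146,689 nodes).
#' @param fine_spacing Fine lattice step in A (default 0.5).
#' @param coarse_dim Nodes per axis of the coarse lattice (default 65).
#' @param coarse_factor Coarse half-extent as a multiple of the molecular
#'   extent (default 1.7).
#' @param ion_exclusion Ion-exclusion (Stern) shell thickness in A added to
#'   atom radii when zeroing the screening term (default 2).
#' @param tol Relative residual convergence target (default 1e-6).
#' @param max_iter Maximum SOR sweeps per level (default 10000).
#' @return A `solver_config` list.
#' @export
solver_config <- function(eps_protein = 4, eps_solvent = 78.54,
                          ionic_strength = 0.150, temperature = 310,
                          fine_dim = 129, fine_spacing = 0.5,
                          coarse_dim = 65, coarse_factor = 1.7,
                          ion_exclusion = 2.0, tol = 1e-6, max_iter = 10000) {
  stopifnot(fine_dim %% 2 == 1, fine_spacing > 0, coarse_dim >= 9,
            eps_protein >= 1, eps_solvent >= 1, tol > 0, coarse_factor >= 1,
            ionic_strength >= 0, temperature > 0)
  structure(list(eps_protein = eps_protein, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, temperature = temperature,
                 fine_dim = as.integer(fine_dim), fine_spacing = fine_spacing,
                 coarse_dim = as.integer(coarse_dim),
                 coarse_factor = coarse_factor, ion_exclusion = ion_exclusion,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "solver_config")
}

#' Node count of the fine lattice
#' @param cfg A [solver_config()].
#' @return `fine_dim^3` as a double (exceeds integer range at default size).
#' @export
grid_node_count <- function(cfg) as.numeric(cfg$fine_dim)^3

new_scalar_grid <- function(origin, spacing, values, units = "kT/e") {
  structure(list(origin = origin, spacing = rep(spacing, length.out = 3),
                 dims = dim(values), values = values, units = units),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("<scalar_grid> %dx%dx%d, spacing %.3g A, units %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$units))
  invisible(x)
}

grid_axes <- function(g) {
  lapply(1:3, function(a) g$origin[a] + (seq_len(g$dims[a]) - 1) * g$spacing[a])
}

# vectorized trilinear interpolation of grid values at points (n x 3)
interp_grid <- function(g, pts) {
  pts <- matrix(pts, ncol = 3)
  tx <- (pts[, 1] - g$origin[1]) / g$spacing[1]
  ty <- (pts[, 2] - g$origin[2]) / g$spacing[2]
  tz <- (pts[, 3] - g$origin[3]) / g$spacing[3]
  out <- rep(NA_real_, nrow(pts))
  ok <- tx >= 0 & ty >= 0 & tz >= 0 &
    tx <= g$dims[1] - 1 & ty <= g$dims[2] - 1 & tz <= g$dims[3] - 1
  if (!any(ok)) return(out)
  i0 <- pmin(floor(tx[ok]), g$dims[1] - 2); fx <- tx[ok] - i0
  j0 <- pmin(floor(ty[ok]), g$dims[2] - 2); fy <- ty[ok] - j0
  k0 <- pmin(floor(tz[ok]), g$dims[3] - 2); fz <- tz[ok] - k0
  v <- g$values
  idx <- function(di, dj, dk) {
    cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)
  }
  out[ok] <-
    v[idx(0, 0, 0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(1, 0, 0)] * fx * (1 - fy) * (1 - fz) +
    v[idx(0, 1, 0)] * (1 - fx) * fy * (1 - fz) +
    v[idx(0, 0, 1)] * (1 - fx) * (1 - fy) * fz +
    v[idx(1, 1, 0)] * fx * fy * (1 - fz) +
    v[idx(1, 0, 1)] * fx * (1 - fy) * fz +
    v[idx(0, 1, 1)] * (1 - fx) * fy * fz +
    v[idx(1, 1, 1)] * fx * fy * fz
  out
}

# Debye-Hueckel monopole boundary potential in kT/e
.dh_potential <- function(r, Q, lB, eps_s, kappa) {
  r <- pmax(r, 1e-6)
  lB * Q * exp(-kappa * r) / (eps_s * r)
}

# assemble and solve one lattice level; boundary holds Dirichlet values
.solve_level <- function(atoms, cfg, origin, spacing, dim3, boundary_u, init_u) {
  dims <- rep(as.integer(dim3), 3)
  npts <- prod(dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing)

  inside <- cpp_mark_spheres(dims, origin, rep(spacing, 3),
                             coords(atoms), atoms$radius)
  eps <- ifelse(inside, cfg$eps_protein, cfg$eps_solvent)

  kb2v <- .kbar2(cfg$ionic_strength, cfg$temperature)
  if (kb2v > 0) {
    excl <- cpp_mark_spheres(dims, origin, rep(spacing, 3),
                             coords(atoms), atoms$radius + cfg$ion_exclusion)
    kb2 <- ifelse(excl, 0, kb2v)
  } else {
    kb2 <- rep(0, npts)
  }

  # spread point charges to the 8 surrounding nodes (trilinear weights)
  lB <- .bjerrum_vac(cfg$temperature)
  f <- numeric(npts)
  ch <- which(abs(atoms$charge) > 0)
  for (a in ch) {
    t3 <- (c(atoms$x[a], atoms$y[a], atoms$z[a]) - origin) / spacing
    i0 <- pmin(pmax(floor(t3), 0), dims - 2)
    fr <- t3 - i0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) fr[1] else 1 - fr[1]) *
           (if (dj) fr[2] else 1 - fr[2]) *
           (if (dk) fr[3] else 1 - fr[3])
      node <- (i0[1] + di) + dims[1] * ((i0[2] + dj) + dims[2] * (i0[3] + dk)) + 1
      f[node] <- f[node] + 4 * pi * lB * atoms$charge[a] * w / spacing^3
    }
  }

  u <- init_u
  # pin the outermost shell to the supplied boundary values
  bshell <- array(FALSE, dims)
  bshell[c(1, dims[1]), , ] <- TRUE
  bshell[, c(1, dims[2]), ] <- TRUE
  bshell[, , c(1, dims[3])] <- TRUE
  u[bshell] <- boundary_u[bshell]

  omega <- 2 / (1 + sin(pi / max(dims)))
  sol <- cpp_sor_lpb(u, eps, kb2, f, dims, spacing, omega, cfg$tol, cfg$max_iter)
  if (!sol$converged) {
    abort(sprintf("PB solver did not converge in %d sweeps (residual %.3g)",
                  cfg$max_iter, sol$residual))
  }
  new_scalar_grid(origin, spacing, array(sol$u, dims))
}

#' Solve the linearized Poisson-Boltzmann equation (focused lattice)
#'
#' Two-level sequential focusing: a coarse lattice spanning
#' `coarse_factor` times the molecular extent is solved with Debye-Hueckel
#' monopole boundary values, then the fine lattice (`fine_dim^3` nodes at
#' `fine_spacing`) is re-solved with boundary values interpolated from the
#' coarse solution. The dielectric map is `eps_protein` inside the van der
#' Waals atom-sphere union and `eps_solvent` outside; the screening term is
#' zeroed inside the molecule plus the ion-exclusion shell. Output potential
#' is in kT/e at the configured temperature.
#'
#' @param assignment Atom tibble with `charge` (e) and `radius` (A) columns,
#'   e.g. from [assign_charges_radii()] or [read_pqr()].
#' @param cfg A [solver_config()].
#' @param center Optional lattice center; default the molecular centroid.
#' @return A `scalar_grid` of the potential on the fine lattice.
#' @export
solve_lpb <- function(assignment, cfg = solver_config(), center = NULL) {
  atoms <- assignment
  if (nrow(atoms) < 1) abort("need at least one atom")
  if (is.null(atoms[["charge"]]) || is.null(atoms[["radius"]])) {
    abort("assignment must carry charge and radius columns")
  }
  xyz <- coords(atoms)
  gc <- center %||% colMeans(xyz)
  Q <- sum(atoms$charge)
  qc <- if (abs(Q) > 1e-12) {
    colSums(xyz * abs(atoms$charge)) / sum(abs(atoms$charge))
  } else gc
  mol_extent <- max(sqrt(rowSums(sweep(xyz, 2, gc)^2)) + atoms$radius)

  half_fine <- (cfg$fine_dim - 1) / 2 * cfg$fine_spacing
  half_coarse <- max(cfg$coarse_factor * mol_extent, 1.1 * half_fine, 5)
  spacing_c <- 2 * half_coarse / (cfg$coarse_dim - 1)
  if (mol_extent > half_coarse + 1e-9) {
    abort("molecule larger than the coarse lattice")
  }

  lB <- .bjerrum_vac(cfg$temperature)
  kb2v <- .kbar2(cfg$ionic_strength, cfg$temperature)
  kappa <- sqrt(kb2v / cfg$eps_solvent)

  dh_grid <- function(origin, spacing, dim3) {
    ax <- lapply(1:3, function(a) origin[a] + (seq_len(dim3) - 1) * spacing)
    r <- sqrt(outer(outer((ax[[1]] - qc[1])^2, (ax[[2]] - qc[2])^2, "+"),
                    (ax[[3]] - qc[3])^2, "+"))
    array(.dh_potential(r, Q, lB, cfg$eps_solvent, kappa), rep(dim3, 3))
  }

  # coarse level: analytic boundary + analytic initial guess
  orig_c <- gc - half_coarse
  u0c <- dh_grid(orig_c, spacing_c, cfg$coarse_dim)
  coarse <- .solve_level(atoms, cfg, orig_c, spacing_c, cfg$coarse_dim,
                         boundary_u = u0c, init_u = u0c)

  # fine level: boundary + initial guess interpolated from the coarse solution
  orig_f <- gc - half_fine
  axf <- lapply(1:3, function(a) orig_f[a] + (seq_len(cfg$fine_dim) - 1) * cfg$fine_spacing)
  ptsf <- as.matrix(expand.grid(x = axf[[1]], y = axf[[2]], z = axf[[3]]))
  u0f <- array(interp_grid(coarse, ptsf), rep(cfg$fine_dim, 3))
  u0f[is.na(u0f)] <- 0
  fine <- .solve_level(atoms, cfg, orig_f, cfg$fine_spacing, cfg$fine_dim,
                       boundary_u = u0f, init_u = u0f)
  attr(fine, "coarse") <- coarse
  attr(fine, "config") <- cfg
  fine
}

#' Electric field as the negative potential gradient
#'
#' E = -grad V by central differences at interior nodes and one-sided
#' differences at lattice boundaries; units (kT/e)/A when V is in kT/e.
#'
#' @param v A `scalar_grid`.
#' @return A `vector_grid` (list of component arrays `ex`, `ey`, `ez` with the
#'   lattice metadata).
#' @export
compute_field <- function(v) {
  stopifnot(all(v$dims >= 3))
  grad_axis <- function(vals, axis, h) {
    d <- dim(vals)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(vals, perm)
    n <- d[axis]
    g <- a
    g[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / (2 * h)
    g[1, , ] <- (a[2, , ] - a[1, , ]) / h
    g[n, , ] <- (a[n, , ] - a[n - 1, , ]) / h
    aperm(g, order(perm))
  }
  structure(list(origin = v$origin, spacing = v$spacing, dims = v$dims,
                 ex = -grad_axis(v$values, 1, v$spacing[1]),
                 ey = -grad_axis(v$values, 2, v$spacing[2]),
                 ez = -grad_axis(v$values, 3, v$spacing[3]),
                 units = paste0(v$units, "/A")),
            class = "vector_grid")
}

#' Sample the potential just outside each atom
#'
#' Each atom center is displaced outward (away from the molecular centroid)
#' by its radius plus `probe_offset`, and the potential is interpolated
#' trilinearly at that point. Points falling outside the lattice yield NA.
#'
#' @param v A `scalar_grid`.
#' @param s Atom tibble (uses `radius` column if present, else element radii).
#' @param probe_offset Outward displacement beyond the atom radius in A
#'   (default 1.4, a water-probe radius).
#' @return `s` with a `surface_potential` column added.
#' @export
sample_surface_potential <- function(v, s, probe_offset = 1.4) {
  xyz <- coords(s)
  radii <- s[["radius"]] %||% element_radius(s$element)
  ctr <- colMeans(xyz)
  dirv <- sweep(xyz, 2, ctr)
  nrm <- sqrt(rowSums(dirv^2))
  dirv[nrm > 1e-9, ] <- dirv[nrm > 1e-9, , drop = FALSE] / nrm[nrm > 1e-9]
  dirv[nrm <= 1e-9, ] <- matrix(rep(c(0, 0, 1), sum(nrm <= 1e-9)),
                                ncol = 3, byrow = TRUE)
  pts <- xyz + dirv * (radii + probe_offset)
  s$surface_potential <- interp_grid(v, pts)
  s
}

#' Write a scalar grid in OpenDX format
#'
#' Emits the `gridpositions`/`gridconnections`/`array` object triplet used by
#' common electrostatics tooling, data in z-fastest order, three values per
#' line in scientific notation.
#'
#' @param g A `scalar_grid`.
#' @param file Optional output path.
#' @return Character vector of DX lines, invisibly.
#' @export
write_dx <- function(g, file = NULL) {
  d <- g$dims
  vals <- as.vector(aperm(g$values, c(3, 2, 1)))  # z fastest
  n <- length(vals)
  pad <- (3 - n %% 3) %% 3
  m <- matrix(c(sprintf("%.6e", vals), rep("", pad)), ncol = 3, byrow = TRUE)
  data_lines <- trimws(apply(m, 1, paste, collapse = " "))
  lines <- c(
    "# OpenDX scalar grid",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", g$spacing[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", g$spacing[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", g$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n),
    data_lines,
    "attribute \"dep\" string \"positions\"",
    "object \"regular positions regular connections\" class field",
    "component \"positions\" value 1",
    "component \"connections\" value 2",
    "component \"data\" value 3"
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read an OpenDX scalar grid
#' @param dx Path or character lines.
#' @param units Units label to attach (default kT/e).
#' @return A `scalar_grid`.
#' @export
read_dx <- function(dx, units = "kT/e") {
  lines <- .pdb_lines(dx)
  lines <- lines[!grepl("^\\s*#", lines)]
  hdr <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(hdr) == 0) abort("malformed DX header: no gridpositions object")
  d <- as.integer(strsplit(trimws(sub(".*counts", "", hdr[1])), "\\s+")[[1]])
  if (length(d) != 3 || anyNA(d)) abort("malformed DX header: bad counts")
  og <- grep("^origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", og[1])), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dl[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- diag(deltas)
  ia <- grep("class array", lines)
  items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", lines[ia[1]]))
  body <- lines[(ia[1] + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|component)", body)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  vals <- vals[!is.na(vals)][seq_len(items)]
  if (length(vals) != prod(d)) abort("DX data length does not match counts")
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  new_scalar_grid(origin, spacing, arr, units = units)
}
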