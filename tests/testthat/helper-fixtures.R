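# shared fixture builders (everything is generated in code; no stored data)

# bare atom table from a coordinate matrix
atoms_from_xyz <- function(xyz, name = "CA", res_name = "GLY", chain = "A",
                           element = "C") {
  n <- nrow(xyz)
  tibble::tibble(
    serial = seq_len(n), name = name, res_name = res_name, chain_id = chain,
    res_seq = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, temp_factor = 0, element = element, het = FALSE
  )
}

# a single point charge ready for the PB solver
point_charge <- function(q = 1, at = c(0, 0, 0), radius = 1.55) {
  s <- atoms_from_xyz(matrix(at, ncol = 3), name = "NZ", res_name = "LYS",
                      element = "N")
  s$charge <- q
  s$radius <- radius
  s
}

# random 3D rotation matrix (seeded by caller)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# minimal fixed-width PDB text: one or more models over the same 10 atoms
make_pdb_text <- function(n_models = 1, n_atoms = 10, jitter = 0) {
  set.seed(42)
  base <- matrix(rnorm(n_atoms * 3, sd = 5), ncol = 3)
  lines <- character(0)
  for (m in seq_len(n_models)) {
    if (n_models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- base + jitter * (m - 1)
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n_atoms), seq_len(n_atoms), xyz[, 1], xyz[, 2], xyz[, 3], 1, 0))
    if (n_models > 1) lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# chain bent by a known hinge angle: an axis of 15 + 15 points with the second
# arm rotated in-plane, emitted as residue pairs offset perpendicular to the
# bend plane so every pair midpoint lies exactly on the axis
bent_helix <- function(angle_deg) {
  th <- angle_deg * pi / 180
  arm1 <- cbind(seq(0, by = 3.8, length.out = 15), 0, 0)
  arm2 <- t(sapply(1:15, function(i) {
    arm1[15, ] + i * 3.8 * c(cos(th), sin(th), 0)
  }))
  ctr <- rbind(arm1, arm2)
  xyz <- do.call(rbind, lapply(seq_len(nrow(ctr)), function(i) {
    rbind(ctr[i, ] + c(0, 0, 1.5), ctr[i, ] - c(0, 0, 1.5))
  }))
  atoms_from_xyz(xyz)
}

# independent PSP-scan oracle built on array shifts (no shared code with the
# compiled scan): candidate = solvent voxel with >= threshold of the 7 scan
# lines blocked by protein on both sides
psp_oracle <- function(protein_arr, threshold = 3) {
  dims <- dim(protein_arr)
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  shift_arr <- function(a, s) {
    out <- array(FALSE, dim(a))
    src <- lapply(1:3, function(ax) {
      i <- seq_len(dims[ax]) - s[ax]
      i
    })
    ok <- lapply(1:3, function(ax) src[[ax]] >= 1 & src[[ax]] <= dims[ax])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  count <- array(0L, dims)
  maxs <- max(dims)
  for (d in dirs) {
    pos <- array(FALSE, dims)
    neg <- array(FALSE, dims)
    for (k in seq_len(maxs)) {
      pos <- pos | shift_arr(protein_arr, -k * d)
      neg <- neg | shift_arr(protein_arr, k * d)
    }
    count <- count + (pos & neg)
  }
  (count >= threshold) & !protein_arr
}
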