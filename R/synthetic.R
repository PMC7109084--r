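# run expr with a fixed RNG stream, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# consensus pKa placements used by every scenario: values far from both pH 7
# and pH 4.5 for residues that never change state, and inside (4.5, 7) for
# the flip set so the state changes between the two pH values
.pka_place <- function(res_name, flip) {
  dplyr::case_when(
    res_name %in% c("ASP", "GLU") & flip ~ 5.5,
    res_name %in% c("ASP", "GLU") & !flip ~ 3.5,
    res_name == "HIS" & flip ~ 6.0,
    res_name == "HIS" & !flip ~ 4.0,
    res_name == "LYS" ~ 10.5,
    res_name == "ARG" ~ 12.5,
    res_name == "TYR" ~ 10.0,
    res_name == "CYS" ~ 9.0
  )
}

.preset_table <- function(name) {
  mk <- function(chain, res_name, n, n_flip = 0) {
    tibble(chain = chain, res_name = rep(res_name, n),
           flip = seq_len(n) <= n_flip)
  }
  res <- switch(name,
    CD1d_a1a2 = bind_rows(
      mk("A", "ASP", 7, 1), mk("A", "GLU", 10, 2), mk("A", "HIS", 4, 4),
      mk("A", "LYS", 9), mk("A", "ARG", 9)),
    GM2AP = bind_rows(
      mk("A", "ASP", 2), mk("A", "GLU", 9, 2), mk("A", "HIS", 3, 3),
      mk("A", "LYS", 2), mk("A", "ARG", 2)),
    SapA_dimer = bind_rows(
      mk("C", "ASP", 6, 2), mk("C", "GLU", 4), mk("C", "LYS", 1),
      mk("C", "ARG", 1),
      mk("D", "ASP", 6, 4), mk("D", "GLU", 4, 2), mk("D", "LYS", 1),
      mk("D", "ARG", 1)),
    PruP3 = bind_rows(
      mk("A", "ASP", 1), mk("A", "LYS", 4), mk("A", "ARG", 4)),
    abort(sprintf("unknown preset '%s'", name))
  )
  res %>%
    group_by(.data$chain) %>%
    mutate(res_seq = row_number()) %>%
    ungroup() %>%
    mutate(pka = .pka_place(.data$res_name, .data$flip))
}

#' Protonation scenario presets
#'
#' Named ionizable-residue compositions whose net side-chain charges at pH 7
#' and pH 4.5 reproduce published worked examples: `CD1d_a1a2` (+1 to +8 via
#' 1 Asp + 2 Glu + 4 His protonating), `GM2AP` (-7 to -2 via 2 Glu + 3 His),
#' `SapA_dimer` (-16 to -8 via 6 acidic residues in chain D and 2 in chain C)
#' and `PruP3` (+7 at both pH values; its single Asp has pKa < 4 and never
#' protonates). The His totals equal the flip sets, since only the flips are
#' published.
#'
#' @param name One of `"CD1d_a1a2"`, `"GM2AP"`, `"SapA_dimer"`, `"PruP3"`.
#' @return A `scenario_preset`: list with `name`, `residues` (tibble with
#'   chain, res_seq, res_name, flip, consensus pka) and `reference_charges`
#'   (named vector, pH 7 and pH 4.5).
#' @export
scenario_preset <- function(name = c("CD1d_a1a2", "GM2AP", "SapA_dimer", "PruP3")) {
  name <- match.arg(name)
  residues <- .preset_table(name)
  ref <- c(CD1d_a1a2 = 1, GM2AP = -7, SapA_dimer = -16, PruP3 = 7)[name]
  ref45 <- c(CD1d_a1a2 = 8, GM2AP = -2, SapA_dimer = -8, PruP3 = 7)[name]
  structure(list(name = name, residues = residues,
                 reference_charges = c(ph7 = unname(ref), ph4.5 = unname(ref45))),
            class = "scenario_preset")
}

.rep_element <- c(CG = "C", CD = "C", NE2 = "N", NZ = "N", CZ = "C",
                  OH = "O", SG = "S")

# one residue = Calpha + (for ionizable types) its representative side-chain
# atom, offset radially so charges are spatially separated
.build_residue_atoms <- function(chain, res_seq, res_name, ca) {
  rows <- tibble(serial = NA_integer_, name = "CA", res_name = res_name,
                 chain_id = chain, res_seq = as.integer(res_seq), icode = "",
                 x = ca[1], y = ca[2], z = ca[3],
                 occupancy = 1, temp_factor = 0, element = "C", het = FALSE)
  rep_at <- .rep_atom[res_name]
  if (!is.na(rep_at)) {
    rows <- bind_rows(rows, rows %>% mutate(
      name = unname(rep_at), element = unname(.rep_element[rep_at]),
      y = .data$y + 1.0, z = .data$z + 1.0))
  }
  rows
}

#' Build the structure and pKa table for a scenario preset
#'
#' Residues are laid out along an extended pseudo-chain (3.8 A Calpha
#' spacing); the pKa table carries three predictor columns (propka, hpp,
#' rosetta) agreeing within 0.1 of the intended consensus value so that the
#' consensus rule resolves every residue.
#'
#' @param preset A `scenario_preset` or its name.
#' @return List with `structure` (atom tibble), `pka_table` (wide tibble) and
#'   `preset`.
#' @export
make_pka_scenario <- function(preset) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  res <- preset$residues
  chains <- unique(res$chain)
  atoms <- purrr::pmap(
    list(res$chain, res$res_seq, res$res_name,
         seq_len(nrow(res)), match(res$chain, chains)),
    function(ch, rs, rn, i, ci) {
      .build_residue_atoms(ch, rs, rn, c((rs - 1) * 3.8, (ci - 1) * 12, 0))
    }) %>% bind_rows()
  atoms$serial <- seq_len(nrow(atoms))
  pka <- res %>%
    select("chain", "res_seq", "res_name") %>%
    mutate(propka = res$pka - 0.05, hpp = res$pka, rosetta = res$pka + 0.05)
  list(structure = atoms, pka_table = pka, preset = preset)
}

#' Net charges of a scenario at both reference pH values
#'
#' Convenience wrapper running the full consensus -> protonation -> net-charge
#' pipeline on a preset at pH 7 and pH 4.5.
#'
#' @param preset A `scenario_preset` or its name.
#' @param agreement_tol,margin Passed to [consensus_pka()] and
#'   [assign_protonation()].
#' @return Named numeric vector `c(ph7 = ..., ph4.5 = ...)`.
#' @export
scenario_net_charges <- function(preset, agreement_tol = 0.5, margin = 0.1) {
  sc <- make_pka_scenario(preset)
  cons <- consensus_pka(sc$pka_table, agreement_tol)
  c(ph7 = net_charge(assign_protonation(cons, 7, margin)),
    ph4.5 = net_charge(assign_protonation(cons, 4.5, margin)))
}

# ideal alpha-helix Calpha trace: rise 1.5 A/residue, 100 deg/residue,
# radius 2.3 A; phase chosen so the mid residue's Calpha lies in the
# vertical plane of the axis (pointing +z)
.helix_ca <- function(n_res, axis_y, axis_z, x0, direction = 1) {
  mid <- ceiling(n_res / 2)
  phase0 <- pi / 2 - (mid - 1) * (100 * pi / 180)
  r <- seq_len(n_res)
  phi <- phase0 + (r - 1) * (100 * pi / 180)
  x <- x0 + direction * (r - 1) * 1.5
  cbind(x = x, y = axis_y + 2.3 * cos(phi), z = axis_z + 2.3 * sin(phi))
}

#' Two-helix portal scaffold above a pseudo-atom sheet
#'
#' Emulates the two antiparallel portal helices over a beta-sheet platform:
#' chain A and chain B are ideal alpha-helices (rise 1.5 A/residue, 100
#' deg/residue) whose axes run parallel at the given separation, above a flat
#' sheet of pseudo-atoms (chain S). The helix phases are chosen so the
#' designated mid-helix aperture Calpha pair is separated by exactly
#' `separation`. Residue identities are alanine unless a composition preset
#' is supplied, in which case its residue types are threaded onto the
#' helices.
#'
#' @param separation Helix-axis separation in A.
#' @param n_res_per_helix Residues per helix (default 21).
#' @param composition Optional `scenario_preset` (or name) supplying residue
#'   identities.
#' @return Atom tibble with attributes `aperture_pair` (list chain_a/res_a/
#'   chain_b/res_b) and `separation`.
#' @export
make_portal_scaffold <- function(separation, n_res_per_helix = 21,
                                 composition = NULL) {
  stopifnot(separation > 0, n_res_per_helix >= 5)
  n <- n_res_per_helix
  # helix axes well above the sheet platform: the only enclosed space is the
  # crevice between the two helix surfaces, which seals at small separations
  # and opens completely at large ones
  zh <- 8
  zs <- -25
  x0 <- -(n - 1) * 1.5 / 2
  ca1 <- .helix_ca(n, 0, zh, x0, 1)
  ca2 <- .helix_ca(n, separation, zh, -x0, -1)

  res_names <- rep("ALA", 2 * n)
  if (!is.null(composition)) {
    if (is.character(composition)) composition <- scenario_preset(composition)
    ids <- composition$residues$res_name
    res_names <- rep(ids, length.out = 2 * n)
  }
  hel <- function(ca, chain, offset) {
    purrr::map(seq_len(nrow(ca)), function(r) {
      .build_residue_atoms(chain, r, res_names[offset + r], ca[r, ])
    }) %>% bind_rows()
  }
  a <- hel(ca1, "A", 0)
  b <- hel(ca2, "B", n)

  # narrow sheet strip centered under the inter-helix midline, deep enough
  # that no scan line links it with the helices into a spurious enclosure
  xs <- seq(x0 - 2, -x0 + 2, by = 2)
  ys <- seq(separation / 2 - 1, separation / 2 + 1, by = 2)
  sheet <- tidyr::expand_grid(x = xs, y = ys) %>%
    mutate(serial = NA_integer_, name = "CA", res_name = "GLY",
           chain_id = "S", res_seq = row_number(), icode = "",
           z = zs, occupancy = 1, temp_factor = 0, element = "C", het = FALSE)
  s <- bind_rows(a, b, sheet[names(a)])
  s$serial <- seq_len(nrow(s))
  mid <- ceiling(n / 2)
  attr(s, "aperture_pair") <- list(chain_a = "A", res_a = mid,
                                   chain_b = "B", res_b = mid)
  attr(s, "separation") <- separation
  s
}

#' Breathing trajectory with a prescribed aperture time course
#'
#' Rigidly displaces one helix (chain B) of a portal scaffold along the
#' aperture direction so the designated Calpha pair follows
#' `d(t) = d_inf + (d0 - d_inf) exp(-t/tau) + N(0, noise_sd)` (exponential
#' relaxation; `model = "ou"` instead gives a stationary Ornstein-Uhlenbeck
#' trace around `d_inf`). Deterministic for a fixed seed.
#'
#' @param scaffold Atom tibble from [make_portal_scaffold()].
#' @param d0 Initial aperture (A).
#' @param d_inf Asymptotic aperture (A).
#' @param tau Relaxation time in frames.
#' @param noise_sd Gaussian noise SD (A).
#' @param n_frames Number of frames (>= 2).
#' @param seed RNG seed for the noise stream.
#' @param model `"relax"` (default) or `"ou"`.
#' @param frame_interval ns per frame (default 0.04).
#' @return A `groove_traj` with attributes `ground_truth` (tibble frame,
#'   distance) and `aperture_pair`.
#' @export
make_breathing_trajectory <- function(scaffold, d0, d_inf, tau, noise_sd,
                                      n_frames, seed = 1,
                                      model = c("relax", "ou"),
                                      frame_interval = 0.04) {
  model <- match.arg(model)
  stopifnot(n_frames >= 2, tau > 0)
  pair <- attr(scaffold, "aperture_pair")
  if (is.null(pair)) abort("scaffold lacks an aperture_pair attribute")
  ia <- .ca_index(scaffold, pair$chain_a, pair$res_a)
  ib <- .ca_index(scaffold, pair$chain_b, pair$res_b)
  xyz <- coords(scaffold)
  u <- xyz[ib, ] - xyz[ia, ]
  d_base <- sqrt(sum(u^2))
  u <- u / d_base

  tvec <- seq_len(n_frames) - 1
  d <- .with_seed(seed, {
    if (model == "relax") {
      d_inf + (d0 - d_inf) * exp(-tvec / tau) + rnorm(n_frames, 0, noise_sd)
    } else {
      out <- numeric(n_frames)
      out[1] <- d0
      for (i in 2:n_frames) {
        out[i] <- out[i - 1] + (d_inf - out[i - 1]) / tau +
          noise_sd * sqrt(2 / tau) * rnorm(1)
      }
      out
    }
  })
  mobile <- which(scaffold$chain_id == pair$chain_b)
  frames <- lapply(d, function(di) {
    f <- xyz
    f[mobile, ] <- f[mobile, , drop = FALSE] +
      matrix(u * (di - d_base), nrow = length(mobile), ncol = 3, byrow = TRUE)
    f
  })
  out <- new_traj(scaffold, frames, frame_interval)
  attr(out, "ground_truth") <- tibble(frame = seq_len(n_frames), distance = d)
  attr(out, "aperture_pair") <- pair
  out
}

# quasi-uniform points on a sphere (Fibonacci lattice)
.fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(x = cos(theta) * sin(phi), y = sin(theta) * sin(phi),
                 z = cos(phi))
}

#' Hollow cavity probe of analytically known volume
#'
#' Pseudo-atoms arranged in concentric spherical layers around an empty
#' interior of radius `r_cavity`. Because a lattice voxel counts as protein
#' when within `atom radius + probe radius` of an atom center, the innermost
#' layer sits at `r_cavity + r_atom + probe`, leaving a cavity of exactly the
#' requested radius whose volume is (4/3) pi r_cavity^3. The construction is
#' verified to be sealed (the cavity is a separate connected component from
#' the exterior); an unsealed shell is an error.
#'
#' @param r_cavity Interior cavity radius (A).
#' @param r_shell Outer extent controlling wall thickness; must exceed
#'   `r_cavity`.
#' @param atom_spacing Target spacing between pseudo-atoms (A, <= 2).
#' @param probe_radius Probe radius used in the seal check (default 1.4).
#' @return Atom tibble with attribute `r_cavity`.
#' @export
make_cavity_probe <- function(r_cavity, r_shell, atom_spacing = 1.5,
                              probe_radius = 1.4) {
  stopifnot(r_shell > r_cavity, r_cavity > 0, atom_spacing <= 2)
  r_atom <- 1.70
  inner <- r_cavity + r_atom + probe_radius
  thickness <- max(r_shell - r_cavity, 2 * atom_spacing)
  layer_r <- seq(inner, inner + thickness, by = atom_spacing)
  pts <- do.call(rbind, lapply(layer_r, function(R) {
    .fib_sphere(max(12, ceiling(4 * pi * R^2 / atom_spacing^2)), R)
  }))
  s <- tibble(serial = seq_len(nrow(pts)), name = "CA", res_name = "GLY",
              chain_id = "X", res_seq = seq_len(nrow(pts)), icode = "",
              x = pts[, 1], y = pts[, 2], z = pts[, 3],
              occupancy = 1, temp_factor = 0, element = "C", het = FALSE)
  # seal check: the cavity must not connect to the lattice exterior
  cfg <- pocket_config(probe_radius = probe_radius)
  lat <- .pocket_lattice(s, cfg)
  protein <- .protein_mask(s, cfg, lat)
  lab <- array(cpp_label_components(!protein, lat$dims, 26L), lat$dims)
  ctr <- pmax(1, round((c(0, 0, 0) - lat$origin) / lat$spacing) + 1)
  cavity_lab <- lab[ctr[1], ctr[2], ctr[3]]
  edge_labs <- unique(c(lab[c(1, lat$dims[1]), , ], lab[, c(1, lat$dims[2]), ],
                        lab[, , c(1, lat$dims[3])]))
  if (cavity_lab == 0 || cavity_lab %in% edge_labs) {
    abort("unsealed shell: cavity leaks to the exterior")
  }
  attr(s, "r_cavity") <- r_cavity
  s
}
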