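#' Read a structure or multi-model trajectory from PDB text
#'
#' Parses PDB-format text (or a file) into a trajectory object: an atom table
#' (the topology, one row per atom with author residue numbering preserved)
#' plus one coordinate matrix per MODEL block. Files without MODEL records
#' yield a single frame. HETATM records are retained and flagged in the `het`
#' column. Alternate locations are collapsed to a single conformer: the
#' highest-occupancy altloc wins, ties prefer altloc "A".
#'
#' @param pdb Path to a PDB file, or PDB text (a single string or a character
#'   vector of lines).
#' @param frame_interval Time between frames in ns (default 0.04, i.e. 2500
#'   frames per 100 ns).
#' @return A `groove_traj` object: list with `topology` (tibble of atoms,
#'   coordinates of frame 1), `frames` (list of n_atoms x 3 matrices) and
#'   `frame_interval`.
#' @export
read_structure <- function(pdb, frame_interval = 0.04) {
  stopifnot(frame_interval > 0)
  lines <- .pdb_lines(pdb)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_lines) == 0L) {
    abort("empty input: no ATOM/HETATM records found")
  }
  # validate the fixed-width numeric fields before handing off to the parser
  for (ln in atom_lines) {
    l <- lines[[ln]]
    if (nchar(l) < 54) {
      abort(sprintf("malformed ATOM/HETATM record at line %d: shorter than 54 columns", ln))
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))))
    if (anyNA(coords)) {
      abort(sprintf("malformed ATOM/HETATM record at line %d: non-numeric coordinate field", ln))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, multi = TRUE, rm.alt = FALSE, verbose = FALSE)

  at <- p$atom
  n_all <- nrow(at)
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) {
    elem[bad] <- sub("^[0-9]*", "", gsub("[0-9']", "", at$elety[bad]))
    elem[bad] <- substr(elem[bad], 1, 1)
  }
  topo <- tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    alt = ifelse(is.na(at$alt), "", at$alt),
    res_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    res_seq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    temp_factor = ifelse(is.na(at$b), 0, at$b),
    element = trimws(elem),
    het = at$type == "HETATM"
  )
  # altloc resolution: highest occupancy, tie -> 'A', then file order
  keep <- topo %>%
    mutate(.row = row_number()) %>%
    group_by(.data$chain_id, .data$res_seq, .data$icode, .data$name, .data$het) %>%
    arrange(dplyr::desc(.data$occupancy), .data$alt != "A", .data$.row, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    arrange(.data$.row)
  idx <- keep$.row
  topo <- topo[idx, , drop = FALSE]
  topo$alt <- NULL

  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    mat <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    dimnames(mat) <- list(NULL, c("x", "y", "z"))
    mat
  })
  topo$x <- frames[[1]][, 1]
  topo$y <- frames[[1]][, 2]
  topo$z <- frames[[1]][, 3]
  new_traj(topo, frames, frame_interval)
}

.pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

new_traj <- function(topology, frames, frame_interval = 0.04) {
  stopifnot(length(frames) >= 1)
  n <- nrow(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3,
               logical(1))
  if (!all(ok)) abort("every frame must be an n_atoms x 3 coordinate matrix")
  structure(list(topology = as_tibble(topology), frames = frames,
                 frame_interval = frame_interval),
            class = "groove_traj")
}

#' @export
print.groove_traj <- function(x, ...) {
  cat(sprintf("<groove_traj> %d atoms, %d frame(s), %.3g ns/frame\n",
              nrow(x$topology), length(x$frames), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t A `groove_traj`.
#' @return Integer frame count.
#' @export
n_frames <- function(t) length(t$frames)

#' Extract one frame of a trajectory as an atom table
#'
#' @param t A `groove_traj`.
#' @param frame Frame index (1-based).
#' @return A tibble of atoms with `x`, `y`, `z` set to that frame's coordinates.
#' @export
structure_frame <- function(t, frame = 1L) {
  stopifnot(inherits(t, "groove_traj"), frame >= 1, frame <= length(t$frames))
  s <- t$topology
  s$x <- t$frames[[frame]][, 1]
  s$y <- t$frames[[frame]][, 2]
  s$z <- t$frames[[frame]][, 3]
  s
}

#' Coerce an atom table to a single-frame trajectory
#' @param s Atom tibble with x/y/z columns.
#' @param frame_interval Time per frame (ns).
#' @return A `groove_traj` with one frame.
#' @export
as_trajectory <- function(s, frame_interval = 0.04) {
  if (inherits(s, "groove_traj")) return(s)
  new_traj(s, list(coords(s)), frame_interval)
}

#' Atom coordinates as a matrix
#' @param s Atom tibble.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(s) {
  m <- cbind(x = s$x, y = s$y, z = s$z)
  storage.mode(m) <- "double"
  m
}

#' Select a chain/residue-range domain
#'
#' Restricts a structure (atom tibble) or a trajectory to the atoms of one
#' chain within an inclusive author-numbering residue range, preserving atom
#' order. Used e.g. to cut the alpha1+alpha2 lipid-binding superdomain
#' (residues 6-186 of CD1d) out of a full-length entry.
#'
#' @param x Atom tibble or `groove_traj`.
#' @param chain Chain identifier (single character).
#' @param res_range Length-2 integer vector `c(lo, hi)`, inclusive. Default
#'   keeps the whole chain.
#' @return Object of the same type, restricted to the selection.
#' @export
select_domain <- function(x, chain, res_range = NULL) {
  if (inherits(x, "groove_traj")) {
    idx <- .domain_idx(x$topology, chain, res_range)
    return(new_traj(x$topology[idx, , drop = FALSE],
                    lapply(x$frames, function(f) f[idx, , drop = FALSE]),
                    x$frame_interval))
  }
  x[.domain_idx(x, chain, res_range), , drop = FALSE]
}

.domain_idx <- function(topo, chain, res_range) {
  if (!chain %in% topo$chain_id) {
    abort(sprintf("chain '%s' not present in structure", chain))
  }
  sel <- topo$chain_id == chain
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2)
    sel <- sel & topo$res_seq >= res_range[1] & topo$res_seq <= res_range[2]
  }
  if (!any(sel)) {
    abort(sprintf("empty selection: chain '%s', residues %s-%s", chain,
                  res_range[1], res_range[2]))
  }
  which(sel)
}

# closed-form least-squares rigid superposition (proper rotation enforced):
# returns the transform mapping mobile onto fixed
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  H <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, center_mobile = cm, center_fixed = cf)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$center_mobile) %*% t(tr$R), 2, tr$center_fixed, "+")
}

.rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose all trajectory frames onto frame 1
#'
#' Least-squares rigid-body (Kabsch, proper rotation) superposition of every
#' frame onto the first over a selected atom subset, so that downstream
#' per-voxel occupancy and grid comparisons live in a common frame.
#'
#' @param t A `groove_traj`.
#' @param selection Integer atom indices to fit on; default all Calpha atoms
#'   (or all atoms if no CA present).
#' @return Aligned `groove_traj` with an `"aligned"` attribute set.
#' @export
align_frames <- function(t, selection = NULL) {
  stopifnot(inherits(t, "groove_traj"))
  if (is.null(selection)) {
    selection <- which(t$topology$name == "CA" & !t$topology$het)
    if (length(selection) == 0L) selection <- seq_len(nrow(t$topology))
  }
  if (length(selection) < 3) abort("alignment selection needs >= 3 atoms")
  ref <- t$frames[[1]][selection, , drop = FALSE]
  sv <- svd(sweep(ref, 2, colMeans(ref)))
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12)) {
    abort("alignment selection is collinear/degenerate")
  }
  frames <- lapply(t$frames, function(f) {
    tr <- kabsch(f[selection, , drop = FALSE], ref)
    apply_transform(f, tr)
  })
  out <- new_traj(t$topology, frames, t$frame_interval)
  out$topology$x <- frames[[1]][, 1]
  out$topology$y <- frames[[1]][, 2]
  out$topology$z <- frames[[1]][, 3]
  attr(out, "aligned") <- TRUE
  out
}

#' Write a structure or trajectory as PDB text
#'
#' Multi-frame trajectories are written as MODEL/ENDMDL blocks (the only
#' trajectory serialization used by this package).
#'
#' @param x Atom tibble or `groove_traj`.
#' @param file Optional path; when `NULL` the PDB text is returned invisibly
#'   as a character vector of lines.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_structure <- function(x, file = NULL) {
  t <- as_trajectory(x)
  topo <- t$topology
  xyz <- do.call(rbind, lapply(t$frames, function(f) as.vector(t(f))))
  tf <- file %||% tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tf, xyz = xyz,
                   type = ifelse(topo$het, "HETATM", "ATOM"),
                   resno = topo$res_seq, resid = topo$res_name,
                   eleno = topo$serial, elety = topo$name,
                   chain = topo$chain_id,
                   insert = ifelse(nzchar(topo$icode), topo$icode, NA),
                   o = topo$occupancy, b = topo$temp_factor,
                   elesy = topo$element)
  out <- readLines(tf, warn = FALSE)
  if (is.null(file)) unlink(tf)
  invisible(out)
}

#' Write a PQR file (whitespace-delimited PDB dialect)
#'
#' PQR replaces the occupancy and B-factor columns of PDB with per-atom charge
#' (e) and radius (A). This is the hand-off format between the protonation
#' bookkeeping and the Poisson-Boltzmann solver.
#'
#' @param s Atom tibble. If it already carries `charge` and `radius` columns
#'   (e.g. from [assign_charges_radii()]), those are used.
#' @param charges,radii Optional explicit per-atom vectors overriding columns.
#' @param file Optional output path.
#' @return Character vector of PQR lines, invisibly.
#' @export
write_pqr <- function(s, charges = NULL, radii = NULL, file = NULL) {
  charges <- charges %||% s[["charge"]]
  radii <- radii %||% s[["radius"]] %||% element_radius(s$element)
  if (is.null(charges) || length(charges) != nrow(s) || anyNA(charges)) {
    i <- if (is.null(charges)) 1L else which(is.na(charges))[1] %||% 1L
    abort(sprintf("missing charge assignment (atom %d: %s %s%d %s)",
                  i, s$res_name[i], s$chain_id[i], s$res_seq[i], s$name[i]))
  }
  if (length(radii) != nrow(s) || anyNA(radii) || any(radii <= 0)) {
    abort("radii must cover every atom and be > 0")
  }
  lines <- sprintf("%-6s %4d %-4s %-4s %s %4d %11.4f %11.4f %11.4f %12.8f %7.4f",
                   ifelse(s$het, "HETATM", "ATOM"), s$serial, s$name,
                   s$res_name, s$chain_id, s$res_seq,
                   s$x, s$y, s$z, charges, radii)
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a PQR file written by [write_pqr()]
#' @param pqr Path or character lines.
#' @return Atom tibble with `charge` and `radius` columns.
#' @export
read_pqr <- function(pqr) {
  lines <- .pdb_lines(pqr)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(lines) == 0L) abort("no atom records in PQR input")
  f <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(f, length, integer(1)) != 11)
  if (length(bad)) abort(sprintf("malformed PQR record at line %d", bad[1]))
  m <- do.call(rbind, f)
  tibble(
    serial = as.integer(m[, 2]), name = m[, 3], res_name = m[, 4],
    chain_id = m[, 5], res_seq = as.integer(m[, 6]), icode = "",
    x = as.numeric(m[, 7]), y = as.numeric(m[, 8]), z = as.numeric(m[, 9]),
    occupancy = 1, temp_factor = 0,
    element = substr(gsub("[0-9]", "", m[, 3]), 1, 1),
    het = m[, 1] == "HETATM",
    charge = as.numeric(m[, 10]), radius = as.numeric(m[, 11])
  )
}
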