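#' Default portal-aperture residue pairs per CD1 isotype
#'
#' The aperture of the groove portal is the Calpha-Calpha distance between one
#' residue on helix alpha1 and one on helix alpha2 flanking the entrance.
#' Bundled defaults: CD1a S77-N151, CD1b F77-Y151, CD1c L77-Y152 (and the
#' alternative D80-Y155 used for the cholesteryl-ester complex), CD1d
#' F77-D151, CD1e F73-Y144.
#'
#' @return Tibble with isotype, residue numbers and expected residue names.
#' @export
aperture_pairs <- function() {
  tibble(
    isotype = c("CD1a", "CD1b", "CD1c_1", "CD1c_2", "CD1d", "CD1e"),
    res_a = c(77L, 77L, 77L, 80L, 77L, 73L),
    name_a = c("SER", "PHE", "LEU", "ASP", "PHE", "PHE"),
    res_b = c(151L, 151L, 152L, 155L, 151L, 144L),
    name_b = c("ASN", "TYR", "TYR", "TYR", "ASP", "TYR")
  )
}

.ca_index <- function(topo, chain, res, expected = NULL) {
  i <- which(topo$chain_id == chain & topo$res_seq == res &
               topo$name == "CA" & !topo$het)
  if (length(i) == 0) {
    abort(sprintf("no Calpha atom for residue %s:%d", chain, res))
  }
  i <- i[1]
  if (!is.null(expected) && topo$res_name[i] != expected) {
    warn(sprintf("residue %s:%d is %s, expected %s",
                 chain, res, topo$res_name[i], expected))
  }
  i
}

#' Portal aperture distance along a trajectory
#'
#' Per-frame Euclidean Calpha-Calpha distance between the two flanking
#' residues; the mean and sample standard deviation are attached as a
#' `summary` attribute.
#'
#' @param t A `groove_traj`.
#' @param pair List/row with `chain_a`, `res_a`, `chain_b`, `res_b` and
#'   optionally `name_a`/`name_b` expected residue names.
#' @return Tibble with `frame`, `time_ns`, `distance` (A).
#' @export
aperture_trace <- function(t, pair) {
  topo <- t$topology
  ia <- .ca_index(topo, pair$chain_a, pair$res_a, pair$name_a %||% NULL)
  ib <- .ca_index(topo, pair$chain_b, pair$res_b, pair$name_b %||% NULL)
  d <- vapply(t$frames, function(f) sqrt(sum((f[ia, ] - f[ib, ])^2)),
              numeric(1))
  out <- tibble(frame = seq_along(d),
                time_ns = (seq_along(d) - 1) * t$frame_interval,
                distance = d)
  attr(out, "summary") <- c(mean = mean(d),
                            sd = if (length(d) > 1) sd(d) else 0)
  out
}

#' Helix bending angle along a trajectory
#'
#' Three Calpha pairs define three midpoints m1, m2, m3 ordered along the
#' helix; the bending is reported as the deviation from linearity,
#' 180 degrees minus the angle at m2 between (m1 - m2) and (m3 - m2).
#'
#' @param t A `groove_traj`.
#' @param anchors List of three pairs, each `list(a = c(chain, res), b =
#'   c(chain, res))` (residues as integers).
#' @return Tibble with `frame`, `time_ns`, `deviation` (degrees).
#' @export
bend_angle_trace <- function(t, anchors) {
  stopifnot(length(anchors) == 3)
  topo <- t$topology
  idx <- lapply(anchors, function(p) {
    c(.ca_index(topo, p$a[[1]], as.integer(p$a[[2]])),
      .ca_index(topo, p$b[[1]], as.integer(p$b[[2]])))
  })
  dev <- vapply(t$frames, function(f) {
    m <- vapply(idx, function(ii) (f[ii[1], ] + f[ii[2], ]) / 2, numeric(3))
    v1 <- m[, 1] - m[, 2]
    v3 <- m[, 3] - m[, 2]
    n1 <- sqrt(sum(v1^2))
    n3 <- sqrt(sum(v3^2))
    if (n1 < 1e-9 || n3 < 1e-9) abort("coincident midpoints: angle undefined")
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v3) / (n1 * n3)))) * 180 / pi
    180 - ang
  }, numeric(1))
  tibble(frame = seq_along(dev),
         time_ns = (seq_along(dev) - 1) * t$frame_interval,
         deviation = dev)
}

#' Default bend anchors: split a helix residue range into thirds
#'
#' The three anchor pairs are the first/last residues of each third of the
#' range - a documented convention, fully overridable.
#'
#' @param chain Chain id.
#' @param res_range Length-2 inclusive residue range of the helix.
#' @return Anchor list for [bend_angle_trace()].
#' @export
bend_anchors_thirds <- function(chain, res_range) {
  r <- seq(res_range[1], res_range[2])
  cuts <- split(r, cut(seq_along(r), 3, labels = FALSE))
  lapply(cuts, function(rr) {
    list(a = list(chain, min(rr)), b = list(chain, max(rr)))
  })
}

#' RMSD trace against a reference structure
#'
#' Per-frame least-squares superposed RMSD (proper rotation) over an atom
#' selection.
#'
#' @param t A `groove_traj`.
#' @param reference Atom tibble (must contain the selection atoms).
#' @param selection Integer atom indices into the trajectory topology;
#'   default all Calpha atoms. Matching into the reference is by
#'   (chain, res_seq, atom name).
#' @return Tibble with `frame`, `time_ns`, `rmsd` (A).
#' @export
rmsd_trace <- function(t, reference, selection = NULL) {
  topo <- t$topology
  if (is.null(selection)) {
    selection <- which(topo$name == "CA" & !topo$het)
    if (length(selection) == 0) selection <- seq_len(nrow(topo))
  }
  key <- function(d) paste(d$chain_id, d$res_seq, d$name, sep = ":")
  mref <- match(key(topo[selection, ]), key(reference))
  if (anyNA(mref)) {
    abort("selection atoms missing from reference (atom mismatch)")
  }
  refxyz <- coords(reference)[mref, , drop = FALSE]
  r <- vapply(t$frames, function(f) {
    mob <- f[selection, , drop = FALSE]
    tr <- kabsch(mob, refxyz)
    .rmsd_xyz(apply_transform(mob, tr), refxyz)
  }, numeric(1))
  tibble(frame = seq_along(r),
         time_ns = (seq_along(r) - 1) * t$frame_interval,
         rmsd = r)
}

#' Pairwise superposed RMSD matrix
#'
#' @param structures List of atom tibbles sharing a common selection.
#' @param selection Optional integer indices applied to each structure
#'   (default: all Calpha atoms of each, which must agree in count).
#' @return Symmetric matrix of superposed RMSDs (A).
#' @export
rmsd_matrix <- function(structures, selection = NULL) {
  get_xyz <- function(s) {
    idx <- selection %||% {
      i <- which(s$name == "CA" & !s$het)
      if (length(i) == 0) seq_len(nrow(s)) else i
    }
    coords(s)[idx, , drop = FALSE]
  }
  xyz <- lapply(structures, get_xyz)
  n_at <- unique(vapply(xyz, nrow, integer(1)))
  if (length(n_at) != 1) abort("incompatible selections across structures")
  n <- length(xyz)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tr <- kabsch(xyz[[j]], xyz[[i]])
      M[i, j] <- M[j, i] <- .rmsd_xyz(apply_transform(xyz[[j]], tr), xyz[[i]])
    }
  }
  M
}

#' 2D correspondence projection of structures by RMSD
#'
#' Classical metric multidimensional scaling (double-centered squared-distance
#' matrix, top two eigenvectors) of the pairwise superposed-RMSD matrix:
#' similar structures land near each other.
#'
#' @param structures List of >= 3 atom tibbles.
#' @param selection Optional shared atom selection (see [rmsd_matrix()]).
#' @return Tibble with `structure`, `dim1`, `dim2`; eigenvalues in the
#'   `"eig"` attribute.
#' @export
rmsd_mds <- function(structures, selection = NULL) {
  if (length(structures) < 3) abort("need >= 3 structures")
  M <- rmsd_matrix(structures, selection)
  mds <- cmdscale(M, k = 2, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < 2) pts <- cbind(pts, 0)[, 1:2, drop = FALSE]
  nm <- names(structures) %||% paste0("structure_", seq_along(structures))
  out <- tibble(structure = nm, dim1 = pts[, 1], dim2 = pts[, 2])
  attr(out, "eig") <- mds$eig
  out
}
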