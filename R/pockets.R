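#' Pocket-detection configuration
#'
#' @param spacing Lattice spacing in A (default 0.8).
#' @param probe_radius Solvent probe radius in A added to atom radii when
#'   building the protein mask (default 1.4).
#' @param scan_threshold Number of the 7 scan directions (3 axes + 4 body
#'   diagonals) that must hit protein on both sides for a solvent voxel to be
#'   a pocket candidate (default 3).
#' @param min_pocket_voxels Smallest cluster kept, in voxels (default 30).
#' @param method `"psp_scan"` (protein-solvent-protein directional scan,
#'   default) or `"dog"` (difference-of-Gaussians response on the smoothed
#'   protein-density lattice).
#' @param dog_sigma Narrow Gaussian width for `method = "dog"`, in A; the wide
#'   width is 1.5x this (default: the probe radius).
#' @return A `pocket_config` list.
#' @export
pocket_config <- function(spacing = 0.8, probe_radius = 1.4,
                          scan_threshold = 3, min_pocket_voxels = 30,
                          method = c("psp_scan", "dog"),
                          dog_sigma = probe_radius) {
  method <- match.arg(method)
  stopifnot(spacing > 0, probe_radius >= 0,
            scan_threshold >= 1, scan_threshold <= 7, min_pocket_voxels >= 1)
  structure(list(spacing = spacing, probe_radius = probe_radius,
                 scan_threshold = as.integer(scan_threshold),
                 min_pocket_voxels = as.integer(min_pocket_voxels),
                 method = method, dog_sigma = dog_sigma),
            class = "pocket_config")
}

# lattice covering the molecule plus a 2*probe margin
.pocket_lattice <- function(s, cfg) {
  xyz <- coords(s)
  radii <- s[["radius"]] %||% element_radius(s$element)
  margin <- 2 * cfg$probe_radius + max(radii)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / cfg$spacing)) + 1L
  list(origin = lo, spacing = rep(cfg$spacing, 3), dims = dims)
}

.protein_mask <- function(s, cfg, lattice) {
  radii <- (s[["radius"]] %||% element_radius(s$element)) + cfg$probe_radius
  cpp_mark_spheres(lattice$dims, lattice$origin, lattice$spacing,
                   coords(s), radii)
}

# separable Gaussian smoothing of a 3D array (truncated kernel, edge-renormalized)
.gauss3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(a, perm)
    d <- dim(x)
    m <- matrix(x, nrow = d[1])
    n <- d[1]
    pad <- matrix(0, nrow = r, ncol = ncol(m))
    mp <- rbind(pad, m, pad)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (t in seq_along(k)) {
      out <- out + k[t] * mp[(t):(t + n - 1), , drop = FALSE]
    }
    aperm(array(out, d), order(perm))
  }
  smooth_axis(smooth_axis(smooth_axis(arr, 1), 2), 3)
}

#' Detect pockets and cavities on a 3D lattice
#'
#' Builds a lattice over the molecule, classifies voxels as protein when
#' within `atom radius + probe_radius` of any atom center, then marks solvent
#' voxels as pocket candidates either by the protein-solvent-protein scan
#' (default) or by a difference-of-Gaussians response on the smoothed protein
#' density. Candidates are clustered by 26-connectivity and clusters smaller
#' than `min_pocket_voxels` are discarded. Pockets are sorted by volume,
#' largest first.
#'
#' @param s Atom tibble (one frame).
#' @param cfg A [pocket_config()].
#' @param lattice Optional fixed lattice (list with origin/spacing/dims), used
#'   internally to share one lattice across trajectory frames.
#' @return A `pocket_set`: list with `lattice`, `pockets` (tibble: id,
#'   n_voxels, volume, centroid x/y/z), `voxels` (list of linear index
#'   vectors) and `labels` (integer array).
#' @export
detect_pockets <- function(s, cfg = pocket_config(), lattice = NULL) {
  if (nrow(s) < 1) abort("need at least one atom")
  lattice <- lattice %||% .pocket_lattice(s, cfg)
  protein <- .protein_mask(s, cfg, lattice)
  if (cfg$method == "psp_scan") {
    cand <- cpp_psp_scan(protein, lattice$dims, cfg$scan_threshold)
  } else {
    # enclosed solvent collects more smoothed protein density at the wide
    # scale than at the narrow one; threshold at half the positive maximum
    dens <- array(as.numeric(protein), lattice$dims)
    s1 <- cfg$dog_sigma / cfg$spacing
    dog <- .gauss3(dens, 1.5 * s1) - .gauss3(dens, s1)
    pos <- dog > 0 & !protein
    thr <- if (any(pos)) 0.5 * max(dog[pos]) else Inf
    cand <- as.vector(dog > thr) & !protein
  }
  labels <- cpp_label_components(cand, lattice$dims, 26L)
  tab <- tabulate(labels)
  keep <- which(tab >= cfg$min_pocket_voxels)
  vox <- lapply(keep, function(l) which(labels == l))
  ord <- order(lengths(vox), decreasing = TRUE)
  vox <- vox[ord]
  vvol <- prod(lattice$spacing)
  cent <- t(vapply(vox, function(ix) {
    ijk <- arrayInd(ix, lattice$dims) - 1
    lattice$origin + colMeans(ijk) * lattice$spacing
  }, numeric(3)))
  if (length(vox) == 0) cent <- matrix(numeric(0), ncol = 3)
  lab_arr <- array(0L, lattice$dims)
  for (p in seq_along(vox)) lab_arr[vox[[p]]] <- p
  structure(list(
    lattice = lattice,
    pockets = tibble(id = seq_along(vox), n_voxels = lengths(vox),
                     volume = lengths(vox) * vvol,
                     x = cent[, 1] %||% numeric(0), y = cent[, 2] %||% numeric(0),
                     z = cent[, 3] %||% numeric(0)),
    voxels = vox, labels = lab_arr, config = cfg
  ), class = "pocket_set")
}

#' @export
print.pocket_set <- function(x, ...) {
  cat(sprintf("<pocket_set> %d pocket(s), total volume %.1f A^3\n",
              nrow(x$pockets), sum(x$pockets$volume)))
  invisible(x)
}

#' Total pocket volume of a pocket set
#' @param p A `pocket_set`.
#' @param site Optional 3-vector: count only the pocket containing (or
#'   nearest to) this point.
#' @return Volume in A^3.
#' @export
pocket_volume <- function(p, site = NULL) {
  if (nrow(p$pockets) == 0) return(0)
  if (is.null(site)) return(sum(p$pockets$volume))
  d2 <- (p$pockets$x - site[1])^2 + (p$pockets$y - site[2])^2 +
    (p$pockets$z - site[3])^2
  p$pockets$volume[which.min(d2)]
}

#' Pocket volume along a trajectory
#'
#' Detects pockets per frame on a lattice fixed to frame 1 (frames should be
#' pre-aligned with [align_frames()]) and reports the total (or site-seeded)
#' pocket volume over time.
#'
#' @param t A `groove_traj`.
#' @param cfg A [pocket_config()].
#' @param site Optional seed point (3-vector in A).
#' @return Tibble with `frame`, `time_ns`, `volume` (A^3).
#' @export
volume_trace <- function(t, cfg = pocket_config(), site = NULL) {
  if (is.null(attr(t, "aligned")) && length(t$frames) > 1) {
    warn("trajectory does not appear to be aligned; computing anyway")
  }
  lattice <- .pocket_lattice(structure_frame(t, 1), cfg)
  vols <- vapply(seq_along(t$frames), function(fr) {
    pocket_volume(detect_pockets(structure_frame(t, fr), cfg, lattice), site)
  }, numeric(1))
  tibble(frame = seq_along(t$frames),
         time_ns = (seq_along(t$frames) - 1) * t$frame_interval,
         volume = vols)
}

#' Per-voxel pocket occupancy across frames
#'
#' Fraction of frames in which each voxel of the shared (frame-1) lattice
#' belongs to a pocket.
#'
#' @param t A `groove_traj` (pre-aligned).
#' @param cfg A [pocket_config()].
#' @return A `scalar_grid` with values in \[0, 1\] and units "occupancy".
#' @export
occupancy_grid <- function(t, cfg = pocket_config()) {
  if (is.null(attr(t, "aligned")) && length(t$frames) > 1) {
    warn("trajectory does not appear to be aligned; computing anyway")
  }
  lattice <- .pocket_lattice(structure_frame(t, 1), cfg)
  acc <- array(0, lattice$dims)
  for (fr in seq_along(t$frames)) {
    ps <- detect_pockets(structure_frame(t, fr), cfg, lattice)
    acc <- acc + (ps$labels > 0)
  }
  g <- new_scalar_grid(lattice$origin, lattice$spacing,
                       acc / length(t$frames), units = "occupancy")
  g
}

#' Occupancy shell: voxels with occupancy in (lo, hi]
#'
#' Persistence shells such as (0.6, 0.8] and (0.8, 1.0] describe how
#' consistently a cavity region is present along a trajectory.
#'
#' @param g Occupancy `scalar_grid` from [occupancy_grid()].
#' @param lo,hi Shell bounds, `0 <= lo < hi <= 1`; voxels with
#'   `lo < occupancy <= hi` are selected.
#' @return List with `voxels` (linear indices) and `volume` (A^3).
#' @export
occupancy_shell <- function(g, lo, hi) {
  stopifnot(lo >= 0, lo < hi, hi <= 1)
  ix <- which(g$values > lo & g$values <= hi)
  list(voxels = ix, volume = length(ix) * prod(g$spacing))
}

#' Savitzky-Golay smoothing of a time series
#'
#' Local least-squares polynomial smoothing (as used for cavity-volume and
#' portal-aperture traces); endpoints are handled by polynomial fits on
#' truncated windows.
#'
#' @param s Tibble with a time axis and a value column (last numeric column),
#'   or a numeric vector.
#' @param window Odd window length in samples (default 51).
#' @param order Polynomial order (default 3, must be < window).
#' @return Same shape as the input with the value column smoothed (tibbles
#'   gain a `smoothed` column).
#' @export
savitzky_golay <- function(s, window = 51, order = 3) {
  stopifnot(window %% 2 == 1, order < window)
  vec <- if (is.numeric(s)) s else s[[ncol(s)]]
  if (length(vec) <= window) abort("window must be shorter than the series")
  sm <- as.numeric(signal::sgolayfilt(vec, p = order, n = window))
  if (is.numeric(s)) return(sm)
  s$smoothed <- sm
  s
}
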