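#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GNM mode set
#' @param x A `gnm_modes` object.
#' @param ... Unused.
#' @return Tibble with `index` (1..n ascending), `lambda`, `zero` flag and
#'   `mode` (non-zero mode numbering, NA for zero modes).
#' @export
tidy.gnm_modes <- function(x, ...) {
  n <- length(x$values)
  tibble(index = seq_len(n), lambda = x$values,
         zero = seq_len(n) <= x$n_zero,
         mode = ifelse(seq_len(n) <= x$n_zero, NA_integer_,
                       seq_len(n) - x$n_zero))
}

#' @rdname tidy.gnm_modes
#' @export
glance.gnm_modes <- function(x, ...) {
  tibble(n_nodes = length(x$values), n_zero = x$n_zero,
         lambda_1 = x$values[x$n_zero + 1], trace = sum(x$values))
}

#' Tidy a pocket set
#' @param x A `pocket_set`.
#' @param ... Unused.
#' @return The per-pocket tibble (id, n_voxels, volume, centroid).
#' @export
tidy.pocket_set <- function(x, ...) x$pockets

#' @rdname tidy.pocket_set
#' @export
glance.pocket_set <- function(x, ...) {
  tibble(n_pockets = nrow(x$pockets), total_volume = sum(x$pockets$volume),
         spacing = x$lattice$spacing[1])
}

#' Tidy a scalar grid into a long voxel table
#' @param x A `scalar_grid`.
#' @param ... Unused.
#' @return Tibble with x, y, z (A) and `value`.
#' @export
tidy.scalar_grid <- function(x, ...) {
  ax <- grid_axes(x)
  g <- tidyr::expand_grid(z = ax[[3]], y = ax[[2]], x = ax[[1]])[, 3:1]
  g$value <- as.vector(x$values)
  as_tibble(g)
}

#' @rdname tidy.scalar_grid
#' @export
glance.scalar_grid <- function(x, ...) {
  tibble(nx = x$dims[1], ny = x$dims[2], nz = x$dims[3],
         spacing = x$spacing[1], min = min(x$values), max = max(x$values),
         units = x$units)
}

#' Plot a time series (volume, aperture, RMSD ...)
#'
#' @param ts Tibble with `time_ns` and a value column; a `smoothed` column
#'   (from [savitzky_golay()]) is overlaid when present.
#' @param y Name of the value column (default: last non-smoothed column).
#' @return A ggplot object.
#' @export
plot_trace <- function(ts, y = NULL) {
  ycol <- y %||% setdiff(names(ts), c("frame", "time_ns", "smoothed"))[1]
  p <- ggplot2::ggplot(ts, ggplot2::aes(x = .data$time_ns,
                                        y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::labs(x = "time (ns)", y = ycol)
  if ("smoothed" %in% names(ts)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                colour = "black", linewidth = 0.8)
  }
  p
}

#' Plot a per-residue GNM amplitude profile
#' @param profile Tibble from [mode_profile()].
#' @return A ggplot object.
#' @export
plot_mode_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$res_seq,
                                        y = .data$amplitude,
                                        colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = attr(profile, "weighting") %||% "amplitude")
}

#' Plot an RMSD-based MDS embedding
#' @param emb Tibble from [rmsd_mds()].
#' @return A ggplot object.
#' @export
plot_mds <- function(emb) {
  ggplot2::ggplot(emb, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    label = .data$structure)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2")
}

#' Mid-plane heatmap of a scalar grid
#' @param object A `scalar_grid`.
#' @param axis Slicing axis (3 = z, default) at the central plane.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_grid <- function(object, axis = 3, ...) {
  mid <- ceiling(object$dims[axis] / 2)
  sl <- switch(axis,
               object$values[mid, , ], object$values[, mid, ],
               object$values[, , mid])
  ax <- grid_axes(object)[setdiff(1:3, axis)]
  d <- tidyr::expand_grid(b = ax[[2]], a = ax[[1]])[, 2:1]
  d$value <- as.vector(sl)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "A", y = "A", fill = object$units)
}

#' Eigenvalue spectrum of a GNM mode set
#' @param object A `gnm_modes` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gnm_modes <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$lambda,
                                  colour = .data$zero)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mode index", y = "eigenvalue")
}
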