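#' Build the Gaussian-network-model Kirchhoff (connectivity) matrix
#'
#' Calpha nodes; off-diagonal K\[i,j\] = -1 when the Calpha pair is within
#' `cutoff`, diagonal = node degree (graph Laplacian of the contact network).
#'
#' @param s Atom tibble (any atom set; Calpha atoms are extracted).
#' @param cutoff Contact cutoff in A (default 7.3, the common GNM choice).
#' @return A `kirchhoff` object: list with `matrix`, `nodes` (tibble chain,
#'   res_seq) and `cutoff`.
#' @export
build_kirchhoff <- function(s, cutoff = 7.3) {
  stopifnot(cutoff > 0)
  ca <- s %>% filter(.data$name == "CA", !.data$het)
  no_ca <- setdiff(unique(s$chain_id[!s$het]), unique(ca$chain_id))
  if (length(no_ca)) {
    abort(sprintf("chain(s) without Calpha atoms: %s",
                  paste(no_ca, collapse = ", ")))
  }
  if (nrow(ca) < 2) abort("need >= 2 Calpha atoms")
  D <- as.matrix(dist(coords(ca)))
  K <- -(D <= cutoff) * 1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  structure(list(matrix = K,
                 nodes = tibble(chain = ca$chain_id, res_seq = ca$res_seq),
                 cutoff = cutoff),
            class = "kirchhoff")
}

#' Gaussian-network-model normal modes
#'
#' Eigendecomposition of the Kirchhoff matrix, eigenvalues ascending.
#' Near-zero eigenvalues (lambda < 1e-8 * lambda_max) correspond to connected
#' components of the contact graph and are excluded from mode indexing:
#' "mode 1" is the lowest non-zero mode.
#'
#' @param k A `kirchhoff` object.
#' @param n_modes Number of non-zero modes to retain (default 20).
#' @return A `gnm_modes` object: eigenvalues, orthonormal eigenvectors,
#'   `n_zero`, node labels.
#' @export
gnm_modes <- function(k, n_modes = 20) {
  n <- nrow(k$matrix)
  stopifnot(n_modes <= n)
  e <- eigen(k$matrix, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lmax <- max(values)
  n_zero <- sum(values < 1e-8 * max(lmax, 1e-300))
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 n_modes = min(n_modes, n - n_zero), nodes = k$nodes),
            class = "gnm_modes")
}

#' @export
print.gnm_modes <- function(x, ...) {
  cat(sprintf("<gnm_modes> %d nodes, %d zero mode(s), lambda_1 = %.4g\n",
              length(x$values), x$n_zero, x$values[x$n_zero + 1]))
  invisible(x)
}

#' Per-residue amplitude profile of selected modes
#'
#' Squared-fluctuation convention: amplitude_i = sum_k u_ki^2 / lambda_k over
#' the requested (non-zero) modes, computed on the full complex and then
#' restricted to one chain if requested. Set `weighted = FALSE` for plain
#' u^2 without the inverse-eigenvalue weighting.
#'
#' @param m A `gnm_modes` object.
#' @param modes Integer indices of non-zero modes (1 = lowest non-zero).
#' @param chain Optional chain restriction.
#' @param weighted Divide each mode's contribution by its eigenvalue?
#' @return Tibble with `chain`, `res_seq`, `amplitude` (and a `weighting`
#'   attribute naming the convention).
#' @export
mode_profile <- function(m, modes = 1, chain = NULL, weighted = TRUE) {
  navail <- length(m$values) - m$n_zero
  if (any(modes < 1) || any(modes > navail)) {
    abort(sprintf("mode indices must be in 1..%d (non-zero modes)", navail))
  }
  amp <- rep(0, length(m$values))
  for (k in modes) {
    u <- m$vectors[, m$n_zero + k]
    w <- if (weighted) 1 / m$values[m$n_zero + k] else 1
    amp <- amp + w * u^2
  }
  out <- m$nodes
  out$amplitude <- amp
  if (!is.null(chain)) {
    out <- out %>% filter(.data$chain == !!chain)
    if (nrow(out) == 0) abort(sprintf("chain '%s' has no nodes", chain))
  }
  attr(out, "weighting") <- if (weighted) "u^2/lambda" else "u^2"
  attr(out, "modes") <- modes
  out
}
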