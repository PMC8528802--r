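#' Synthetic smooth coil sensitivity maps
#'
#' Gaussian-profile receive sensitivities for coils placed around the object,
#' with a smooth low-order phase per coil; deterministic given the geometry.
#' Used by the phantom fixtures; real data would bring measured maps instead.
#'
#' @param dims image dimensions (length 2 or 3).
#' @param n_coils number of coils (>= 1).
#' @param width Gaussian width as a fraction of the matrix size.
#' @return complex array of dim `c(dims, n_coils)` with unit root-sum-of-
#'   squares over coils at every voxel.
#' @export
make_coil_maps <- function(dims, n_coils = 4L, width = 0.8) {
  dims <- as.integer(dims)
  d <- length(dims)
  stopifnot(d %in% c(2L, 3L), n_coils >= 1L)
  grid <- coord_grid(dims)                      # voxels x d, in [-0.5, 0.5)
  maps <- matrix(0 + 0i, nrow = prod(dims), ncol = n_coils)
  for (c_i in seq_len(n_coils)) {
    ang <- 2 * pi * (c_i - 1) / n_coils
    center <- c(0.6 * cos(ang), 0.6 * sin(ang), if (d == 3L) 0)[seq_len(d)]
    r2 <- rowSums(sweep(grid, 2L, center)^2)
    mag <- exp(-r2 / (2 * width^2))
    phase <- 2 * pi * (0.3 * grid[, 1L] * cos(ang) +
                       0.3 * grid[, 2L] * sin(ang))
    maps[, c_i] <- mag * exp(1i * phase)
  }
  rss <- sqrt(rowSums(Mod(maps)^2))
  maps <- maps / rss
  array(maps, c(dims, n_coils))
}

# voxel-center coordinates in units of the field of view, matching the NDFT
coord_grid <- function(dims) {
  ax <- lapply(dims, function(n) (seq_len(n) - 1 - n %/% 2) / n)
  as.matrix(do.call(expand.grid, ax))
}

#' Adaptive (Walsh-style) coil sensitivity estimation
#'
#' Estimates per-voxel sensitivities as the dominant eigenvector of the local
#' coil-signal covariance, computed over a sliding spatial block, the standard
#' adaptive coil-combination approach. The output is normalized to unit
#' root-sum-of-squares per voxel and the global phase is fixed by making the
#' first coil's map real-positive wherever it is nonzero. Voxels whose local
#' covariance is all zero fall back to a unit vector on the first coil and are
#' flagged.
#'
#' @param coil_images complex array `c(dims, n_coils)` of per-coil images
#'   (e.g. the first subspace component reconstructed per coil).
#' @param block odd sliding-block width in voxels (default 5).
#' @param iterations power-method iterations (default 20).
#' @return list with `maps` (complex array like the input, unit RSS),
#'   `flagged` (logical array of degenerate voxels).
#' @export
estimate_coil_maps <- function(coil_images, block = 5L, iterations = 20L) {
  dd <- dim(coil_images)
  n_coils <- dd[length(dd)]
  dims <- dd[-length(dd)]
  nvox <- prod(dims)
  ci <- matrix(coil_images, nrow = nvox, ncol = n_coils)

  # local covariance C[i,j](v) = box-smoothed img_i * conj(img_j)
  cov <- array(0 + 0i, c(nvox, n_coils, n_coils))
  for (i in seq_len(n_coils)) for (j in seq_len(n_coils)) {
    prod_ij <- array(ci[, i] * Conj(ci[, j]), dims)
    cov[, i, j] <- as.vector(box_smooth(prod_ij, block))
  }

  # power iteration for the dominant eigenvector, vectorized over voxels
  v <- matrix(0 + 0i, nvox, n_coils)
  v[, 1L] <- 1
  for (it in seq_len(iterations)) {
    w <- matrix(0 + 0i, nvox, n_coils)
    for (i in seq_len(n_coils))
      for (j in seq_len(n_coils))
        w[, i] <- w[, i] + cov[, i, j] * v[, j]
    nw <- sqrt(rowSums(Mod(w)^2))
    ok <- nw > 0
    v[ok, ] <- w[ok, ] / nw[ok]
  }
  flagged <- rowSums(Mod(cov)^2) == 0
  v[flagged, ] <- 0
  v[flagged, 1L] <- 1
  # unit RSS (power iteration already yields unit vectors) + phase reference
  ph <- v[, 1L]
  a <- Mod(ph)
  adj <- ifelse(a > 0, Conj(ph) / a, 1 + 0i)
  v <- v * adj
  list(maps = array(v, c(dims, n_coils)),
       flagged = array(flagged, dims))
}

# separable moving-average box filter with edge renormalization
box_smooth <- function(arr, w) {
  if (w <= 1L) return(arr)
  half <- (w - 1L) %/% 2L
  dims <- dim(arr)
  out <- arr
  cnt <- array(1, dims)
  for (axis in seq_along(dims)) {
    out <- running_sum(out, axis, half)
    cnt <- running_sum(cnt, axis, half)
  }
  out / cnt
}

# sum over a window of +/- half along one axis (zero padding)
running_sum <- function(arr, axis, half) {
  dims <- dim(arr)
  n <- dims[axis]
  perm <- c(axis, seq_along(dims)[-axis])
  m <- aperm(arr, perm)
  dim(m) <- c(n, prod(dims[-axis]))
  cs <- apply(m, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  upper <- pmin(seq_len(n) + half, n)
  lower <- seq_len(n) - half - 1L
  res <- cs[upper, , drop = FALSE] -
    rbind(matrix(0, sum(lower < 1L), ncol(cs)),
          cs[lower[lower >= 1L], , drop = FALSE])
  dim(res) <- dims[perm]
  aperm(res, order(perm))
}
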