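#' Variable-density spiral k-space trajectory with golden-angle rotations
#'
#' Builds one variable-density Archimedean spiral interleaf and assigns each
#' repetition a rotated copy: in 2D the interleaf is rotated in-plane by
#' golden-angle increments; in 3D an additional spherical rotation (taken from
#' a Fibonacci-sphere direction sequence) tilts the spiral plane so that the
#' repetitions jointly cover the 3D k-space ball. k-space coordinates are in
#' cycles per field of view, so the Nyquist radius is `matrix_size / 2`; all
#' sample radii stay at or below it, and rotations preserve radii exactly.
#'
#' @param matrix_size reconstruction matrix size per axis.
#' @param fov_mm field of view in mm (metadata; the trajectory itself is in
#'   normalized units).
#' @param interleaves number of base interleaves the spiral is designed for
#'   (controls the turn count; repetition r uses one rotated interleaf).
#' @param samples_per_interleaf samples along one interleaf.
#' @param repetitions number of repetitions (one interleaf each).
#' @param mode `"2d"` or `"3d"`.
#' @param density_exponent radius grows as tau^density_exponent along the
#'   interleaf; > 1 samples the k-space center more densely (default 1.5).
#' @return object of class `qti_trajectory`: list with `kpts` (list of
#'   per-repetition sample matrices, samples x d), `matrix_size`, `fov_mm`,
#'   `mode`, and the generation parameters.
#' @export
make_spiral_trajectory <- function(matrix_size, fov_mm = 225,
                                   interleaves = 1L,
                                   samples_per_interleaf = 1024L,
                                   repetitions = 880L,
                                   mode = c("2d", "3d"),
                                   density_exponent = 1.5) {
  mode <- match.arg(mode)
  stopifnot(matrix_size >= 4, interleaves >= 1, samples_per_interleaf >= 8,
            repetitions >= 1, density_exponent > 0)
  kmax <- matrix_size / 2
  n_turns <- max(1, matrix_size / (2 * interleaves))
  tau <- seq(0, 1, length.out = samples_per_interleaf + 1L)[-1L]
  r <- kmax * tau^density_exponent
  th <- 2 * pi * n_turns * tau
  base <- cbind(kx = r * cos(th), ky = r * sin(th))

  golden <- pi * (3 - sqrt(5))        # ~137.5 deg golden-angle increment
  d <- if (mode == "2d") 2L else 3L
  kpts <- vector("list", repetitions)
  for (rep_i in seq_len(repetitions)) {
    phi <- (rep_i - 1L) * golden
    rot2 <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)
    pts <- base %*% rot2
    if (mode == "3d") {
      # Fibonacci-sphere direction for this repetition's plane normal
      i <- rep_i - 1L
      zc <- 1 - 2 * (i + 0.5) / repetitions
      az <- i * golden * 2
      nvec <- c(sqrt(1 - zc^2) * cos(az), sqrt(1 - zc^2) * sin(az), zc)
      rot3 <- rotation_to_z(nvec)
      pts <- cbind(pts, 0) %*% t(rot3)
    }
    colnames(pts) <- c("kx", "ky", "kz")[seq_len(d)]
    kpts[[rep_i]] <- pts
  }
  structure(list(kpts = kpts, matrix_size = as.integer(matrix_size),
                 fov_mm = fov_mm, mode = mode,
                 interleaves = as.integer(interleaves),
                 samples_per_interleaf = as.integer(samples_per_interleaf),
                 repetitions = as.integer(repetitions),
                 density_exponent = density_exponent,
                 kmax = kmax),
            class = "qti_trajectory")
}

# rotation matrix mapping the z-axis onto unit vector v (Rodrigues)
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(z[2] * v[3] - z[3] * v[2],
          z[3] * v[1] - z[1] * v[3],
          z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' @export
print.qti_trajectory <- function(x, ...) {
  uf <- x$matrix_size^(if (x$mode == "2d") 2 else 3) /
    nrow(x$kpts[[1L]])
  cat(sprintf(paste0("Spiral trajectory (%s): %d repetitions x %d samples, ",
                     "matrix %d, per-repetition undersampling %.3g\n"),
              x$mode, x$repetitions, nrow(x$kpts[[1L]]), x$matrix_size, uf))
  invisible(x)
}

#' Per-repetition undersampling factor of a trajectory
#' @param traj a `qti_trajectory`.
#' @return Cartesian voxel count divided by acquired samples per repetition.
#' @export
undersampling_factor <- function(traj) {
  stopifnot(inherits(traj, "qti_trajectory"))
  traj$matrix_size^(if (traj$mode == "2d") 2L else 3L) / nrow(traj$kpts[[1L]])
}

#' Density-compensation weights for one interleaf
#'
#' Radial-annulus weights: samples are binned by |k| and each bin weighted by
#' the k-space area (2D) or volume (3D) of its annulus divided by the sample
#' count in it. Each weight carries the k-space measure its sample stands for,
#' divided by the Cartesian cell count, so the density-compensated adjoint
#' matches the amplitude of the Cartesian inverse DFT restricted to the
#' covered k-space ball (on a fully sampled Cartesian set these weights reduce
#' to 1/N each).
#'
#' @param kpts sample matrix (samples x d) of one repetition.
#' @param dims image dimensions (Cartesian matrix the weights normalize to).
#' @param bins number of radial annuli.
#' @return numeric weight per sample.
#' @export
density_weights <- function(kpts, dims, bins = 64L) {
  d <- ncol(kpts)
  dims <- as.integer(dims)
  stopifnot(length(dims) == d)
  r <- sqrt(rowSums(kpts^2))
  rmax <- max(r) * (1 + 1e-12)
  edges <- seq(0, rmax, length.out = bins + 1L)
  bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), bins)
  vol <- if (d == 2L) pi * diff(edges^2) else (4 / 3) * pi * diff(edges^3)
  cnt <- tabulate(bin, nbins = bins)
  w <- vol[bin] / pmax(cnt[bin], 1L)
  w / prod(dims)
}

#' Export / import a trajectory as CSV
#'
#' Long format with columns `repetition`, `sample`, `kx`, `ky` (and `kz` in
#' 3D); metadata is carried in a JSON sidecar written next to the CSV.
#'
#' @param traj a `qti_trajectory`.
#' @param path CSV path.
#' @return the path / the restored `qti_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "qti_trajectory"))
  tab <- do.call(rbind, lapply(seq_along(traj$kpts), function(r) {
    k <- traj$kpts[[r]]
    cbind(repetition = r, sample = seq_len(nrow(k)), k)
  }))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  meta <- traj[c("matrix_size", "fov_mm", "mode", "interleaves",
                 "samples_per_interleaf", "repetitions", "density_exponent",
                 "kmax")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cols <- intersect(c("kx", "ky", "kz"), names(tab))
  kpts <- lapply(split(tab, tab$repetition), function(df)
    as.matrix(df[order(df$sample), cols, drop = FALSE]))
  names(kpts) <- NULL
  structure(c(list(kpts = kpts), meta), class = "qti_trajectory")
}
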