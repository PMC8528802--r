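#' Subspace coefficient images of a phantom under a schedule
#'
#' Simulates the EPG time-series of every in-mask voxel (exactly, per voxel)
#' and projects it onto the temporal basis, yielding the rank-`r` coefficient
#' images that the acquisition model samples. Out-of-mask voxels are zero.
#'
#' @param maps a [qti_maps()] object (the ground-truth parameter maps).
#' @param schedule a [qti_schedule()].
#' @param basis a [compute_subspace()] basis for that schedule.
#' @param max_epg_order EPG truncation order.
#' @return complex matrix (voxels x rank); attribute `dims` carries the
#'   spatial dimensions.
#' @export
phantom_coeffs <- function(maps, schedule, basis, max_epg_order = 100L) {
  stopifnot(inherits(maps, "qti_maps"), inherits(basis, "qti_basis"))
  dims <- dim(maps$t1)
  nvox <- prod(dims)
  use <- as.vector(maps$mask) & as.vector(maps$t1) > 0 &
    as.vector(maps$t2) > 0 & as.vector(maps$pd) > 0
  coeffs <- matrix(0 + 0i, nvox, basis$rank)
  if (any(use)) {
    p <- data.frame(t1_ms = as.vector(maps$t1)[use],
                    t2_ms = as.vector(maps$t2)[use],
                    pd = as.vector(maps$pd)[use])
    sig <- simulate_batch(p, schedule, max_epg_order = max_epg_order)
    coeffs[use, ] <- compress_signal(sig, basis)
  }
  attr(coeffs, "dims") <- dims
  coeffs
}

# forward sampling operator: coefficient images -> k-space samples
# coeffs: nvox x rank complex; returns array (samples, coils, reps)
sense_forward <- function(coeffs, phi, traj, coil_maps, dims) {
  nrep <- length(traj$kpts)
  m <- nrow(traj$kpts[[1L]])
  n_coils <- ncol(coil_maps)
  y <- array(0 + 0i, c(m, n_coils, nrep))
  for (r in seq_len(nrep)) {
    img_r <- as.vector(coeffs %*% phi[r, ])
    for (c_i in seq_len(n_coils))
      y[, c_i, r] <- ndft_forward_cpp(traj$kpts[[r]],
                                      as.complex(coil_maps[, c_i] * img_r),
                                      dims)
  }
  y
}

# adjoint of sense_forward; optional per-sample weights (same for all reps,
# vector) or per-rep (list)
sense_adjoint <- function(y, phi, traj, coil_maps, dims, weights = NULL) {
  nrep <- length(traj$kpts)
  n_coils <- ncol(coil_maps)
  nvox <- nrow(coil_maps)
  rank <- ncol(phi)
  out <- matrix(0 + 0i, nvox, rank)
  for (r in seq_len(nrep)) {
    w <- if (is.null(weights)) NULL
         else if (is.list(weights)) weights[[r]] else weights
    tmp <- complex(length.out = nvox)
    for (c_i in seq_len(n_coils)) {
      yr <- y[, c_i, r]
      if (!is.null(w)) yr <- yr * w
      tmp <- tmp + Conj(coil_maps[, c_i]) *
        ndft_adjoint_cpp(traj$kpts[[r]], as.complex(yr), dims)
    }
    out <- out + outer(tmp, Conj(phi[r, ]))
  }
  out
}

#' Simulate an undersampled spiral transient-state acquisition
#'
#' Samples the coil-weighted instantaneous image of each repetition at that
#' repetition's spiral trajectory points through the exact non-uniform Fourier
#' transform, and adds seeded white complex Gaussian noise. The instantaneous
#' images are generated in the temporal subspace (the voxel signals are
#' subspace-projected first), which makes the 3D/880-repetition problem
#' tractable and is exact up to the (tiny) subspace projection residual.
#'
#' @param coeffs subspace coefficient images from [phantom_coeffs()] (or any
#'   complex voxels x rank matrix with a `dims` attribute).
#' @param basis the temporal basis the coefficients live in; its row count
#'   must equal the trajectory's repetition count.
#' @param traj a [make_spiral_trajectory()] result.
#' @param coil_maps complex array `c(dims, n_coils)`; default: one uniform
#'   coil.
#' @param noise_sigma absolute standard deviation of the complex Gaussian
#'   noise per sample (real and imaginary each); 0 for noiseless.
#' @param seed RNG seed for the noise.
#' @return object of class `qti_kspace`: `data` (samples x coils x reps),
#'   `traj`, `dims`, `noise_sigma`, `seed`.
#' @export
simulate_acquisition <- function(coeffs, basis, traj, coil_maps = NULL,
                                 noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(basis, "qti_basis"), inherits(traj, "qti_trajectory"))
  dims <- attr(coeffs, "dims")
  if (is.null(dims)) stop("coeffs must carry a 'dims' attribute")
  dims <- as.integer(dims)
  if (length(traj$kpts) != nrow(basis$vectors))
    stop("trajectory repetition count does not match the basis")
  if (ncol(traj$kpts[[1L]]) != length(dims))
    stop("trajectory dimensionality does not match the image dimensions")
  if (is.null(coil_maps))
    coil_maps <- array(1 + 0i, c(dims, 1L))
  cm <- matrix(coil_maps, nrow = prod(dims))
  y <- sense_forward(coeffs, basis$vectors, traj, cm, dims)
  if (noise_sigma > 0) {
    set.seed(seed)
    y <- y + array(complex(real = stats::rnorm(length(y), 0, noise_sigma),
                           imaginary = stats::rnorm(length(y), 0, noise_sigma)),
                   dim(y))
  }
  structure(list(data = y, traj = traj, dims = dims,
                 noise_sigma = noise_sigma, seed = seed),
            class = "qti_kspace")
}

#' Reconstruct subspace coefficient images from undersampled k-space
#'
#' Three reconstruction routes for the per-repetition spiral data:
#' \describe{
#'   \item{zero_fill}{density-compensated adjoint of the sampling operator,
#'     contracted over time with the temporal basis and coil-combined.}
#'   \item{view_share}{as zero_fill, after sharing k-space across a sliding
#'     temporal window with triangular weights decaying in temporal distance
#'     (options `window`, default 8 repetitions to each side).}
#'   \item{lrtv}{iterative compressed sensing: minimizes
#'     \eqn{\|A(c) - y\|^2 + \lambda_{TV} \sum_j TV(c_j)} over coefficient
#'     images constrained to the temporal subspace, by monotone proximal
#'     gradient descent with the step size from a power-method estimate of
#'     the operator norm (options `lambda_tv`, `iterations` default 40,
#'     `tv_iterations`, `power_iterations`).}
#' }
#'
#' @param kspace a [simulate_acquisition()] result (or compatible object).
#' @param basis the temporal basis (rank defines the component count).
#' @param coil_maps complex array `c(dims, n_coils)` of sensitivities;
#'   default: one uniform coil.
#' @param method `"zero_fill"`, `"view_share"` or `"lrtv"`.
#' @param options named list of method options (see above; `dcf_weights` /
#'   `dcf_bins` override the density-compensation weights).
#' @return object of class `qti_svdimages`: `coeffs` (voxels x rank complex),
#'   `dims`, `rank`, `method`, plus `objective` (per-iteration) for lrtv.
#' @export
reconstruct <- function(kspace, basis, coil_maps = NULL,
                        method = c("zero_fill", "view_share", "lrtv"),
                        options = list()) {
  method <- match.arg(method)
  stopifnot(inherits(basis, "qti_basis"))
  traj <- kspace$traj
  dims <- as.integer(kspace$dims)
  y <- kspace$data
  if (is.null(coil_maps)) coil_maps <- array(1 + 0i, c(dims, 1L))
  cm <- matrix(coil_maps, nrow = prod(dims))
  phi <- basis$vectors
  nrep <- length(traj$kpts)

  opt <- function(name, default)
    if (!is.null(options[[name]])) options[[name]] else default

  w <- opt("dcf_weights", density_weights(traj$kpts[[1L]], dims = dims,
                                          bins = opt("dcf_bins", 64L)))

  res <- switch(
    method,
    zero_fill = sense_adjoint(y, phi, traj, cm, dims, weights = w),
    view_share = {
      window <- opt("window", 8L)
      phi_s <- share_basis_weights(phi, window)
      sense_adjoint(y, phi_s, traj, cm, dims, weights = w)
    },
    lrtv = {
      lambda_tv <- opt("lambda_tv", 1e-3)
      iterations <- opt("iterations", 40L)
      tv_iter <- opt("tv_iterations", 30L)
      pow_iter <- opt("power_iterations", 10L)
      # warm start from the density-compensated adjoint (standard practice)
      init <- opt("init", sense_adjoint(y, phi, traj, cm, dims, weights = w))
      lrtv_solve(y, phi, traj, cm, dims, lambda_tv, iterations, tv_iter,
                 pow_iter, init = init,
                 verbose = isTRUE(options$verbose))
    })
  obj <- attr(res, "objective")
  attr(res, "objective") <- NULL
  structure(list(coeffs = res, dims = dims, rank = ncol(phi),
                 method = method, objective = obj),
            class = "qti_svdimages")
}

#' @export
print.qti_svdimages <- function(x, ...) {
  cat(sprintf("Subspace image series: %s voxels x rank %d (%s)\n",
              paste(x$dims, collapse = "x"), x$rank, x$method))
  invisible(x)
}

# temporally smoothed conjugate basis weights for k-space view-sharing:
# sharing rep r' data into target rep r with triangular weight, reorganized
# as per-source-rep effective basis weights
share_basis_weights <- function(phi, window) {
  nrep <- nrow(phi)
  offs <- -window:window
  kern <- 1 - abs(offs) / (window + 1)
  out <- matrix(0 + 0i, nrep, ncol(phi))
  norm <- numeric(nrep)
  for (i in seq_along(offs)) {
    r <- seq_len(nrep)
    rs <- r + offs[i]            # source rep feeding target r
    ok <- rs >= 1L & rs <= nrep
    norm[r[ok]] <- norm[r[ok]] + kern[i]
  }
  for (i in seq_along(offs)) {
    r <- seq_len(nrep)
    rs <- r + offs[i]
    ok <- rs >= 1L & rs <= nrep
    # target r takes data from source rs with weight kern/norm(r):
    # effective weight on source rep rs accumulates conj-free phi at target r
    out[rs[ok], ] <- out[rs[ok], ] + (kern[i] / norm[r[ok]]) * phi[r[ok], ]
  }
  out
}

# monotone proximal-gradient (ISTA) solver for the LRTV objective
lrtv_solve <- function(y, phi, traj, cm, dims, lambda_tv, iterations,
                       tv_iter, pow_iter, init = NULL, verbose = FALSE) {
  nvox <- nrow(cm)
  rank <- ncol(phi)
  # power method for ||A^H A||
  set.seed(17L)
  c0 <- matrix(complex(real = stats::rnorm(nvox * rank),
                       imaginary = stats::rnorm(nvox * rank)), nvox, rank)
  lmax <- 1
  for (i in seq_len(pow_iter)) {
    c1 <- sense_adjoint(sense_forward(c0, phi, traj, cm, dims),
                        phi, traj, cm, dims)
    lmax <- sqrt(sum(Mod(c1)^2)) / sqrt(sum(Mod(c0)^2))
    c0 <- c1 / sqrt(sum(Mod(c1)^2))
  }
  if (!is.finite(lmax) || lmax <= 0) {
    warning("power method did not converge; using unit step")
    lmax <- 1
  }
  step <- 0.9 / (2 * lmax)

  cc <- if (is.null(init)) matrix(0 + 0i, nvox, rank) else init
  objective <- numeric(iterations)
  tv_of <- function(m) sum(vapply(seq_len(rank), function(j)
    tv_norm(array(m[, j], dims)), numeric(1)))
  for (it in seq_len(iterations)) {
    resid <- sense_forward(cc, phi, traj, cm, dims) - y
    grad <- 2 * sense_adjoint(resid, phi, traj, cm, dims)
    prop <- cc - step * grad
    for (j in seq_len(rank))
      prop[, j] <- as.vector(prox_tv(array(prop[, j], dims),
                                     lambda_tv * step, iters = tv_iter))
    f_prop <- sum(Mod(sense_forward(prop, phi, traj, cm, dims) - y)^2) +
      lambda_tv * tv_of(prop)
    f_cur <- sum(Mod(resid)^2) + lambda_tv * tv_of(cc)
    if (f_prop <= f_cur) cc <- prop        # monotone acceptance
    objective[it] <- min(f_prop, f_cur)
    if (verbose) message(sprintf("lrtv iter %3d  objective %.6g", it,
                                 objective[it]))
  }
  attr(cc, "objective") <- objective
  cc
}

# ---- isotropic total variation on complex 2D/3D arrays ----------------------

# forward-difference gradient along each axis (Neumann boundary)
tv_grad <- function(u) {
  dims <- dim(u)
  lapply(seq_along(dims), function(ax) {
    idx_hi <- slice_index(dims, ax, c(2:dims[ax], dims[ax]))
    g <- u[idx_hi] - as.vector(u)
    dim(g) <- dims
    g
  })
}

# negative adjoint of tv_grad (divergence)
tv_div <- function(p) {
  dims <- dim(p[[1L]])
  out <- array(0 + 0i, dims)
  for (ax in seq_along(dims)) {
    g <- p[[ax]]
    shifted <- slice_index(dims, ax, c(1L, seq_len(dims[ax] - 1L)))
    gm <- g[shifted]
    dim(gm) <- dims
    first <- slice_assign_mask(dims, ax, 1L)
    last <- slice_assign_mask(dims, ax, dims[ax])
    d <- g - gm
    d[first] <- g[first]
    d[last] <- -gm[last]
    out <- out + d
  }
  out
}

slice_index <- function(dims, axis, ord) {
  idx <- lapply(dims, seq_len)
  idx[[axis]] <- ord
  as.matrix(do.call(expand.grid, idx))
}

slice_assign_mask <- function(dims, axis, at) {
  m <- array(FALSE, dims)
  idx <- lapply(dims, seq_len)
  idx[[axis]] <- at
  do.call(`[<-`, c(list(m), idx, list(TRUE)))
}

#' Isotropic total variation of a (complex) image
#' @param u 2D or 3D array.
#' @return scalar TV value.
#' @export
tv_norm <- function(u) {
  g <- tv_grad(u)
  sum(sqrt(Reduce(`+`, lapply(g, function(x) Mod(x)^2))))
}

# proximal operator of lambda * TV via Chambolle's dual projection algorithm,
# extended to complex images (dual fields are complex, projected by modulus)
prox_tv <- function(z, lambda, iters = 30L) {
  if (lambda <= 0) return(z)
  dims <- dim(z)
  tau <- if (length(dims) == 2L) 0.2 else 0.1
  p <- lapply(seq_along(dims), function(i) array(0 + 0i, dims))
  for (it in seq_len(iters)) {
    u <- z - lambda * tv_div(p)
    g <- tv_grad(u)
    mag <- sqrt(Reduce(`+`, lapply(g, function(x) Mod(x)^2)))
    denom <- 1 + (tau / lambda) * mag
    for (i in seq_along(p))
      p[[i]] <- (p[[i]] + (tau / lambda) * g[[i]]) / denom
  }
  z - lambda * tv_div(p)
}
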