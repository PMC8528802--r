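#' ROI-based statistics of quantitative maps
#'
#' One row per ROI with the voxel count and the mean and population standard
#' deviation of T1 and T2 over in-mask voxels, in the order the masks are
#' given (the layout of the cohort summary table).
#'
#' @param maps a [qti_maps()] object.
#' @param masks named list of logical arrays matching the maps' shape.
#' @return data.frame with columns `name`, `n_voxels`, `t1_mean`, `t1_std`,
#'   `t2_mean`, `t2_std`.
#' @export
roi_statistics <- function(maps, masks) {
  stopifnot(inherits(maps, "qti_maps"), is.list(masks),
            !is.null(names(masks)))
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!identical(dim(as.array(m)), dim(maps$t1)))
      stop("ROI '", nm, "' does not match the map extent")
    v <- as.logical(m)
    n <- sum(v)
    if (n < 1L) stop("empty ROI: ", nm)
    t1 <- maps$t1[v]; t2 <- maps$t2[v]
    data.frame(name = nm, n_voxels = n,
               t1_mean = mean(t1), t1_std = pop_sd(t1),
               t2_mean = mean(t2), t2_std = pop_sd(t2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Fit a Gaussian mixture to (T1, T2) samples
#'
#' Expectation-maximization with seeded k-means initialization and full 2x2
#' covariances, run on the raw (T1, T2) values in ms (no standardization,
#' unless requested). Convergence is declared when the log-likelihood gain
#' drops below `tol` or after `max_iter` iterations. A near-singular
#' component covariance is regularized by adding `1e-6 * trace` to its
#' diagonal (with a message). Components are reordered by ascending mean T1,
#' so for the necrotic/non-enhancing tumor ROI component 1 is the solid-like
#' (core I) and component 2 the fluid-like (core II) population.
#'
#' @param samples numeric matrix or data.frame with two columns (T1, T2) in
#'   ms.
#' @param k number of components (default 2); requires `nrow(samples) >=
#'   10 * k`.
#' @param seed RNG seed for the initialization.
#' @param max_iter,tol EM stopping rule (defaults 500 and 1e-6).
#' @param standardize z-score the features before fitting and map the model
#'   back (default FALSE).
#' @return object of class `qti_gmm`: `weights`, `means` (k x 2), `covs`
#'   (2 x 2 x k), `loglik`, `n_iter`, `converged`, `seed`.
#' @export
fit_t1t2_gmm <- function(samples, k = 2L, seed = 1L, max_iter = 500L,
                         tol = 1e-6, standardize = FALSE) {
  x <- as.matrix(samples)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 2L)
  n <- nrow(x)
  k <- as.integer(k)
  if (n < 10L * k) stop("need at least 10 samples per component")
  ctr <- c(0, 0); scl <- c(1, 1)
  if (standardize) {
    ctr <- colMeans(x); scl <- apply(x, 2L, stats::sd)
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  }

  # deterministic, order-invariant k-means init: centers seeded at the
  # per-coordinate quantiles, then Lloyd iterations (assignments depend only
  # on the sample set, so the fit is invariant to sample permutation)
  set.seed(seed)
  qs <- (seq_len(k) - 0.5) / k
  centers <- cbind(stats::quantile(x[, 1L], qs, names = FALSE),
                   stats::quantile(x[, 2L], qs, names = FALSE))
  km <- stats::kmeans(x, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd")
  means <- km$centers
  covs <- array(0, c(2L, 2L, k))
  weights <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  for (j in seq_len(k)) {
    xj <- x[km$cluster == j, , drop = FALSE]
    covs[, , j] <- regularize_cov(pop_cov(xj, colMeans(xj)))
  }

  loglik <- -Inf
  converged <- FALSE
  it <- 0L
  resp <- NULL
  while (it < max_iter) {
    it <- it + 1L
    # E step (log-sum-exp for stability)
    logd <- vapply(seq_len(k), function(j)
      log(weights[j]) + dmvnorm2_log(x, means[j, ], covs[, , j]),
      numeric(n))
    if (!is.matrix(logd)) logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_ll <- sum(lse)
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2L, mu)
      sig <- crossprod(xc * resp[, j], xc) / nk[j]
      means[j, ] <- mu
      covs[, , j] <- regularize_cov((sig + t(sig)) / 2)
    }
    if (is.finite(loglik) && new_ll - loglik < tol) {
      loglik <- new_ll
      converged <- TRUE
      break
    }
    loglik <- new_ll
  }
  ord <- order(means[, 1L])
  means <- means[ord, , drop = FALSE]
  covs <- covs[, , ord, drop = FALSE]
  weights <- weights[ord]
  if (standardize) {
    means <- sweep(sweep(means, 2L, scl, `*`), 2L, ctr, `+`)
    for (j in seq_len(k))
      covs[, , j] <- covs[, , j] * tcrossprod(scl)
    # log-likelihood in original units: subtract the Jacobian term
    loglik <- loglik - n * sum(log(scl))
  }
  dimnames(means) <- list(NULL, c("t1_ms", "t2_ms"))
  structure(list(k = k, weights = weights, means = means, covs = covs,
                 loglik = loglik, n_iter = it, converged = converged,
                 seed = as.integer(seed), standardize = standardize),
            class = "qti_gmm")
}

pop_cov <- function(x, mu) {
  xc <- sweep(x, 2L, mu)
  crossprod(xc) / nrow(x)
}

regularize_cov <- function(sig) {
  ok <- tryCatch({ chol(sig); TRUE }, error = function(e) FALSE)
  if (!ok || min(diag(sig)) <= 0) {
    message("near-singular component covariance regularized")
    sig <- sig + diag(2L) * (1e-6 * sum(diag(sig)) + 1e-12)
  }
  sig
}

# log-density of a bivariate normal, closed form
dmvnorm2_log <- function(x, mu, sig) {
  a <- sig[1, 1]; b <- sig[1, 2]; d <- sig[2, 2]
  det_s <- a * d - b * b
  dx <- x[, 1L] - mu[1L]; dy <- x[, 2L] - mu[2L]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

#' @export
print.qti_gmm <- function(x, ...) {
  cat(sprintf("T1-T2 Gaussian mixture, k = %d (loglik %.4g, %d EM iterations%s)\n",
              x$k, x$loglik, x$n_iter,
              if (x$converged) "" else ", not converged"))
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: weight %.3f, mean T1 %.0f ms, mean T2 %.0f ms\n",
                j, x$weights[j], x$means[j, 1L], x$means[j, 2L]))
  invisible(x)
}

#' Posterior probabilities of a fitted T1-T2 mixture
#' @param model a `qti_gmm`.
#' @param samples matrix with two columns (T1, T2) in ms.
#' @return matrix (samples x k) of posterior component probabilities.
#' @export
gmm_posterior <- function(model, samples) {
  stopifnot(inherits(model, "qti_gmm"))
  x <- as.matrix(samples)
  n <- nrow(x)
  logd <- vapply(seq_len(model$k), function(j)
    log(model$weights[j]) + dmvnorm2_log(x, model$means[j, ],
                                         model$covs[, , j]),
    numeric(n))
  if (!is.matrix(logd)) logd <- matrix(logd, nrow = n)
  m <- apply(logd, 1L, max)
  p <- exp(logd - m)
  p / rowSums(p)
}

#' Back-project a fitted mixture to the image volume
#'
#' Assigns every in-mask voxel the maximum-posterior component (1 = solid-like
#' core I, 2 = fluid-like core II when fitted on the necrotic/non-enhancing
#' ROI); out-of-mask voxels are 0. Deterministic given the fitted model.
#'
#' @param model a fitted `qti_gmm`.
#' @param maps a [qti_maps()] object.
#' @param mask logical array selecting the voxels to classify.
#' @return integer array of the maps' shape with labels in `{0, 1, ..., k}`.
#' @export
classify_voxels <- function(model, maps, mask) {
  stopifnot(inherits(model, "qti_gmm"), inherits(maps, "qti_maps"))
  mask <- array(as.logical(mask), dim(maps$t1))
  out <- array(0L, dim(maps$t1))
  if (any(mask)) {
    s <- cbind(maps$t1[mask], maps$t2[mask])
    p <- gmm_posterior(model, s)
    out[mask] <- max.col(p, ties.method = "first")
  }
  out
}

#' Export a fitted mixture as JSON
#' @param model a `qti_gmm`.
#' @param path output path.
#' @return `path` / the restored `qti_gmm`.
#' @export
save_gmm <- function(model, path) {
  stopifnot(inherits(model, "qti_gmm"))
  obj <- unclass(model)
  obj$covs <- lapply(seq_len(model$k), function(j) model$covs[, , j])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gmm
#' @export
load_gmm <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  k <- as.integer(obj$k)
  covs <- array(0, c(2L, 2L, k))
  for (j in seq_len(k))
    covs[, , j] <- matrix(unlist(obj$covs[[j]]), 2L, 2L, byrow = TRUE)
  means <- do.call(rbind, lapply(obj$means, unlist))
  dimnames(means) <- list(NULL, c("t1_ms", "t2_ms"))
  structure(list(k = k, weights = as.numeric(unlist(obj$weights)),
                 means = means, covs = covs,
                 loglik = as.numeric(obj$loglik),
                 n_iter = as.integer(obj$n_iter),
                 converged = isTRUE(obj$converged),
                 seed = as.integer(obj$seed),
                 standardize = isTRUE(obj$standardize)),
            class = "qti_gmm")
}
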