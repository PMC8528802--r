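#' Reference tissue classes for the digital brain-tumor phantom
#'
#' Per-tissue (T1, T2) distributions for contralateral white and gray matter,
#' peritumoral edema, enhancing tumor and the two necrotic/non-enhancing tumor
#' core subcomponents (core I, solid-like; core II, fluid-like), as measured
#' at 3T in a glioma cohort. CSF relaxation values and the per-tissue proton
#' densities are not part of that summary; they are implementer defaults from
#' standard 3T literature ranges, exposed here for configuration.
#'
#' @return data.frame with one row per tissue class: `name`, `label`,
#'   `t1_mean`, `t1_std`, `t2_mean`, `t2_std` (ms), `pd_mean`, `pd_std` (a.u.).
#' @export
default_tissues <- function() {
  data.frame(
    name = c("WM", "GM", "CSF", "edema", "enhancing", "core_I", "core_II"),
    label = 1:7,
    t1_mean = c(903, 1353, 4000, 1369, 1685, 1550, 2188),
    t1_std  = c(76,  184,  200,  264,  340,  195,  375),
    t2_mean = c(46,  66,   1500, 91,   111,  92,   297),
    t2_std  = c(11,  24,   150,  35,   70,   38,   111),
    pd_mean = c(0.70, 0.85, 1.00, 0.95, 0.90, 0.90, 1.00),
    pd_std  = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic brain-tumor phantom
#'
#' Parametric geometry standing in for a patient volume: an ellipsoidal brain
#' (gray-matter shell around a white-matter interior, with ellipsoidal CSF
#' ventricles) plus a spherical tumor complex — a core I blob containing a
#' smaller core II blob, an enhancing rim around the core and a peritumoral
#' edema shell around that. Per-voxel T1 and T2 are drawn independently from
#' each tissue's normal distribution truncated to the dictionary ranges
#' ([10, 5000] ms for T1, [10, 2000] ms for T2), so every phantom voxel is
#' matchable; PD is truncated at 0. The draw is deterministic given the seed.
#'
#' @param shape integer vector of length 2 or 3, each entry >= 16.
#' @param tissues tissue table as from [default_tissues()].
#' @param seed RNG seed.
#' @param geometry named list overriding the default geometry (fractions of
#'   the matrix size): `brain_radius`, `gm_thickness`, `ventricle_radius`,
#'   `tumor_center`, `core_radius`, `core2_radius`, `rim_thickness`,
#'   `edema_thickness`.
#' @param voxel_size_mm voxel size recorded in the maps.
#' @param smooth_sigma optional Gaussian smoothing (in voxels) of the drawn
#'   parameter fields for spatial texture; 0 (default) keeps the draw
#'   statistics exact.
#' @return object of class `qti_phantom`: `labels` (integer array, 0 =
#'   background), `maps` (ground-truth [qti_maps()]), `roi_masks` (named list
#'   of logical arrays, including the combined `necrotic_nonenhancing` ROI),
#'   `tissues`, `seed`, `geometry`.
#' @export
make_phantom <- function(shape = c(64L, 64L), tissues = default_tissues(),
                         seed = 1L, geometry = list(), voxel_size_mm = 1.125,
                         smooth_sigma = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 16L))
  geo <- utils::modifyList(list(
    brain_radius = 0.42, gm_thickness = 0.08, ventricle_radius = 0.08,
    tumor_center = c(0.15, 0.10, 0), core_radius = 0.10,
    core2_radius = 0.05, rim_thickness = 0.035, edema_thickness = 0.09),
    geometry)
  d <- length(shape)
  grid <- coord_grid(shape)                       # voxels x d in [-0.5, 0.5)

  ell <- function(center, radii) {
    radii <- rep_len(radii, d)
    rowSums(sweep(sweep(grid, 2L, center[seq_len(d)]), 2L, radii, `/`)^2) <= 1
  }
  labels <- integer(nrow(grid))
  lab <- function(nm) tissues$label[tissues$name == nm]

  brain <- ell(rep(0, d), geo$brain_radius)
  wm_core <- ell(rep(0, d), geo$brain_radius - geo$gm_thickness)
  labels[brain] <- lab("GM")
  labels[wm_core] <- lab("WM")
  vr <- geo$ventricle_radius
  labels[ell(c(-0.10, -0.05, 0), c(vr, 1.6 * vr, vr))] <- lab("CSF")
  labels[ell(c(0.10, -0.05, 0), c(vr, 1.6 * vr, vr))] <- lab("CSF")

  tc <- geo$tumor_center
  r_edema <- geo$core_radius + geo$rim_thickness + geo$edema_thickness
  r_rim <- geo$core_radius + geo$rim_thickness
  if (sqrt(sum(tc[seq_len(d)]^2)) + r_edema > geo$brain_radius)
    stop("tumor complex does not fit inside the brain")
  labels[ell(tc, r_edema)] <- lab("edema")
  labels[ell(tc, r_rim)] <- lab("enhancing")
  labels[ell(tc, geo$core_radius)] <- lab("core_I")
  labels[ell(tc, geo$core2_radius)] <- lab("core_II")

  set.seed(seed)
  t1 <- t2 <- pd <- numeric(nrow(grid))
  for (i in seq_len(nrow(tissues))) {
    v <- labels == tissues$label[i]
    n <- sum(v)
    if (!n) next
    t1[v] <- rtruncnorm(n, tissues$t1_mean[i], tissues$t1_std[i], 10, 5000)
    t2[v] <- rtruncnorm(n, tissues$t2_mean[i], tissues$t2_std[i], 10, 2000)
    pd[v] <- rtruncnorm(n, tissues$pd_mean[i], tissues$pd_std[i], 0, Inf)
  }
  t1 <- array(t1, shape); t2 <- array(t2, shape); pd <- array(pd, shape)
  labels <- array(labels, shape)
  if (smooth_sigma > 0) {
    t1 <- gauss_smooth(t1, smooth_sigma)
    t2 <- gauss_smooth(t2, smooth_sigma)
    pd <- gauss_smooth(pd, smooth_sigma)
    bg <- labels == 0L
    t1[bg] <- 0; t2[bg] <- 0; pd[bg] <- 0
  }

  roi <- stats::setNames(
    lapply(tissues$label, function(l) labels == l), tissues$name)
  roi$necrotic_nonenhancing <- roi$core_I | roi$core_II

  structure(list(
    labels = labels,
    maps = qti_maps(t1, t2, pd, voxel_size_mm = voxel_size_mm,
                    mask = labels > 0L),
    roi_masks = roi, tissues = tissues, seed = as.integer(seed),
    geometry = geo),
    class = "qti_phantom")
}

#' @export
print.qti_phantom <- function(x, ...) {
  cat(sprintf("Brain-tumor phantom %s (seed %d): %d tissue classes, %d in-brain voxels\n",
              paste(dim(x$labels), collapse = "x"), x$seed,
              nrow(x$tissues), sum(x$labels > 0L)))
  invisible(x)
}

# truncated-normal draws via the inverse-CDF of the untruncated normal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# separable Gaussian smoothing (reflective edges) used for optional texture
gauss_smooth <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  dims <- dim(arr)
  for (ax in seq_along(dims)) {
    n <- dims[ax]
    perm <- c(ax, seq_along(dims)[-ax])
    m <- aperm(arr, perm)
    dim(m) <- c(n, prod(dims[-ax]))
    idx <- outer(-r:r, seq_len(n), `+`)
    idx <- abs(idx - 1L) %% (2L * n - 2L) + 1L     # reflect
    idx[idx > n] <- 2L * n - idx[idx > n]
    sm <- matrix(0, n, ncol(m))
    for (i in seq_len(2L * r + 1L))
      sm <- sm + k[i] * m[idx[i, ], , drop = FALSE]
    dim(sm) <- dims[perm]
    arr <- aperm(sm, order(perm))
  }
  arr
}

#' Export / import a phantom as NIfTI volumes plus a JSON manifest
#'
#' Writes `labels`, `t1`, `t2`, `pd` and one file per ROI mask as NIfTI, and a
#' `manifest.json` with the tissue table, seed, geometry and voxel size. A
#' round trip reproduces the phantom up to floating-point storage precision.
#'
#' @param phantom a `qti_phantom`.
#' @param dir target directory.
#' @return the directory / the restored `qti_phantom`.
#' @export
export_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "qti_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$maps$voxel_size_mm
  write_volume(phantom$labels, file.path(dir, "labels.nii"), vs)
  write_maps(phantom$maps, dir)
  for (nm in names(phantom$roi_masks))
    write_volume(phantom$roi_masks[[nm]] + 0,
                 file.path(dir, paste0("roi_", nm, ".nii")), vs)
  jsonlite::write_json(
    list(seed = phantom$seed, geometry = phantom$geometry,
         tissues = phantom$tissues, voxel_size_mm = vs,
         shape = dim(phantom$labels),
         roi_names = names(phantom$roi_masks)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_phantom
#' @export
import_phantom <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  need <- c("labels.nii", "t1.nii", "t2.nii", "pd.nii")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing phantom files: ", paste(missing, collapse = ", "))
  labels <- read_volume(file.path(dir, "labels.nii"))
  maps <- read_maps(dir)
  roi <- stats::setNames(lapply(mf$roi_names, function(nm) {
    p <- file.path(dir, paste0("roi_", nm, ".nii"))
    if (!file.exists(p)) stop("missing ROI mask file: ", p)
    read_volume(p)$data > 0
  }), mf$roi_names)
  structure(list(labels = array(as.integer(round(labels$data)),
                                dim(labels$data)),
                 maps = maps, roi_masks = roi,
                 tissues = as.data.frame(mf$tissues),
                 seed = as.integer(mf$seed), geometry = mf$geometry),
            class = "qti_phantom")
}
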