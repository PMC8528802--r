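#' Quantitative parameter maps
#'
#' Container for voxelwise T1, T2 and proton-density volumes (2D or 3D), the
#' central product of the pipeline.
#'
#' @param t1,t2,pd numeric arrays of equal shape; T1 and T2 in ms, PD in
#'   arbitrary units. Non-negative; zeros mark background.
#' @param voxel_size_mm isotropic voxel size in mm (> 0).
#' @param mask logical array of the same shape (default: voxels with t1 > 0).
#' @return object of class `qti_maps`.
#' @export
qti_maps <- function(t1, t2, pd, voxel_size_mm = 1.125, mask = NULL) {
  t1 <- as.array(t1); t2 <- as.array(t2); pd <- as.array(pd)
  stopifnot(identical(dim(t1), dim(t2)), identical(dim(t1), dim(pd)),
            voxel_size_mm > 0)
  if (any(t1 < 0, na.rm = TRUE) || any(t2 < 0, na.rm = TRUE) ||
      any(pd < 0, na.rm = TRUE))
    stop("parameter maps must be non-negative")
  if (is.null(mask)) mask <- t1 > 0
  mask <- array(as.logical(mask), dim(t1))
  structure(list(t1 = t1, t2 = t2, pd = pd,
                 voxel_size_mm = as.numeric(voxel_size_mm), mask = mask),
            class = "qti_maps")
}

#' @export
print.qti_maps <- function(x, ...) {
  cat(sprintf("Quantitative maps %s, %.4g mm voxels, %d in-mask voxels\n",
              paste(dim(x$t1), collapse = "x"), x$voxel_size_mm,
              sum(x$mask)))
  invisible(x)
}

# write a (possibly 2D) array as NIfTI with the voxel size in the header
write_volume <- function(arr, path, voxel_size_mm) {
  d <- dim(arr)
  if (length(d) == 2L) dim(arr) <- c(d, 1L)
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(-1, rep(voxel_size_mm, 3L), 0, 0, 0, 0)))
  img <- RNifti::asNifti(unclass(arr) + 0, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))    # plain array, header stripped
  d <- dim(arr)
  if (length(d) == 3L && d[3L] == 1L) dim(arr) <- d[1:2]
  list(data = arr, voxel_size_mm = RNifti::pixdim(img)[1L])
}

#' Write / read quantitative maps as NIfTI volumes
#'
#' Writes `t1.nii`, `t2.nii`, `pd.nii` and `mask.nii` into a
#' directory, with the voxel size recorded in the headers.
#'
#' @param maps a `qti_maps`.
#' @param dir target directory (created if needed).
#' @return the directory / the restored `qti_maps`.
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "qti_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(maps$t1, file.path(dir, "t1.nii"), maps$voxel_size_mm)
  write_volume(maps$t2, file.path(dir, "t2.nii"), maps$voxel_size_mm)
  write_volume(maps$pd, file.path(dir, "pd.nii"), maps$voxel_size_mm)
  write_volume(maps$mask + 0, file.path(dir, "mask.nii"), maps$voxel_size_mm)
  invisible(dir)
}

#' @rdname write_maps
#' @export
read_maps <- function(dir) {
  t1 <- read_volume(file.path(dir, "t1.nii"))
  t2 <- read_volume(file.path(dir, "t2.nii"))
  pd <- read_volume(file.path(dir, "pd.nii"))
  mk <- read_volume(file.path(dir, "mask.nii"))
  qti_maps(t1$data, t2$data, pd$data, voxel_size_mm = t1$voxel_size_mm,
           mask = mk$data > 0)
}
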