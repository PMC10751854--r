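# Calibrated CT volume container: 3D HU array + voxel-index -> mm affine.

#' Create a CT volume
#'
#' Holds a 3D array of calibrated Hounsfield Units together with a 4 x 4 affine
#' mapping 0-based voxel indices to world mm coordinates. The affine maps the
#' voxel CENTER: world = A %*% c(i, j, k, 1) for the center of voxel (i,j,k).
#'
#' @param data 3D numeric array of HU values (finite).
#' @param affine 4 x 4 voxel-index-to-mm matrix (invertible, positive spacing).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, affine) {
  if (length(dim(data)) != 3L)
    stop("CT volume must be a 3D scalar image")
  affine <- matrix(as.double(affine), 4, 4)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("voxel spacing must be strictly positive")
  if (!all(is.finite(data))) stop("HU values must be finite")
  structure(list(data = data, affine = affine),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel spacing derived from the affine
#' @param ct a `ct_volume`.
#' @return numeric length-3 vector (dx, dy, dz) in mm.
#' @export
voxel_spacing <- function(ct) {
  sqrt(colSums(ct$affine[1:3, 1:3]^2))
}

#' Voxel volume in mL
#' @param ct a `ct_volume`.
#' @return scalar voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(ct) {
  abs(det(ct$affine[1:3, 1:3])) / 1000
}

# World-mm coordinates of all voxel centers (N x 3, column-major voxel order).
voxel_centers <- function(ct) {
  d <- dim(ct$data)
  i <- (seq_len(d[1]) - 1)
  j <- (seq_len(d[2]) - 1)
  k <- (seq_len(d[3]) - 1)
  idx <- cbind(rep(i, times = d[2] * d[3]),
               rep(rep(j, each = d[1]), times = d[3]),
               rep(k, each = d[1] * d[2]))
  sweep(idx %*% t(ct$affine[1:3, 1:3]), 2, ct$affine[1:3, 4], `+`)
}

# Mesh vertices mapped into continuous 0-based voxel-index space.
world_to_index <- function(points, ct) {
  inv <- solve(ct$affine)
  p1 <- cbind(points, 1)
  (p1 %*% t(inv))[, 1:3, drop = FALSE]
}

#' Read a CT volume from NIfTI
#'
#' HU values are assumed already calibrated (rescale slope/intercept applied by
#' the writer, per the NIfTI standard handled by RNifti).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return a `ct_volume`.
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("CT volume must be a 3D scalar image, got ", length(dim(img)), "D")
  aff <- RNifti::xform(img)
  if (is.null(aff)) stop("NIfTI image carries no affine")
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))
  ct_volume(arr, matrix(aff, 4, 4))
}

#' Write a CT volume to NIfTI
#' @param ct a `ct_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(ct, path) {
  img <- RNifti::asNifti(ct$data)
  img <- RNifti::`sform<-`(img, structure(ct$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
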