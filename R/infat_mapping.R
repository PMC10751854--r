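# inFAT mapping: wall voxel mask between the shells, HU-threshold fat
# classification, and the volume / intensity / normalised summary metrics.

#' HU thresholds for inFAT classification
#'
#' Defaults follow the published ranges: inFAT is wall tissue with HU in
#' [-194, -5]; dense inFAT occupies [-194, -50] and fat-myocardium admixture
#' (-50, -5]. Both subranges are quoted inclusive at -50, which would double
#' count that boundary; here -50 HU is assigned to the dense class so that the
#' two subranges partition the inFAT range exactly (no overlap, no gap) and
#' dense + admixture = inFAT holds as exact voxel arithmetic.
#'
#' @param infat_low,infat_high inFAT range bounds (HU).
#' @param dense_high dense/admixture boundary (HU).
#' @return an object of class `hu_thresholds`.
#' @export
hu_thresholds <- function(infat_low = -194, dense_high = -50, infat_high = -5) {
  if (!(infat_low < dense_high && dense_high < infat_high))
    stop("thresholds must satisfy infat_low < dense_high < infat_high")
  structure(list(infat_low = infat_low, dense_high = dense_high,
                 infat_high = infat_high), class = "hu_thresholds")
}

#' Build the wall voxel mask between the two shells
#'
#' A voxel belongs to the wall when its center lies inside the epicardial
#' shell and outside the endocardial shell (watertight scanline parity test in
#' voxel-index space). When a landmark set is supplied, the appendage, mitral
#' valve and distal pulmonary veins (beyond `exclusion_mm` from the ostium
#' planes) are removed via [apply_exclusions()].
#'
#' @param ct a `ct_volume`.
#' @param endo,epi closed `surface_mesh` shells (endo strictly inside epi).
#' @param landmarks optional `landmark_set` (on `epi`).
#' @param exclusion_mm PV exclusion distance from the ostium plane (mm).
#' @return an object of class `wall_mask`: logical array (`$mask`) plus voxel
#'   bookkeeping.
#' @export
build_wall_mask <- function(ct, endo, epi, landmarks = NULL, exclusion_mm = 5) {
  if (!is_closed_manifold(endo) || !is_closed_manifold(epi))
    stop("shells must be closed 2-manifold surfaces")
  nn <- point_mesh_distance(endo$vertices, epi)
  inside <- points_in_mesh(endo$vertices, epi) | nn$distance <= 1e-9
  if (!all(inside))
    stop("shells intersect: endocardial vertex ", which(!inside)[1],
         " lies outside the epicardial shell")
  d <- dim(ct$data)
  in_epi <- cpp_voxelize(world_to_index(epi$vertices, ct), epi$faces,
                         d[1], d[2], d[3])
  in_endo <- cpp_voxelize(world_to_index(endo$vertices, ct), endo$faces,
                          d[1], d[2], d[3])
  mask <- array(in_epi & !in_endo, d)
  message(sprintf("wall mask: %d voxels between shells (%.2f mL)",
                  sum(mask), sum(mask) * voxel_volume_ml(ct)))
  wm <- structure(list(mask = mask, voxel_volume_ml = voxel_volume_ml(ct),
                       exclusion_mm = exclusion_mm),
                  class = "wall_mask")
  if (!is.null(landmarks))
    wm <- apply_exclusions(wm, ct, landmarks, epi, exclusion_mm)
  wm
}

#' Remove appendage, mitral valve and distal pulmonary veins from a wall mask
#'
#' Removes wall voxels on the vein side of each PV ostium plane farther than
#' `exclusion_mm` from it, and all voxels beyond the appendage and mitral
#' annulus planes. The plane cut is restricted laterally to the projected
#' (dilated) ostium loop footprint, so only the tubular vein / appendage /
#' valve region is removed.
#'
#' @param wall a `wall_mask`.
#' @param ct the `ct_volume` the mask lives on.
#' @param landmarks a `landmark_set`.
#' @param epi the epicardial `surface_mesh` the loops refer to.
#' @param exclusion_mm PV exclusion distance (mm), default 5.
#' @return the pruned `wall_mask`.
#' @export
apply_exclusions <- function(wall, ct, landmarks, epi, exclusion_mm = 5) {
  idx <- which(wall$mask)
  if (!length(idx)) return(wall)
  ctr <- voxel_centers(ct)[idx, , drop = FALSE]
  drop <- points_excluded(ctr, landmarks, epi, exclusion_mm = exclusion_mm)
  wall$mask[idx[drop]] <- FALSE
  wall$exclusion_mm <- exclusion_mm
  message(sprintf("exclusions: removed %d voxels (appendage/MV/distal PV); %d remain",
                  sum(drop), sum(wall$mask)))
  wall
}

#' Classify wall voxels into fat classes by HU
#'
#' Dense inFAT: HU in [infat_low, dense_high]; fat-myocardium admixture:
#' HU in (dense_high, infat_high]; all other wall voxels are `none`.
#' Voxels outside the wall mask are never classified.
#'
#' @param ct a `ct_volume`.
#' @param wall a `wall_mask`.
#' @param thresholds a [hu_thresholds()].
#' @return integer array matching the volume: 0 none/outside, 1 dense,
#'   2 admixture; class `fat_classes` with the thresholds attached.
#' @export
classify_fat <- function(ct, wall, thresholds = hu_thresholds()) {
  hu <- ct$data
  cls <- array(0L, dim(hu))
  m <- wall$mask
  cls[m & hu >= thresholds$infat_low & hu <= thresholds$dense_high] <- 1L
  cls[m & hu > thresholds$dense_high & hu <= thresholds$infat_high] <- 2L
  structure(cls, class = "fat_classes", thresholds = thresholds,
            voxel_volume_ml = wall$voxel_volume_ml)
}

#' Compute the per-patient inFAT summary metrics
#'
#' Volumes are voxel counts times the voxel volume; mean HU per class is the
#' arithmetic mean over class voxels (reported missing when a class is
#' empty). The six normalised metrics divide each class volume by the LA
#' cavity volume (endocardial mesh volume, divergence theorem) and by the
#' segmented wall volume.
#'
#' @param classes a `fat_classes` array from [classify_fat()].
#' @param ct the `ct_volume`.
#' @param wall the `wall_mask`.
#' @param la_volume_ml LA cavity volume (mL); default from `endo` if given.
#' @param endo optional endocardial mesh used to derive `la_volume_ml`.
#' @return one-row data.frame of class `wall_fat_metrics` with columns
#'   `infat_ml, dense_ml, admix_ml, infat_hu, dense_hu, admix_hu, la_vol_ml,
#'   wall_vol_ml` and the six `*_lavol_au` / `*_wallvol_au` normalised values.
#' @export
compute_metrics <- function(classes, ct, wall, la_volume_ml = NULL,
                            endo = NULL) {
  if (is.null(la_volume_ml)) {
    if (is.null(endo)) stop("supply la_volume_ml or the endocardial mesh")
    la_volume_ml <- mesh_volume(endo) / 1000
  }
  vv <- wall$voxel_volume_ml
  wall_vol <- sum(wall$mask) * vv
  if (wall_vol <= 0) stop("zero wall volume: normalisation undefined")
  n_dense <- sum(classes == 1L)
  n_admix <- sum(classes == 2L)
  hu <- ct$data
  mean_or_na <- function(sel) if (any(sel)) mean(hu[sel]) else NA_real_
  dense_ml <- n_dense * vv
  admix_ml <- n_admix * vv
  infat_ml <- dense_ml + admix_ml
  out <- data.frame(
    infat_ml = infat_ml, dense_ml = dense_ml, admix_ml = admix_ml,
    infat_hu = mean_or_na(classes == 1L | classes == 2L),
    dense_hu = mean_or_na(classes == 1L),
    admix_hu = mean_or_na(classes == 2L),
    la_vol_ml = la_volume_ml, wall_vol_ml = wall_vol,
    infat_lavol_au = infat_ml / la_volume_ml,
    dense_lavol_au = dense_ml / la_volume_ml,
    admix_lavol_au = admix_ml / la_volume_ml,
    infat_wallvol_au = infat_ml / wall_vol,
    dense_wallvol_au = dense_ml / wall_vol,
    admix_wallvol_au = admix_ml / wall_vol)
  class(out) <- c("wall_fat_metrics", "data.frame")
  out
}
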