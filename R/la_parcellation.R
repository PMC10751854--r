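# 19-segment anatomical parcellation of the LA epicardial shell.
#
# Band regions (PV antra, carinae, ridge) are defined by geodesic distance to
# the landmark loops on the mesh edge graph; the remaining wall sectors
# (posterior, floor, septal, anterior, left lateral) are defined in a
# landmark-derived anatomical frame, with equal-split internal subdivision.
# Every retained face receives exactly one label, so the labels partition the
# shell by construction, and all ingredients (loop distances, frame axes)
# are equivariant under rigid motion of mesh + landmarks.

#' Names of the 19 LA segments
#' @return data.frame with `label` (1..19) and `name`.
#' @export
la_segment_names <- function() {
  data.frame(label = 1:19, name = c(
    "posterior wall (superior-left)", "posterior wall (superior-right)",
    "posterior wall (inferior-left)", "posterior wall (inferior-right)",
    "floor (left)", "floor (right)",
    "septal wall",
    "anterior wall (superior-left)", "anterior wall (superior-right)",
    "anterior wall (inferior-left)", "anterior wall (inferior-right)",
    "left lateral wall",
    "left carina", "right carina",
    "LIPV antrum", "LSPV antrum",
    "LA ridge",
    "RIPV antrum", "RSPV antrum"))
}

PV_SEGMENT <- c(LSPV = 16L, LIPV = 15L, RSPV = 19L, RIPV = 18L)

# Geodesic distance from every mesh vertex to the nearest vertex of each loop
# (Dijkstra on the edge graph with exact edge lengths).
loop_geodesics <- function(mesh, landmarks) {
  f <- mesh$faces
  e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]))
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  out <- lapply(landmarks$loops, function(idx) {
    dm <- igraph::distances(g, v = idx, algorithm = "dijkstra")
    apply(dm, 2, min)
  })
  names(out) <- names(landmarks$loops)
  out
}

# Anatomical frame (left, posterior, superior unit axes + center) from the
# landmark set: taken from the stored axes when present, else derived from
# the loop geometry (PV centroids vs body center, superior vs inferior PVs).
anatomical_frame <- function(mesh, landmarks) {
  ctr <- colMeans(mesh$vertices)
  if (!is.null(landmarks$axes)) {
    ax <- landmarks$axes
    return(list(center = ctr,
                left = ax$left / sqrt(sum(ax$left^2)),
                posterior = ax$posterior / sqrt(sum(ax$posterior^2)),
                superior = ax$superior / sqrt(sum(ax$superior^2))))
  }
  lc <- lapply(names(PV_SEGMENT), function(nm)
    colMeans(loop_coords(landmarks, nm, mesh)))
  names(lc) <- names(PV_SEGMENT)
  mv <- colMeans(loop_coords(landmarks, "MV", mesh))
  post <- (lc$LSPV + lc$LIPV + lc$RSPV + lc$RIPV) / 4 - ctr
  post <- post / sqrt(sum(post^2))
  sup <- (lc$LSPV + lc$RSPV) / 2 - (lc$LIPV + lc$RIPV) / 2
  sup <- sup - sum(sup * post) * post
  sup <- sup / sqrt(sum(sup^2))
  lft <- c(post[2] * sup[3] - post[3] * sup[2],
           post[3] * sup[1] - post[1] * sup[3],
           post[1] * sup[2] - post[2] * sup[1])
  if (sum(lft * ((lc$LSPV + lc$LIPV) / 2 - ctr)) < 0) lft <- -lft
  # re-orthogonalise sup against the plane of post/lft handedness
  list(center = ctr, left = lft, posterior = post, superior = sup)
}

#' Parcellate the LA epicardial shell into 19 segments
#'
#' Faces on the appendage / mitral-valve side of their ostium planes and the
#' distal pulmonary veins (beyond `exclusion_mm` of the PV ostium planes) are
#' excluded (label 0). PV antra are the retained ostium collars plus faces
#' within `antrum_mm` geodesic distance of the ostium loop; the carinae are
#' the bands within `band_mm` of both ipsilateral PV loops; the LA ridge is
#' the band between the LSPV antrum and the appendage boundary. Remaining
#' faces are assigned to posterior wall (1-4, 2x2 equal split), floor (5-6),
#' septal wall (7), anterior wall incl. roof (8-11, 2x2), and left lateral
#' wall (12) in the landmark-derived anatomical frame.
#'
#' @param epi epicardial `surface_mesh`.
#' @param landmarks `landmark_set` on `epi`.
#' @param exclusion_mm distal-PV exclusion distance (mm), default 5.
#' @param antrum_mm geodesic antrum width on the atrial body (mm).
#' @param band_mm geodesic half-width for carina/ridge bands (mm).
#' @return an object of class `segment_model`: per-face `face_label`
#'   (0 = excluded, 1..19 otherwise), `names`, face areas, and the mesh.
#' @export
parcellate <- function(epi, landmarks, exclusion_mm = 5,
                       antrum_mm = 5, band_mm = 8) {
  fc <- face_centroids(epi)
  nf <- nrow(fc)
  geo_v <- loop_geodesics(epi, landmarks)
  # face distance to a loop = min over its vertices
  geo_f <- lapply(geo_v, function(dv)
    pmin(dv[epi$faces[, 1]], dv[epi$faces[, 2]], dv[epi$faces[, 3]]))

  label <- rep(NA_integer_, nf)
  excl <- points_excluded(fc, landmarks, epi, exclusion_mm = exclusion_mm)
  label[excl] <- 0L

  # PV antra: retained collar (not excluded, on the vein side) is captured by
  # geodesic proximity to the ostium loop; nearest PV loop wins.
  pv_d <- do.call(cbind, geo_f[names(PV_SEGMENT)])
  near_pv <- apply(pv_d, 1, min)
  which_pv <- apply(pv_d, 1, which.min)
  # collar faces sit on the vein side within exclusion_mm of the plane; their
  # geodesic distance to the loop is at most exclusion_mm plus funnel slack
  is_antrum <- is.na(label) & near_pv <= antrum_mm + exclusion_mm * 0.999 &
    vein_side_face(fc, landmarks)
  is_antrum <- is_antrum | (is.na(label) & near_pv <= antrum_mm)
  label[is_antrum] <- PV_SEGMENT[which_pv[is_antrum]]

  # LA ridge: band between the LSPV antrum and the appendage boundary.
  ridge <- is.na(label) & geo_f$LAA <= band_mm & geo_f$LSPV <= band_mm
  label[ridge] <- 17L
  # carinae: bands between ipsilateral PV ostia.
  label[is.na(label) & geo_f$LSPV <= band_mm & geo_f$LIPV <= band_mm] <- 13L
  label[is.na(label) & geo_f$RSPV <= band_mm & geo_f$RIPV <= band_mm] <- 14L

  # wall sectors in the anatomical frame
  fr <- anatomical_frame(epi, landmarks)
  rel <- sweep(fc, 2, fr$center)
  px <- as.vector(rel %*% fr$left)
  py <- as.vector(rel %*% fr$posterior)
  pz <- as.vector(rel %*% fr$superior)
  lco <- function(nm) {
    v <- sweep(loop_coords(landmarks, nm, epi), 2, fr$center)
    list(x = v %*% fr$left, z = v %*% fr$superior)
  }
  l_s <- lco("LSPV"); l_i <- lco("LIPV"); r_s <- lco("RSPV"); r_i <- lco("RIPV")
  z_top <- (max(l_s$z) + max(r_s$z)) / 2   # superior edges of superior PVs
  z_bot <- (min(l_i$z) + min(r_i$z)) / 2   # inferior edges of inferior PVs
  x_l <- (min(l_s$x) + min(l_i$x)) / 2     # medial edge of the left PV column
  x_r <- (max(r_s$x) + max(r_i$x)) / 2     # medial edge of the right PV column
  x_mid <- (x_l + x_r) / 2
  z_mid <- (z_top + z_bot) / 2

  # epsilon-tolerant comparisons: mesh symmetries can place face centroids
  # exactly on a derived boundary, where raw float comparison would not be
  # rigid-motion invariant
  eps <- 1e-9
  ge <- function(a, b) a >= b - eps
  le <- function(a, b) a <= b + eps
  todo <- which(is.na(label))
  for (i in todo) {
    if (ge(py[i], 0) && le(pz[i], z_top) && ge(pz[i], z_bot) &&
        le(px[i], x_l) && ge(px[i], x_r)) {
      # posterior wall 2x2: 1 sup-left, 2 sup-right, 3 inf-left, 4 inf-right
      label[i] <- if (ge(pz[i], z_mid)) (if (ge(px[i], x_mid)) 1L else 2L)
                  else (if (ge(px[i], x_mid)) 3L else 4L)
    } else if (ge(py[i], 0) && !ge(pz[i], z_bot)) {
      label[i] <- if (ge(px[i], x_mid)) 5L else 6L     # floor left / right
    } else if (!ge(px[i], x_r) && !ge(pz[i], z_top)) {
      label[i] <- 7L                                   # septal wall
    } else if (!le(px[i], x_l) && !ge(pz[i], z_mid)) {
      label[i] <- 12L                                  # left lateral wall
    } else {
      # anterior wall incl. roof, 2x2 split
      label[i] <- if (ge(pz[i], z_mid)) (if (ge(px[i], x_mid)) 8L else 9L)
                  else (if (ge(px[i], x_mid)) 10L else 11L)
    }
  }
  structure(list(face_label = label, names = la_segment_names(),
                 face_areas = mesh_face_areas(epi), mesh = epi),
            class = "segment_model")
}

# TRUE for faces on the positive (vein) side of any PV ostium plane within
# its loop footprint: the retained antral collars.
vein_side_face <- function(fc, landmarks) {
  out <- rep(FALSE, nrow(fc))
  for (nm in names(PV_SEGMENT)) {
    pl <- landmarks$planes[[nm]]
    d <- as.vector((fc - matrix(pl$point, nrow(fc), 3, byrow = TRUE)) %*% pl$normal)
    out <- out | d > 0
  }
  out
}

#' @export
print.segment_model <- function(x, ...) {
  tb <- table(factor(x$face_label, levels = 0:19))
  cat(sprintf("<segment_model> %d faces: %d excluded, %d segments non-empty\n",
              length(x$face_label), tb["0"], sum(tb[-1] > 0)))
  invisible(x)
}

#' Summarise a parcellation
#' @param object a `segment_model`.
#' @param ... unused.
#' @return data.frame with label, name, face count and area per segment.
#' @export
summary.segment_model <- function(object, ...) {
  nm <- object$names
  data.frame(
    label = nm$label, name = nm$name,
    n_faces = vapply(nm$label, function(l) sum(object$face_label == l), integer(1)),
    area_mm2 = vapply(nm$label, function(l)
      sum(object$face_areas[object$face_label == l]), numeric(1)))
}

#' Label wall voxels by segment
#'
#' Each wall voxel inherits the label of the nearest labeled (non-excluded)
#' epicardial face center; ties break to the lowest face index.
#'
#' @param segments a `segment_model`.
#' @param wall a `wall_mask`.
#' @param ct the `ct_volume` the mask lives on.
#' @return integer array: 0 outside the wall, 1..19 inside.
#' @export
label_wall_voxels <- function(segments, wall, ct) {
  lab <- array(0L, dim(wall$mask))
  idx <- which(wall$mask)
  if (!length(idx)) return(lab)
  fc <- face_centroids(segments$mesh)
  keep <- segments$face_label > 0
  nearest <- cpp_nearest_row(voxel_centers(ct)[idx, , drop = FALSE],
                             fc[keep, , drop = FALSE])
  lab[idx] <- segments$face_label[keep][nearest]
  lab
}
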