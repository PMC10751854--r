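# Anatomical landmark sets: PV ostium loops, mitral annulus, LAA ostium,
# ostium planes. Loops are ordered vertex-index lists on the epicardial mesh.

PV_LABELS <- c("LSPV", "LIPV", "RSPV", "RIPV")

#' Create a landmark set
#'
#' Loops are ordered 1-based vertex indices on the epicardial mesh; planes are
#' given explicitly as (point, normal) pairs in mm, with the normal pointing
#' away from the atrial body (toward the vein / appendage / ventricle).
#'
#' @param loops named list with entries `LSPV`, `LIPV`, `RSPV`, `RIPV`
#'   (pulmonary vein ostia), `LAA` (appendage ostium) and `MV` (mitral
#'   annulus), each an integer vector of epicardial vertex indices forming a
#'   simple closed polyline.
#' @param planes named list of `list(point =, normal =)` for each of the four
#'   PVs, `LAA` and `MV`.
#' @param mesh the epicardial `surface_mesh` the loop indices refer to.
#' @param axes optional named list of unit vectors `superior`, `left`,
#'   `posterior` defining the anatomical body frame; when absent the frame is
#'   derived from the loop geometry.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(loops, planes, mesh, axes = NULL) {
  need <- c(PV_LABELS, "LAA", "MV")
  if (!all(need %in% names(loops)))
    stop("missing landmark loops: ", paste(setdiff(need, names(loops)), collapse = ", "))
  if (!all(need %in% names(planes)))
    stop("missing ostium plane for: ", paste(setdiff(need, names(planes)), collapse = ", "))
  nv <- nrow(mesh$vertices)
  for (nm in need) {
    idx <- as.integer(loops[[nm]])
    if (length(idx) < 3L || anyDuplicated(idx))
      stop("loop '", nm, "' is not a simple closed polyline")
    if (any(idx < 1L) || any(idx > nv))
      stop("loop '", nm, "' has vertex indices off the mesh surface")
    loops[[nm]] <- idx
  }
  planes <- lapply(planes, function(p) {
    n <- as.double(p$normal)
    list(point = as.double(p$point), normal = n / sqrt(sum(n^2)))
  })
  structure(list(loops = loops[need], planes = planes[need],
                 axes = axes, n_mesh_vertices = nv),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> loops:",
      paste(sprintf("%s(%d)", names(x$loops), lengths(x$loops)), collapse = " "), "\n")
  invisible(x)
}

# mm coordinates of a named loop.
loop_coords <- function(landmarks, name, mesh) {
  mesh$vertices[landmarks$loops[[name]], , drop = FALSE]
}

#' Read a landmark set from JSON
#' @param path JSON file written by [write_landmarks()].
#' @param mesh the epicardial `surface_mesh` the loops refer to.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path, mesh) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  loops <- c(j$pv_ostia, list(LAA = j$laa_ostium, MV = j$mitral_annulus))
  axes <- if (!is.null(j$axes)) lapply(j$axes, as.double) else NULL
  landmark_set(loops, j$ostium_planes, mesh, axes = axes)
}

#' Write a landmark set to JSON
#' @param landmarks a `landmark_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  j <- list(
    pv_ostia = landmarks$loops[PV_LABELS],
    laa_ostium = landmarks$loops$LAA,
    mitral_annulus = landmarks$loops$MV,
    ostium_planes = landmarks$planes)
  if (!is.null(landmarks$axes)) j$axes <- landmarks$axes
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Exclusion test for arbitrary points: beyond the (dilated-footprint) ostium
# plane of any PV by more than `exclusion_mm`, or beyond the LAA / mitral
# annulus plane at all. The lateral footprint is the ostium loop projected on
# its plane, dilated about its centroid, so the plane cut removes only the
# vein/appendage/valve side and never far-away body wall.
points_excluded <- function(points, landmarks, mesh,
                            exclusion_mm = 5, dilate = 1.6) {
  excl <- rep(FALSE, nrow(points))
  margins <- c(LSPV = exclusion_mm, LIPV = exclusion_mm,
               RSPV = exclusion_mm, RIPV = exclusion_mm, LAA = 0, MV = 0)
  for (nm in names(margins)) {
    pl <- landmarks$planes[[nm]]
    if (is.null(pl)) stop("missing ostium plane for ", nm)
    n <- pl$normal
    d <- as.vector((points - matrix(pl$point, nrow(points), 3, byrow = TRUE)) %*% n)
    cand <- d > margins[[nm]]
    if (!any(cand)) next
    lc <- loop_coords(landmarks, nm, mesh)
    b <- plane_basis(n)
    ctr <- colMeans(lc)
    poly2 <- sweep(lc, 2, ctr) %*% b * dilate
    pts2 <- sweep(points[cand, , drop = FALSE], 2, ctr) %*% b
    inside <- point_in_polygon(pts2, poly2)
    excl[which(cand)[inside]] <- TRUE
  }
  excl
}

# Orthonormal in-plane basis for a unit normal.
plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, v)
}

# Vectorised even-odd point-in-polygon (2D).
point_in_polygon <- function(pts, poly) {
  np <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- np
  x <- pts[, 1]; y <- pts[, 2]
  for (i in seq_len(np)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}
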