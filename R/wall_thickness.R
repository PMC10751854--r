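# Left atrial wall thickness (LAWT): distance from each endocardial vertex to
# its projection on the epicardial shell, with the standard colour binning.

LAWT_BINS <- c("red", "yellow", "green", "blue", "purple")

#' Compute the left atrial wall thickness map
#'
#' Thickness at each endocardial vertex is the Euclidean distance to its
#' projection on the epicardial surface. The default projection is the
#' nearest point on the epicardial mesh (point-to-triangle minimisation);
#' `mode = "normal_ray"` instead casts a ray along the outward vertex normal
#' and uses the first epicardial intersection (falling back to nearest-point
#' where the ray misses). Both definitions coincide on concentric spheres.
#' The mean thickness is area-weighted by barycentric vertex areas so that it
#' is invariant to mesh density.
#'
#' @param endo,epi closed `surface_mesh` shells; `endo` must lie strictly
#'   inside `epi`.
#' @param mode `"nearest"` (default) or `"normal_ray"`.
#' @return an object of class `thickness_map`: list with per-vertex
#'   `thickness_mm`, `colour` bin, `mean_thickness_mm`, and the endocardial
#'   mesh.
#' @export
compute_lawt <- function(endo, epi, mode = c("nearest", "normal_ray")) {
  mode <- match.arg(mode)
  nn <- point_mesh_distance(endo$vertices, epi)
  # vertices exactly on the epicardial surface (endo == epi) are admissible
  inside <- points_in_mesh(endo$vertices, epi) | nn$distance <= 1e-9
  if (!all(inside)) {
    bad <- which(!inside)[1]
    stop("endocardial vertex ", bad, " lies outside the epicardial shell")
  }
  thickness <- nn$distance
  if (mode == "normal_ray") {
    normals <- vertex_normals(endo)
    ray <- ray_mesh_first_hit(endo$vertices, normals, epi)
    hit <- is.finite(ray)
    thickness[hit] <- ray[hit]
  }
  va <- vertex_areas(endo)
  structure(list(thickness_mm = thickness,
                 colour = bin_thickness(thickness),
                 mean_thickness_mm = sum(thickness * va) / sum(va),
                 mode = mode,
                 endo = endo),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d vertices, mean LAWT %.2f mm, range [%.2f, %.2f] mm\n",
              length(x$thickness_mm), x$mean_thickness_mm,
              min(x$thickness_mm), max(x$thickness_mm)))
  invisible(x)
}

#' Colour-bin wall thickness values
#'
#' Half-open bins: red < 1 mm, 1 <= yellow < 2, 2 <= green < 3, 3 <= blue < 4,
#' purple >= 4 mm. Boundary values fall in the upper-named bin.
#'
#' @param t thickness in mm (non-negative).
#' @return factor with levels red/yellow/green/blue/purple.
#' @export
bin_thickness <- function(t) {
  if (any(t < 0)) stop("thickness must be non-negative")
  cut(t, breaks = c(-Inf, 1, 2, 3, 4, Inf), right = FALSE, labels = LAWT_BINS)
}

# Area-weighted outward vertex normals.
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    s <- rowsum(fn, f[, k])
    idx <- as.integer(rownames(s))
    n[idx, ] <- n[idx, ] + s
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# First positive ray-triangle intersection distance per origin (Inf = miss).
ray_mesh_first_hit <- function(origins, dirs, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- rep(Inf, nrow(origins))
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    d <- dirs[i, ]
    a <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - a
    e2 <- v[f[, 3], , drop = FALSE] - a
    # Moller-Trumbore, vectorised over faces
    p <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
               d[3] * e2[, 1] - d[1] * e2[, 3],
               d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * p)
    ok <- abs(det) > 1e-12
    tv <- sweep(-a, 2, o, `+`)
    u <- rowSums(tv * p) / det
    q <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
               tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
               tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    w <- as.vector(q %*% d) / det
    tt <- rowSums(e2 * q) / det
    hit <- ok & u >= 0 & w >= 0 & (u + w) <= 1 & tt > 1e-9
    if (any(hit)) out[i] <- min(tt[hit])
  }
  out
}

#' Write a thickness map (per-vertex PLY scalar + CSV)
#' @param tm a `thickness_map`.
#' @param csv_path per-vertex CSV output (vertex, thickness_mm, colour).
#' @param ply_path optional PLY with a `thickness` vertex property.
#' @return `csv_path`, invisibly.
#' @export
write_thickness_map <- function(tm, csv_path, ply_path = NULL) {
  df <- data.frame(vertex = seq_along(tm$thickness_mm),
                   thickness_mm = tm$thickness_mm,
                   colour = as.character(tm$colour))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(ply_path))
    write_mesh(tm$endo, ply_path,
               vertex_data = data.frame(thickness = tm$thickness_mm))
  invisible(csv_path)
}
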