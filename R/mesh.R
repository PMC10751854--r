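# Triangulated surface meshes: constructor, validation, geometry utilities.

#' Create a triangulated surface mesh
#'
#' Vertices are world (mm) coordinates; faces are 1-based triangle vertex
#' indices. On construction the mesh can be validated as a closed 2-manifold
#' (every undirected edge shared by exactly two faces, consistent winding) and
#' its winding normalised so that the enclosed volume is positive (outward
#' normals).
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param validate check closed-manifoldness and fail otherwise.
#' @param orient flip winding if the signed volume is negative.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE, orient = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (validate && !is_closed_manifold(m))
    stop("mesh is not a closed 2-manifold surface")
  if (orient && mesh_volume(m) < 0) {
    m$faces <- m$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, enclosed volume %.2f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Test whether a mesh is a closed 2-manifold
#'
#' Every undirected edge must be shared by exactly two faces and each directed
#' edge must occur exactly once (consistent winding).
#'
#' @param mesh a `surface_mesh` (or list with `vertices`/`faces`).
#' @return logical scalar.
#' @export
is_closed_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- as.double(max(f))
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  cnt <- table(key)
  if (!all(cnt == 2L)) return(FALSE)
  dkey <- e[, 1] * (nv + 1) + e[, 2]
  !anyDuplicated(dkey)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#'
#' Sum of signed tetrahedron volumes from the origin; positive for outward
#' winding.
#'
#' @param mesh a `surface_mesh`.
#' @return volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c)
  bc <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(a * bc) / 6
}

#' Per-face areas of a triangle mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# Barycentric vertex areas (one third of each incident face area): used for
# mesh-density-invariant averaging of per-vertex scalars.
vertex_areas <- function(mesh) {
  fa <- mesh_face_areas(mesh)
  va <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    s <- rowsum(fa / 3, mesh$faces[, k])
    idx <- as.integer(rownames(s))
    va[idx] <- va[idx] + s[, 1]
  }
  va
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# Unit-sphere icosphere by recursive subdivision of an icosahedron.
# Vertices lie exactly on the unit sphere.
icosphere <- function(subdiv = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- edge_key(e[, 1], e[, 2])
    uk <- unique(keys)
    mid_of <- match(keys, uk) + nv
    ue <- e[!duplicated(keys), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_of[seq_len(nf)]
    m23 <- mid_of[nf + seq_len(nf)]
    m31 <- mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

# Sphere / ellipsoid meshes with vertices exactly on the analytic surface.
ellipsoid_mesh <- function(semiaxes, center = c(0, 0, 0), subdiv = 5L) {
  ico <- icosphere(subdiv)
  v <- sweep(ico$vertices, 2, semiaxes, `*`)
  v <- sweep(v, 2, center, `+`)
  surface_mesh(v, ico$faces)
}

sphere_mesh <- function(radius, center = c(0, 0, 0), subdiv = 5L) {
  ellipsoid_mesh(rep(radius, 3), center, subdiv)
}

# Apply a rigid (or affine) transform to mesh vertices.
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  surface_mesh(v, mesh$faces, validate = FALSE, orient = FALSE)
}

#' Distances from points to a mesh surface
#'
#' Nearest-point (point-to-triangle) distance from each query point to the
#' surface, with the index of the nearest face and the foot point.
#'
#' @param points numeric P x 3 matrix (mm).
#' @param mesh a `surface_mesh`.
#' @return list with `distance`, `face` (1-based) and `point` (P x 3 foot points).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  cpp_point_mesh_dist(points, mesh$vertices, mesh$faces)
}

#' Watertight point-in-mesh test
#'
#' Ray-parity test (ray cast along +x with a fixed deterministic sub-voxel
#' jitter) against a closed mesh.
#'
#' @param points numeric P x 3 matrix (mm).
#' @param mesh a `surface_mesh`.
#' @return logical vector, `TRUE` where the point lies inside.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  cpp_points_in_mesh(points, mesh$vertices, mesh$faces)
}
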