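# ASCII PLY and OBJ surface I/O. All coordinates are world mm.

#' Read a triangulated surface mesh (PLY or OBJ)
#'
#' ASCII PLY and OBJ files are supported. When `role` is `"endo"` or `"epi"`
#' the mesh must be a closed 2-manifold (validation error otherwise); winding
#' is normalised to outward (positive enclosed volume) in all cases.
#'
#' @param path mesh file, format chosen by extension (.ply/.obj).
#' @param role `"endo"`, `"epi"` or `"other"`; shells are validated as closed.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, role = c("other", "endo", "epi")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              ply = read_ply(path),
              obj = read_obj(path),
              stop("unsupported mesh format: .", ext))
  validate <- role %in% c("endo", "epi")
  tryCatch(
    surface_mesh(m$vertices, m$faces, validate = validate, orient = TRUE),
    error = function(e) stop(role, " shell '", basename(path), "': ",
                             conditionMessage(e), call. = FALSE))
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1]), "ply")) stop("not a PLY file")
  if (!any(grepl("^format\\s+ascii", lines))) stop("only ASCII PLY is supported")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face counts")
  # vertex property names, in declared order
  el_lines <- grep("^element ", hdr)
  vstart <- grep("^element vertex", hdr)[1]
  vend <- el_lines[el_lines > vstart]
  vend <- if (length(vend)) min(vend) else hdr_end
  vprops <- sub("^property\\s+\\S+\\s+", "", grep("^property ", hdr[vstart:vend], value = TRUE))
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vlines <- body[seq_len(nv)]
  flines <- body[nv + seq_len(nf)]
  vmat <- matrix(scan(text = vlines, quiet = TRUE), nrow = nv, byrow = TRUE)
  colnames(vmat) <- vprops[seq_len(ncol(vmat))]
  xyz <- vmat[, c("x", "y", "z"), drop = FALSE]
  fnum <- lapply(strsplit(trimws(flines), "\\s+"), as.integer)
  counts <- vapply(fnum, `[`, integer(1), 1)
  if (any(counts != 3L)) stop("only triangulated PLY faces are supported")
  fmat <- t(vapply(fnum, function(r) r[2:4], integer(3))) + 1L
  extra <- vmat[, setdiff(colnames(vmat), c("x", "y", "z")), drop = FALSE]
  list(vertices = xyz, faces = fmat,
       vertex_data = if (ncol(extra)) as.data.frame(extra) else NULL)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("OBJ file has no vertices/faces")
  v <- matrix(scan(text = sub("^v\\s+", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  ftok <- strsplit(sub("^f\\s+", "", fl), "\\s+")
  if (any(lengths(ftok) != 3L)) stop("only triangulated OBJ faces are supported")
  f <- t(vapply(ftok, function(tk) as.integer(sub("/.*$", "", tk)), integer(3)))
  list(vertices = v, faces = f)
}

#' Write a mesh as ASCII PLY
#'
#' Optional per-vertex numeric properties (e.g. a wall-thickness scalar or a
#' segment label) are written as extra vertex properties.
#'
#' @param mesh a `surface_mesh`.
#' @param path output .ply path.
#' @param vertex_data optional data.frame of per-vertex numeric columns.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, vertex_data = NULL) {
  v <- mesh$vertices
  nv <- nrow(v)
  nf <- nrow(mesh$faces)
  props <- c("property double x", "property double y", "property double z")
  vm <- v
  if (!is.null(vertex_data)) {
    stopifnot(nrow(vertex_data) == nv)
    for (nm in names(vertex_data)) {
      props <- c(props, paste("property double", nm))
      vm <- cbind(vm, as.double(vertex_data[[nm]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv), props,
               paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(vm, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}
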