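# Synthetic CT phantoms with analytic two-shell LA-like geometry, planted
# intramyocardial fat deposits and full ground truth.
#
# All three shapes are star-shaped about the origin, so region membership is
# evaluated analytically from the radial surface functions and the meshes are
# radial samplings of the same surfaces (vertices exactly on the analytic
# surface). Noise-free phantoms therefore give exact voxel-count arithmetic.

#' Specify a synthetic CT phantom
#'
#' @param shape `"concentric_spheres"`, `"ellipsoid_shell"` or `"la_like"`
#'   (ellipsoid body + 4 pulmonary-vein tubes + appendage stub + mitral
#'   annulus marker).
#' @param endo_radius endocardial radius (mm), concentric spheres only.
#' @param endo_semiaxes,epi_semiaxes ellipsoid semi-axes (mm);
#'   `endo_semiaxes` also sets the `la_like` body.
#' @param wall_thickness wall thickness (mm): a constant, or a function of
#'   unit direction vectors returning per-direction thickness (smoothly
#'   varying walls). Used by all shapes except `ellipsoid_shell`, whose
#'   epicardium is its own ellipsoid.
#' @param spacing voxel spacing (mm), scalar (isotropic) or length 3.
#' @param hu named list of tissue HU levels: `blood_pool`, `myocardium`,
#'   `epicardial_fat`, `background`.
#' @param noise_sd additive Gaussian noise SD (HU).
#' @param seed integer seed fixing all phantom randomness.
#' @param subdiv icosphere subdivision level of the shell meshes.
#' @param eat_thickness thickness (mm) of the epicardial fat layer outside the
#'   epicardial shell (tests that extra-shell fat is never counted).
#' @param la named list of LA-like geometry parameters (see Details).
#'
#' @details The `la_like` geometry places four PV tubes posteriorly (LSPV,
#' LIPV, RSPV, RIPV), an appendage stub antero-superior-left and a mitral
#' annulus loop infero-anterior, as radial protrusions/markers on the
#' ellipsoid body. `la` entries: `pv_dirs` (4 x 3 unit rows), `pv_alpha_in`,
#' `pv_alpha_out` (funnel inner/outer angular radii, rad), `pv_length` (mm),
#' `laa_dir`, `laa_alpha_in`, `laa_alpha_out`, `laa_length`, `mv_dir`,
#' `mv_alpha`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("concentric_spheres", "ellipsoid_shell", "la_like"),
                         endo_radius = 20,
                         endo_semiaxes = c(30, 28, 26),
                         epi_semiaxes = NULL,
                         wall_thickness = 2,
                         spacing = 0.5,
                         hu = list(blood_pool = 350, myocardium = 40,
                                   epicardial_fat = -100, background = -1000),
                         noise_sd = 10,
                         seed = 1L,
                         subdiv = 5L,
                         eat_thickness = 3,
                         la = list()) {
  shape <- match.arg(shape)
  spacing <- as.double(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0))
  thick_fn <- if (is.function(wall_thickness)) wall_thickness
              else function(u) rep(wall_thickness, nrow(u))
  probe <- thick_fn(icosphere(1L)$vertices)
  if (any(probe <= 0)) stop("thickness field must be > 0 everywhere")
  if (shape == "ellipsoid_shell") {
    if (is.null(epi_semiaxes)) epi_semiaxes <- endo_semiaxes + 2
    if (any(epi_semiaxes <= endo_semiaxes))
      stop("epicardial ellipsoid must strictly contain the endocardial one")
  }
  la_def <- list(
    pv_dirs = rbind(LSPV = c(0.72, 0.58, 0.55),
                    LIPV = c(0.80, 0.58, -0.40),
                    RSPV = c(-0.72, 0.58, 0.55),
                    RIPV = c(-0.80, 0.58, -0.40)),
    pv_alpha_in = 10 * pi / 180, pv_alpha_out = 16 * pi / 180, pv_length = 12,
    laa_dir = c(0.68, -0.38, 0.62),
    laa_alpha_in = 9 * pi / 180, laa_alpha_out = 14 * pi / 180, laa_length = 9,
    mv_dir = c(0, -0.35, -0.94), mv_alpha = 30 * pi / 180)
  la <- modifyList(la_def, la)
  la$pv_dirs <- t(apply(la$pv_dirs, 1, function(d) d / sqrt(sum(d^2))))
  la$laa_dir <- la$laa_dir / sqrt(sum(la$laa_dir^2))
  la$mv_dir <- la$mv_dir / sqrt(sum(la$mv_dir^2))
  structure(list(shape = shape, endo_radius = endo_radius,
                 endo_semiaxes = endo_semiaxes, epi_semiaxes = epi_semiaxes,
                 thickness = thick_fn,
                 constant_thickness = if (is.function(wall_thickness)) NA_real_
                                      else wall_thickness,
                 spacing = spacing, hu = hu, noise_sd = noise_sd,
                 seed = as.integer(seed), subdiv = as.integer(subdiv),
                 eat_thickness = eat_thickness, la = la),
            class = "phantom_spec")
}

# smoothstep on [0,1]
sstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# Radial surface functions (mm radius as a function of unit direction u).
radial_body <- function(u, semiaxes) {
  1 / sqrt(rowSums(sweep(u, 2, semiaxes, `/`)^2))
}

# la_like: body plus PV/LAA funnel bumps.
radial_la_endo <- function(u, spec) {
  la <- spec$la
  r <- radial_body(u, spec$endo_semiaxes)
  bump <- function(d, a_in, a_out, len) {
    ct <- as.vector(u %*% d)
    len * sstep((ct - cos(a_out)) / (cos(a_in) - cos(a_out)))
  }
  for (k in seq_len(nrow(la$pv_dirs)))
    r <- r + bump(la$pv_dirs[k, ], la$pv_alpha_in, la$pv_alpha_out, la$pv_length)
  r + bump(la$laa_dir, la$laa_alpha_in, la$laa_alpha_out, la$laa_length)
}

# Endocardial / epicardial radius for star-shaped phantoms.
phantom_radii <- function(u, spec) {
  t_u <- spec$thickness(u)
  switch(spec$shape,
    concentric_spheres = list(endo = rep(spec$endo_radius, nrow(u)),
                              epi = rep(spec$endo_radius, nrow(u)) + t_u),
    la_like = {
      re <- radial_la_endo(u, spec)
      list(endo = re, epi = re + t_u)
    },
    stop("phantom_radii undefined for shape ", spec$shape))
}

# Analytic membership of arbitrary points (mm) in the endo / epi compartments.
phantom_membership <- function(points, spec) {
  if (spec$shape == "ellipsoid_shell") {
    qe <- rowSums(sweep(points, 2, spec$endo_semiaxes, `/`)^2)
    qE <- rowSums(sweep(points, 2, spec$epi_semiaxes, `/`)^2)
    qf <- rowSums(sweep(points, 2, spec$epi_semiaxes + spec$eat_thickness, `/`)^2)
    return(list(endo = qe < 1, epi = qE < 1, eat = qf < 1))
  }
  r <- sqrt(rowSums(points^2))
  u <- points / pmax(r, 1e-12)
  rad <- phantom_radii(u, spec)
  list(endo = r < rad$endo, epi = r < rad$epi,
       eat = r < rad$epi + spec$eat_thickness)
}

# Radially sampled mesh of a star-shaped surface.
radial_mesh <- function(spec, which = c("endo", "epi")) {
  which <- match.arg(which)
  ico <- icosphere(spec$subdiv)
  r <- phantom_radii(ico$vertices, spec)[[which]]
  surface_mesh(ico$vertices * r, ico$faces)
}

phantom_meshes <- function(spec) {
  if (spec$shape == "ellipsoid_shell") {
    list(endo = ellipsoid_mesh(spec$endo_semiaxes, subdiv = spec$subdiv),
         epi = ellipsoid_mesh(spec$epi_semiaxes, subdiv = spec$subdiv))
  } else {
    list(endo = radial_mesh(spec, "endo"), epi = radial_mesh(spec, "epi"))
  }
}

# Landmark loops / planes for the la_like shape, on the epicardial mesh.
phantom_landmarks <- function(spec, epi) {
  la <- spec$la
  v <- epi$vertices
  r <- sqrt(rowSums(v^2))
  u <- v / r
  ring <- function(d, alpha) {
    ct <- as.vector(u %*% d)
    theta <- acos(pmin(1, pmax(-1, ct)))
    tol <- 2.2 * 1.1 / 2^spec$subdiv  # ~2 mesh edge angles
    cand <- which(abs(theta - alpha) < tol)
    if (length(cand) < 8)
      stop("landmark ring too sparse; increase subdiv")
    b <- plane_basis(d)
    az <- atan2(u[cand, , drop = FALSE] %*% b[, 2],
                u[cand, , drop = FALSE] %*% b[, 1])
    # one vertex per azimuth bin (closest to the nominal ring angle)
    bins <- cut(as.vector(az), breaks = seq(-pi, pi, length.out = 33),
                include.lowest = TRUE)
    keep <- unlist(lapply(split(seq_along(cand), bins), function(ii) {
      if (!length(ii)) return(integer(0))
      ii[which.min(abs(theta[cand][ii] - alpha))]
    }), use.names = FALSE)
    sel <- cand[keep]
    sel[order(atan2(u[sel, , drop = FALSE] %*% b[, 2],
                    u[sel, , drop = FALSE] %*% b[, 1]))]
  }
  loops <- list()
  planes <- list()
  for (k in seq_len(nrow(la$pv_dirs))) {
    nm <- rownames(la$pv_dirs)[k]
    d <- la$pv_dirs[k, ]
    loops[[nm]] <- ring(d, la$pv_alpha_out)
    planes[[nm]] <- list(point = colMeans(v[loops[[nm]], , drop = FALSE]),
                         normal = d)
  }
  loops$LAA <- ring(la$laa_dir, la$laa_alpha_out)
  planes$LAA <- list(point = colMeans(v[loops$LAA, , drop = FALSE]),
                     normal = la$laa_dir)
  loops$MV <- ring(la$mv_dir, la$mv_alpha)
  planes$MV <- list(point = colMeans(v[loops$MV, , drop = FALSE]),
                    normal = la$mv_dir)
  axes <- list(superior = c(0, 0, 1), left = c(1, 0, 0), posterior = c(0, 1, 0))
  landmark_set(loops, planes, epi, axes = axes)
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Voxel HU equals the level of the analytic region containing the voxel
#' center plus seeded Gaussian noise; shell meshes sample the same analytic
#' surfaces. Deterministic given the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `la_phantom`: list with `ct` (a [ct_volume()])
#'   and `truth` (meshes, landmark set, analytic cavity volume, analytic wall
#'   mask, planted deposits, seed).
#' @export
make_phantom <- function(spec) {
  sp <- spec$spacing
  half <- switch(spec$shape,
    concentric_spheres = spec$endo_radius + max(probe_thickness(spec)) +
      spec$eat_thickness + 2,
    ellipsoid_shell = max(spec$epi_semiaxes) + spec$eat_thickness + 2,
    la_like = max(spec$endo_semiaxes) + spec$la$pv_length +
      max(probe_thickness(spec)) + spec$eat_thickness + 2)
  dims <- 2L * as.integer(ceiling(half / sp))  # even: centers off lattice planes
  affine <- diag(4)
  diag(affine)[1:3] <- sp
  affine[1:3, 4] <- -(dims - 1) / 2 * sp
  ct <- ct_volume(array(0, dims), affine)

  if (min(probe_thickness(spec)) < 2 * max(sp))
    warning("wall thinner than 2 voxels: partial-volume regime")

  meshes <- phantom_meshes(spec)
  # Tissue compartments are defined by the shell meshes themselves (the same
  # geometry the mapping stage receives); the analytic radial functions serve
  # the epicardial-fat layer and the ground-truth volumes.
  in_epi <- cpp_voxelize(world_to_index(meshes$epi$vertices, ct),
                         meshes$epi$faces, dims[1], dims[2], dims[3])
  in_endo <- cpp_voxelize(world_to_index(meshes$endo$vertices, ct),
                          meshes$endo$faces, dims[1], dims[2], dims[3])
  ctr <- voxel_centers(ct)
  mem <- phantom_membership(ctr, spec)
  tissue <- rep(spec$hu$background, nrow(ctr))
  tissue[mem$eat] <- spec$hu$epicardial_fat
  tissue[in_epi] <- spec$hu$myocardium
  tissue[in_endo] <- spec$hu$blood_pool
  data <- tissue
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    data <- data + rnorm(length(data), 0, spec$noise_sd)
  }
  ct$data <- array(data, dims)
  landmarks <- if (spec$shape == "la_like")
    phantom_landmarks(spec, meshes$epi) else NULL
  cavity_ml <- switch(spec$shape,
    concentric_spheres = 4 / 3 * pi * spec$endo_radius^3 / 1000,
    ellipsoid_shell = 4 / 3 * pi * prod(spec$endo_semiaxes) / 1000,
    la_like = mesh_volume(meshes$endo) / 1000)
  wall_true <- array(in_epi & !in_endo, dims)
  truth <- structure(list(
    endo = meshes$endo, epi = meshes$epi, landmarks = landmarks,
    cavity_volume_ml = cavity_ml,
    wall_volume_ml = sum(wall_true) * prod(sp) / 1000,
    wall_mask_true = wall_true,
    deposits = list(), seed = spec$seed, noise_sd = spec$noise_sd,
    spec = spec), class = "phantom_truth")
  structure(list(ct = ct, truth = truth), class = "la_phantom")
}

probe_thickness <- function(spec) {
  if (spec$shape == "ellipsoid_shell") spec$epi_semiaxes - spec$endo_semiaxes
  else spec$thickness(icosphere(2L)$vertices)
}

#' @export
print.la_phantom <- function(x, ...) {
  cat(sprintf("<la_phantom> %s, cavity %.2f mL, wall %.2f mL, %d fat deposit(s)\n",
              x$truth$spec$shape, x$truth$cavity_volume_ml,
              x$truth$wall_volume_ml, length(x$truth$deposits)))
  invisible(x)
}

#' Plant an intramyocardial fat deposit in a phantom
#'
#' Grows a connected voxel blob inside the wall compartment by accreting wall
#' voxels in order of Euclidean distance from a seed voxel (preferring the
#' target segment when one is requested), then assigns each blob voxel an HU
#' value drawn uniformly from `hu_range` plus the phantom's Gaussian noise.
#' The recorded true volume is the blob voxel count times the voxel volume
#' (within one voxel volume of `target_volume_ml`).
#'
#' @param phantom an `la_phantom` from [make_phantom()].
#' @param target_volume_ml requested deposit volume (mL).
#' @param class `"dense"` or `"admixture"`; validates `hu_range` against the
#'   class HU support ([-194,-50) dense, [-50,-5] admixture).
#' @param hu_range length-2 HU interval the deposit is drawn from; defaults
#'   `c(-85, -70)` for dense and `c(-30, -22)` for admixture (two noise SDs
#'   clear of the class boundaries at the default 10 HU noise).
#' @param segment target segment label 1..19 (la_like phantoms only), or
#'   `NULL` to place the deposit at the first interior wall voxel.
#' @param center optional mm coordinates overriding the seed location.
#' @return the updated `la_phantom` (deposit appended to `truth$deposits`).
#' @export
plant_fat <- function(phantom, target_volume_ml,
                      class = c("dense", "admixture"),
                      hu_range = NULL, segment = NULL, center = NULL) {
  class <- match.arg(class)
  if (!is.null(segment)) segment <- as.integer(segment)
  truth <- phantom$truth
  spec <- truth$spec
  ct <- phantom$ct
  if (is.null(hu_range))
    hu_range <- if (class == "dense") c(-85, -70) else c(-30, -22)
  ok <- if (class == "dense") hu_range[1] >= -194 && hu_range[2] < -50
        else hu_range[1] >= -50 && hu_range[2] <= -5
  if (!ok) stop("hu_range outside the ", class, " HU support")

  sp <- voxel_spacing(ct)
  ctr <- voxel_centers(ct)
  interior <- interior_wall_voxels(ctr, spec, margin = 0.6 * max(sp))
  if (!is.null(truth$landmarks))
    interior[interior] <- !points_excluded(ctr[interior, , drop = FALSE],
                                           truth$landmarks, truth$epi)
  idx_all <- which(interior)
  n_vox <- round(target_volume_ml / voxel_volume_ml(ct))
  if (n_vox < 1) stop("target volume smaller than one voxel")
  if (n_vox > length(idx_all))
    stop("deposit too large for the wall compartment")

  seg_labels <- NULL
  if (!is.null(segment)) {
    if (is.null(truth$landmarks))
      stop("segment-targeted deposits require an la_like phantom")
    seg <- phantom_parcellation(phantom)
    fc <- face_centroids(truth$epi)
    in_seg <- which(seg$face_label == segment)
    if (!length(in_seg)) stop("target segment ", segment, " is empty")
    ref <- fc[in_seg[which.min(rowSums(sweep(fc[in_seg, , drop = FALSE], 2,
                               colMeans(fc[in_seg, , drop = FALSE]))^2))], ]
    seed_pos <- ref
    wall_lab <- cpp_nearest_row(ctr[idx_all, , drop = FALSE],
                                fc[seg$face_label > 0, , drop = FALSE])
    seg_labels <- seg$face_label[seg$face_label > 0][wall_lab]
  } else if (!is.null(center)) {
    seed_pos <- as.double(center)
  } else {
    seed_pos <- ctr[idx_all[1], ]
  }
  d2 <- rowSums(sweep(ctr[idx_all, , drop = FALSE], 2, seed_pos)^2)
  key <- if (is.null(seg_labels)) d2 else d2 + (seg_labels != segment) * 1e9
  take <- idx_all[order(key, idx_all)][seq_len(n_vox)]

  set.seed(truth$seed + 7919L * (length(truth$deposits) + 1L))
  hu <- runif(n_vox, hu_range[1], hu_range[2])
  if (truth$noise_sd > 0) hu <- hu + rnorm(n_vox, 0, truth$noise_sd)
  ct$data[take] <- hu

  truth$deposits <- c(truth$deposits, list(list(
    segment = segment, class = class,
    volume_ml = n_vox * voxel_volume_ml(ct),
    hu_range = hu_range, n_vox = n_vox, voxel_idx = take)))
  phantom$ct <- ct
  phantom$truth <- truth
  phantom
}

# Wall voxels at least `margin` mm clear of both shells (analytic).
interior_wall_voxels <- function(points, spec, margin) {
  if (spec$shape == "ellipsoid_shell") {
    qe <- rowSums(sweep(points, 2, spec$endo_semiaxes + margin, `/`)^2)
    qE <- rowSums(sweep(points, 2, spec$epi_semiaxes - margin, `/`)^2)
    return(qe > 1 & qE < 1)
  }
  r <- sqrt(rowSums(points^2))
  u <- points / pmax(r, 1e-12)
  rad <- phantom_radii(u, spec)
  r > rad$endo + margin & r < rad$epi - margin
}

# Cached parcellation of the phantom's epicardial mesh.
phantom_parcellation <- function(phantom) {
  p <- attr(phantom$truth, "parcellation")
  if (is.null(p)) {
    p <- parcellate(phantom$truth$epi, phantom$truth$landmarks)
  }
  p
}

#' Write phantom artifacts to disk
#'
#' Emits the NIfTI volume, PLY shells, landmark JSON and a truth manifest
#' (JSON) into a directory, in the same formats the I/O layer reads.
#'
#' @param phantom an `la_phantom`.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    volume = file.path(dir, "volume.nii.gz"),
    endo = file.path(dir, "endo.ply"),
    epi = file.path(dir, "epi.ply"),
    landmarks = if (!is.null(phantom$truth$landmarks))
      file.path(dir, "landmarks.json") else NULL,
    truth = file.path(dir, "truth.json"))
  write_ct_volume(phantom$ct, paths$volume)
  write_mesh(phantom$truth$endo, paths$endo)
  write_mesh(phantom$truth$epi, paths$epi)
  if (!is.null(paths$landmarks))
    write_landmarks(phantom$truth$landmarks, paths$landmarks)
  manifest <- list(
    shape = phantom$truth$spec$shape,
    seed = phantom$truth$seed,
    noise_sd = phantom$truth$noise_sd,
    cavity_volume_ml = phantom$truth$cavity_volume_ml,
    wall_volume_ml = phantom$truth$wall_volume_ml,
    deposits = lapply(phantom$truth$deposits, function(d)
      d[c("segment", "class", "volume_ml", "hu_range", "n_vox")]))
  jsonlite::write_json(manifest, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
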