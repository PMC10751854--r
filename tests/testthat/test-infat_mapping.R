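# Wall mask construction, exclusions, HU classification, metrics.

test_that("scanline wall mask equals the winding-number oracle voxel for voxel", {
  # independent oracle: generalised winding number per voxel center, pure R
  spec <- phantom_spec("concentric_spheres", endo_radius = 8,
                       wall_thickness = 2.5, spacing = 1.5, noise_sd = 0,
                       seed = 4, subdiv = 2)
  ph <- suppressWarnings(make_phantom(spec))   # deliberately coarse grid
  wall <- suppressMessages(build_wall_mask(ph$ct, ph$truth$endo, ph$truth$epi))
  ctr <- lafat:::voxel_centers(ph$ct)
  oracle <- winding_inside(ctr, ph$truth$epi) &
    !winding_inside(ctr, ph$truth$endo)
  expect_identical(as.vector(wall$mask), oracle)
})

test_that("coincident shells give an empty mask; intersecting shells error", {
  ph <- fixture("tiny_sphere", function()
    make_phantom(phantom_spec("concentric_spheres", endo_radius = 8,
                              wall_thickness = 2, spacing = 1.0,
                              noise_sd = 0, seed = 6, subdiv = 3)))
  m <- ph$truth$endo
  wall <- suppressMessages(build_wall_mask(ph$ct, m, m))
  expect_equal(sum(wall$mask), 0L)
  big <- surface_mesh(m$vertices * 1.4, m$faces)
  expect_error(suppressMessages(build_wall_mask(ph$ct, big, ph$truth$epi)),
               "intersect")
})

test_that("distal PV exclusion retains a 5 mm collar beyond each ostium plane", {
  run <- fix_la_run()
  ph <- run$phantom
  lm <- ph$truth$landmarks
  ctr <- lafat:::voxel_centers(ph$ct)
  idx <- which(run$wall$mask)
  sp <- max(voxel_spacing(ph$ct))
  for (nm in c("LSPV", "LIPV", "RSPV", "RIPV")) {
    pl <- lm$planes[[nm]]
    d <- as.vector(sweep(ctr[idx, , drop = FALSE], 2, pl$point) %*% pl$normal)
    # vein-side voxels close to the tube axis: none beyond the collar
    lateral <- sqrt(rowSums((sweep(ctr[idx, , drop = FALSE], 2, pl$point) -
                             outer(d, pl$normal))^2))
    vein <- d > 0 & lateral < 8
    expect_lte(max(d[vein]), 5 + sp)            # nothing past the collar
    expect_gt(max(d[vein]), 5 - 2 * sp)         # collar itself retained
  }
  # appendage: nothing on the far side of the LAA ostium plane near its axis
  pl <- lm$planes$LAA
  d <- as.vector(sweep(ctr[idx, , drop = FALSE], 2, pl$point) %*% pl$normal)
  lateral <- sqrt(rowSums((sweep(ctr[idx, , drop = FALSE], 2, pl$point) -
                           outer(d, pl$normal))^2))
  expect_lte(max(d[d > -Inf & lateral < 6]), sp)
})

test_that("missing ostium planes are rejected", {
  run <- fix_la_run()
  lm <- run$phantom$truth$landmarks
  lm$planes$RSPV <- NULL
  expect_error(apply_exclusions(run$wall, run$phantom$ct, lm,
                                run$phantom$truth$epi), "RSPV")
})

test_that("HU boundary semantics match the documented convention", {
  # -100 dense, -30 admixture, -50 dense (boundary), 0 / -200 unclassified
  hu <- array(c(-100, -30, -50, 0, -200, -5, -194, -4.999), c(8, 1, 1))
  ct <- ct_volume(hu, diag(4))
  wall <- structure(list(mask = array(TRUE, c(8, 1, 1)), voxel_volume_ml = 1e-3,
                         exclusion_mm = 5), class = "wall_mask")
  cls <- classify_fat(ct, wall)
  expect_identical(as.vector(unclass(cls)),
                   c(1L, 2L, 1L, 0L, 0L, 2L, 1L, 0L))
  # voxels outside the mask are never classified
  wall$mask[1:2] <- FALSE
  expect_identical(as.vector(unclass(classify_fat(ct, wall)))[1:2], c(0L, 0L))
  expect_error(hu_thresholds(-50, -194, -5), "must satisfy")
})

test_that("volumes widen monotonically with the thresholds on random phantoms", {
  set.seed(202)
  for (rep in 1:20) {
    r <- runif(1, 7, 10)
    spec <- phantom_spec("concentric_spheres", endo_radius = r,
                         wall_thickness = runif(1, 3, 4), spacing = 1.0,
                         noise_sd = runif(1, 0, 15), seed = 300 + rep,
                         subdiv = 2)
    ph <- make_phantom(spec)
    ph <- plant_fat(ph, runif(1, 0.05, 0.2), "dense",
                    hu_range = sort(runif(2, -190, -55)))
    ph <- plant_fat(ph, runif(1, 0.05, 0.2), "admixture",
                    hu_range = sort(runif(2, -48, -7)),
                    center = c(0, 0, -r - 1))
    wall <- suppressMessages(build_wall_mask(ph$ct, ph$truth$endo,
                                             ph$truth$epi))
    base <- compute_metrics(classify_fat(ph$ct, wall, hu_thresholds()),
                            ph$ct, wall, endo = ph$truth$endo)
    wide <- compute_metrics(
      classify_fat(ph$ct, wall, hu_thresholds(-300, -50, 20)),
      ph$ct, wall, endo = ph$truth$endo)
    expect_gte(wide$infat_ml, base$infat_ml)
    dense_up <- compute_metrics(
      classify_fat(ph$ct, wall, hu_thresholds(-194, -30, -5)),
      ph$ct, wall, endo = ph$truth$endo)
    expect_gte(dense_up$dense_ml, base$dense_ml)
    expect_equal(base$infat_ml, base$dense_ml + base$admix_ml)  # conservation
  }
})

test_that("metrics arithmetic and identities hold exactly", {
  # 1000 dense voxels at 0.5 mm isotropic and uniform -80 HU
  d <- c(10, 10, 10)
  hu <- array(-80, d)
  ct <- ct_volume(hu, diag(c(0.5, 0.5, 0.5, 1)))
  wall <- structure(list(mask = array(TRUE, d), voxel_volume_ml = 0.5^3 / 1000,
                         exclusion_mm = 5), class = "wall_mask")
  m <- compute_metrics(classify_fat(ct, wall), ct, wall, la_volume_ml = 100)
  expect_equal(m$dense_ml, 0.125)
  expect_equal(m$dense_hu, -80)
  expect_equal(m$infat_lavol_au, 0.125 / 100)
  expect_true(is.na(m$admix_hu))        # empty class -> missing, never 0

  run <- fix_la_run()
  mm <- run$metrics
  # normalisation identity to 1e-12 relative tolerance
  expect_equal(mm$infat_lavol_au * mm$la_vol_ml, mm$infat_ml, tolerance = 1e-12)
  expect_equal(mm$dense_wallvol_au * mm$wall_vol_ml, mm$dense_ml, tolerance = 1e-12)
  # volume-weighted mean identity
  expect_equal(mm$infat_hu * mm$infat_ml,
               mm$dense_hu * mm$dense_ml + mm$admix_hu * mm$admix_ml,
               tolerance = 1e-9)
  # mean inFAT HU lies between the class means
  expect_true(mm$dense_hu <= mm$infat_hu && mm$infat_hu <= mm$admix_hu)
  expect_error(compute_metrics(run$classes, run$phantom$ct,
                               structure(list(mask = array(FALSE, dim(run$wall$mask)),
                                              voxel_volume_ml = 1e-3),
                                         class = "wall_mask"),
                               la_volume_ml = 100), "zero wall volume")
})

test_that("epicardial fat outside the shell is never counted", {
  ph <- fix_sphere()   # has a -100 HU EAT layer outside the epicardium
  wall <- fix_sphere_wall()
  cls <- classify_fat(ph$ct, wall)
  m <- compute_metrics(cls, ph$ct, wall, endo = ph$truth$endo)
  expect_equal(m$infat_ml, 0)
})
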