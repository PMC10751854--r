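# Phantom generator: analytic truth, determinism, fat planting, cohorts.

test_that("concentric-sphere phantom has analytic cavity volume and exact wall HU", {
  ph <- fix_sphere()
  expect_equal(ph$truth$cavity_volume_ml, 4 / 3 * pi * 20^3 / 1000,
               tolerance = 1e-12)
  # noise-free: every wall voxel sits exactly at the myocardial level
  hu <- ph$ct$data[ph$truth$wall_mask_true]
  expect_true(all(hu == 40))
  # blood pool and background are exactly at their levels too
  expect_true(all(ph$ct$data %in% c(350, 40, -100, -1000)))
})

test_that("phantoms are bit-reproducible given the seed", {
  spec <- phantom_spec("concentric_spheres", endo_radius = 8,
                       wall_thickness = 2, spacing = 1.0, noise_sd = 12,
                       seed = 99)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$truth$wall_mask_true, b$truth$wall_mask_true)
})

test_that("planted deposits honour volume quantisation and HU class support", {
  spec <- phantom_spec("concentric_spheres", endo_radius = 15,
                       wall_thickness = 3, spacing = 0.5, noise_sd = 0,
                       seed = 5)
  ph <- make_phantom(spec)
  ph <- plant_fat(ph, 0.5, "dense")
  d <- ph$truth$deposits[[1]]
  vv <- voxel_volume_ml(ph$ct)
  expect_lte(abs(d$volume_ml - 0.5), vv)          # <= one voxel volume
  expect_equal(vv, 0.000125)
  # noise-free: planted HU values live strictly inside the dense range
  hu <- ph$ct$data[d$voxel_idx]
  expect_true(all(hu >= -194 & hu <= -50))
  # deposits lie strictly between the shells
  expect_true(all(ph$truth$wall_mask_true[d$voxel_idx]))
  # class/range mismatch is rejected
  expect_error(plant_fat(ph, 0.1, "dense", hu_range = c(-40, -30)), "support")
  expect_error(plant_fat(ph, 0.1, "admixture", hu_range = c(-80, -60)), "support")
  # oversized deposit cannot fit
  expect_error(plant_fat(ph, 100, "dense"), "too large")
})

test_that("segment-targeted deposits are recorded with their labels", {
  ph <- fix_la()
  labs <- vapply(ph$truth$deposits, function(d) d$segment, integer(1))
  expect_identical(labs, c(16L, 2L))
  cls <- vapply(ph$truth$deposits, function(d) d$class, character(1))
  expect_identical(cls, c("dense", "admixture"))
})

test_that("cohort generator reproduces the requested sizes and group medians", {
  co <- make_cohort(c(paroxysmal = 30, persistent = 30, control = 20), seed = 1)
  expect_equal(nrow(co), 80L)
  expect_equal(as.vector(table(co$group)[c("paroxysmal", "persistent", "control")]),
               c(30L, 30L, 20L))
  expect_true(all(co$infat_ml >= 0))
  expect_identical(co$patient_id[1], "P001")

  # medians converge to the specified group medians as n grows
  big <- make_cohort(c(paroxysmal = 3000, persistent = 3000, control = 3000),
                     seed = 2)
  med <- tapply(big$infat_ml, big$group, median)
  expect_equal(as.vector(med[c("control", "paroxysmal", "persistent")]),
               c(0.275, 0.415, 0.460), tolerance = 0.05)
  # normalised metrics are consistent with the drawn volumes
  expect_equal(big$infat_lavol_au, big$infat_ml / big$la_vol_ml)
})

test_that("null effect spec gives exchangeable groups", {
  spec <- null_effect_spec()
  expect_identical(spec$infat_ml$median$persistent, spec$infat_ml$median$control)
  expect_identical(spec$bmi$mean$paroxysmal, spec$bmi$mean$control)
  co <- make_cohort(effect_spec = spec, seed = 10)
  expect_equal(nrow(co), 80L)
})

test_that("thin walls trigger the partial-volume warning, not an error", {
  expect_warning(
    make_phantom(phantom_spec("concentric_spheres", endo_radius = 8,
                              wall_thickness = 1.2, spacing = 1.0,
                              noise_sd = 0, seed = 3)),
    "partial-volume")
})
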