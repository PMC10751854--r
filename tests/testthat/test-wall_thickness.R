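# LAWT: analytic shells, dense-sampling oracle, invariances, colour bins.

test_that("concentric spheres give 2 mm everywhere within discretisation error", {
  ph <- fix_sphere()
  tm <- compute_lawt(ph$truth$endo, ph$truth$epi)
  expect_lt(max(abs(tm$thickness_mm - 2)), 0.02)        # 1 %
  expect_lt(abs(tm$mean_thickness_mm - 2) / 2, 0.005)   # 0.5 %
  # thickness sits just under the 2 mm bin edge (inscribed mesh), so the
  # half-open binning may put vertices in yellow or green, nothing else
  expect_true(all(tm$colour %in% c("yellow", "green")))
})

test_that("coincident shells give zero thickness everywhere", {
  s <- lafat:::sphere_mesh(10, subdiv = 3)
  tm <- compute_lawt(s, s)
  expect_true(all(tm$thickness_mm == 0))
  expect_equal(tm$mean_thickness_mm, 0)
})

test_that("an endocardial vertex outside the epicardium is reported by index", {
  endo <- lafat:::sphere_mesh(10, subdiv = 2)
  epi <- lafat:::sphere_mesh(11, subdiv = 3)
  endo$vertices[5, ] <- endo$vertices[5, ] * 1.3        # poke through
  expect_error(compute_lawt(endo, epi), "vertex 5")
})

test_that("ellipsoid thickness matches a dense surface-sampling oracle", {
  endo <- lafat:::ellipsoid_mesh(c(30, 25, 20), subdiv = 4)
  epi <- lafat:::ellipsoid_mesh(c(32, 27, 22), subdiv = 5)
  tm <- compute_lawt(endo, epi)
  set.seed(71)
  vs <- sample(nrow(endo$vertices), 30)
  n <- 250000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  s <- t(sweep(u, 2, c(32, 27, 22), `*`))
  for (i in vs) {
    oracle <- sqrt(min(colSums((s - endo$vertices[i, ])^2)))
    expect_lt(abs(oracle - tm$thickness_mm[i]), 0.05)
  }
})

test_that("thickness is homogeneous of degree one under uniform scaling", {
  endo <- lafat:::ellipsoid_mesh(c(12, 10, 9), subdiv = 3)
  epi <- lafat:::ellipsoid_mesh(c(14, 12, 11), subdiv = 3)
  t1 <- compute_lawt(endo, epi)$thickness_mm
  k <- 2.5
  endo_k <- surface_mesh(endo$vertices * k, endo$faces)
  epi_k <- surface_mesh(epi$vertices * k, epi$faces)
  t2 <- compute_lawt(endo_k, epi_k)$thickness_mm
  expect_equal(t2, k * t1, tolerance = 1e-9)
})

test_that("normal-ray mode agrees with nearest-point on concentric spheres", {
  endo <- lafat:::sphere_mesh(10, subdiv = 3)
  epi <- lafat:::sphere_mesh(12, subdiv = 4)
  a <- compute_lawt(endo, epi, mode = "nearest")
  b <- compute_lawt(endo, epi, mode = "normal_ray")
  expect_equal(a$thickness_mm, b$thickness_mm, tolerance = 0.02)
})

test_that("colour bins are half-open with boundaries in the upper bin", {
  expect_identical(as.character(bin_thickness(c(0.5, 1.0, 1.99, 2.0, 3.0, 4.0, 7))),
                   c("red", "yellow", "yellow", "green", "blue", "purple", "purple"))
  expect_error(bin_thickness(-0.1), "non-negative")
})

test_that("mean thickness is area-weighted, hence mesh-density invariant", {
  coarse <- compute_lawt(lafat:::sphere_mesh(10, subdiv = 2),
                         lafat:::sphere_mesh(12, subdiv = 4))
  fine <- compute_lawt(lafat:::sphere_mesh(10, subdiv = 4),
                       lafat:::sphere_mesh(12, subdiv = 4))
  expect_equal(coarse$mean_thickness_mm, fine$mean_thickness_mm,
               tolerance = 0.02)
})
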