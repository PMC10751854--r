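# Regional inFAT distribution: percentages, degenerate cases, truth recovery.

# Minimal constructed wall: labels and classes on a flat block.
toy_regional <- function(fat_per_segment, voxels_per_segment = 100,
                         vv = 1e-3) {
  n_seg <- 19
  labels <- array(rep(1:n_seg, each = voxels_per_segment),
                  c(voxels_per_segment * n_seg, 1, 1))
  classes <- array(0L, dim(labels))
  for (s in seq_along(fat_per_segment)) {
    n_fat <- fat_per_segment[s]
    if (n_fat > 0) {
      idx <- which(labels == s)[seq_len(n_fat)]
      classes[idx] <- 1L
    }
  }
  attr(classes, "voxel_volume_ml") <- vv
  wall <- structure(list(mask = array(TRUE, dim(labels)),
                         voxel_volume_ml = vv, exclusion_mm = 5),
                    class = "wall_mask")
  list(labels = labels, classes = classes, wall = wall)
}

test_that("single-segment fat gives the 100/0 pattern", {
  toy <- toy_regional(setNames(c(rep(0, 15), 50, 0, 0, 0), NULL))
  out <- relative_infat_percentage(toy$classes, toy$labels)
  expect_equal(out$rel_infat_pct[16], 100)
  expect_equal(out$rel_infat_pct[-16], rep(0, 18))
})

test_that("0.3/0.1 mL fat split gives 75/25", {
  toy <- toy_regional(c(0, 100, rep(0, 16), 300), voxels_per_segment = 400)
  out <- relative_infat_percentage(toy$classes, toy$labels)
  expect_equal(out$rel_infat_pct[19], 75)
  expect_equal(out$rel_infat_pct[2], 25)
})

test_that("percentage vectors sum to 100 within 1e-9 and respect the partition", {
  set.seed(31)
  toy <- toy_regional(sample(0:40, 19, replace = TRUE) + 1,
                      voxels_per_segment = 60)
  fat <- relative_infat_percentage(toy$classes, toy$labels)
  vol <- regional_volume_percentage(toy$labels, toy$wall)
  expect_equal(sum(fat$rel_infat_pct), 100, tolerance = 1e-9)
  expect_equal(sum(vol$regional_vol_pct), 100, tolerance = 1e-9)
  # direct count oracle
  counts <- vapply(1:19, function(l) sum(toy$labels == l), numeric(1))
  expect_equal(vol$regional_vol_pct, 100 * counts / sum(counts))
})

test_that("relative percentage is invariant to uniform rescaling of fat volumes", {
  a <- toy_regional(c(5, 10, 15, rep(0, 16)))
  b <- toy_regional(3 * c(5, 10, 15, rep(0, 16)))
  pa <- relative_infat_percentage(a$classes, a$labels)$rel_infat_pct
  pb <- relative_infat_percentage(b$classes, b$labels)$rel_infat_pct
  expect_equal(pa, pb)
})

test_that("zero total fat reports missing values with a warning, empty mask errors", {
  toy <- toy_regional(rep(0, 19))
  expect_warning(out <- relative_infat_percentage(toy$classes, toy$labels),
                 "zero")
  expect_true(all(is.na(out$rel_infat_pct)))
  empty_wall <- toy$wall
  empty_wall$mask[] <- FALSE
  expect_error(regional_volume_percentage(toy$labels, empty_wall), "empty")
})

test_that("multi-deposit phantom percentages match the truth manifest", {
  run <- fix_la_run()
  deps <- run$phantom$truth$deposits
  truth_vol <- vapply(1:19, function(l)
    sum(vapply(deps, function(d)
      if (identical(d$segment, l)) d$volume_ml else 0, numeric(1))),
    numeric(1))
  truth_pct <- 100 * truth_vol / sum(truth_vol)
  reg <- regional_distribution(run$classes, run$labels, run$wall)
  expect_lt(max(abs(reg$rel_infat_pct - truth_pct)), 2)
  expect_equal(sum(reg$rel_infat_pct), 100, tolerance = 1e-9)
  expect_equal(sum(reg$regional_vol_pct), 100, tolerance = 1e-9)
})
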