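test_that("phantom generation is deterministic and honors the severity dial", {
  spec <- small_spec(sheath_mm = sheaths(flexor_3 = 1.5), seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$labels$labels, b$labels$labels)

  none <- generate_phantom(small_spec(seed = 5))
  expect_false(any(none$inflammation))

  # inflammation never overlaps tendon or bone labels
  expect_false(any(a$inflammation & a$labels$labels != 0L))
})

test_that("realized sheath thickness matches the requested width within a voxel", {
  tr <- generate_phantom(small_spec(sheath_mm = sheaths(flexor_3 = 4), seed = 3))
  w <- measured_sheath_thickness(tr, "flexor_3")
  expect_lt(abs(w - 4), max(tr$spec$spacing))
  expect_equal(measured_sheath_thickness(tr, "flexor_1"), 0)
})

test_that("simulated acquisition follows the slice-averaging protocol", {
  tr <- fx_phantom()
  ax <- simulate_acquisition(tr, "axial")
  co <- simulate_acquisition(tr, "coronal")
  expect_equal(ax$spacing[3], 3.3)   # 3 mm thickness + 0.3 mm gap
  expect_equal(co$spacing[2], 2.2)   # 2 mm thickness + 0.2 mm gap
  expect_equal(ax$spacing[1:2], tr$image$spacing[1:2])

  # constants are preserved by the slab average
  const <- vol3d(array(7, c(8, 8, 40)), spacing = c(0.5, 0.5, 0.5))
  cs <- simulate_acquisition(const, "axial")
  expect_equal(range(cs$voxels), c(7, 7))

  # one bright high-resolution slice inside a slab contributes its value
  # divided by the number of slices per slab
  v <- array(0, c(4, 4, 40))
  v[, , 9] <- 60   # slice extent [3.75, 4.25] mm lies inside the second slab window
  one <- simulate_acquisition(vol3d(v, spacing = c(0.5, 0.5, 0.5)), "axial")
  expect_equal(one$voxels[1, 1, 2], 60 * 0.5 / 3, tolerance = 1e-9)

  expect_error(simulate_acquisition(tr, "sagittal"))
  thin <- vol3d(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 4))
  expect_error(simulate_acquisition(thin, "axial"), "finer")
})

test_that("acquisition model is linear", {
  set.seed(1)
  a <- vol3d(array(rnorm(4 * 4 * 30), c(4, 4, 30)), spacing = c(0.5, 0.5, 0.5))
  b <- vol3d(array(rnorm(4 * 4 * 30), c(4, 4, 30)), spacing = c(0.5, 0.5, 0.5))
  mix <- vol3d(2 * a$voxels + 3 * b$voxels, spacing = a$spacing)
  lhs <- simulate_acquisition(mix, "axial")$voxels
  rhs <- 2 * simulate_acquisition(a, "axial")$voxels +
    3 * simulate_acquisition(b, "axial")$voxels
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("visual grades follow the thickness intervals", {
  expect_equal(grade_from_thickness(c(0, 1.9, 2, 4.9, 5, 8)),
               c(0, 1, 2, 2, 3, 3))
  expect_error(grade_from_thickness(-1), "negative")

  tr <- generate_phantom(small_spec(
    sheath_mm = sheaths(extensor_I = 1.9, flexor_2 = 5, flexor_4 = 2), seed = 2))
  sc <- simulate_visual_scores(tr)
  expect_equal(unname(sc$grades["extensor_I"]), 1)
  expect_equal(unname(sc$grades["flexor_2"]), 3)
  expect_equal(unname(sc$grades["flexor_4"]), 2)
  expect_equal(unname(sc$grades["flexor_1"]), 0)
  expect_equal(sc$total, 6)

  # monotonicity: thicker sheaths never lower the grade (noise off)
  widths <- c(0, 0.5, 1.9, 2, 3, 4.9, 5, 7)
  expect_true(all(diff(grade_from_thickness(widths)) >= 0))
})

test_that("cohorts respect the severity mix and are reproducible", {
  base <- small_spec()
  coh <- generate_cohort(9, mix = c(1, 1, 1) / 3, seed = 4, base_spec = base)
  cats <- vapply(coh, `[[`, 0L, "category")
  expect_equal(as.vector(table(factor(cats, 0:2))), c(3, 3, 3))
  for (e in coh)
    expect_equal(categorize_vmax(e$scores), e$category)

  coh2 <- generate_cohort(9, mix = c(1, 1, 1) / 3, seed = 4, base_spec = base)
  expect_identical(coh[[5]]$truth$image$voxels, coh2[[5]]$truth$image$voxels)
  expect_identical(lapply(coh, `[[`, "category"), lapply(coh2, `[[`, "category"))

  zero <- generate_cohort(5, mix = c(1, 0, 0), seed = 1, base_spec = base)
  expect_true(all(vapply(zero, function(e) all(e$truth$sheath_mm == 0), TRUE)))

  severe <- generate_cohort(3, mix = c(0, 0, 1), seed = 1, base_spec = base)
  expect_true(all(vapply(severe, function(e) max(e$scores$grades) >= 1.5, TRUE)))

  expect_error(generate_cohort(0, seed = 1), "positive")
  expect_error(generate_cohort(3, mix = c(0.5, 0.5, 0.5), seed = 1), "summing")
})
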