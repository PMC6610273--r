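# Two dark tubes on a bright background: the canonical watershed scenario.
two_tube_image <- function(noise = 0) {
  d <- c(48, 32, 24); sp <- c(0.5, 0.5, 0.5)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  tube <- function(cx, cy, r) {
    m2 <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= r^2
    array(m2, d)
  }
  t1 <- tube(8, 8, 2); t2 <- tube(16, 8, 2)
  v <- array(100, d)
  v[t1 | t2] <- 30
  if (noise > 0) v <- v + array(rnorm(prod(d), 0, noise), d)
  list(img = vol3d(v, spacing = sp), t1 = t1, t2 = t2,
       labels = region_label_map(
         array(1L * t1 + 2L * t2, d), spacing = sp))
}

test_that("markers erode labels, stay disjoint, and fall back when labels vanish", {
  tt <- two_tube_image()

  mk0 <- make_markers(tt$labels, erosion_mm = 0, dilation_mm = 1)
  expect_identical(unname(mk0 == 1L), tt$t1)   # zero erosion keeps the label

  mk <- make_markers(tt$labels, erosion_mm = 0.6, dilation_mm = 1)
  expect_true(sum(mk == 1L) > 0 && sum(mk == 1L) < sum(tt$t1))
  expect_false(any(mk == 1L & mk == 2L))
  expect_true(all(which(mk == 1L) %in% which(tt$t1)))

  # a label too thin to survive erosion falls back to its innermost voxel
  thin <- region_label_map(array(0L, c(12, 12, 6)), spacing = c(0.5, 0.5, 0.5))
  thin$labels[6, 3:9, ] <- 4L
  expect_warning(mkt <- make_markers(thin, erosion_mm = 2, dilation_mm = 1),
                 "innermost")
  expect_equal(sum(mkt == 4L), 1)

  bones_only <- region_label_map(array(11L, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(make_markers(bones_only), "no tendon")
})

test_that("watershed recovers the tubes up to a one-voxel boundary band", {
  tt <- two_tube_image(noise = 2)
  mk <- make_markers(tt$labels, erosion_mm = 0.6, dilation_mm = 1.5)
  regs <- watershed_segment(tt$img, mk)
  expect_equal(vapply(regs, `[[`, 0L, "code"), c(1L, 2L))

  d <- dim(tt$img$voxels)
  for (i in 1:2) {
    auto <- array(FALSE, d)
    auto[regs[[i]]$voxels] <- TRUE
    pr <- precision_recall(auto, if (i == 1) tt$t1 else tt$t2)
    expect_gte(pr["precision"], 0.9)
    expect_gte(pr["recall"], 0.9)
  }

  # regions contain their own markers and are pairwise disjoint
  expect_true(all(which(mk == 1L) %in% regs[[1]]$voxels))
  expect_length(intersect(regs[[1]]$voxels, regs[[2]]$voxels), 0)

  # markers for one tube only yield exactly one region
  mk1 <- mk
  mk1[mk1 == 2L] <- 0L
  regs1 <- watershed_segment(tt$img, mk1)
  expect_length(regs1, 1)

  # flooding is complete: on a flat relief every voxel reaches some marker
  flood <- tenoquant:::cpp_watershed(rep(0, prod(d)), as.integer(mk), d)
  expect_true(all(flood != 0L))

  expect_error(watershed_segment(tt$img, array(0L, d)), "empty marker")
})

test_that("intensity and volume rules reject implausible regions", {
  grid <- list(dim = c(10, 10, 10), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  reg <- function(code, vox, mi, ml)
    structure(list(code = code, voxels = vox, mean_intensity = mi,
                   volume_ml = ml), class = "segmented_region")
  regions <- list(
    reg(1L, 1:500, 80, 0.5),      # too bright for a tendon
    reg(2L, 501:505, 50, 0.005),  # too small
    reg(3L, 601:620, 50, 0.02)    # plausible
  )
  kept <- filter_regions(regions, grid)
  expect_setequal(unique(as.vector(kept$labels)), c(0L, 3L))

  # boundary values: rules are "> 75" and "< 0.01 ml", both exclusive
  edge <- filter_regions(list(reg(4L, 1:10, 75, 0.01)), grid)
  expect_true(any(edge$labels == 4L))

  none <- filter_regions(list(), grid)
  expect_true(all(none$labels == 0L))
})

test_that("precision and recall count voxel overlap with NA for empty masks", {
  m <- array(FALSE, c(4, 4, 4)); m[1:2, , ] <- TRUE

  expect_equal(unname(precision_recall(m, m)), c(1, 1))

  disj <- array(FALSE, c(4, 4, 4)); disj[3:4, , ] <- TRUE
  expect_equal(unname(precision_recall(m, disj)), c(0, 0))

  half <- m; half[1, , ] <- FALSE   # auto = half of manual, nothing outside
  expect_equal(unname(precision_recall(half, m)), c(1, 0.5))

  empty <- array(FALSE, c(4, 4, 4))
  expect_true(is.na(precision_recall(empty, m)["precision"]))
  expect_true(is.na(precision_recall(m, empty)["recall"]))

  # duality: precision(a, m) == recall(m, a)
  set.seed(3)
  for (i in 1:5) {
    a <- array(runif(64) < 0.4, c(4, 4, 4))
    b <- array(runif(64) < 0.4, c(4, 4, 4))
    if (!any(a) || !any(b)) next
    expect_equal(precision_recall(a, b)[["precision"]],
                 precision_recall(b, a)[["recall"]])
  }
})
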