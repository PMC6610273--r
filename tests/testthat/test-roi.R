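test_that("hand segmentation recovers the skin-bounded extent", {
  tr <- fx_phantom()
  hm <- hand_mask(tr$image)
  pr <- precision_recall(hm, tr$hand)
  expect_gte(pr["precision"], 0.98)
  expect_gte(pr["recall"], 0.98)

  expect_error(hand_mask(vol3d(array(0, c(6, 6, 6)), spacing = c(1, 1, 1))),
               "degenerate")

  # an isolated bright speck is dropped by the largest-component rule
  d <- c(24, 24, 12)
  v <- array(0, d)
  blob <- tenoquant:::ellipsoid_mask(d, c(1, 1, 1), c(12, 12, 6), c(6, 6, 4))
  v[blob] <- 100
  v[2, 2, 2] <- 100
  hm2 <- hand_mask(vol3d(v, spacing = c(1, 1, 1)))
  expect_false(hm2[2, 2, 2])
  pr2 <- precision_recall(hm2, blob)
  expect_gte(pr2["precision"], 0.99)
  expect_gte(pr2["recall"], 0.99)

  # corner seeds on tissue are skipped with a warning
  v3 <- v
  v3[1, 1, ] <- 100
  expect_warning(hand_mask(vol3d(v3, spacing = c(1, 1, 1))), "skipped")
})

test_that("proximal boundary sits where radius and ulna are closest", {
  # constructed bones: two tilted blocks whose in-plane gap narrows with z
  d <- c(40, 20, 15)
  lab <- array(0L, d)
  for (z in 1:15) {
    half_gap <- abs(z - 12) + 2         # narrowest at z = 12
    lab[(20 - half_gap - 4):(20 - half_gap), 8:12, z] <- 13L  # radius
    lab[(20 + half_gap):(20 + half_gap + 4), 8:12, z] <- 14L  # ulna
  }
  labels <- region_label_map(lab, spacing = c(0.5, 0.5, 1))
  z_star <- proximal_boundary(labels)
  gap <- bone_gap_bruteforce(labels)
  expect_equal(z_star, max(which(gap == min(gap))))
  expect_equal(z_star, 12)

  # touching bones: zero distance wins
  lab2 <- array(0L, c(10, 10, 5))
  lab2[4, 5, 3] <- 13L; lab2[5, 5, 3] <- 14L   # adjacent at z = 3
  lab2[2, 5, c(1, 2, 4, 5)] <- 13L; lab2[9, 5, c(1, 2, 4, 5)] <- 14L
  expect_equal(proximal_boundary(region_label_map(lab2, spacing = c(1, 1, 1))), 3)

  # tie resolves to the most distal slice
  lab3 <- array(0L, c(10, 10, 6))
  lab3[3, 5, c(2, 5)] <- 13L; lab3[6, 5, c(2, 5)] <- 14L
  expect_equal(proximal_boundary(region_label_map(lab3, spacing = c(1, 1, 1))), 5)

  no_radius <- region_label_map(array(rep(c(0L, 14L), c(99, 1)), c(10, 10, 1)),
                                spacing = c(1, 1, 1))
  expect_error(proximal_boundary(no_radius), "radius")
})

test_that("distal boundary maximizes the hamate cross-section", {
  d <- c(20, 20, 40)
  lab <- array(0L, d)
  ham <- tenoquant:::ellipsoid_mask(d, c(1, 1, 1), c(10, 10, 30), c(5, 5, 6))
  lab[ham] <- 12L
  labels <- region_label_map(lab, spacing = c(1, 1, 1))
  counts <- apply(lab == 12L, 3, sum)
  expect_equal(distal_boundary(labels), max(which(counts == max(counts))))
  expect_equal(distal_boundary(labels), 31)  # ellipsoid center z = 30 mm, 1-based

  single <- array(0L, c(6, 6, 30)); single[3, 3, 25] <- 12L
  expect_equal(distal_boundary(region_label_map(single, spacing = c(1, 1, 1))), 25)

  tie <- array(0L, c(6, 6, 30)); tie[3, 3, 29] <- 12L; tie[3, 3, 30] <- 12L
  expect_equal(distal_boundary(region_label_map(tie, spacing = c(1, 1, 1))), 30)

  expect_error(distal_boundary(region_label_map(array(0L, c(4, 4, 4)),
                                                spacing = c(1, 1, 1))), "hamate")
})

test_that("the ROI is the distance shell predicted by geometry", {
  # isolated straight tube, radius 1.5 mm, on a 0.25 mm grid
  d <- c(88, 88, 40); sp <- c(0.25, 0.25, 0.25)
  xs <- (seq_len(d[1]) - 1) * sp[1]; ys <- (seq_len(d[2]) - 1) * sp[2]
  r_t <- 1.5
  tube <- array(outer((xs - 11)^2, (ys - 11)^2, `+`) <= r_t^2, d)
  tendons <- region_label_map(array(8L * tube, d), spacing = sp)
  hand <- array(TRUE, d)

  roi <- build_roi(tendons, tendons, hand, D = 3, bounds = c(1, d[3]))
  vol_roi <- sum(roi$mask) * prod(sp)
  vol_analytic <- pi * ((r_t + 3)^2 - r_t^2) * (d[3] * sp[3])
  expect_lt(abs(vol_roi - vol_analytic) / vol_analytic, 0.10)

  # monotone in D and excluded from all labeled voxels
  roi2 <- build_roi(tendons, tendons, hand, D = 2, bounds = c(1, d[3]))
  expect_true(all(roi$mask[roi2$mask]))
  expect_false(any(roi$mask & tendons$labels != 0L))

  # axial bounds clip the shell
  roi_slice <- build_roi(tendons, tendons, hand, D = 3, bounds = c(7, 7))
  zidx <- unique(which(roi_slice$mask, arr.ind = TRUE)[, 3])
  expect_equal(zidx, 7)

  # exclusion dominates: tendon buried in bone yields an empty ROI
  buried <- tendons
  buried$labels[tendons$labels == 0L] <- 11L
  expect_warning(
    empty <- build_roi(tendons, buried, hand, D = 0.2, bounds = c(1, d[3])),
    "empty")
  expect_equal(sum(empty$mask), 0)

  expect_error(build_roi(tendons, tendons, hand, D = 0, bounds = c(1, 2)), "positive")
  none <- region_label_map(array(0L, d), spacing = sp)
  expect_error(build_roi(none, none, hand, D = 3, bounds = c(1, 2)), "tendon")
})
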