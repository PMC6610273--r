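# Registration accuracy is assessed on phantoms deformed by known affine
# maps; fusion and handedness behavior on constructed label maps.

shift_voxels <- function(v, s) {
  d <- dim(v)
  v[pmin(pmax(seq_len(d[1]) - s[1], 1), d[1]),
    pmin(pmax(seq_len(d[2]) - s[2], 1), d[2]),
    pmin(pmax(seq_len(d[3]) - s[3], 1), d[3])]
}

test_that("affine registration recovers identity, translation and scale", {
  img <- fx_phantom()$image

  self <- register_affine(img, img, levels = c(4, 2), max_iter = 15)
  expect_lt(max(abs(self$t)), 0.1 * min(img$spacing))
  expect_lt(max(abs(self$A - diag(3))), 1e-6)

  # target translated by (2, -3, 1) voxels = (1, -1.5, 0.5) mm
  tgt <- vol3d(shift_voxels(img$voxels, c(2, -3, 1)), img$spacing, img$origin)
  tfm <- register_affine(img, tgt, levels = c(4, 2), max_iter = 30)
  pts <- as.matrix(expand.grid(c(6, 26), c(6, 26), c(6, 18)))
  err <- tenoquant:::apply_transform(tfm, pts) - sweep(pts, 2, c(1, -1.5, 0.5))
  expect_lt(max(abs(err)), 0.5 * min(img$spacing))
  expect_lte(tfm$similarity,
             mean((img$voxels - tgt$voxels)^2) + 1e-9)  # no worse than identity

  # target scaled by 1.05 about the center
  g <- tenoquant:::as_grid(img)
  ctr <- g$origin + (g$dim - 1) * g$spacing / 2
  fwd <- affine_transform(diag(3) / 1.05, c(0, 0, 0), ctr)
  tgt_s <- vol3d(array(
    tenoquant:::sample_volume(img, tenoquant:::apply_transform(
      fwd, tenoquant:::grid_points(g))), g$dim), img$spacing, img$origin)
  tfm_s <- register_affine(img, tgt_s, levels = c(4, 2), max_iter = 40)
  expect_lt(max(abs(diag(tfm_s$A) - 1 / 1.05)), 0.01)
})

test_that("label transfer follows the transform and maps outside to background", {
  lab <- region_label_map(array(0L, c(10, 10, 10)), spacing = c(1, 1, 1))
  lab$labels[4:6, 4:6, 4:6] <- 3L
  grid <- list(dim = c(10, 10, 10), spacing = c(1, 1, 1), origin = c(0, 0, 0))

  same <- transfer_labels(affine_transform(), lab, grid)
  expect_identical(same$labels, lab$labels)

  # transform target -> atlas shifted one voxel: content moves the other way
  t1 <- transfer_labels(affine_transform(t = c(1, 0, 0)), lab, grid)
  expect_identical(t1$labels[3:5, 4:6, 4:6], lab$labels[4:6, 4:6, 4:6])

  off <- transfer_labels(affine_transform(t = c(100, 0, 0)), lab, grid)
  expect_true(all(off$labels == 0L))
})

test_that("majority vote takes pluralities and sends ties to background", {
  g <- c(4, 4, 2)
  mk <- function(code) region_label_map(array(code, g), spacing = c(1, 1, 1))

  unanimous <- majority_vote(list(mk(5L), mk(5L), mk(5L)))
  expect_true(all(unanimous$labels == 5L))

  # 7 votes flexor-2 vs 6 background
  votes <- c(lapply(1:7, function(i) mk(8L)), lapply(1:6, function(i) mk(0L)))
  expect_true(all(majority_vote(votes)$labels == 8L))

  # 6 flexor-2 vs 7 background: plurality goes to background
  votes2 <- c(lapply(1:6, function(i) mk(8L)), lapply(1:7, function(i) mk(0L)))
  expect_true(all(majority_vote(votes2)$labels == 0L))

  # two-way tie between non-background labels resolves to background
  tie <- majority_vote(list(mk(3L), mk(9L)))
  expect_true(all(tie$labels == 0L))

  # permutation invariance
  set.seed(1)
  cands <- lapply(1:5, function(i)
    region_label_map(array(sample(c(0L, 2L, 8L), prod(g), TRUE), g),
                     spacing = c(1, 1, 1)))
  v1 <- majority_vote(cands)
  v2 <- majority_vote(rev(cands))
  expect_identical(v1$labels, v2$labels)
  expect_true(all(v1$labels %in% c(0L, 2L, 8L)))

  expect_error(majority_vote(list()), "no candidate")
  small <- region_label_map(array(0L, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_error(majority_vote(list(mk(1L), small)), "share")
})

test_that("handedness preparation mirrors only opposite-handed targets", {
  tr <- fx_phantom()
  atlas <- atlas_set(list(list(image = tr$image, labels = tr$labels)),
                     handedness = "right")

  rightward <- prepare_for_handedness(atlas, "right")
  expect_identical(rightward$pairs[[1]]$image$voxels, tr$image$voxels)

  leftward <- prepare_for_handedness(atlas, "left")
  expect_identical(leftward$pairs[[1]]$image$voxels,
                   mirror_horizontal(tr$image)$voxels)
  expect_identical(leftward$pairs[[1]]$labels$labels,
                   mirror_horizontal(tr$labels)$labels)

  # stateless: preparing twice from the stored atlas gives the same output
  leftward2 <- prepare_for_handedness(atlas, "left")
  expect_identical(leftward$pairs[[1]]$image$voxels,
                   leftward2$pairs[[1]]$image$voxels)
})
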