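test_that("severity categories follow the V_max intervals", {
  sheet <- function(vmax) {
    g <- stats::setNames(rep(0, 10), region_names())
    g["flexor_2"] <- vmax
    visual_score_sheet(g)
  }
  expect_equal(categorize_vmax(sheet(0)), 0L)
  expect_equal(categorize_vmax(sheet(0.5)), 1L)
  expect_equal(categorize_vmax(sheet(1)), 1L)    # boundary: 0 < Vmax <= 1
  expect_equal(categorize_vmax(sheet(1.5)), 2L)
  expect_equal(categorize_vmax(sheet(3)), 2L)
})

test_that("stratified sampling is balanced, reproducible and validated", {
  categories <- rep(0:2, c(200, 261, 102))
  split <- sample_training_set(categories, n_per_category = 20, seed = 3)
  expect_length(split$training, 60)
  expect_length(split$validation, 503)
  expect_equal(as.vector(table(categories[split$training])), c(20, 20, 20))
  expect_setequal(c(split$training, split$validation), seq_along(categories))

  again <- sample_training_set(categories, n_per_category = 20, seed = 3)
  expect_identical(split, again)
  other <- sample_training_set(categories, n_per_category = 20, seed = 4)
  expect_false(identical(split$training, other$training))

  # exhaustive case: every patient trains, nobody validates
  exact <- sample_training_set(rep(0:2, each = 4), n_per_category = 4, seed = 1)
  expect_length(exact$validation, 0)

  expect_error(sample_training_set(rep(0L, 30), n_per_category = 20, seed = 1),
               "category 1")
})

test_that("pearson matches hand computation and the textbook formula", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)[["r"]], 1)
  expect_equal(pearson(1:10, -(1:10))[["r"]], -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))[["r"]], 0.8)

  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(pearson(x, y)[["r"]], pearson_twopass(x, y), tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "length")
})

test_that("grid search finds a planted optimum and breaks ties lexicographically", {
  # the qualifying mass inside [0.82, 0.94) is split over 0.82 and 0.935 so
  # that only their SUM is affine in the visual total; any window that
  # misses one of them, or that includes the non-affine decoys at 0.5,
  # 0.815 or 0.94, cannot reach r = 1
  totals <- c(0, 2, 5, 9, 14, 20)
  wobble <- c(0, 2, 1, 3, 0, 2)         # non-affine in totals
  pv <- lapply(seq_along(totals), function(i) {
    k <- 2 * totals[i] + 10             # qualifying count, affine in total
    c(rep(0.82, k / 2 + wobble[i]), rep(0.935, k / 2 - wobble[i]),
      rep(0.815, 10 + wobble[i]),
      rep(0.94, 10 + 2 * wobble[i]),
      rep(0.5, 60 - k - 3 * wobble[i]))
  })
  fit <- grid_search(list(pv), totals, D_values = 3)
  expect_equal(fit$D, 3)
  expect_equal(fit$t_low, 0.82)
  expect_equal(fit$t_high, 0.94)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  # many tied optimal windows: the lexicographically smallest wins, with D
  # iterated before the thresholds
  tie <- lapply(c(1, 2, 4), function(tot) c(rep(0.25, 10 + tot), rep(0.75, 30 - tot)))
  fit2 <- grid_search(list(tie, tie), c(1, 2, 4), D_values = c(2, 3))
  expect_equal(fit2$D, 2)
  expect_equal(fit2$t_low, 0)
  expect_equal(fit2$t_high, 0.26)

  expect_error(grid_search(list(list(c(0.5), c(0.5))), c(1, 1), D_values = 1),
               "distinct")
})

test_that("leave-one-out atlas validation records rates and failures", {
  tr <- fx_phantom()
  pairs <- lapply(1:3, function(i) list(image = tr$image, labels = tr$labels))
  atlas <- atlas_set(pairs)

  # perfect transfer: segmenting with the held-out truth labels themselves
  res <- loocv_atlas(atlas, function(target, rest) rest$pairs[[1]]$labels)
  expect_true(all(res$precision_median == 1))
  expect_true(all(res$recall_median == 1))
  expect_true(all(res$failures == 0))

  # half-truth segmenter: recall 0.5, precision 1
  halver <- function(target, rest) {
    lab <- rest$pairs[[1]]$labels
    d <- dim(lab$labels)
    keep <- array(FALSE, d)
    keep[, , seq_len(floor(d[3] / 2))] <- TRUE   # tubes are z-uniform
    out <- lab
    out$labels[!keep] <- 0L
    out
  }
  res2 <- loocv_atlas(atlas, halver)
  expect_true(all(abs(res2$recall_median - 0.5) < 0.1))
  expect_true(all(res2$precision_median == 1))

  # a segmenter that never finds extensor III: counted as failures
  dropper <- function(target, rest) {
    out <- rest$pairs[[1]]$labels
    out$labels[out$labels == 3L] <- 0L
    out
  }
  res3 <- loocv_atlas(atlas, dropper)
  expect_equal(res3$failures[res3$region == "extensor_III"], 3)
  expect_true(is.na(res3$precision_median[res3$region == "extensor_III"]))

  expect_error(loocv_atlas(atlas_set(pairs[1]), identity), "two atlas")
})
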