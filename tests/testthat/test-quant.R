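test_that("two-cluster FCM resolves well-separated intensities", {
  x <- c(rep(0, 1000), rep(100, 1000))
  m <- fit_fcm2(x)
  expect_lt(abs(m$centers[1] - 0), 0.5)
  expect_lt(abs(m$centers[2] - 100), 0.5)
  expect_gt(membership_c2(100, m), 0.99)

  # a point exactly midway between the centers has membership one half
  mid <- mean(m$centers)
  expect_equal(membership_c2(mid, m), 0.5, tolerance = 1e-12)

  # memberships complement each other by construction of the update
  probe <- seq(-10, 110, by = 7)
  u2 <- membership_c2(probe, m)
  expect_true(all(u2 >= 0 & u2 <= 1))

  # objective decreases monotonically
  expect_true(all(diff(m$objective) <= 1e-8 * m$objective[1]))

  expect_error(fit_fcm2(rep(3, 50)), "degenerate")
})

test_that("FCM matches an independent fixed-point oracle on a Gaussian mixture", {
  set.seed(123)
  n <- 1e5
  x <- c(rnorm(0.7 * n, 40, 5), rnorm(0.3 * n, 180, 10))
  m <- fit_fcm2(x)
  oracle <- fcm2_bruteforce(x, restarts = 100, tol = 1e-10, seed = 9)
  expect_lt(max(abs(m$centers - oracle$centers)), 5)
})

test_that("FCM centers agree with an established implementation", {
  set.seed(11)
  x <- c(rnorm(3000, 35, 6), rnorm(1500, 160, 12))
  m <- fit_fcm2(x)
  ref <- e1071::cmeans(matrix(x), centers = matrix(quantile(x, c(0.25, 0.75))),
                       m = 2, iter.max = 300)
  expect_equal(sort(as.vector(ref$centers)), m$centers, tolerance = 0.01)
})

test_that("FCM memberships are scale-equivariant", {
  set.seed(5)
  x <- c(rnorm(2000, 30, 4), rnorm(2000, 120, 8))
  m1 <- fit_fcm2(x)
  m2 <- fit_fcm2(3 * x)
  expect_equal(m2$centers, 3 * m1$centers, tolerance = 1e-3)
  probe <- seq(10, 140, by = 10)
  expect_equal(membership_c2(3 * probe, m2), membership_c2(probe, m1),
               tolerance = 1e-4)
})

test_that("the one-sided map zeroes everything below the C2 center", {
  v <- array(c(10, 50, 99.9, 100, 150, 0, 20, 130), c(2, 2, 2))
  img <- vol3d(v, spacing = c(1, 1, 1))
  model <- structure(list(centers = c(20, 100), m = 2, iterations = 1,
                          objective = 1, converged = TRUE), class = "fcm2_model")
  osm <- one_sided_map(img, model)
  expect_true(all(osm$p[v < 100] == 0))
  # at exactly the center the voxel is retained with its membership
  expect_equal(osm$p[v == 100], membership_c2(100, model))
  expect_true(all(osm$p[v > 100] > 0))
  expect_true(all(osm$p >= 0 & osm$p <= 1))

  # if every voxel is at or above c2 the map is just u2
  hi <- vol3d(array(c(100, 120, 150, 200), c(1, 2, 2)), spacing = c(1, 1, 1))
  osm2 <- one_sided_map(hi, model)
  expect_equal(as.vector(osm2$p), membership_c2(c(100, 120, 150, 200), model))
})

test_that("the fraction statistic honors the half-open threshold window", {
  p <- array(c(0, 0.5, 0.81, 0.82, 0.83, 0.90, 0.93, 0.94, 0.95, 1.0),
             c(10, 1, 1))
  roi <- array(TRUE, c(10, 1, 1))
  res <- tenosynovitis_fraction(as_c2_map(p), roi, 0.82, 0.94)
  expect_identical(res$fraction, 0.4)   # 0.82 in, 0.94 out
  expect_identical(res$n_qualifying, 4L)

  full <- tenosynovitis_fraction(as_c2_map(p), roi, 0, 1)
  expect_identical(full$fraction, 0.9)  # the exact 1.0 is excluded

  zero <- tenosynovitis_fraction(as_c2_map(array(0, c(10, 1, 1))), roi, 0.82, 0.94)
  expect_identical(zero$fraction, 0)

  none <- tenosynovitis_fraction(as_c2_map(p), array(FALSE, c(10, 1, 1)), 0.82, 0.94)
  expect_identical(none$fraction, 0)
  expect_true(none$empty_roi)

  expect_error(tenosynovitis_fraction(as_c2_map(p), roi, 0.9, 0.9), "t_low")

  # widening the window never lowers the fraction
  fr <- function(lo, hi) tenosynovitis_fraction(as_c2_map(p), roi, lo, hi)$fraction
  expect_true(fr(0.8, 0.95) >= fr(0.82, 0.94))
  expect_true(fr(0.82, 0.96) >= fr(0.82, 0.94))
})
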