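# Intensity-adaptive quantification. Per-acquisition intensity scales are
# absorbed by a two-cluster fuzzy C-means fit to all voxel intensities; the
# high cluster C2 tracks enhancing (synovial) tissue. Memberships in C2 are
# zeroed below the C2 center, keeping only hyper-enhancing voxels, and
# tenosynovitis is the fraction of ROI voxels whose one-sided membership
# falls in a calibrated probability window.

#' Two-cluster fuzzy C-means on image intensities
#'
#' Standard fuzzy C-means with c = 2 clusters on a 1D intensity sample:
#' memberships `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centers the
#' u^m-weighted intensity means, alternated until the centers move less
#' than `tol`. Centers are initialized at the 25th and 75th intensity
#' percentiles, which makes the fit deterministic, and are returned sorted
#' (`c1 < c2`). The objective `sum u^m d^2` is non-increasing over
#' iterations and its trace is returned.
#'
#' @param x numeric vector of intensities (all voxels of the image; at
#'   least two distinct values).
#' @param m fuzziness exponent (default 2).
#' @param tol convergence tolerance on maximum center movement.
#' @param max_iter iteration cap; non-convergence yields a warning, with
#'   the model still returned.
#' @return An object of class `fcm2_model`: `centers` (c1 < c2), `m`,
#'   `iterations`, `objective` (trace), `converged`.
#' @export
fit_fcm2 <- function(x, m = 2, tol = 1e-5, max_iter = 300) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2L)
    stop("degenerate clustering: need at least two distinct intensities",
         call. = FALSE)
  centers <- unname(quantile(x, c(0.25, 0.75)))
  if (centers[1] == centers[2]) centers <- range(x)
  exp_u <- 2 / (m - 1)
  obj_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- abs(x - centers[1])
    d2 <- abs(x - centers[2])
    # memberships for c = 2; exact-hit voxels get crisp membership
    r <- (d1 / d2)^exp_u
    u1 <- 1 / (1 + r)
    u1[d1 == 0] <- 1
    u1[d2 == 0 & d1 > 0] <- 0
    u2 <- 1 - u1
    w1 <- u1^m; w2 <- u2^m
    obj_trace <- c(obj_trace, sum(w1 * d1^2 + w2 * d2^2))
    new_centers <- c(sum(w1 * x) / sum(w1), sum(w2 * x) / sum(w2))
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fuzzy C-means did not converge within ", max_iter, " iterations",
            call. = FALSE)
  if (centers[1] > centers[2]) centers <- rev(centers)
  if (centers[1] == centers[2])
    stop("degenerate clustering: coincident cluster centers", call. = FALSE)
  structure(list(centers = centers, m = m, iterations = it,
                 objective = obj_trace, converged = converged),
            class = "fcm2_model")
}

#' @export
print.fcm2_model <- function(x, ...) {
  cat(sprintf("<fcm2_model> centers c1 = %.3f, c2 = %.3f (m = %g, %d iterations)\n",
              x$centers[1], x$centers[2], x$m, x$iterations))
  invisible(x)
}

#' Membership in the high-intensity cluster
#'
#' Evaluates the converged C2 membership `u2` at arbitrary intensities.
#' `u1 + u2 = 1` everywhere; a value exactly midway between the centers has
#' `u2 = 0.5` (for m = 2).
#'
#' @param x numeric intensities.
#' @param model an [fit_fcm2()] model.
#' @return Numeric vector of memberships in `[0, 1]`.
#' @export
membership_c2 <- function(x, model) {
  d1 <- abs(x - model$centers[1])
  d2 <- abs(x - model$centers[2])
  r <- (d2 / d1)^(2 / (model$m - 1))
  u2 <- 1 / (1 + r)
  u2[d2 == 0] <- 1
  u2[d1 == 0 & d2 > 0] <- 0
  u2
}

#' One-sided C2 probability map
#'
#' Per-voxel C2 membership with every voxel whose intensity lies strictly
#' below the C2 cluster center set to zero: healthy enhancing synovium near
#' the center keeps only the upper side, isolating hyper-enhancing
#' (inflamed) tissue. A voxel exactly at the C2 center is retained (the
#' removal rule is "lower than" the center).
#'
#' @param img a [vol3d()].
#' @param model an [fit_fcm2()] model fitted on this image's intensities.
#' @return An object of class `one_sided_c2`: list with `p` (3D array of
#'   values in `[0, 1]`) and the model.
#' @export
one_sided_map <- function(img, model) {
  stopifnot(is_vol3d(img), inherits(model, "fcm2_model"))
  u2 <- membership_c2(as.numeric(img$voxels), model)
  u2[as.numeric(img$voxels) < model$centers[2]] <- 0
  structure(list(p = array(u2, dim(img$voxels)), model = model,
                 spacing = img$spacing),
            class = "one_sided_c2")
}

#' Tenosynovitis fraction statistic
#'
#' The quantitative tenosynovitis measurement: the fraction of measurement
#' ROI voxels whose one-sided C2 probability lies in the half-open window
#' `T_L <= p < T_H`. The window is calibrated against visual scores (see
#' [grid_search()]); defaults are the method's reference operating point.
#'
#' @param map a [one_sided_map()] result.
#' @param roi a [build_roi()] result (or logical mask).
#' @param t_low,t_high window thresholds, `0 <= t_low < t_high <= 1`.
#' @return An object of class `quant_result`: `fraction`, `n_roi`,
#'   `n_qualifying`, `t_low`, `t_high`, `D` (if known), `empty_roi` flag.
#' @export
tenosynovitis_fraction <- function(map, roi, t_low = 0.82, t_high = 0.94) {
  stopifnot(inherits(map, "one_sided_c2"))
  if (t_low < 0 || t_high > 1 || t_low >= t_high)
    stop("need 0 <= t_low < t_high <= 1", call. = FALSE)
  mask <- if (inherits(roi, "measurement_roi")) roi$mask else roi
  if (!identical(dim(mask), dim(map$p)))
    stop("ROI and probability map must share a grid", call. = FALSE)
  p <- map$p[mask]
  n <- length(p)
  q <- sum(p >= t_low & p < t_high)
  structure(list(
    fraction = if (n == 0) 0 else q / n,
    n_roi = n,
    n_qualifying = q,
    t_low = t_low, t_high = t_high,
    D = if (inherits(roi, "measurement_roi")) roi$D else NA_real_,
    empty_roi = n == 0
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> fraction %.4f (%d of %d ROI voxels in [%.2f, %.2f))%s\n",
              x$fraction, x$n_qualifying, x$n_roi, x$t_low, x$t_high,
              if (x$empty_roi) " [empty ROI]" else ""))
  invisible(x)
}
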