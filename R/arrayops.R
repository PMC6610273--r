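# Internal array machinery shared by the acquisition model, the SRR solver,
# the registration pyramid and the morphology helpers. All operators are
# separable along the three grid axes and applied as sparse matrix products,
# which keeps everything matrix-free at the volume level.

# Apply a matrix M (n_out x n_axis) along one axis of a 3D array. Axes 1
# and 3 reshape without permutation; only axis 2 needs an aperm round trip.
# M may be a base matrix (small axes: dense BLAS beats sparse dispatch) or
# a sparse Matrix (large axes, where the banded structure pays off).
axis_apply <- function(arr, M, axis) {
  d <- dim(arr)
  n_out <- nrow(M)
  dense <- is.matrix(M)
  mul <- function(A, B) if (dense) A %*% B else as.matrix(A %*% B)
  tM <- function() if (dense) t(M) else Matrix::t(M)
  if (axis == 1L) {
    out <- mul(M, matrix(arr, nrow = d[1]))
    dim(out) <- c(n_out, d[2], d[3])
    out
  } else if (axis == 3L) {
    out <- mul(matrix(arr, ncol = d[3]), tM())
    dim(out) <- c(d[1], d[2], n_out)
    out
  } else {
    a <- aperm(arr, c(1, 3, 2))
    out <- mul(matrix(a, ncol = d[2]), tM())
    dim(out) <- c(d[1], d[3], n_out)
    aperm(out, c(1, 3, 2))
  }
}

# Box-overlap weight matrix: rows are output samples (center `oc`, window
# width `w`), columns input samples (center `ic`, extent `is`). Entry (i, j)
# is the length of overlap between output window i and input voxel extent j,
# normalized so each row sums to 1 (partition of unity: constants map to
# constants even where the window is truncated by the grid edge).
overlap_weights <- function(oc, w, ic, is) {
  n_in <- length(ic)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_along(oc)) {
    lo <- oc[i] - w / 2
    hi <- oc[i] + w / 2
    j0 <- max(1L, floor((lo - (ic[1] - is / 2)) / is) + 1L)
    j1 <- min(n_in, ceiling((hi - (ic[1] - is / 2)) / is) + 1L)
    if (j1 < j0) next
    j <- j0:j1
    ov <- pmax(0, pmin(hi, ic[j] + is / 2) - pmax(lo, ic[j] - is / 2))
    keep <- ov > 0
    if (!any(keep)) next
    rows <- c(rows, rep.int(i, sum(keep)))
    cols <- c(cols, j[keep])
    vals <- c(vals, ov[keep])
  }
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(length(oc), n_in))
  rs <- Matrix::rowSums(M)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% M
}

# Banded convolution matrix (dense) with replicate boundary handling.
kernel_matrix <- function(n, kern) {
  r <- (length(kern) - 1L) / 2L
  M <- matrix(0, n, n)
  for (k in seq_along(kern)) {
    off <- k - 1L - r
    j <- pmin(pmax(seq_len(n) + off, 1L), n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + kern[k]
  }
  M
}

gaussian_kernel <- function(sigma_vox, deriv = FALSE) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (deriv) -x / sigma_vox^2 * g else g
}

# Separable Gaussian smoothing, sigma in mm per axis.
gauss_smooth <- function(arr, sigma_mm, spacing) {
  if (length(sigma_mm) == 1) sigma_mm <- rep(sigma_mm, 3)
  for (a in 1:3) {
    sv <- sigma_mm[a] / spacing[a]
    if (sv < 1e-3 || dim(arr)[a] < 3) next
    arr <- axis_apply(arr, kernel_matrix(dim(arr)[a], gaussian_kernel(sv)), a)
  }
  arr
}

# Gaussian-derivative gradient magnitude in physical units (1/mm scaling).
gradient_magnitude <- function(arr, spacing, sigma_mm = 0.3) {
  g2 <- array(0, dim(arr))
  for (a in 1:3) {
    sv <- max(sigma_mm / spacing[a], 0.5)
    da <- arr
    for (b in 1:3) {
      if (dim(da)[b] < 3) next
      kern <- if (b == a) gaussian_kernel(sv, deriv = TRUE) / spacing[a]
              else gaussian_kernel(max(sigma_mm / spacing[b], 0.5))
      da <- axis_apply(da, kernel_matrix(dim(da)[b], kern), b)
    }
    g2 <- g2 + da^2
  }
  sqrt(g2)
}

# 6-neighbor graph Laplacian with replicate boundary: sum over face
# neighbors of (x_j - x_i). Symmetric, so L^T L = L %*% L.
laplacian3 <- function(arr) {
  out <- cpp_laplacian6(arr, dim(arr))
  dim(out) <- dim(arr)
  out
}

#' Euclidean distance to a voxel set
#'
#' Exact Euclidean distance transform: for every voxel, the distance in mm
#' to the nearest `TRUE` voxel of `mask`, honoring anisotropic spacing.
#' Voxels are treated as point samples at their centers.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm (length 3).
#' @return Numeric 3D array of distances (0 on the mask, `Inf` if the mask
#'   is empty).
#' @export
distance_to <- function(mask, spacing) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- cpp_edt(as.logical(mask), dim(mask), as.numeric(spacing))
  array(d, dim(mask))
}

# Morphology via the distance transform (radii in mm).
erode_mm <- function(mask, radius, spacing) {
  if (radius <= 0) return(mask)
  mask & (distance_to(!mask, spacing) > radius)
}

dilate_mm <- function(mask, radius, spacing) {
  if (radius <= 0) return(mask)
  distance_to(mask, spacing) <= radius
}

# Connected components, 26-connectivity.
label_components <- function(mask) {
  array(cpp_label_components(as.logical(mask), dim(mask)), dim(mask))
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}
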