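# Multi-atlas machinery: a pluggable transform provider (affine optimizer or
# identity for co-registered data), nearest-neighbor label transfer and
# per-voxel majority-vote fusion.

#' Affine spatial transform
#'
#' Parametric map from target physical coordinates to atlas physical
#' coordinates: `T(x) = A (x - c) + c + t`, with `A` a 3x3 matrix, `t` a
#' translation (mm) and `c` a fixed center (mm) about which the linear part
#' acts. Twelve free parameters.
#'
#' @param A 3x3 matrix (must be non-singular).
#' @param t translation, length 3 (mm).
#' @param center rotation/scaling center, length 3 (mm).
#' @param similarity mean squared intensity difference achieved when the
#'   transform came out of registration (`NA` otherwise).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0), center = c(0, 0, 0),
                             similarity = NA_real_) {
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) < 1e-12) stop("affine matrix is singular", call. = FALSE)
  structure(list(A = A, t = as.numeric(t), center = as.numeric(center),
                 similarity = similarity),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> translation", sprintf("%.3f", x$t), "mm\n")
  print(round(x$A, 4))
  if (!is.na(x$similarity)) cat("  MSD:", format(x$similarity), "\n")
  invisible(x)
}

# Map Nx3 physical points through the transform.
apply_transform <- function(tr, pts) {
  sweep(pts, 2, tr$center) %*% t(tr$A) +
    matrix(tr$center + tr$t, nrow(pts), 3, byrow = TRUE)
}

# Physical coordinates of every voxel of a grid, as an Nx3 matrix.
grid_points <- function(g) {
  cbind(
    rep(g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1],
        times = g$dim[2] * g$dim[3]),
    rep(rep(g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2],
            each = g$dim[1]), times = g$dim[3]),
    rep(g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3],
        each = g$dim[1] * g$dim[2])
  )
}

# Interior sample points of a grid: voxels at least `margin` mm away from
# every face. A fixed interior point set keeps the similarity metric smooth
# under moderate transforms (no samples cross the volume boundary) and
# comparable across iterations.
interior_points <- function(g, margin) {
  idx <- lapply(1:3, function(a) {
    co <- g$origin[a] + (seq_len(g$dim[a]) - 1) * g$spacing[a]
    keep <- co >= g$origin[a] + margin &
            co <= g$origin[a] + (g$dim[a] - 1) * g$spacing[a] - margin
    if (!any(keep)) keep[ceiling(g$dim[a] / 2)] <- TRUE
    keep
  })
  pts <- grid_points(g)
  keep3 <- as.vector(outer(outer(idx[[1]], idx[[2]], `&`), idx[[3]], `&`))
  list(pts = pts[keep3, , drop = FALSE], keep = keep3)
}

# Trilinear sampling of a vol3d at physical points (outside -> fill).
sample_volume <- function(img, pts, fill = 0) {
  xi <- (pts[, 1] - img$origin[1]) / img$spacing[1]
  yi <- (pts[, 2] - img$origin[2]) / img$spacing[2]
  zi <- (pts[, 3] - img$origin[3]) / img$spacing[3]
  cpp_trilinear(as.numeric(img$voxels), dim(img$voxels), xi, yi, zi, fill)
}

# Downsample a volume by an integer factor per axis (box average), with a
# little Gaussian presmoothing to avoid aliasing.
downsample_volume <- function(img, factor) {
  if (all(factor == 1)) return(img)
  v <- gauss_smooth(img$voxels, 0.4 * factor * img$spacing, img$spacing)
  g <- list(dim = pmax(2L, floor(dim(img$voxels) / factor)),
            spacing = img$spacing * factor,
            origin = img$origin + (factor - 1) / 2 * img$spacing)
  Ws <- lapply(1:3, function(a) {
    oc <- g$origin[a] + (seq_len(g$dim[a]) - 1) * g$spacing[a]
    as.matrix(overlap_weights(oc, g$spacing[a], axis_coords(img, a), img$spacing[a]))
  })
  for (a in 1:3) v <- axis_apply(v, Ws[[a]], a)
  vol3d(v, spacing = g$spacing, origin = g$origin)
}

# Central-difference spatial gradient of a volume (per mm), as three arrays.
volume_gradient <- function(img) {
  v <- img$voxels
  d <- dim(v)
  gs <- vector("list", 3)
  for (a in 1:3) {
    n <- d[a]
    up <- c(2:n, n); dn <- c(1, 1:(n - 1))
    den <- 2 * img$spacing[a]
    g <- if (a == 1) (v[up, , , drop = FALSE] - v[dn, , , drop = FALSE])
         else if (a == 2) (v[, up, , drop = FALSE] - v[, dn, , drop = FALSE])
         else (v[, , up, drop = FALSE] - v[, , dn, drop = FALSE])
    gs[[a]] <- g / den
  }
  gs
}

#' Register an atlas image to a target image (affine, multi-resolution)
#'
#' Estimates the 12-parameter affine transform minimizing the mean squared
#' intensity difference between the target and the resampled atlas image,
#' by gradient descent with backtracking line search over a coarse-to-fine
#' resolution pyramid. The analytic gradient uses the atlas image gradient
#' sampled at the transformed points. Starting from the identity and
#' accepting only improving steps guarantees the achieved similarity is
#' never worse than the identity's. If no improving step exists at the
#' finest level and the final similarity exceeds the identity's, a
#' registration-failure condition is signaled carrying the identity
#' transform.
#'
#' @param atlas_img,target_img [vol3d()] volumes with overlapping extents.
#' @param levels integer downsampling factors, coarse to fine.
#' @param max_iter gradient-descent iterations per level (each level runs a
#'   translation-only stage, then the full affine).
#' @param step0 initial step length in scaled parameter units.
#' @param margin_mm margin excluded from the similarity samples at every
#'   target face, so moderate transforms never push samples across the
#'   atlas boundary (which would make the metric discontinuous).
#' @return An [affine_transform()] with the achieved MSD in `$similarity`.
#' @export
register_affine <- function(atlas_img, target_img, levels = c(4, 2, 1),
                            max_iter = 40, step0 = 0.1, margin_mm = 4) {
  stopifnot(is_vol3d(atlas_img), is_vol3d(target_img))
  check_grid_overlap(dim(atlas_img$voxels), atlas_img$spacing, atlas_img$origin,
                     dim(target_img$voxels), target_img$spacing, target_img$origin)
  g_t <- as_grid(target_img)
  center <- g_t$origin + (g_t$dim - 1) * g_t$spacing / 2
  # parameter scale: translations in mm, matrix entries unitless; couple them
  # through the field radius so one step unit moves points comparably
  radius <- max((g_t$dim - 1) * g_t$spacing) / 2

  theta <- c(as.numeric(diag(3)), 0, 0, 0)   # A column-major, then t

  for (fac in levels) {
    tgt <- downsample_volume(target_img, rep(fac, 3))
    atl <- downsample_volume(atlas_img, rep(fac, 3))
    gl <- as_grid(tgt)
    ip <- interior_points(gl, margin_mm)
    pts <- ip$pts
    tv <- as.numeric(tgt$voxels)[ip$keep]
    grads <- volume_gradient(atl)
    gvols <- lapply(grads, function(g) vol3d(g, atl$spacing, atl$origin))

    msd_of <- function(th) {
      tr <- affine_transform(matrix(th[1:9], 3, 3), th[10:12], center)
      av <- sample_volume(atl, apply_transform(tr, pts))
      mean((av - tv)^2)
    }
    # gradient in scaled parameter units: matrix entries act through lever
    # arms up to `radius` mm, so their components are divided by radius to
    # match the translation scale (a diagonal preconditioner)
    grad_of <- function(th) {
      tr <- affine_transform(matrix(th[1:9], 3, 3), th[10:12], center)
      tp <- apply_transform(tr, pts)
      av <- sample_volume(atl, tp)
      res <- av - tv
      G <- cbind(sample_volume(gvols[[1]], tp),
                 sample_volume(gvols[[2]], tp),
                 sample_volume(gvols[[3]], tp))
      xc <- sweep(pts, 2, center)
      g <- numeric(12)
      for (i in 1:3) {
        rg <- res * G[, i]
        for (j in 1:3) g[(j - 1) * 3 + i] <- 2 * mean(rg * xc[, j]) / radius
        g[9 + i] <- 2 * mean(rg)
      }
      g
    }

    descend <- function(theta, free, max_iter) {
      f <- msd_of(theta)
      step <- step0
      for (it in seq_len(max_iter)) {
        g <- grad_of(theta)
        g[!free] <- 0
        gn <- sqrt(sum(g^2))
        if (gn < 1e-14) break
        dir <- -g / gn
        dir[1:9] <- dir[1:9] / radius   # scaled units back to matrix entries
        improved <- FALSE
        while (step > 1e-7) {
          cand <- theta + step * dir
          fc <- msd_of(cand)
          if (fc < f - 1e-14) {
            theta <- cand; f <- fc
            step <- step * 1.5
            improved <- TRUE
            break
          }
          step <- step / 2
        }
        if (!improved) break
      }
      theta
    }
    # translation first, then the full affine
    theta <- descend(theta, c(rep(FALSE, 9), rep(TRUE, 3)), max_iter)
    theta <- descend(theta, rep(TRUE, 12), max_iter)
  }

  final <- affine_transform(matrix(theta[1:9], 3, 3), theta[10:12], center,
                            similarity = msd_of_final(atlas_img, target_img,
                                                      theta, center, margin_mm))
  id_msd <- msd_of_final(atlas_img, target_img,
                         c(as.numeric(diag(3)), 0, 0, 0), center, margin_mm)
  if (final$similarity > id_msd) {
    warning("registration failed to improve on the identity transform",
            call. = FALSE)
    return(affine_transform(center = center, similarity = id_msd))
  }
  final
}

msd_of_final <- function(atlas_img, target_img, theta, center, margin_mm) {
  tr <- affine_transform(matrix(theta[1:9], 3, 3), theta[10:12], center)
  ip <- interior_points(as_grid(target_img), margin_mm)
  av <- sample_volume(atlas_img, apply_transform(tr, ip$pts))
  mean((av - as.numeric(target_img$voxels)[ip$keep])^2)
}

#' Transfer atlas labels to a target grid through a transform
#'
#' Each target voxel is mapped into atlas space and takes the label of the
#' nearest atlas voxel; coordinates falling outside the atlas extent become
#' background.
#'
#' @param tr an [affine_transform()] (target physical -> atlas physical).
#' @param atlas_lab a [region_label_map()].
#' @param target target grid descriptor.
#' @return A [region_label_map()] on the target grid.
#' @export
transfer_labels <- function(tr, atlas_lab, target) {
  g <- as_grid(target)
  pts <- apply_transform(tr, grid_points(g))
  i <- round((pts[, 1] - atlas_lab$origin[1]) / atlas_lab$spacing[1]) + 1
  j <- round((pts[, 2] - atlas_lab$origin[2]) / atlas_lab$spacing[2]) + 1
  k <- round((pts[, 3] - atlas_lab$origin[3]) / atlas_lab$spacing[3]) + 1
  d <- dim(atlas_lab$labels)
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- integer(prod(g$dim))
  if (any(inside)) {
    lin <- (k[inside] - 1) * d[1] * d[2] + (j[inside] - 1) * d[1] + i[inside]
    out[inside] <- atlas_lab$labels[lin]
  }
  region_label_map(array(out, g$dim), spacing = g$spacing, origin = g$origin)
}

#' Fuse candidate label maps by per-voxel majority vote
#'
#' Plurality fusion: at each voxel the label with the highest count across
#' candidates wins; any tie (including between two non-background labels)
#' resolves to background, the conservative "neither" outcome. With a
#' closed vocabulary and up to a dozen classes a strict absolute majority
#' may be unattainable, so plurality is used, as is standard in multi-atlas
#' fusion.
#'
#' @param candidates non-empty list of [region_label_map()] on one grid.
#' @return A [region_label_map()].
#' @export
majority_vote <- function(candidates) {
  if (!length(candidates)) stop("no candidate label maps", call. = FALSE)
  d <- dim(candidates[[1]]$labels)
  for (cd in candidates)
    if (!identical(dim(cd$labels), d) ||
        max(abs(cd$spacing - candidates[[1]]$spacing)) > 1e-9)
      stop("candidate label maps must share one grid", call. = FALSE)
  codes <- sort(unique(unlist(lapply(candidates, function(cd)
    unique(as.vector(cd$labels))))))
  codes <- setdiff(codes, 0L)
  n <- prod(d)
  bg_count <- integer(n)
  for (cd in candidates) bg_count <- bg_count + (as.vector(cd$labels) == 0L)
  best_count <- bg_count
  best_code <- integer(n)           # background
  tied <- logical(n)
  for (code in codes) {
    cnt <- integer(n)
    for (cd in candidates) cnt <- cnt + (as.vector(cd$labels) == code)
    gt <- cnt > best_count
    eq <- cnt == best_count & cnt > 0L
    best_code[gt] <- code
    best_count[gt] <- cnt[gt]
    tied[gt] <- FALSE
    tied[eq] <- TRUE
  }
  best_code[tied] <- 0L
  region_label_map(array(best_code, d),
                   spacing = candidates[[1]]$spacing,
                   origin = candidates[[1]]$origin)
}

#' Atlas set
#'
#' A collection of (intensity volume, label map) pairs from manually
#' annotated reference wrists, all of one handedness.
#'
#' @param pairs list of `list(image = vol3d, labels = region_label_map)`.
#' @param handedness `"right"` (the convention for stored atlases) or
#'   `"left"`.
#' @return An object of class `atlas_set`.
#' @export
atlas_set <- function(pairs, handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  if (!length(pairs)) stop("atlas set must be non-empty", call. = FALSE)
  for (p in pairs) {
    stopifnot(is_vol3d(p$image), inherits(p$labels, "region_label_map"))
    if (!identical(dim(p$image$voxels), dim(p$labels$labels)))
      stop("atlas image and labels must share a grid", call. = FALSE)
  }
  structure(list(pairs = pairs, handedness = handedness), class = "atlas_set")
}

#' @export
length.atlas_set <- function(x) length(x$pairs)

#' Load an atlas set from a directory
#'
#' Reads paired `caseNN_img.nii.gz` / `caseNN_lab.nii.gz` files (any case
#' identifier works; `_img` / `_lab` suffixes pair them).
#'
#' @param dir directory containing the paired NIfTI files.
#' @param handedness handedness of the stored atlas wrists.
#' @return An [atlas_set()].
#' @export
load_atlas_dir <- function(dir, handedness = "right") {
  imgs <- sort(list.files(dir, pattern = "_img\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(imgs)) stop("no *_img.nii[.gz] files in ", dir, call. = FALSE)
  pairs <- lapply(imgs, function(f) {
    lab <- sub("_img\\.nii", "_lab.nii", f)
    if (!file.exists(lab)) stop("missing label map for ", f, call. = FALSE)
    list(image = load_volume(f), labels = load_label_map(lab))
  })
  atlas_set(pairs, handedness = handedness)
}

#' Adapt an atlas set to the target wrist's handedness
#'
#' Atlases are stored for one handedness (conventionally right wrists).
#' Targets of the opposite handedness receive horizontally mirrored copies
#' of every atlas image and label map; matching targets get the atlas
#' unchanged. The stored atlas is never modified.
#'
#' @param atlas an [atlas_set()].
#' @param target_handedness `"left"` or `"right"`.
#' @return An [atlas_set()] ready for registration against the target.
#' @export
prepare_for_handedness <- function(atlas, target_handedness = c("right", "left")) {
  target_handedness <- match.arg(target_handedness)
  if (target_handedness == atlas$handedness) return(atlas)
  flipped <- lapply(atlas$pairs, function(p)
    list(image = mirror_horizontal(p$image),
         labels = mirror_horizontal(p$labels)))
  atlas_set(flipped, handedness = target_handedness)
}

#' Segment a target image with a multi-atlas vote
#'
#' Convenience wrapper running the full atlas stage: handedness
#' preparation, per-atlas registration, nearest-neighbor label transfer to
#' the target grid, and majority-vote fusion.
#'
#' @param target a [vol3d()] (typically the SRR volume).
#' @param atlas an [atlas_set()].
#' @param handedness handedness of the target wrist.
#' @param registration `"affine"` for the multi-resolution optimizer, or
#'   `"identity"` when atlas and target are already co-registered (e.g.
#'   phantoms generated on one grid).
#' @param ... passed on to [register_affine()].
#' @return A fused [region_label_map()] on the target grid.
#' @export
atlas_segment <- function(target, atlas, handedness = "right",
                          registration = c("affine", "identity"), ...) {
  registration <- match.arg(registration)
  atlas <- prepare_for_handedness(atlas, handedness)
  g <- as_grid(target)
  cands <- lapply(atlas$pairs, function(p) {
    if (registration == "identity") {
      # co-registered grids: nearest-neighbor resampling is the identity
      # transfer, without the per-voxel coordinate mapping
      resample_labels_nearest(p$labels, g)
    } else {
      tr <- register_affine(p$image, target, ...)
      transfer_labels(tr, p$labels, g)
    }
  })
  majority_vote(cands)
}
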