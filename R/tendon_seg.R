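# Tendon segmentation: atlas-derived landmarks are eroded into inside
# markers, their dilated complement becomes the outside marker, a
# marker-based watershed of the gradient-magnitude image grows the tendons,
# and implausible catchments are rejected by intensity and volume rules.

OUTSIDE_MARKER <- 99L

#' Build watershed markers from fused atlas labels
#'
#' Inside markers are the morphological erosion of each tendon label
#' (distance-transform based, radius in mm); the outside marker is the
#' complement of the dilated union of all tendon labels. A tendon label
#' that vanishes under erosion falls back to its single innermost voxel
#' (maximum distance to the label boundary), with a warning, so every
#' region with atlas support keeps a marker.
#'
#' @param fused a [region_label_map()] containing at least one tendon label.
#' @param erosion_mm marker erosion radius (mm).
#' @param dilation_mm dilation radius for the outside-marker exclusion zone
#'   (mm).
#' @return Integer 3D array of class `marker_image`: tendon codes 1-10 for
#'   inside markers, 99 for the outside marker, 0 elsewhere. Spacing kept
#'   in attribute `spacing`.
#' @export
make_markers <- function(fused, erosion_mm = 0.4, dilation_mm = 1.0) {
  stopifnot(inherits(fused, "region_label_map"))
  sp <- fused$spacing
  lab <- fused$labels
  present <- intersect(tendon_codes(), unique(as.vector(lab)))
  if (!length(present))
    stop("fused label map contains no tendon labels", call. = FALSE)
  markers <- array(0L, dim(lab))
  union_tendon <- array(FALSE, dim(lab))
  for (code in present) {
    m <- lab == code
    union_tendon <- union_tendon | m
    din <- distance_to(!m, sp)
    marker <- m & din > erosion_mm
    if (!any(marker)) {
      warning("tendon label ", code, " vanished under erosion; ",
              "falling back to its innermost voxel", call. = FALSE)
      inner <- which(m)[which.max(din[m])]
      marker <- array(FALSE, dim(lab))
      marker[inner] <- TRUE
    }
    markers[marker] <- code
  }
  outside <- !dilate_mm(union_tendon, dilation_mm, sp)
  markers[outside] <- OUTSIDE_MARKER
  structure(markers, spacing = sp, class = c("marker_image", "array"))
}

#' Marker-based watershed segmentation of tendons
#'
#' Floods the Gaussian-derivative gradient magnitude of the image from the
#' markers (26-connectivity, deterministic tie-breaking). Voxels captured
#' by the outside marker are discarded; each surviving catchment becomes
#' one segmented region per tendon code, carrying its mean intensity in
#' native units and its volume in ml.
#'
#' @param img a [vol3d()].
#' @param markers a `marker_image` from [make_markers()].
#' @param sigma_mm smoothing scale of the gradient filter (mm).
#' @return List of `segmented_region` objects (fields `code`, `voxels`
#'   linear indices, `mean_intensity`, `volume_ml`).
#' @export
watershed_segment <- function(img, markers, sigma_mm = 0.3) {
  stopifnot(is_vol3d(img))
  if (!any(markers > 0L)) stop("empty marker image", call. = FALSE)
  if (!identical(dim(img$voxels), dim(markers)))
    stop("image and markers must share a grid", call. = FALSE)
  relief <- gradient_magnitude(img$voxels, img$spacing, sigma_mm)
  lab <- cpp_watershed(as.numeric(relief), as.integer(markers), dim(markers))
  lab <- array(lab, dim(markers))
  voxvol_ml <- prod(img$spacing) / 1000
  codes <- setdiff(sort(unique(as.vector(lab))), c(0L, OUTSIDE_MARKER))
  lapply(codes, function(code) {
    vox <- which(lab == code)
    structure(list(code = code,
                   voxels = vox,
                   mean_intensity = mean(img$voxels[vox]),
                   volume_ml = length(vox) * voxvol_ml),
              class = "segmented_region")
  })
}

#' @export
print.segmented_region <- function(x, ...) {
  cat(sprintf("<segmented_region> code %d: %d voxels, %.4f ml, mean intensity %.1f\n",
              x$code, length(x$voxels), x$volume_ml, x$mean_intensity))
  invisible(x)
}

#' Reject implausible tendon segmentations
#'
#' Tendons are dark on contrast-enhanced fat-saturated images, so
#' catchments whose mean intensity exceeds `intensity_max` (default 75,
#' native units) are removed, as are fragments smaller than
#' `min_volume_ml` (default 0.01 ml). Survivors are written to a label map
#' under their tendon codes; an empty result is allowed (it marks a failed
#' segmentation).
#'
#' @param regions list of `segmented_region` from [watershed_segment()].
#' @param grid grid descriptor for the output map.
#' @param intensity_max mean-intensity rejection threshold (regions above
#'   are dropped).
#' @param min_volume_ml volume rejection threshold (regions below are
#'   dropped).
#' @return A [region_label_map()] of surviving tendon regions.
#' @export
filter_regions <- function(regions, grid, intensity_max = 75, min_volume_ml = 0.01) {
  g <- as_grid(grid)
  out <- array(0L, g$dim)
  for (r in regions) {
    if (r$mean_intensity > intensity_max) next
    if (r$volume_ml < min_volume_ml) next
    out[r$voxels] <- as.integer(r$code)
  }
  region_label_map(out, spacing = g$spacing, origin = g$origin)
}

#' Segmentation precision and recall
#'
#' Voxel-overlap agreement between an automatic and a manual mask:
#' precision is the fraction of automatically segmented voxels that lie in
#' the manual segmentation; recall is the fraction of manual voxels that
#' were found automatically. Undefined rates (empty automatic mask for
#' precision, empty manual mask for recall) are reported as `NA`, not 0.
#'
#' @param auto,manual logical arrays on one grid.
#' @return Named numeric: `precision`, `recall`.
#' @export
precision_recall <- function(auto, manual) {
  if (!identical(dim(auto), dim(manual)))
    stop("masks must share a grid", call. = FALSE)
  inter <- sum(auto & manual)
  na <- sum(auto)
  nm <- sum(manual)
  c(precision = if (na == 0) NA_real_ else inter / na,
    recall = if (nm == 0) NA_real_ else inter / nm)
}
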