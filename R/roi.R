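# Measurement ROI: the distance-D shell around the segmented tendons,
# restricted to the hand, excluding every labeled structure, and bounded
# along the axial axis by two bone-derived slice rules.

#' Segment the hand extent
#'
#' Approximates the image region bounded by skin: the air background is
#' grown from the four corners of every axial slice (voxels connected to a
#' corner seed and below the intensity tolerance), the result is inverted,
#' and the largest connected component is kept. Corner seeds that fall on
#' tissue are skipped with a warning; if every seed is skipped, an error is
#' raised.
#'
#' @param img a [vol3d()].
#' @param tolerance background intensity tolerance; voxels strictly below
#'   it can join the background region. Default: 10% of the 99th intensity
#'   percentile, which adapts to the acquisition's intensity scale.
#' @return Logical 3D array (`TRUE` inside the hand).
#' @export
hand_mask <- function(img, tolerance = NULL) {
  stopifnot(is_vol3d(img))
  v <- img$voxels
  if (is.null(tolerance)) tolerance <- 0.1 * quantile(v, 0.99, names = FALSE)
  d <- dim(v)
  low <- v < tolerance
  corners <- cbind(
    rep(c(1L, d[1], 1L, d[1]), d[3]),
    rep(c(1L, 1L, d[2], d[2]), d[3]),
    rep(seq_len(d[3]), each = 4)
  )
  seed_ok <- low[corners]
  if (!any(seed_ok))
    stop("no background found at any slice corner (degenerate image)",
         call. = FALSE)
  if (any(!seed_ok))
    warning(sum(!seed_ok), " corner seed(s) fell on tissue and were skipped",
            call. = FALSE)
  comp <- label_components(low)
  seed_labels <- setdiff(unique(comp[corners[seed_ok, , drop = FALSE]]), 0L)
  background <- array(comp %in% seed_labels, d)
  fg <- !background
  if (!any(fg)) stop("no foreground component found", call. = FALSE)
  out <- largest_component(fg)
  if (!any(out)) stop("no foreground component found", call. = FALSE)
  out
}

#' Proximal axial boundary from the radius-ulna gap
#'
#' The proximal end of the measurement region is the axial slice on which
#' the distal radius and ulna come closest: for every slice containing both
#' bones, the minimum in-plane Euclidean distance between their voxels is
#' computed, and the slice with the smallest distance is returned (most
#' distal slice on ties).
#'
#' @param labels a [region_label_map()] containing radius and ulna labels.
#' @return Axial slice index (1-based).
#' @export
proximal_boundary <- function(labels) {
  lab <- labels$labels
  sp <- labels$spacing
  rad_code <- label_code("radius"); uln_code <- label_code("ulna")
  if (!any(lab == rad_code)) stop("radius label absent", call. = FALSE)
  if (!any(lab == uln_code)) stop("ulna label absent", call. = FALSE)
  nz <- dim(lab)[3]
  gap <- rep(Inf, nz)
  for (z in seq_len(nz)) {
    sl <- lab[, , z]
    rad <- sl == rad_code
    uln <- sl == uln_code
    if (!any(rad) || !any(uln)) next
    dmap <- cpp_edt(as.logical(uln), c(dim(sl), 1L), c(sp[1], sp[2], 1))
    gap[z] <- min(dmap[as.vector(rad)])
  }
  if (all(!is.finite(gap)))
    stop("no axial slice contains both radius and ulna", call. = FALSE)
  max(which(gap == min(gap)))
}

#' Distal axial boundary from the hamate
#'
#' The distal end of the measurement region is the axial slice holding the
#' largest number of hamate voxels (its widest cross-section, near the
#' hook); ties resolve to the most distal slice.
#'
#' @param labels a [region_label_map()] containing the hamate label.
#' @return Axial slice index (1-based).
#' @export
distal_boundary <- function(labels) {
  lab <- labels$labels
  ham <- lab == label_code("hamate")
  if (!any(ham)) stop("hamate label absent", call. = FALSE)
  counts <- apply(ham, 3, sum)
  max(which(counts == max(counts)))
}

#' Build the measurement ROI around the segmented tendons
#'
#' The ROI contains every voxel within Euclidean distance `D` (mm,
#' inclusive, honoring anisotropic spacing) of a segmented tendon voxel,
#' that carries no label itself, lies inside the hand mask, and whose axial
#' slice index falls within `[proximal, distal]`.
#'
#' @param tendons [region_label_map()] of segmented tendons (non-empty).
#' @param all_labels [region_label_map()] of every labeled structure
#'   (tendons and bones) to exclude from the ROI.
#' @param hand logical hand mask on the same grid.
#' @param D shell distance in mm (> 0).
#' @param bounds integer length-2 `(proximal, distal)` axial slice indices.
#' @return An object of class `measurement_roi`: list with logical `mask`,
#'   `D`, `proximal`, `distal`. Empty result is allowed, with a warning.
#' @export
build_roi <- function(tendons, all_labels, hand, D, bounds) {
  stopifnot(inherits(tendons, "region_label_map"),
            inherits(all_labels, "region_label_map"))
  if (D <= 0) stop("`D` must be positive (mm)", call. = FALSE)
  bounds <- as.integer(bounds)
  if (length(bounds) != 2L || bounds[1] > bounds[2])
    stop("`bounds` must be (proximal, distal) with proximal <= distal",
         call. = FALSE)
  tmask <- tendons$labels %in% tendon_codes()
  dim(tmask) <- dim(tendons$labels)
  if (!any(tmask)) stop("no segmented tendon voxels", call. = FALSE)
  dt <- distance_to(tmask, tendons$spacing)
  mask <- dt <= D & all_labels$labels == 0L & hand
  zidx <- slice.index(mask, 3)
  mask <- mask & zidx >= bounds[1] & zidx <= bounds[2]
  if (!any(mask)) warning("measurement ROI is empty", call. = FALSE)
  structure(list(mask = mask, D = D,
                 proximal = bounds[1], distal = bounds[2],
                 spacing = tendons$spacing),
            class = "measurement_roi")
}

#' @export
print.measurement_roi <- function(x, ...) {
  cat(sprintf("<measurement_roi> D = %g mm, %d voxels, axial slices %d..%d\n",
              x$D, sum(x$mask), x$proximal, x$distal))
  invisible(x)
}
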