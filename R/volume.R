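#' Volumetric scalar image
#'
#' The basic container used throughout the pipeline: a 3D scalar array with
#' per-axis physical spacing and an axis-aligned origin. Voxels are point
#' samples; the physical position of voxel `(i, j, k)` (1-based R indices)
#' is `origin + (c(i, j, k) - 1) * spacing`. Array axes are always in
#' anatomical order `(x, y, z)`: x runs left-right, y dorsal-volar, z
#' proximal-distal, so z indexes the axial slices. The through-slice axis of
#' an anisotropic acquisition is carried in metadata (`plane`,
#' `thick_axis`, `slice_thickness`) rather than by permuting the array, so
#' that co-registered scans share one coordinate frame.
#'
#' @param voxels numeric 3D array of intensities (finite values only).
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#'   For anisotropic scans the through-slice component is the *effective*
#'   spacing, i.e. slice thickness plus inter-slice gap.
#' @param origin numeric length-3, physical position (mm) of the first voxel.
#' @param plane acquisition plane: `"axial"`, `"coronal"` or
#'   `"isotropic-SRR"`.
#' @param slice_thickness slice-profile width in mm along the through-slice
#'   axis; `NA` for isotropic volumes.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(voxels, spacing, origin = c(0, 0, 0),
                  plane = c("isotropic-SRR", "axial", "coronal"),
                  slice_thickness = NA_real_) {
  plane <- match.arg(plane)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions",
         call. = FALSE)
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("volume contains non-finite intensities", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         plane = plane, slice_thickness = as.numeric(slice_thickness)),
    class = "vol3d"
  )
}

#' @export
dim.vol3d <- function(x) dim(x$voxels)

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, plane %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$plane))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              min(x$voxels), max(x$voxels), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Through-slice anatomical axis implied by the acquisition plane.
plane_axis <- function(plane) {
  switch(plane, axial = 3L, coronal = 2L, `isotropic-SRR` = 3L)
}

# Physical sample coordinates along one axis.
axis_coords <- function(img, axis) {
  img$origin[axis] + (seq_len(dim(img$voxels)[axis]) - 1) * img$spacing[axis]
}

is_vol3d <- function(x) inherits(x, "vol3d")

#' Anatomical region label vocabulary
#'
#' Closed integer vocabulary for the structures the pipeline labels:
#' the ten tendon regions graded for tenosynovitis (six extensor
#' compartments I-VI on the dorsal side, four flexor regions 1-4 on the
#' volar side), the carpal bone block with the hamate distinguished (its
#' widest axial slice defines the distal measurement boundary), and the
#' distal radius and ulna (their closest approach defines the proximal
#' boundary). Code 0 is background.
#'
#' @return data.frame with columns `code`, `name`, `class`
#'   (`"background"`, `"tendon"`, `"bone"`).
#' @export
label_vocabulary <- function() {
  data.frame(
    code = 0:14,
    name = c("background",
             paste0("extensor_", c("I", "II", "III", "IV", "V", "VI")),
             paste0("flexor_", 1:4),
             "carpal", "hamate", "radius", "ulna"),
    class = c("background", rep("tendon", 10), rep("bone", 4)),
    stringsAsFactors = FALSE
  )
}

#' @rdname label_vocabulary
#' @export
tendon_codes <- function() 1:10

#' @rdname label_vocabulary
#' @export
bone_codes <- function() 11:14

#' @rdname label_vocabulary
#' @export
region_names <- function() label_vocabulary()$name[2:11]

label_code <- function(name) {
  v <- label_vocabulary()
  i <- match(name, v$name)
  if (anyNA(i)) stop("unknown region name: ", paste(name[is.na(i)], collapse = ", "),
                     call. = FALSE)
  v$code[i]
}

#' Region label map
#'
#' Integer-labeled 3D grid sharing the geometry of a reference volume.
#' Every voxel carries exactly one code from [label_vocabulary()]; unknown
#' codes are rejected.
#'
#' @param labels integer 3D array.
#' @param spacing,origin grid geometry (mm), as in [vol3d()].
#' @return An object of class `region_label_map`.
#' @export
region_label_map <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (anyNA(labels)) stop("label map contains NA", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), label_vocabulary()$code)
  if (length(bad))
    stop("label codes outside the vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(labels = labels, spacing = spacing, origin = as.numeric(origin)),
            class = "region_label_map")
}

#' @export
dim.region_label_map <- function(x) dim(x$labels)

#' @export
print.region_label_map <- function(x, ...) {
  d <- dim(x$labels)
  present <- sort(unique(as.vector(x$labels)))
  v <- label_vocabulary()
  cat(sprintf("<region_label_map> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  labels present:", paste(v$name[match(present, v$code)], collapse = ", "), "\n")
  invisible(x)
}

#' Read a 3D volume from a NIfTI file
#'
#' Loads a NIfTI-1 image (`.nii` / `.nii.gz`), casting intensities to double
#' and taking spacing and origin from the header. Only strictly 3D,
#' axis-aligned payloads are accepted.
#'
#' @param path path to the NIfTI file.
#' @param plane acquisition plane recorded on the result (metadata only).
#' @param slice_thickness optional slice-profile width (mm); defaults to the
#'   through-slice spacing for axial/coronal planes.
#' @return A [vol3d()].
#' @export
load_volume <- function(path, plane = "isotropic-SRR", slice_thickness = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L)
    stop("expected a 3D payload, got ", length(d), " dimensions in ", path,
         call. = FALSE)
  vox <- array(as.numeric(im), dim = d)
  if (anyNA(vox) || any(!is.finite(vox)))
    stop("non-finite voxel values in ", path, call. = FALSE)
  sp <- RNifti::pixdim(im)[1:3]
  xf <- RNifti::xform(im)
  org <- as.numeric(xf[1:3, 4])
  vol3d(vox, spacing = sp, origin = org, plane = plane,
        slice_thickness = slice_thickness)
}

#' Write a volume or label map to a NIfTI file
#'
#' @param x a [vol3d()] or [region_label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (is_vol3d(x)) {
    arr <- x$voxels; sp <- x$spacing; org <- x$origin; dt <- "double"
  } else if (inherits(x, "region_label_map")) {
    arr <- x$labels; sp <- x$spacing; org <- x$origin; dt <- "int16"
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- sp
  m <- diag(4)                      # axis-aligned qform carries the origin
  diag(m)[1:3] <- sp
  m[1:3, 4] <- org
  RNifti::`qform<-`(im, structure(m, code = 2L)) -> im
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}

#' Read a region label map from a NIfTI file
#'
#' @param path path to the NIfTI file.
#' @return A [region_label_map()]; codes outside the vocabulary are rejected.
#' @export
load_label_map <- function(path) {
  v <- load_volume(path)
  lab <- round(v$voxels)
  if (max(abs(lab - v$voxels)) > 1e-6)
    stop("non-integer values in label map ", path, call. = FALSE)
  region_label_map(array(as.integer(lab), dim(lab)),
                   spacing = v$spacing, origin = v$origin)
}

#' Mirror a volume or label map across the left-right axis
#'
#' Used to match right-wrist atlases to left-wrist targets: the voxel grid
#' is reversed along the anatomical x axis; spacing and origin are kept.
#' Applying it twice is the identity.
#'
#' @param img a [vol3d()] or [region_label_map()].
#' @return Object of the same class, mirrored.
#' @export
mirror_horizontal <- function(img) {
  if (is_vol3d(img)) {
    img$voxels <- img$voxels[dim(img$voxels)[1]:1, , , drop = FALSE]
  } else if (inherits(img, "region_label_map")) {
    img$labels <- img$labels[dim(img$labels)[1]:1, , , drop = FALSE]
  } else stop("cannot mirror object of class ", class(img)[1], call. = FALSE)
  img
}

# Check that two axis-aligned grids overlap in physical space (per axis).
check_grid_overlap <- function(src_dim, src_sp, src_org, tgt_dim, tgt_sp, tgt_org) {
  for (a in 1:3) {
    s_lo <- src_org[a] - src_sp[a] / 2
    s_hi <- src_org[a] + (src_dim[a] - 0.5) * src_sp[a]
    t_lo <- tgt_org[a] - tgt_sp[a] / 2
    t_hi <- tgt_org[a] + (tgt_dim[a] - 0.5) * tgt_sp[a]
    if (s_hi < t_lo || t_hi < s_lo)
      stop("source and target grids are physically disjoint along axis ", a,
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Resample a label map to a new grid by nearest neighbor
#'
#' Each target voxel takes the label of the physically nearest source
#' voxel, so no new label codes can appear. Grids must overlap in physical
#' space. Used to carry manually drawn axial labels onto the isotropic
#' reconstruction grid.
#'
#' @param lab a [region_label_map()].
#' @param target a [vol3d()], [region_label_map()] or a list with elements
#'   `dim`, `spacing`, `origin` defining the output grid.
#' @return A [region_label_map()] on the target grid.
#' @export
resample_labels_nearest <- function(lab, target) {
  g <- as_grid(target)
  check_grid_overlap(dim(lab$labels), lab$spacing, lab$origin,
                     g$dim, g$spacing, g$origin)
  idx <- vector("list", 3)
  for (a in 1:3) {
    tc <- g$origin[a] + (seq_len(g$dim[a]) - 1) * g$spacing[a]
    i <- round((tc - lab$origin[a]) / lab$spacing[a]) + 1
    idx[[a]] <- pmin(pmax(i, 1L), dim(lab$labels)[a])
  }
  out <- lab$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  region_label_map(out, spacing = g$spacing, origin = g$origin)
}

# Normalize grid descriptors.
as_grid <- function(x) {
  if (is_vol3d(x)) list(dim = dim(x$voxels), spacing = x$spacing, origin = x$origin)
  else if (inherits(x, "region_label_map"))
    list(dim = dim(x$labels), spacing = x$spacing, origin = x$origin)
  else if (is.list(x) && all(c("dim", "spacing", "origin") %in% names(x)))
    list(dim = as.integer(x$dim), spacing = as.numeric(x$spacing),
         origin = as.numeric(x$origin))
  else stop("cannot interpret grid from class ", class(x)[1], call. = FALSE)
}

#' Nearest-neighbor resampling of an intensity volume
#'
#' Baseline upsampling used for comparison against super-resolution
#' reconstruction: each target voxel copies the nearest source voxel.
#'
#' @param img a [vol3d()].
#' @param target target grid (see [resample_labels_nearest()]).
#' @return A [vol3d()] on the target grid.
#' @export
resample_nearest <- function(img, target) {
  g <- as_grid(target)
  check_grid_overlap(dim(img$voxels), img$spacing, img$origin,
                     g$dim, g$spacing, g$origin)
  idx <- vector("list", 3)
  for (a in 1:3) {
    tc <- g$origin[a] + (seq_len(g$dim[a]) - 1) * g$spacing[a]
    i <- round((tc - img$origin[a]) / img$spacing[a]) + 1
    idx[[a]] <- pmin(pmax(i, 1L), dim(img$voxels)[a])
  }
  vol3d(img$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
        spacing = g$spacing, origin = g$origin)
}

#' Per-region visual grade sheet
#'
#' Ordinal tenosynovitis grades for the ten tendon regions, on the 0-3
#' scale driven by the maximum width of peritendinous enhancement
#' (grade 0 normal; 1 below 2 mm; 2 from 2 to below 5 mm; 3 at 5 mm or
#' more). Grades are the mean of two readers, hence steps of 0.5; the
#' total is their sum (range 0-30).
#'
#' @param grades numeric vector of 10 grades, optionally named by
#'   [region_names()]; unnamed vectors are taken in that order.
#' @return An object of class `visual_score_sheet` with fields `grades`
#'   and `total`.
#' @export
visual_score_sheet <- function(grades) {
  if (length(grades) != 10L) stop("expected 10 per-region grades", call. = FALSE)
  if (is.null(names(grades))) names(grades) <- region_names()
  if (!setequal(names(grades), region_names()))
    stop("grade names must be the 10 tendon regions", call. = FALSE)
  grades <- grades[region_names()]
  if (any(grades < 0 | grades > 3)) stop("grades must lie in [0, 3]", call. = FALSE)
  if (any(abs(grades * 2 - round(grades * 2)) > 1e-9))
    stop("grades must be multiples of 0.5 (two-reader means)", call. = FALSE)
  structure(list(grades = grades, total = sum(grades)),
            class = "visual_score_sheet")
}

#' @export
print.visual_score_sheet <- function(x, ...) {
  cat("<visual_score_sheet> total", x$total, "\n")
  print(x$grades)
  invisible(x)
}
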