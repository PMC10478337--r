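#' Construct a CT volume in Hounsfield units
#'
#' The basic raw-data container: a 3D voxel grid of Hounsfield-unit (HU)
#' values plus per-axis physical spacing in millimetres. HU is the calibrated
#' CT attenuation scale (air about -1000, water 0, soft tissue about +40).
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin optional physical origin, passed through to writers.
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat(sprintf("<hu_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a binary label mask
#'
#' @param voxels array of 0/1 (or logical) voxels; must match the shape of
#'   the volume it annotates.
#' @param spacing voxel spacing in mm (copied from the source volume).
#' @param role one of `"lung"`, `"lesion"`, `"pseudo"`, `"gt"`.
#' @return an object of class `label_mask` (integer 0/1 array plus metadata).
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1),
                       role = c("lesion", "lung", "pseudo", "gt")) {
  role <- match.arg(role)
  v <- voxels
  if (is.logical(v)) v <- v * 1L
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  if (length(dim(v)) != 3L) stop("mask must be a 2D or 3D array")
  if (!all(v %in% c(0L, 1L))) stop("mask values must be exactly 0 or 1")
  storage.mode(v) <- "integer"
  structure(list(voxels = v, spacing = as.numeric(spacing), role = role),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask role=%s> %s voxels, %d foreground\n", x$role,
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI files (`.nii` / `.nii.gz`) are read with RNifti; a directory is
#' interpreted as one DICOM series (uncompressed little-endian), with the
#' rescale slope/intercept applied so returned voxel values are in Hounsfield
#' units, slices ordered along the scan axis, and spacing taken from the
#' header (in-plane pixel spacing and slice spacing/thickness in mm).
#'
#' @param path a NIfTI file or a directory containing one DICOM series.
#' @return a [hu_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path)
  if (dir.exists(path)) return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  vox <- array(as.vector(img), dim = dim(img))  # drop reader attributes
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  pd <- RNifti::pixdim(img)
  spacing <- rep(1, 3)
  spacing[seq_along(pd)[1:min(3, length(pd))]] <- pd[1:min(3, length(pd))]
  spacing[spacing <= 0 | !is.finite(spacing)] <- 1
  v <- hu_volume(vox, spacing)
  attr(v, "nifti_template") <- img
  v
}

#' Read a binary mask from NIfTI
#'
#' Values are binarized at 0.5 (masks are stored as 0/1 but may come back as
#' other numeric types depending on the writer).
#'
#' @param path NIfTI file.
#' @param role semantic role tag, see [label_mask()].
#' @return a [label_mask()].
#' @export
read_mask <- function(path, role = "lesion") {
  v <- read_volume(path)
  label_mask(v$voxels >= 0.5, spacing = v$spacing, role = role)
}

#' Write a binary mask as unsigned 8-bit NIfTI
#'
#' Geometry (spacing, orientation) is copied from the reference volume when
#' it carries a NIfTI header; a round-trip through [read_mask()] reproduces
#' the voxels exactly.
#'
#' @param mask a [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param reference a [hu_volume()] with matching shape, or `NULL` to use the
#'   mask's own spacing.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path, reference = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  vox <- mask$voxels
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "hu_volume"))
    if (!identical(dim(vox), dim(reference$voxels)))
      stop("mask shape ", paste(dim(vox), collapse = "x"),
           " does not match reference shape ",
           paste(dim(reference$voxels), collapse = "x"))
    tmpl <- attr(reference, "nifti_template")
    spacing <- reference$spacing
  } else {
    tmpl <- NULL
    spacing <- mask$spacing
  }
  img <- RNifti::asNifti(vox, reference = tmpl)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a volume as NIfTI
#'
#' @param volume a [hu_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "hu_volume"))
  img <- RNifti::asNifti(volume$voxels, reference = attr(volume, "nifti_template"))
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Clip and normalize Hounsfield units to a [0, 255] image
#'
#' HU values are clipped to `[lo, hi]` and mapped affinely so that `lo -> 0`
#' and `hi -> 255`, the standard windowing used to convert raw CT data to an
#' 8-bit-range grayscale image before model input. The default window
#' [-1200, 600] covers aerated lung through dense tissue and bone.
#'
#' @param volume a [hu_volume()] (or bare array).
#' @param lo,hi clip bounds in HU, `lo < hi`.
#' @return an object of class `normalized_image`: the same-shaped array with
#'   values in `[0, 255]`, spacing carried along.
#' @export
hu_clip_normalize <- function(volume, lo = -1200, hi = 600) {
  if (lo >= hi) stop("lo must be < hi")
  vox <- if (inherits(volume, "hu_volume")) volume$voxels else volume
  spacing <- if (inherits(volume, "hu_volume")) volume$spacing else c(1, 1, 1)
  px <- pmin(pmax(vox, lo), hi)
  px <- 255 * (px - lo) / (hi - lo)
  structure(list(pixels = px, spacing = spacing, window = c(lo, hi)),
            class = "normalized_image")
}

#' @export
print.normalized_image <- function(x, ...) {
  cat(sprintf("<normalized_image> %s, window [%g, %g] HU -> [0, 255]\n",
              paste(dim(x$pixels), collapse = "x"), x$window[1], x$window[2]))
  invisible(x)
}

#' Resample slices to the model input size
#'
#' Each axial slice is resampled to `side x side` with bilinear
#' interpolation and rescaled from [0, 255] to [0, 1], the form the backbone
#' consumes.
#'
#' @param image a `normalized_image` from [hu_clip_normalize()].
#' @param side output side length in pixels (>= 8).
#' @return array `side x side x n_slices` with values in [0, 1].
#' @export
to_model_input <- function(image, side = 256L) {
  side <- as.integer(side)
  if (side < 8L) stop("side must be >= 8")
  px <- if (inherits(image, "normalized_image")) image$pixels else image
  if (length(dim(px)) == 2L) dim(px) <- c(dim(px), 1L)
  if (prod(dim(px)) == 0L) stop("image is empty")
  ns <- dim(px)[3]
  out <- array(0, c(side, side, ns))
  for (s in seq_len(ns)) {
    sl <- px[, , s]
    if (all(dim(sl) == c(side, side))) {
      out[, , s] <- sl
    } else {
      out[, , s] <- resize_slice(sl, side, side, bilinear = TRUE)
    }
  }
  out / 255
}

# resize one 2D slice; bilinear for intensities, nearest for masks
resize_slice <- function(slice, h, w, bilinear = TRUE) {
  flt <- if (bilinear) "bilinear" else "none"
  as.matrix(EBImage::resize(EBImage::Image(slice), w = h, h = w, filter = flt))
}
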