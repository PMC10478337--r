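#' HU interval
#'
#' A labelled Hounsfield-unit interval. The intervals used throughout are the
#' lesion interval [-750, 50] (ground-glass opacity plus consolidation), the
#' GGO subrange [-750, -300) and the consolidation subrange [-300, 50]; the
#' boundary value -300 HU is assigned to consolidation.
#'
#' @param lo,hi interval bounds in HU, `lo < hi`.
#' @param label free-text label.
#' @return an object of class `hu_interval`.
#' @export
hu_interval <- function(lo = -750, hi = 50, label = "lesion") {
  if (!(lo < hi)) stop("lo must be < hi")
  structure(list(lo = lo, hi = hi, label = label), class = "hu_interval")
}

#' Generate an HU-threshold pseudo-label
#'
#' The zero-cost lesion label: a voxel is foreground iff it lies inside the
#' lung mask and its HU value falls in the closed interval. With the default
#' interval [-750, 50] this captures ground-glass opacity and consolidation
#' but also any healthy dense tissue (vessels, airway walls) in the same
#' range - the pseudo-labels are deliberately noisy and receive no
#' morphological cleanup.
#'
#' @param volume a [hu_volume()].
#' @param lung a [label_mask()] with the same shape (the lung gate); pass
#'   `NULL` to threshold without gating.
#' @param interval a [hu_interval()], default [-750, 50].
#' @return a [label_mask()] with role `"pseudo"`.
#' @export
generate_pseudolabel <- function(volume, lung, interval = hu_interval()) {
  stopifnot(inherits(volume, "hu_volume"))
  inside <- volume$voxels >= interval$lo & volume$voxels <= interval$hi
  if (!is.null(lung)) {
    stopifnot(inherits(lung, "label_mask"))
    if (!identical(dim(lung$voxels), dim(volume$voxels)))
      stop("lung mask shape does not match volume shape")
    inside <- inside & lung$voxels == 1L
  }
  label_mask(inside, spacing = volume$spacing, role = "pseudo")
}

#' Split a lesion mask into GGO and consolidation
#'
#' Lesion voxels with HU in [-750, -300) are labelled ground-glass opacity
#' (1) and voxels in [-300, 50] consolidation (2); the shared boundary -300
#' goes to consolidation. Lesion voxels outside [-750, 50] entirely (possible
#' when the mask comes from an expert rather than the HU rule) are left as
#' background and counted in the `n_outside` attribute.
#'
#' @param volume a [hu_volume()].
#' @param lesion a [label_mask()] of the lesion, same shape.
#' @return an object of class `subtype_mask`: integer array with 0 =
#'   background, 1 = GGO, 2 = consolidation.
#' @export
classify_lesion_subtypes <- function(volume, lesion) {
  stopifnot(inherits(volume, "hu_volume"), inherits(lesion, "label_mask"))
  if (!identical(dim(lesion$voxels), dim(volume$voxels)))
    stop("lesion mask shape does not match volume shape")
  hu <- volume$voxels
  les <- lesion$voxels == 1L
  out <- array(0L, dim(hu))
  out[les & hu >= -750 & hu < -300] <- 1L
  out[les & hu >= -300 & hu <= 50] <- 2L
  n_outside <- sum(les) - sum(out > 0L)
  structure(list(voxels = out, spacing = volume$spacing,
                 n_outside = n_outside),
            class = "subtype_mask")
}

#' @export
print.subtype_mask <- function(x, ...) {
  cat(sprintf("<subtype_mask> %s: %d GGO, %d consolidation voxels",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels == 1L), sum(x$voxels == 2L)))
  if (x$n_outside > 0) cat(sprintf(" (%d lesion voxels outside [-750, 50])",
                                   x$n_outside))
  cat("\n")
  invisible(x)
}

#' Threshold-based lung mask
#'
#' A simple morphological lung extractor for when no expert lung mask is
#' supplied: voxels below `air_hi` HU are candidate air; connected components
#' (6-connectivity, 3D) touching the volume border are removed (exterior
#' air), components smaller than `min_component_fraction` of the volume are
#' dropped, and the survivors are closed with a small structuring element to
#' fill vessel-scale gaps. Intended for phantoms and rough gating, not as a
#' substitute for a dedicated lung segmenter.
#'
#' @param volume a [hu_volume()].
#' @param air_hi upper HU bound for lung candidate voxels.
#' @param min_component_fraction minimum component size as a fraction of the
#'   total voxel count.
#' @param close_radius radius (voxels) of the closing element; 0 disables.
#' @return a [label_mask()] with role `"lung"`; if no component survives the
#'   mask is empty and carries attribute `warning = TRUE`.
#' @export
simple_lung_mask <- function(volume, air_hi = -320, min_component_fraction = 0.005,
                             close_radius = 1L) {
  stopifnot(inherits(volume, "hu_volume"))
  vox <- volume$voxels
  cand <- vox < air_hi
  dims <- dim(cand)
  lab <- .cc_label_3d(as.logical(cand), as.integer(dims))
  keep <- logical(max(lab, 0L))
  if (length(keep)) {
    # exterior air reaches the in-plane borders; the z faces are excluded
    # because lungs commonly extend beyond the scanned slab
    border <- unique(c(lab[1, , ], lab[dims[1], , ], lab[, 1, ], lab[, dims[2], ]))
    border <- border[border > 0L]
    sizes <- tabulate(lab[lab > 0L], nbins = length(keep))
    keep <- sizes >= min_component_fraction * prod(dims)
    keep[border] <- FALSE
  }
  mask <- array(lab > 0L & keep[pmax(lab, 1L)], dims)
  if (!any(mask)) {
    out <- label_mask(array(0L, dims), spacing = volume$spacing, role = "lung")
    attr(out, "warning") <- TRUE
    return(out)
  }
  if (close_radius > 0L) {
    dil <- .binary_dilate_3d(as.logical(mask), as.integer(dims),
                             as.integer(close_radius))
    # erosion = complement of dilation of complement
    mask <- !.binary_dilate_3d(!dil, as.integer(dims), as.integer(close_radius))
    dim(mask) <- dims
  }
  label_mask(mask, spacing = volume$spacing, role = "lung")
}

#' Quantify infection burden
#'
#' Volumes are foreground voxel counts times the physical voxel volume
#' (product of the spacing components); the infection ratio is lesion volume
#' over lung volume. Lesion voxels outside the lung are intersected away and
#' counted in `n_outside_lung`.
#'
#' @param lung,lesion [label_mask()]s of identical shape.
#' @param subtypes optional `subtype_mask` from [classify_lesion_subtypes()].
#' @param spacing voxel spacing in mm (defaults to the lung mask's).
#' @return an object of class `lesion_report` (also a one-row data.frame)
#'   with columns `lung_volume_ml`, `lesion_volume_ml`, `infection_ratio`,
#'   `ggo_volume_ml`, `consolidation_volume_ml`, `n_outside_lung`,
#'   `empty_lung`.
#' @export
quantify_infection <- function(lung, lesion, subtypes = NULL, spacing = NULL) {
  stopifnot(inherits(lung, "label_mask"), inherits(lesion, "label_mask"))
  if (!identical(dim(lung$voxels), dim(lesion$voxels)))
    stop("lung and lesion masks must share a shape")
  if (is.null(spacing)) spacing <- lung$spacing
  vox_ml <- prod(spacing) / 1000  # mm^3 -> ml
  les <- lesion$voxels == 1L & lung$voxels == 1L
  n_outside <- sum(lesion$voxels == 1L) - sum(les)
  n_lung <- sum(lung$voxels == 1L)
  n_les <- sum(les)
  empty_lung <- n_lung == 0L
  ratio <- if (empty_lung) NA_real_ else n_les / n_lung
  ggo_ml <- cons_ml <- NA_real_
  if (!is.null(subtypes)) {
    if (!identical(dim(subtypes$voxels), dim(lung$voxels)))
      stop("subtype mask shape mismatch")
    ggo_ml <- sum(subtypes$voxels == 1L & les) * vox_ml
    cons_ml <- sum(subtypes$voxels == 2L & les) * vox_ml
  }
  out <- data.frame(lung_volume_ml = n_lung * vox_ml,
                    lesion_volume_ml = n_les * vox_ml,
                    infection_ratio = ratio,
                    ggo_volume_ml = ggo_ml,
                    consolidation_volume_ml = cons_ml,
                    n_outside_lung = n_outside,
                    empty_lung = empty_lung)
  class(out) <- c("lesion_report", "data.frame")
  out
}
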