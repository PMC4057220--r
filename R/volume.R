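#' CT attenuation volume
#'
#' Container for a 3D grid of CT attenuation values in Hounsfield units (HU)
#' together with the physical voxel spacing. The axis convention is fixed:
#' the first array dimension runs left--right, the second ventral to dorsal
#' (anterior to posterior, supine acquisition), the third apex to base
#' (cranial to caudal). All regional operations rely on this convention;
#' [read_hu_volume()] documents how it maps onto NIfTI files.
#'
#' @param values 3D numeric array of attenuation values (HU). Must be finite.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm,
#'   strictly positive, in array-dimension order.
#' @return An object of class `hu_volume`: a list with elements `values`
#'   and `spacing`.
#' @examples
#' vol <- hu_volume(array(-805, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' vol
#' @seealso [lung_mask()], [summarize_voxels()]
#' @export
hu_volume <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array of HU values", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` contains non-finite attenuation values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  structure(list(values = values, spacing = spacing), class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], mean %.1f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Lung label mask
#'
#' Voxel label grid aligned with an [hu_volume()]: 0 = background,
#' 1 = right lung, 2 = left lung.
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @param spacing voxel spacing in mm (as for [hu_volume()]).
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad) > 0)
    stop("mask contains invalid label(s): ",
         paste(bad, collapse = ", "),
         " (allowed: 0 background, 1 right lung, 2 left lung)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0) || !all(is.finite(spacing)))
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lung_mask> %d x %d x %d voxels: %d right, %d left\n",
              d[1], d[2], d[3],
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

# Check that a volume and mask share grid and spacing.
check_aligned <- function(volume, mask) {
  stopifnot(inherits(volume, "hu_volume"), inherits(mask, "lung_mask"))
  if (!identical(dim(volume$values), dim(mask$labels)))
    stop("volume and mask have different grid shapes", call. = FALSE)
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop("volume and mask have different voxel spacing", call. = FALSE)
  invisible(TRUE)
}

#' Select voxels of a lung mask
#'
#' Builds a logical selector over the voxel grid for one lung or both.
#'
#' @param mask a [lung_mask()].
#' @param lung `"both"`, `"right"` or `"left"`.
#' @return Logical 3D array, `TRUE` for selected voxels.
#' @export
mask_selector <- function(mask, lung = c("both", "right", "left")) {
  lung <- match.arg(lung)
  switch(lung,
         both  = mask$labels > 0L,
         right = mask$labels == 1L,
         left  = mask$labels == 2L)
}

# Resolve a voxel selector (logical array or linear indices) to linear
# indices into the volume, validating bounds.
resolve_voxels <- function(volume, voxels) {
  n <- length(volume$values)
  if (is.logical(voxels)) {
    if (length(voxels) != n)
      stop("logical selector does not match the volume grid", call. = FALSE)
    idx <- which(voxels)
  } else {
    idx <- as.integer(voxels)
    if (length(idx) > 0 && (min(idx) < 1L || max(idx) > n))
      stop("voxel indices out of volume bounds", call. = FALSE)
  }
  if (length(idx) == 0L)
    stop("empty region: no voxels selected", call. = FALSE)
  idx
}

# Voxel volume in ml (spacing is in mm; 1 ml = 1000 mm^3).
voxel_volume_ml <- function(spacing) prod(spacing) / 1000
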