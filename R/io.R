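#' Read a CT attenuation volume from NIfTI
#'
#' Reads a 3D NIfTI image (.nii or .nii.gz) as an [hu_volume()], taking the
#' voxel spacing from the header. The array is used in native (i, j, k)
#' order; the package's axis convention (x left--right, y ventral--dorsal,
#' z apex--base) corresponds to a supine RAS/LPS axial acquisition — callers
#' must reorient beforehand if their data differ. A warning is emitted when
#' the intensity range does not look HU-valued (no negative values).
#'
#' @param path path to a readable NIfTI file.
#' @return An [hu_volume()].
#' @export
read_hu_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI image, got ", length(dim(vals)), "D",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (min(vals) >= 0)
    warning("volume has no negative values; it does not look HU-valued",
            call. = FALSE)
  hu_volume(vals, spacing)
}

#' Read a lung label mask from NIfTI
#'
#' Labels must be 0 (background), 1 (right lung), 2 (left lung); any other
#' label is an error naming the offending value.
#'
#' @param path path to a readable NIfTI file.
#' @param volume optional [hu_volume()] to validate shape and spacing
#'   against.
#' @return A [lung_mask()].
#' @export
read_lung_mask <- function(path, volume = NULL) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  mask <- lung_mask(labels, RNifti::pixdim(img)[1:3])
  if (!is.null(volume)) check_aligned(volume, mask)
  mask
}

#' Write a volume or mask to NIfTI
#'
#' @param x an [hu_volume()] or [lung_mask()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "hu_volume")) {
    arr <- x$values; sp <- x$spacing
  } else if (inherits(x, "lung_mask")) {
    arr <- x$labels; sp <- x$spacing
  } else stop("`x` must be an hu_volume or lung_mask", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Whole-lung quantitative CT analysis
#'
#' Runs the densitometric pipeline on a volume/mask pair: gas/tissue
#' decomposition for the total lung and each lung separately, aeration
#' compartment fractions (mass and volume), the low-attenuation
#' (emphysema) volume fraction, and bounding-box extents. When subject
#' anthropometrics are supplied, all registered reference-equation volumes,
#' normative regression predictions and the aeration states implied by each
#' predicted TLC are appended.
#'
#' @param volume an [hu_volume()].
#' @param mask the aligned [lung_mask()].
#' @param subj optional [subject()] for the normative block.
#' @param scheme a [compartment_scheme()].
#' @param mode gas-fraction mode, see [gas_fraction()].
#' @return Object of class `lung_report`: a list of data.frames
#'   `summary`, `compartments`, `emphysema`, `extents` and (with a subject)
#'   `normative`.
#' @export
run_analyze <- function(volume, mask, subj = NULL,
                        scheme = compartment_scheme(),
                        mode = c("literal", "clamped")) {
  mode <- match.arg(mode)
  check_aligned(volume, mask)
  regions <- list(total = mask$labels > 0L,
                  right = mask$labels == 1L,
                  left = mask$labels == 2L)
  regions <- Filter(function(sel) any(sel), regions)

  summary_rows <- lapply(names(regions), function(rn) {
    s <- summarize_voxels(volume, regions[[rn]], mode = mode)
    data.frame(region = rn, n_voxels = s$n_voxels,
               total_volume_ml = s$total_volume_ml,
               gas_volume_ml = s$gas_volume_ml,
               tissue_volume_ml = s$tissue_volume_ml,
               tissue_mass_g = s$tissue_mass_g, mean_hu = s$mean_hu,
               gas_tissue_ratio = s$gas_tissue_ratio)
  })
  comp_rows <- lapply(names(regions), function(rn) {
    cs <- compartment_summary(volume, regions[[rn]], scheme, mode = mode)
    cbind(region = rn, cs)
  })
  emph_rows <- lapply(names(regions), function(rn) {
    data.frame(region = rn,
               threshold_hu = scheme$emphysema_threshold,
               low_attenuation_pct = low_attenuation_volume_fraction(
                 volume, regions[[rn]], scheme$emphysema_threshold))
  })

  out <- list(summary = do.call(rbind, summary_rows),
              compartments = do.call(rbind, comp_rows),
              emphysema = do.call(rbind, emph_rows),
              extents = lung_extents(mask))

  if (!is.null(subj)) {
    stopifnot(inherits(subj, "subject"))
    tissue <- out$summary$tissue_mass_g[out$summary$region == "total"]
    eq <- reference_equations()
    pred <- vapply(eq$id, function(id)
      predict_reference_volume(subj, id), numeric(1))
    states <- lapply(pred, function(g) predicted_aeration_state(g, tissue))
    out$normative <- data.frame(
      equation = eq$id, quantity = eq$quantity,
      predicted_volume_ml = unname(pred),
      gas_tissue_ratio = vapply(states, `[[`, 0, "gas_tissue_ratio"),
      estimated_ct_hu = vapply(states, `[[`, 0, "estimated_ct_hu"),
      row.names = NULL)
    out$regressions <- data.frame(
      regression = c("lung_weight_vs_height", "supine_tlc_vs_height"),
      predicted = c(predict_regression(subj$height, "lung_weight_vs_height"),
                    predict_regression(subj$height, "supine_tlc_vs_height")))
  } else {
    message("no subject anthropometrics supplied: normative block omitted")
  }
  class(out) <- "lung_report"
  out
}

#' @export
print.lung_report <- function(x, ...) {
  cat("<lung_report>\n== summary ==\n")
  print(x$summary)
  cat("== compartments ==\n")
  print(x$compartments)
  cat("== emphysema ==\n")
  print(x$emphysema)
  if (!is.null(x$normative)) {
    cat("== normative ==\n")
    print(x$normative)
  }
  invisible(x)
}

#' Write a report's tables as CSV files
#'
#' One CSV per table (`summary.csv`, `compartments.csv`, `emphysema.csv`,
#' `extents.csv`, and `normative.csv` / `regressions.csv` when present),
#' written deterministically (fixed column order, no row names), so
#' identical input yields byte-identical files.
#'
#' @param report a [run_analyze()] result (or any named list of
#'   data.frames).
#' @param dir output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- Filter(is.data.frame, unclass(report))
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
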