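# Tissue density used to convert tissue volume (ml) to mass (g). Fixed at
# 1 g/ml: the two-compartment model places tissue at water density.
TISSUE_DENSITY_G_PER_ML <- 1.0

#' Gas fraction of a voxel from its CT number
#'
#' Under the two-compartment model, `gas fraction = HU / -1000`: a voxel at
#' -1000 HU is pure gas, a voxel at 0 HU pure tissue. In `"literal"` mode
#' the formula is evaluated as-is, so voxels above 0 HU get a slightly
#' negative gas fraction; `"clamped"` mode truncates to \[0, 1\] for use
#' with dense pathology or contrast.
#'
#' @param hu numeric vector of CT numbers (HU); must be finite.
#' @param mode `"literal"` (default, the model formula verbatim) or
#'   `"clamped"`.
#' @return Numeric vector of gas fractions.
#' @examples
#' gas_fraction(c(-1000, -500, 0))
#' gas_fraction(100, mode = "clamped")
#' @export
gas_fraction <- function(hu, mode = c("literal", "clamped")) {
  mode <- match.arg(mode)
  if (!is.numeric(hu) || !all(is.finite(hu)))
    stop("`hu` must be finite numeric CT numbers", call. = FALSE)
  f <- hu / -1000
  if (mode == "clamped") f <- pmin(pmax(f, 0), 1)
  f
}

#' Aeration compartment scheme
#'
#' HU cut points separating the four aeration compartments, plus the low
#' attenuation threshold conventionally used to quantitate emphysema.
#' Defaults place the compartments at the standard integer ranges:
#' overinflated below -900 HU, well inflated \[-900, -500), poorly inflated
#' \[-500, -100), noninflated at or above -100 HU.
#'
#' @param boundaries strictly increasing HU cut points (length 3) within
#'   \[-1000, 100\].
#' @param emphysema_threshold HU threshold for the low-attenuation volume
#'   fraction (default -950).
#' @return Object of class `compartment_scheme`.
#' @export
compartment_scheme <- function(boundaries = c(-900, -500, -100),
                               emphysema_threshold = -950) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0) ||
      any(boundaries < -1000 | boundaries > 100))
    stop("`boundaries` must be 3 strictly increasing HU values in [-1000, 100]",
         call. = FALSE)
  structure(list(boundaries = boundaries,
                 names = c("overinflated", "well", "poorly", "noninflated"),
                 emphysema_threshold = emphysema_threshold),
            class = "compartment_scheme")
}

#' Classify CT numbers into aeration compartments
#'
#' Compartment intervals are half-open at the cut points so that every
#' integer HU value lands in the conventional integer range: -901 HU is
#' overinflated while -900 HU is well inflated; -501 is well inflated while
#' -500 is poorly inflated; -101 is poorly inflated while -100 is
#' noninflated. Values outside \[-1000, 100\] are classified into the
#' nearest end compartment (masks are assumed to exclude bone and contrast);
#' callers that care can count them via `attr(, "n_out_of_range")`.
#'
#' @param hu numeric vector of CT numbers.
#' @param scheme a [compartment_scheme()].
#' @return Factor with levels `overinflated`, `well`, `poorly`,
#'   `noninflated`, with attribute `n_out_of_range`.
#' @examples
#' classify_compartment(c(-901, -900, -500, -100))
#' @export
classify_compartment <- function(hu, scheme = compartment_scheme()) {
  stopifnot(inherits(scheme, "compartment_scheme"))
  if (!is.numeric(hu) || !all(is.finite(hu)))
    stop("`hu` must be finite numeric CT numbers", call. = FALSE)
  idx <- findInterval(hu, scheme$boundaries) + 1L
  out <- factor(scheme$names[idx], levels = scheme$names)
  attr(out, "n_out_of_range") <- sum(hu < -1000 | hu > 100)
  out
}

#' Densitometric summary of a voxel set
#'
#' Applies the gas/tissue decomposition to every selected voxel and
#' aggregates: total volume = voxel count times voxel volume; gas volume =
#' sum of per-voxel gas fractions times voxel volume; tissue volume is the
#' remainder; tissue mass equals tissue volume at 1 g/ml.
#'
#' @param volume an [hu_volume()].
#' @param voxels logical array over the grid, or linear voxel indices.
#'   Must select at least one voxel.
#' @param mode gas-fraction mode, see [gas_fraction()].
#' @return Object of class `densitometry_summary`: a list with
#'   `n_voxels`, `total_volume_ml`, `gas_volume_ml`, `tissue_volume_ml`,
#'   `tissue_mass_g`, `mean_hu`, `gas_tissue_ratio`, `n_out_of_range`.
#'   `gas_tissue_ratio` is `Inf` (with a warning) when the region holds no
#'   tissue.
#' @examples
#' vol <- hu_volume(array(c(-1000, -500, 0), dim = c(3, 1, 1)),
#'                  spacing = c(10, 10, 20))
#' summarize_voxels(vol, rep(TRUE, 3))
#' @export
summarize_voxels <- function(volume, voxels, mode = c("literal", "clamped")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "hu_volume"))
  idx <- resolve_voxels(volume, voxels)
  hu <- volume$values[idx]
  vv <- voxel_volume_ml(volume$spacing)

  n <- length(idx)
  total <- n * vv
  gas <- sum(gas_fraction(hu, mode)) * vv
  tissue <- total - gas
  mass <- tissue * TISSUE_DENSITY_G_PER_ML
  ratio <- if (tissue == 0) {
    warning("region holds no tissue; gas/tissue ratio is infinite",
            call. = FALSE)
    Inf
  } else gas / tissue

  structure(list(n_voxels = n,
                 total_volume_ml = total,
                 gas_volume_ml = gas,
                 tissue_volume_ml = tissue,
                 tissue_mass_g = mass,
                 mean_hu = mean(hu),
                 gas_tissue_ratio = ratio,
                 n_out_of_range = sum(hu < -1000 | hu > 100)),
            class = "densitometry_summary")
}

#' @export
print.densitometry_summary <- function(x, ...) {
  cat(sprintf(paste0("<densitometry_summary> %d voxels\n",
                     "  total %.1f ml = gas %.1f ml + tissue %.1f ml ",
                     "(%.1f g)\n  mean %.1f HU, gas/tissue %.3f\n"),
              x$n_voxels, x$total_volume_ml, x$gas_volume_ml,
              x$tissue_volume_ml, x$tissue_mass_g, x$mean_hu,
              x$gas_tissue_ratio))
  if (x$n_out_of_range > 0)
    cat(sprintf("  note: %d voxel(s) outside [-1000, 100] HU\n",
                x$n_out_of_range))
  invisible(x)
}

#' Per-compartment masses, volumes and fractions
#'
#' Splits a voxel set by aeration compartment and reports, per compartment,
#' the tissue mass, the voxel volume, the mass fraction (share of the
#' region's total tissue mass, the convention behind headline "percentage of
#' lung weight" figures) and the volume fraction (share of total volume,
#' the convention of attenuation histograms).
#'
#' @inheritParams summarize_voxels
#' @param scheme a [compartment_scheme()].
#' @return A data.frame with one row per compartment and columns
#'   `compartment`, `tissue_mass_g`, `volume_ml`, `mass_fraction_pct`,
#'   `volume_fraction_pct`, plus attributes `tissue_mass_g` and
#'   `total_volume_ml` for the whole region.
#' @export
compartment_summary <- function(volume, voxels, scheme = compartment_scheme(),
                                mode = c("literal", "clamped")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "hu_volume"))
  idx <- resolve_voxels(volume, voxels)
  hu <- volume$values[idx]
  vv <- voxel_volume_ml(volume$spacing)
  comp <- classify_compartment(hu, scheme)

  tissue_ml <- (1 - gas_fraction(hu, mode)) * vv
  mass_by <- vapply(scheme$names, function(cc) sum(tissue_ml[comp == cc]),
                    numeric(1)) * TISSUE_DENSITY_G_PER_ML
  vol_by <- vapply(scheme$names, function(cc) sum(comp == cc),
                   numeric(1)) * vv
  total_mass <- sum(mass_by)
  total_vol <- sum(vol_by)
  if (total_mass == 0)
    stop("region holds no tissue: compartment mass fractions undefined",
         call. = FALSE)

  out <- data.frame(compartment = factor(scheme$names, levels = scheme$names),
                    tissue_mass_g = unname(mass_by),
                    volume_ml = unname(vol_by),
                    mass_fraction_pct = unname(100 * mass_by / total_mass),
                    volume_fraction_pct = unname(100 * vol_by / total_vol),
                    row.names = NULL)
  attr(out, "tissue_mass_g") <- total_mass
  attr(out, "total_volume_ml") <- total_vol
  out
}

#' Low-attenuation volume fraction
#'
#' Percentage of a region's volume below an HU threshold. With the
#' conventional -950 HU threshold this is the standard CT index of
#' emphysema.
#'
#' @inheritParams summarize_voxels
#' @param threshold HU threshold in \[-1000, 0\]; voxels strictly below it
#'   count as low attenuation.
#' @return Percentage (0--100) of the region volume below `threshold`.
#' @export
low_attenuation_volume_fraction <- function(volume, voxels,
                                            threshold = -950) {
  stopifnot(inherits(volume, "hu_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < -1000 || threshold > 0)
    stop("`threshold` must be a single HU value in [-1000, 0]", call. = FALSE)
  idx <- resolve_voxels(volume, voxels)
  100 * mean(volume$values[idx] < threshold)
}
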