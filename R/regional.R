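#' Body surface area (Du Bois)
#'
#' `BSA = 0.007184 * weight^0.425 * height_cm^0.725`, the Du Bois formula.
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_m standing height in metres (> 0).
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive", call. = FALSE)
  0.007184 * weight_kg^0.425 * (height_m * 100)^0.725
}

#' Build the 10 x 10 regional grid of a lung mask
#'
#' Each lung is cut, along its apex--base physical extent, into 10 equal
#' slabs ("sections"); within each section the ventral-most to dorsal-most
#' mask extent is cut into 10 equal-height sterno-vertebral levels (level 1
#' most ventral, level 10 most dorsal), yielding up to 100 elements per lung.
#' Extents are physical (voxel edges, so a 100-voxel span at 2 mm spacing is
#' 200 mm), per lung and per section, which makes the binning robust to
#' anisotropic spacing. Voxels are assigned by centre coordinate; a centre
#' exactly on a bin edge goes to the more dorsal / more basal bin.
#'
#' @param mask a [lung_mask()].
#' @param spacing voxel spacing in mm; defaults to the mask's.
#' @return Object of class `regional_grid`: integer arrays `section` and
#'   `level` (0 outside the mask), matrix `level_height_cm` (2 lungs x 10
#'   sections; NA where a section is empty), vector `section_extent_cm`
#'   per lung, and the spacing.
#' @export
build_regional_grid <- function(mask, spacing = mask$spacing) {
  stopifnot(inherits(mask, "lung_mask"))
  lab <- mask$labels
  if (!any(lab > 0L))
    stop("mask is empty for both lungs", call. = FALSE)
  d <- dim(lab)
  section <- array(0L, d)
  level <- array(0L, d)
  level_height_cm <- matrix(NA_real_, nrow = 2, ncol = 10,
                            dimnames = list(c("right", "left"), NULL))
  section_extent_cm <- c(right = NA_real_, left = NA_real_)

  # bin centre coordinates into k equal bins spanning [lo, hi] (physical
  # edges); centres on an internal edge go to the higher-index bin
  bin_assign <- function(centers, lo, hi, k = 10L) {
    h <- (hi - lo) / k
    pmin(pmax(floor((centers - lo) / h) + 1L, 1L), k)
  }

  for (lg in 1:2) {
    idx <- which(lab == lg)
    if (length(idx) == 0L) next
    ai <- arrayInd(idx, d)
    sp <- mask$spacing
    # physical apex-base extent of this lung, voxel edges included
    z_lo <- (min(ai[, 3]) - 1) * sp[3]
    z_hi <- max(ai[, 3]) * sp[3]
    zc <- (ai[, 3] - 0.5) * sp[3]
    sec <- bin_assign(zc, z_lo, z_hi)
    section[idx] <- sec
    section_extent_cm[lg] <- (z_hi - z_lo) / 10

    for (s in 1:10) {
      in_s <- sec == s
      if (!any(in_s)) next
      j <- ai[in_s, 2]
      y_lo <- (min(j) - 1) * sp[2]
      y_hi <- max(j) * sp[2]
      yc <- (j - 0.5) * sp[2]
      level[idx[in_s]] <- bin_assign(yc, y_lo, y_hi)
      level_height_cm[lg, s] <- (y_hi - y_lo) / 10 / 10  # mm -> cm, / 10 bins
    }
  }
  structure(list(section = section, level = level,
                 level_height_cm = level_height_cm,
                 section_extent_cm = section_extent_cm,
                 spacing = mask$spacing, labels = lab),
            class = "regional_grid")
}

#' Merge same-numbered regional elements and summarize
#'
#' For `axis = "sternovertebral"`, all level-k elements across the 10
#' apex--base sections are merged, giving 10 ventral-to-dorsal regions per
#' lung; for `axis = "apexbase"`, same-numbered sections are merged, giving
#' 10 apex-to-base regions. Each merged region is summarized with
#' [summarize_voxels()]; when a body surface area is supplied, gas and
#' tissue volumes are also reported normalized by BSA (ml/m^2).
#'
#' @param grid a [build_regional_grid()] result.
#' @param volume the aligned [hu_volume()].
#' @param axis `"sternovertebral"` (default) or `"apexbase"`.
#' @param bsa body surface area in m^2, or `NULL` to skip normalization.
#' @param mode gas-fraction mode, see [gas_fraction()].
#' @return A data.frame (class `regional_profile`) with one row per
#'   (lung, region 1..10): volumes, tissue mass, mean HU, gas/tissue ratio,
#'   and BSA-normalized columns when `bsa` is given. Empty regions carry
#'   zero volumes and NA means.
#' @export
merge_regions <- function(grid, volume,
                          axis = c("sternovertebral", "apexbase"),
                          bsa = NULL, mode = c("literal", "clamped")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "regional_grid"), inherits(volume, "hu_volume"))
  if (!identical(dim(grid$section), dim(volume$values)))
    stop("regional grid and volume have different grid shapes", call. = FALSE)
  if (!is.null(bsa) && (!is.numeric(bsa) || length(bsa) != 1L || bsa <= 0))
    stop("`bsa` must be a single positive area in m^2", call. = FALSE)

  assign_arr <- if (axis == "sternovertebral") grid$level else grid$section
  rows <- list()
  for (lg in 1:2) {
    lung_name <- c("right", "left")[lg]
    for (r in 1:10) {
      sel <- grid$labels == lg & assign_arr == r
      n <- sum(sel)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          lung = lung_name, region = r, n_voxels = 0L,
          total_volume_ml = 0, gas_volume_ml = 0, tissue_volume_ml = 0,
          tissue_mass_g = 0, mean_hu = NA_real_,
          gas_tissue_ratio = NA_real_)
        next
      }
      s <- summarize_voxels(volume, sel, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        lung = lung_name, region = r, n_voxels = s$n_voxels,
        total_volume_ml = s$total_volume_ml, gas_volume_ml = s$gas_volume_ml,
        tissue_volume_ml = s$tissue_volume_ml, tissue_mass_g = s$tissue_mass_g,
        mean_hu = s$mean_hu, gas_tissue_ratio = s$gas_tissue_ratio)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(bsa)) {
    out$gas_per_bsa_ml_m2 <- out$gas_volume_ml / bsa
    out$tissue_per_bsa_ml_m2 <- out$tissue_volume_ml / bsa
  }
  attr(out, "axis") <- axis
  class(out) <- c("regional_profile", "data.frame")
  out
}

#' Superimposed hydrostatic pressure profile
#'
#' Treating the lung as a fluid, the pressure superimposed on a region is
#' the weight of the parenchyma above it: with level densities rho_k (g/ml)
#' and level heights h_k (cm), the pressure at the dorsal boundary of level
#' k is `sum_{j<=k} rho_j h_j` and at its midpoint
#' `sum_{j<k} rho_j h_j + rho_k h_k / 2` (1 g/cm^3 x 1 cm = 1 cmH2O).
#' The average superimposed pressure is the unweighted mean of the midpoint
#' pressures over levels with positive height; for a uniform column of
#' density rho and height H this is rho H / 2, and the dorsal-most boundary
#' pressure is rho H, the textbook column-weight formula. A tissue-weighted
#' average is reported alongside as an attribute.
#'
#' @param density_g_ml densities of the 10 ventral-to-dorsal levels (g/ml,
#'   non-negative). A level's density is its tissue mass over its total
#'   volume.
#' @param height_cm the 10 level heights (cm, non-negative); a zero-height
#'   level contributes nothing and is excluded from the average.
#' @param tissue_mass_g optional per-level tissue masses used for the
#'   tissue-weighted average (defaults to `density_g_ml * height_cm` as
#'   relative weights).
#' @return A data.frame (class `sp_profile`) with columns `level`,
#'   `density_g_ml`, `height_cm`, `pressure_mid_cmh2o`,
#'   `pressure_dorsal_cmh2o`; attributes `average_sp_cmh2o`,
#'   `average_sp_tissue_weighted_cmh2o` and `lung_height_cm`.
#' @examples
#' superimposed_pressure(c(0.1, 0.3, rep(0, 8)), c(10, 10, rep(0, 8)))
#' @export
superimposed_pressure <- function(density_g_ml, height_cm,
                                  tissue_mass_g = NULL) {
  if (length(density_g_ml) != 10L || length(height_cm) != 10L)
    stop("expected 10 levels of densities and heights", call. = FALSE)
  if (any(!is.finite(density_g_ml)) || any(!is.finite(height_cm)) ||
      any(density_g_ml < 0) || any(height_cm < 0))
    stop("densities and heights must be finite and non-negative",
         call. = FALSE)
  w <- density_g_ml * height_cm
  dorsal <- cumsum(w)
  mid <- dorsal - w / 2
  nz <- height_cm > 0
  avg <- mean(mid[nz])
  wts <- if (is.null(tissue_mass_g)) w else tissue_mass_g
  avg_tw <- if (sum(wts[nz]) > 0) weighted.mean(mid[nz], wts[nz]) else 0
  out <- data.frame(level = 1:10, density_g_ml = density_g_ml,
                    height_cm = height_cm,
                    pressure_mid_cmh2o = mid,
                    pressure_dorsal_cmh2o = dorsal)
  attr(out, "average_sp_cmh2o") <- avg
  attr(out, "average_sp_tissue_weighted_cmh2o") <- avg_tw
  attr(out, "lung_height_cm") <- sum(height_cm)
  class(out) <- c("sp_profile", "data.frame")
  out
}

#' Superimposed pressure profile of one lung
#'
#' Derives the 10-level density and height inputs of
#' [superimposed_pressure()] from a regional grid: level k's density is the
#' tissue mass over total volume of the merged sterno-vertebral level k, and
#' its height is the mean, over the level's voxels, of the per-section level
#' heights (sections are binned independently, so their level heights can
#' differ).
#'
#' @param grid a [build_regional_grid()] result.
#' @param volume the aligned [hu_volume()].
#' @param lung `"right"` or `"left"`.
#' @param mode gas-fraction mode.
#' @return An `sp_profile`, see [superimposed_pressure()].
#' @export
superimposed_pressure_profile <- function(grid, volume,
                                          lung = c("right", "left"),
                                          mode = c("literal", "clamped")) {
  lung <- match.arg(lung)
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "regional_grid"))
  lg <- match(lung, c("right", "left"))
  if (!any(grid$labels == lg))
    stop(sprintf("%s lung is empty in this mask", lung), call. = FALSE)

  density <- numeric(10)
  height <- numeric(10)
  mass <- numeric(10)
  for (k in 1:10) {
    sel <- grid$labels == lg & grid$level == k
    if (!any(sel)) next
    s <- summarize_voxels(volume, sel, mode = mode)
    density[k] <- s$tissue_mass_g / s$total_volume_ml
    mass[k] <- s$tissue_mass_g
    # each voxel inherits its section's level height
    secs <- grid$section[sel]
    height[k] <- mean(grid$level_height_cm[lg, secs])
  }
  superimposed_pressure(density, height, tissue_mass_g = mass)
}

#' Bounding-box extents of the lungs
#'
#' Physical bounding-box extent (voxel edges included) of each lung and of
#' both lungs combined, along the three grid axes. Axis `x` is left--right
#' (transverse), `y` ventral--dorsal (sterno-vertebral), `z` apex--base
#' (cranio-caudal); the mapping of these geometric axes onto radiological
#' plane-size conventions is left to the caller.
#'
#' @param mask a [lung_mask()].
#' @param spacing voxel spacing in mm; defaults to the mask's.
#' @return A data.frame with columns `lung` (`right`, `left`, `both`),
#'   `axis` (`x`, `y`, `z`) and `extent_mm` (NA for an empty lung).
#' @export
lung_extents <- function(mask, spacing = mask$spacing) {
  stopifnot(inherits(mask, "lung_mask"))
  d <- dim(mask$labels)
  one <- function(sel, name) {
    idx <- which(sel)
    if (length(idx) == 0L)
      return(data.frame(lung = name, axis = c("x", "y", "z"),
                        extent_mm = NA_real_))
    ai <- arrayInd(idx, d)
    ext <- vapply(1:3, function(a)
      (max(ai[, a]) - min(ai[, a]) + 1) * spacing[a], numeric(1))
    data.frame(lung = name, axis = c("x", "y", "z"), extent_mm = ext)
  }
  rbind(one(mask$labels == 1L, "right"),
        one(mask$labels == 2L, "left"),
        one(mask$labels > 0L, "both"))
}
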