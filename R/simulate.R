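#' Digital lung phantom specification
#'
#' Describes a two-ellipsoid digital lung phantom on a regular grid. Three
#' attenuation fields are supported:
#' \describe{
#'   \item{uniform}{every lung voxel at `base_hu`.}
#'   \item{gradient}{`base_hu` at each lung's centre plus a linear
#'     ventral-to-dorsal ramp of `gradient_hu_per_cm` HU per cm (denser
#'     dorsally for positive values, emulating the gravitational density
#'     gradient of a supine lung).}
#'   \item{mixture}{voxels take band-interior anchor HU values
#'     (-950, -700, -300, -50) with voxel counts apportioned so the tissue
#'     mass splits across the four aeration compartments at the requested
#'     percentages; voxels are laid out ventral to dorsal from most to
#'     least aerated, mimicking the gravitational ordering.}
#' }
#' Optional Gaussian HU noise is added, then values are clipped to
#' \[-1000, 100\]. For the mixture field keep `noise_sd` below ~15 HU so
#' jitter cannot cross a band edge (anchors sit >= 50 HU inside their
#' bands).
#'
#' @param shape grid dimensions (default `c(64, 64, 64)`).
#' @param spacing voxel spacing mm (default 2 mm isotropic).
#' @param right_center,left_center ellipsoid centres in mm.
#' @param right_radii,left_radii ellipsoid semi-axes in mm (x, y, z).
#' @param base_hu baseline attenuation (default -805, the reference
#'   population mean lung density).
#' @param gradient_hu_per_cm ventral-to-dorsal HU ramp (default 0).
#' @param mixture named percentages summing to 100 for compartments
#'   `overinflated`, `well`, `poorly`, `noninflated`, or `NULL`.
#' @param noise_sd Gaussian HU noise SD (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2, 2, 2),
                         right_center = c(32, 64, 64),
                         right_radii = c(26, 40, 58),
                         left_center = c(96, 64, 64),
                         left_radii = c(26, 40, 58),
                         base_hu = -805,
                         gradient_hu_per_cm = 0,
                         mixture = NULL,
                         noise_sd = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0),
            length(right_center) == 3L, length(left_center) == 3L,
            all(right_radii > 0), all(left_radii > 0),
            is.numeric(noise_sd), noise_sd >= 0)
  if (!is.null(mixture)) {
    need <- c("overinflated", "well", "poorly", "noninflated")
    if (!setequal(names(mixture), need))
      stop("`mixture` must be named percentages for: ",
           paste(need, collapse = ", "), call. = FALSE)
    mixture <- mixture[need]
    if (abs(sum(mixture) - 100) > 1e-9)
      stop("`mixture` percentages must sum to 100", call. = FALSE)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 right_center = right_center, right_radii = right_radii,
                 left_center = left_center, left_radii = left_radii,
                 base_hu = base_hu, gradient_hu_per_cm = gradient_hu_per_cm,
                 mixture = mixture, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Anchor HU values used by the mixture field, one per compartment, each at
# least 50 HU inside its band.
MIXTURE_ANCHORS_HU <- c(overinflated = -950, well = -700,
                        poorly = -300, noninflated = -50)

# Largest-remainder apportionment of n items into shares (sums to n).
apportion <- function(shares, n) {
  raw <- shares / sum(shares) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a digital lung phantom
#'
#' Voxelizes the two lung ellipsoids of a [phantom_spec()], fills them with
#' the requested attenuation field and returns the volume, the mask and an
#' analytically derived ground truth (ellipsoid volumes from
#' `4/3 pi a b c`, mean HU from the field definition — not from the
#' voxelization), so pipeline output can be checked against values the
#' voxel grid never saw.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([hu_volume()]), `mask`
#'   ([lung_mask()]) and `truth` (list: per-lung and total analytic volumes
#'   in ml, expected mean HU / gas fraction, and for mixture fields the
#'   achieved compartment mass fractions).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  extent <- d * sp

  for (side in c("right", "left")) {
    ctr <- spec[[paste0(side, "_center")]]
    rad <- spec[[paste0(side, "_radii")]]
    if (any(ctr - rad < 0) || any(ctr + rad > extent))
      stop(side, " lung ellipsoid extends outside the grid", call. = FALSE)
  }

  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  inside <- function(ctr, rad) {
    dx2 <- ((xc - ctr[1]) / rad[1])^2
    dy2 <- ((yc - ctr[2]) / rad[2])^2
    dz2 <- ((zc - ctr[3]) / rad[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  }
  in_r <- inside(spec$right_center, spec$right_radii)
  in_l <- inside(spec$left_center, spec$left_radii)
  if (any(in_r & in_l))
    stop("lung ellipsoids overlap", call. = FALSE)

  labels <- array(0L, d)
  labels[in_r] <- 1L
  labels[in_l] <- 2L
  mask <- lung_mask(labels, sp)

  vals <- array(20, d)  # soft-tissue background
  truth <- list()
  ell_vol_ml <- function(rad) 4 / 3 * pi * prod(rad) / 1000
  truth$right_volume_ml <- ell_vol_ml(spec$right_radii)
  truth$left_volume_ml <- ell_vol_ml(spec$left_radii)
  truth$total_volume_ml <- truth$right_volume_ml + truth$left_volume_ml

  if (is.null(spec$mixture)) {
    # uniform / gradient field; the gradient is anchored at each lung's
    # centre, so by symmetry the analytic lung-mean HU is base_hu
    for (lg in 1:2) {
      sel <- if (lg == 1) in_r else in_l
      ctr_y <- spec[[c("right_center", "left_center")[lg]]][2]
      idx <- which(sel)
      jj <- arrayInd(idx, d)[, 2]
      hu <- spec$base_hu + spec$gradient_hu_per_cm * (yc[jj] - ctr_y) / 10
      vals[idx] <- hu
    }
    truth$mean_hu <- spec$base_hu
    truth$gas_fraction <- spec$base_hu / -1000
    truth$gas_volume_ml <- truth$gas_fraction * truth$total_volume_ml
    truth$tissue_mass_g <- truth$total_volume_ml - truth$gas_volume_ml
  } else {
    tf <- 1 + MIXTURE_ANCHORS_HU / 1000   # per-voxel tissue fraction
    shares <- spec$mixture / tf           # voxel counts per unit mass share
    for (lg in 1:2) {
      idx <- which(if (lg == 1) in_r else in_l)
      n <- length(idx)
      counts <- apportion(shares, n)
      # ventral -> dorsal, most to least aerated
      ord <- idx[order(arrayInd(idx, d)[, 2])]
      hu_seq <- rep(MIXTURE_ANCHORS_HU, counts)
      vals[ord] <- hu_seq
    }
    achieved_mass <- vapply(seq_along(tf), function(i)
      sum(vals[labels > 0L] == MIXTURE_ANCHORS_HU[i]) * tf[i], numeric(1))
    truth$mass_fraction_pct <- setNames(
      100 * achieved_mass / sum(achieved_mass), names(MIXTURE_ANCHORS_HU))
    truth$target_mass_fraction_pct <- spec$mixture
    truth$mean_hu <- NA_real_
  }

  if (spec$noise_sd > 0) {
    vals <- withr::with_seed(spec$seed, {
      idx <- which(labels > 0L)
      vals[idx] <- vals[idx] + rnorm(length(idx), 0, spec$noise_sd)
      vals
    })
  }
  vals <- pmin(pmax(vals, -1000), 100)
  dim(vals) <- d

  list(volume = hu_volume(vals, sp), mask = mask, truth = truth)
}

#' Calibrate regression noise to a target fit quality
#'
#' For a linear generative model `y = a + b x + e` with predictor SD
#' `s_x` and Gaussian noise SD `s_e`, the population coefficient of
#' determination is `r2 = (b s_x)^2 / ((b s_x)^2 + s_e^2)`. Inverting gives
#' the noise SD that makes simulated fits match a published r-squared:
#' `s_e = |b| s_x sqrt((1 - r2) / r2)`.
#'
#' @param slope generating slope `b`.
#' @param predictor_sd SD of the predictor in the simulated population.
#' @param target_r2 target coefficient of determination, in (0, 1).
#' @return Noise SD in response units.
#' @examples
#' calibrate_noise_sd(1633.7, 0.1, 0.49)
#' @export
calibrate_noise_sd <- function(slope, predictor_sd, target_r2) {
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 1)
    stop("`target_r2` must lie strictly between 0 and 1", call. = FALSE)
  if (predictor_sd < 0)
    stop("`predictor_sd` must be non-negative", call. = FALSE)
  abs(slope) * predictor_sd * sqrt((1 - target_r2) / target_r2)
}

# SD of a two-component normal mixture (used for the pooled height SD of a
# mixed-sex cohort).
mixture_sd <- function(p, means, sds) {
  m <- sum(p * means)
  sqrt(sum(p * (sds^2 + means^2)) - m^2)
}

#' Synthetic cohort specification
#'
#' Parameters of the synthetic normative cohort generator. Defaults encode
#' the reference population: 100 subjects (53 male / 47 female), per-sex
#' normal anthropometrics from [reference_population()], lung weight and
#' supine TLC generated from the registered height regressions
#' (`lung_weight_vs_height`, `supine_tlc_vs_height`) with Gaussian noise
#' calibrated by [calibrate_noise_sd()] to the published r-squared of each
#' fit — using the analytic mixed-sex height SD, since the published fits
#' pool the sexes. Compartment percentages and superimposed pressure are
#' drawn around the reference means.
#'
#' @param n cohort size (>= 2).
#' @param male_fraction fraction of males (default 0.53).
#' @param r2_lung_weight,r2_supine_tlc target fit quality for the two
#'   generative regressions (defaults: the registered published values).
#' @param seed RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100, male_fraction = 0.53,
                        r2_lung_weight = NULL, r2_supine_tlc = NULL,
                        seed = 1L) {
  if (!is.numeric(n) || n < 2)
    stop("`n` must be >= 2", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1)
    stop("`male_fraction` must be in [0, 1]", call. = FALSE)
  if (is.null(r2_lung_weight))
    r2_lung_weight <- get_lung_regression("lung_weight_vs_height")$r_squared
  if (is.null(r2_supine_tlc))
    r2_supine_tlc <- get_lung_regression("supine_tlc_vs_height")$r_squared
  structure(list(n = as.integer(n), male_fraction = male_fraction,
                 r2_lung_weight = r2_lung_weight,
                 r2_supine_tlc = r2_supine_tlc,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw from a normal, resampling any draw at or below `lower` (physical
# quantities cannot be negative). Returns the draws plus a truncation count.
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  n_trunc <- 0L
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    n_trunc <- n_trunc + length(bad)
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower)
  }
  attr(x, "n_truncated") <- n_trunc
  x
}

#' Generate a synthetic normative cohort
#'
#' Draws per-sex anthropometrics and CT summaries with the generative
#' structure described in [cohort_spec()]. Total lung volume is gas volume
#' plus lung weight (1 g tissue = 1 ml), mean HU is `-1000 * gas / total`,
#' so every generated subject satisfies the densitometric identities
#' exactly. Reproducible: the same spec (including seed) yields a
#' bit-identical table.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame (one row per subject): `id`, `sex`, `age_years`,
#'   `height_m`, `weight_kg`, `bsa_m2`, `lung_weight_g`, `gas_volume_ml`,
#'   `total_volume_ml`, `mean_hu`, `gas_tissue_ratio`,
#'   `overinflated_pct`, `well_inflated_pct`, `poorly_inflated_pct`,
#'   `noninflated_pct`, `avg_sp_cmh2o`. Attribute `n_truncated` counts
#'   resampled negative draws.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n
  n_male <- round(n * spec$male_fraction)
  sex <- rep(c("male", "female"), c(n_male, n - n_male))

  par_of <- function(v, g) c(ref_value(v, g, "mean"), ref_value(v, g, "sd"))
  n_trunc <- 0L
  draw <- function(v, lower = 0) {
    out <- numeric(n)
    for (g in c("male", "female")) {
      idx <- sex == g
      if (!any(idx)) next
      p <- par_of(v, g)
      x <- rnorm_trunc(sum(idx), p[1], p[2], lower)
      n_trunc <<- n_trunc + attr(x, "n_truncated")
      out[idx] <- as.numeric(x)
    }
    out
  }

  height <- draw("height_m", lower = 0.5)
  weight <- draw("weight_kg", lower = 1)
  age <- draw("age_years", lower = 18)

  # pooled height SD of the mixed-sex generating population
  p <- c(n_male, n - n_male) / n
  h_sd <- mixture_sd(p,
                     c(ref_value("height_m", "male"),
                       ref_value("height_m", "female")),
                     c(ref_value("height_m", "male", "sd"),
                       ref_value("height_m", "female", "sd")))

  lw_reg <- get_lung_regression("lung_weight_vs_height")
  tlc_reg <- get_lung_regression("supine_tlc_vs_height")
  lw_sd <- calibrate_noise_sd(lw_reg$slope, h_sd, spec$r2_lung_weight)
  tlc_sd <- calibrate_noise_sd(tlc_reg$slope, h_sd, spec$r2_supine_tlc)

  # responses are left exactly linear-plus-Gaussian: truncating them would
  # bias the fitted coefficients away from the generating values
  lung_weight <- lw_reg$intercept + lw_reg$slope * height +
    rnorm(n, 0, lw_sd)
  gas <- tlc_reg$intercept + tlc_reg$slope * height + rnorm(n, 0, tlc_sd)

  total <- gas + lung_weight  # 1 g tissue occupies 1 ml
  mean_hu <- -1000 * gas / total

  over <- draw("overinflated_pct")
  poor <- draw("poorly_inflated_pct")
  non <- draw("noninflated_pct")
  well <- 100 - over - poor - non
  bad <- which(well <= 0)
  while (length(bad) > 0) {
    n_trunc <- n_trunc + length(bad)
    for (g in c("male", "female")) {
      idx <- intersect(bad, which(sex == g))
      if (!length(idx)) next
      over[idx] <- as.numeric(rnorm_trunc(length(idx),
        ref_value("overinflated_pct", g), ref_value("overinflated_pct", g, "sd")))
      poor[idx] <- as.numeric(rnorm_trunc(length(idx),
        ref_value("poorly_inflated_pct", g), ref_value("poorly_inflated_pct", g, "sd")))
      non[idx] <- as.numeric(rnorm_trunc(length(idx),
        ref_value("noninflated_pct", g), ref_value("noninflated_pct", g, "sd")))
    }
    well <- 100 - over - poor - non
    bad <- which(well <= 0)
  }
  sp_v <- draw("avg_sp_cmh2o")

  out <- data.frame(id = seq_len(n), sex = sex, age_years = age,
                    height_m = height, weight_kg = weight,
                    bsa_m2 = bsa_dubois(weight, height),
                    lung_weight_g = lung_weight,
                    gas_volume_ml = gas, total_volume_ml = total,
                    mean_hu = mean_hu, gas_tissue_ratio = gas / lung_weight,
                    overinflated_pct = over, well_inflated_pct = well,
                    poorly_inflated_pct = poor, noninflated_pct = non,
                    avg_sp_cmh2o = sp_v)
  attr(out, "n_truncated") <- n_trunc
  attr(out, "noise_sd") <- c(lung_weight_g = lw_sd, gas_volume_ml = tlc_sd)
  out
}

#' Parameter-recovery simulation for the normative regressions
#'
#' Generates `reps` independent synthetic cohorts of size `n`, fits the
#' requested response on height by OLS in each, and averages slope,
#' intercept and r-squared across replicates. Because each cohort is
#' generated from the registered regression line with noise calibrated to
#' its published fit quality, the averages recover the published
#' coefficients up to Monte-Carlo error, which is also reported
#' (`se_* = sd across replicates / sqrt(reps)`).
#'
#' @param regression_id `"lung_weight_vs_height"` or
#'   `"supine_tlc_vs_height"`.
#' @param n subjects per cohort (default 100).
#' @param reps number of replicate cohorts (default 200).
#' @param seed RNG seed for the whole simulation.
#' @return A list: `mean_slope`, `mean_intercept`, `mean_r_squared`, their
#'   Monte-Carlo standard errors `se_slope`, `se_intercept`,
#'   `se_r_squared`, the `generating` coefficients, `n` and `reps`.
#' @export
simulate_regression_recovery <- function(regression_id =
                                           c("lung_weight_vs_height",
                                             "supine_tlc_vs_height"),
                                         n = 100, reps = 200, seed = 1L) {
  regression_id <- match.arg(regression_id)
  reg <- get_lung_regression(regression_id)
  response <- if (regression_id == "lung_weight_vs_height")
    "lung_weight_g" else "gas_volume_ml"

  fits <- withr::with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      # draws flow from the single ambient stream seeded above
      coh <- generate_cohort_impl(cohort_spec(n = n))
      fit_linear_regression(coh$height_m, coh[[response]])
    })
  })
  slopes <- vapply(fits, `[[`, 0, "slope")
  ints <- vapply(fits, `[[`, 0, "intercept")
  r2s <- vapply(fits, `[[`, 0, "r_squared")
  list(mean_slope = mean(slopes),
       mean_intercept = mean(ints),
       mean_r_squared = mean(r2s),
       se_slope = sd(slopes) / sqrt(reps),
       se_intercept = sd(ints) / sqrt(reps),
       se_r_squared = sd(r2s) / sqrt(reps),
       generating = list(slope = reg$slope, intercept = reg$intercept,
                         r_squared = reg$r_squared),
       n = n, reps = reps)
}
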