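# Fixture builders and independent oracles shared across test files.

# Cuboid phantom: a box of `dims` voxels entirely labelled as one lung,
# with HU given by a function of the (x, y, z) voxel centre in mm.
cuboid_volume <- function(dims, spacing, hu_fun, label = 1L) {
  d <- as.integer(dims)
  xc <- (seq_len(d[1]) - 0.5) * spacing[1]
  yc <- (seq_len(d[2]) - 0.5) * spacing[2]
  zc <- (seq_len(d[3]) - 0.5) * spacing[3]
  grid <- expand.grid(x = xc, y = yc, z = zc)
  vals <- array(hu_fun(grid$x, grid$y, grid$z), dim = d)
  list(volume = hu_volume(vals, spacing),
       mask = lung_mask(array(label, d), spacing))
}

# Literal per-voxel densitometry oracle: loops over selected voxels and
# accumulates the two decomposition formulas one voxel at a time.
densitometry_oracle <- function(volume, sel) {
  idx <- which(sel)
  vv <- prod(volume$spacing) / 1000
  total <- 0; gas <- 0; hu_sum <- 0
  for (i in idx) {
    hu <- volume$values[i]
    total <- total + vv
    gas <- gas + (hu / -1000) * vv
    hu_sum <- hu_sum + hu
  }
  list(total = total, gas = gas, tissue = total - gas,
       mean_hu = hu_sum / length(idx))
}

# Closed-form two-variable OLS (textbook formulas), independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  s2 <- sse / (n - 2)
  se_b <- sqrt(s2 / sxx)
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  tcrit <- qt(0.975, n - 2)
  list(slope = b, intercept = a, r_squared = 1 - sse / sst,
       slope_ci = c(b - tcrit * se_b, b + tcrit * se_b),
       intercept_ci = c(a - tcrit * se_a, a + tcrit * se_a))
}

# Pooled-variance t statistic from the textbook formula.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Brute-force superimposed-pressure oracle: for every in-mask voxel,
# integrate the tissue fraction along its ventral->dorsal column down to
# the voxel centre, then average over voxels.
sp_voxel_oracle <- function(volume, mask, lung_label = 1L) {
  d <- dim(volume$values)
  sp <- volume$spacing
  dy_cm <- sp[2] / 10
  total <- 0; count <- 0
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) {
    col_lab <- mask$labels[i, , k]
    in_col <- which(col_lab == lung_label)
    if (length(in_col) == 0) next
    tf <- 1 + volume$values[i, , k] / 1000
    tf[col_lab != lung_label] <- 0
    cum <- cumsum(tf * dy_cm)
    p_center <- cum - tf * dy_cm / 2
    total <- total + sum(p_center[in_col])
    count <- count + length(in_col)
  }
  total / count
}

# Printed compartment mass mixture of the reference population, with the
# one-point rounding excess spread equally so the mixture is realizable
# (sums to 100).
reference_mixture <- function() {
  m <- c(overinflated = 11, well = 65, poorly = 18, noninflated = 7)
  m - (sum(m) - 100) / 4
}
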