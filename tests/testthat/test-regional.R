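test_that("regional grid partitions each lung into 10 equal-height bins per section", {
  # cuboid lung spanning 200 mm ventral-dorsal: every level 20 mm (2 cm)
  cb <- cuboid_volume(c(10, 100, 20), c(2, 2, 5),
                      function(x, y, z) -805)
  g <- build_regional_grid(cb$mask)
  expect_true(all(abs(g$level_height_cm["right", ] - 2) < 1e-12))
  # every in-mask voxel assigned exactly one (section, level)
  expect_true(all(g$section[cb$mask$labels == 1L] %in% 1:10))
  expect_true(all(g$level[cb$mask$labels == 1L] %in% 1:10))
  # each level holds exactly a tenth of the voxels
  expect_true(all(table(g$level[cb$mask$labels == 1L]) == 10 * 100 * 20 / 10))
})

test_that("per-section level heights follow each section's own extent", {
  # apical half 100 mm deep, basal half 200 mm deep (two stacked cuboids)
  d <- c(10, 100, 20)
  lab <- array(0L, d)
  lab[, 1:50, 1:10] <- 1L    # apex half: 50 voxels * 2 mm = 100 mm deep
  lab[, 1:100, 11:20] <- 1L  # base half: 200 mm deep
  mask <- lung_mask(lab, c(2, 2, 5))
  g <- build_regional_grid(mask)
  expect_true(all(abs(g$level_height_cm["right", 1:5] - 1) < 1e-9))
  expect_true(all(abs(g$level_height_cm["right", 6:10] - 2) < 1e-9))
})

test_that("a voxel centre on a bin edge goes to the more dorsal bin", {
  # 20 voxels of 1 mm: extent [0, 20], level edges every 2 mm; voxel 5
  # has centre 4.5 (level 3 spans [4, 6)), voxel centre exactly on an edge
  # only arises with even centres, so use spacing 4 and 5 voxels:
  # extent [0, 20], edges at 2, 4, ..., centre of voxel 2 = 6 mm = edge of
  # levels 3/4 -> level 4
  cb <- cuboid_volume(c(1, 5, 1), c(4, 4, 4), function(x, y, z) -805)
  g <- build_regional_grid(cb$mask)
  # centres 2, 6, 10, 14, 18; bin height 2 mm; centre 6 is the 3/4 edge
  expect_equal(g$level[1, 2, 1], 4L)
  # the dorsal-most centre stays in level 10 (clamped, not level 11)
  expect_equal(g$level[1, 5, 1], 10L)
})

test_that("merged regional profiles partition the whole lung and track gradients", {
  grad <- cuboid_volume(c(10, 50, 20), c(3, 4, 5),
                        function(x, y, z) -950 + 1.2 * y)
  g <- build_regional_grid(grad$mask)
  whole <- summarize_voxels(grad$volume, mask_selector(grad$mask))

  for (axis in c("sternovertebral", "apexbase")) {
    prof <- merge_regions(g, grad$volume, axis = axis, bsa = 1.8)
    right <- prof[prof$lung == "right", ]
    expect_equal(sum(right$gas_volume_ml), whole$gas_volume_ml,
                 tolerance = 1e-9)
    expect_equal(sum(right$tissue_mass_g), whole$tissue_mass_g,
                 tolerance = 1e-9)
    expect_equal(sum(right$total_volume_ml), whole$total_volume_ml,
                 tolerance = 1e-9)
    expect_equal(right$gas_per_bsa_ml_m2, right$gas_volume_ml / 1.8)
  }

  # ventral->dorsal density gradient: merged tissue mass strictly
  # increasing with level, gas/tissue ratio strictly decreasing
  sv <- merge_regions(g, grad$volume, axis = "sternovertebral")
  right <- sv[sv$lung == "right", ]
  expect_true(all(diff(right$tissue_mass_g) > 0))
  expect_true(all(diff(right$gas_tissue_ratio) < 0))

  # uniform phantom: all merged levels carry equal tissue mass
  unif <- cuboid_volume(c(10, 50, 20), c(3, 4, 5), function(x, y, z) -805)
  gu <- build_regional_grid(unif$mask)
  su <- merge_regions(gu, unif$volume)
  ru <- su[su$lung == "right", ]
  expect_equal(ru$tissue_mass_g, rep(ru$tissue_mass_g[1], 10),
               tolerance = 1e-9)

  expect_error(merge_regions(g, grad$volume, bsa = -1), "bsa")
})

test_that("superimposed pressure integrates the column weight as hand-computed", {
  # two 10-cm levels of density 0.1 and 0.3 g/ml, padded with zero-height
  # levels
  p <- superimposed_pressure(c(0.1, 0.3, rep(0, 8)), c(10, 10, rep(0, 8)))
  expect_equal(p$pressure_dorsal_cmh2o[1:2], c(1.0, 4.0))
  expect_equal(p$pressure_mid_cmh2o[1:2], c(0.5, 2.5))
  expect_equal(attr(p, "average_sp_cmh2o"), 1.5)
  expect_equal(attr(p, "lung_height_cm"), 20)

  # zero tissue everywhere -> all pressures zero
  p0 <- superimposed_pressure(rep(0, 10), rep(2, 10))
  expect_true(all(p0$pressure_dorsal_cmh2o == 0))
  expect_equal(attr(p0, "average_sp_cmh2o"), 0)

  # uniform density: dorsal-most pressure is rho * H, average rho * H / 2
  pu <- superimposed_pressure(rep(0.2, 10), rep(1.5, 10))
  expect_equal(pu$pressure_dorsal_cmh2o[10], 0.2 * 15)
  expect_equal(attr(pu, "average_sp_cmh2o"), 0.2 * 15 / 2)

  # dorsal-boundary pressure non-decreasing; average bracketed by the
  # level-1 midpoint and the level-10 dorsal pressure
  set.seed(3)
  for (i in 1:5) {
    dens <- runif(10, 0, 0.5)
    h <- runif(10, 0.5, 3)
    pr <- superimposed_pressure(dens, h)
    expect_true(all(diff(pr$pressure_dorsal_cmh2o) >= 0))
    avg <- attr(pr, "average_sp_cmh2o")
    expect_gte(avg, pr$pressure_mid_cmh2o[1])
    expect_lte(avg, pr$pressure_dorsal_cmh2o[10])
  }
  expect_error(superimposed_pressure(rep(0.1, 9), rep(1, 9)), "10 levels")
})

test_that("10-level superimposed pressure agrees with a per-voxel column oracle", {
  grad <- cuboid_volume(c(8, 60, 10), c(3, 3, 6),
                        function(x, y, z) -950 + 1.0 * y)
  g <- build_regional_grid(grad$mask)
  prof <- superimposed_pressure_profile(g, grad$volume, "right")
  oracle <- sp_voxel_oracle(grad$volume, grad$mask, 1L)
  expect_equal(attr(prof, "average_sp_cmh2o"), oracle, tolerance = 0.05)
})

test_that("sterno-vertebral profiles are invariant to flipping the apex-base axis", {
  grad <- cuboid_volume(c(6, 40, 12), c(3, 3, 5),
                        function(x, y, z) -900 + 1.5 * y + 0.2 * z)
  g1 <- build_regional_grid(grad$mask)
  p1 <- merge_regions(g1, grad$volume)

  flip <- function(a) a[, , dim(a)[3]:1, drop = FALSE]
  vol2 <- hu_volume(flip(grad$volume$values), grad$volume$spacing)
  mask2 <- lung_mask(flip(grad$mask$labels), grad$mask$spacing)
  g2 <- build_regional_grid(mask2)
  p2 <- merge_regions(g2, vol2)
  expect_equal(p1$tissue_mass_g, p2$tissue_mass_g, tolerance = 1e-9)
  expect_equal(p1$gas_volume_ml, p2$gas_volume_ml, tolerance = 1e-9)
})

test_that("lung extents report physical bounding boxes", {
  d <- c(20, 100, 30)
  lab <- array(0L, d)
  lab[2:11, 1:100, 1:30] <- 1L
  mask <- lung_mask(lab, c(2, 2, 5))
  ext <- lung_extents(mask)
  r <- ext[ext$lung == "right", ]
  expect_equal(r$extent_mm[r$axis == "x"], 20)
  expect_equal(r$extent_mm[r$axis == "y"], 200)
  expect_equal(r$extent_mm[r$axis == "z"], 150)
  # empty left lung flagged as NA
  expect_true(all(is.na(ext$extent_mm[ext$lung == "left"])))
  # combined extent at least each single lung's
  lab[15:20, 10:20, 5:10] <- 2L
  ext2 <- lung_extents(lung_mask(lab, c(2, 2, 5)))
  for (ax in c("x", "y", "z")) {
    e <- ext2$extent_mm[ext2$axis == ax]
    expect_gte(e[3], max(e[1], e[2]))
  }

  # 50-mm-radius sphere: extents within one voxel of 100 mm
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64),
                                      spacing = c(2, 2, 2),
                                      right_center = c(60, 64, 64),
                                      right_radii = c(50, 50, 50),
                                      left_center = c(122, 10, 10),
                                      left_radii = c(4, 4, 4)))
  es <- lung_extents(ph$mask)
  sph <- es$extent_mm[es$lung == "right"]
  expect_true(all(abs(sph - 100) <= 2))
})

test_that("body surface area follows the Du Bois formula", {
  expect_equal(bsa_dubois(72, 1.70), 0.007184 * 72^0.425 * 170^0.725)
  expect_error(bsa_dubois(-1, 1.7), "positive")
})
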