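# Builds small volumes in code; voxel pitch 1 um unless noted.

solid_mes_volume <- function(ias_frac = 0, n = 24, seed = 1) {
  lm <- leaf_labels()
  set.seed(seed)
  lab <- array(lm[["mesophyll_cell"]], c(n, n, n))
  if (ias_frac > 0) {
    k <- round(ias_frac * n^3)
    lab[sample(n^3, k)] <- lm[["ias"]]
  }
  labeled_volume(lab, 1)
}

test_that("porosity covers its degenerate and counting cases", {
  expect_equal(porosity(solid_mes_volume(0)), 0)
  lm <- leaf_labels()
  all_ias <- labeled_volume(array(lm[["ias"]], c(8, 8, 8)), 1)
  expect_equal(porosity(all_ias), 1)
  v <- solid_mes_volume(0.3, seed = 2)
  cnt <- tissue_counts(v)
  expect_equal(porosity(v), cnt[["ias"]] / (cnt[["ias"]] + cnt[["mesophyll_cell"]]))
  empty <- labeled_volume(array(lm[["background"]], c(4, 4, 4)), 1)
  expect_error(porosity(empty), "no mesophyll")
})

test_that("BSE and vein voxels are excluded from porosity unless requested", {
  lm <- leaf_labels()
  lab <- array(lm[["mesophyll_cell"]], c(10, 10, 10))
  lab[1:5, , ] <- lm[["ias"]]
  lab[, , 1:2] <- lm[["bse"]]
  v <- labeled_volume(lab, 1)
  expect_equal(porosity(v), 0.5)
  expect_lt(porosity(v, denominator_extra = c("bse", "vein")), 0.5)
})

test_that("airspace-to-cell ratio equals theta/(1-theta) to machine precision", {
  for (s in 1:5) {
    v <- solid_mes_volume(runif(1, 0.1, 0.9), seed = s)
    th <- porosity(v)
    expect_equal(vias_to_vcell(v), th / (1 - th), tolerance = 1e-14)
  }
  lm <- leaf_labels()
  expect_error(vias_to_vcell(labeled_volume(array(lm[["ias"]], c(4, 4, 4)), 1)),
               "no mesophyll-cell")
})

test_that("surface area estimator matches closed forms for sphere and plane", {
  lm <- leaf_labels()
  n <- 64
  r <- 25
  cc <- (n + 1) / 2
  lab <- array(lm[["ias"]], c(n, n, n))
  zz <- slice.index(lab, 1); yy <- slice.index(lab, 2); xx <- slice.index(lab, 3)
  lab[(zz - cc)^2 + (yy - cc)^2 + (xx - cc)^2 <= r^2] <- lm[["mesophyll_cell"]]
  v <- labeled_volume(lab, 1)
  area <- sa_mes_per_vmes(v) * n^3
  expect_lt(abs(area - 4 * pi * r^2) / (4 * pi * r^2), 0.05)

  lab2 <- array(lm[["ias"]], c(n, n, n))
  lab2[1:(n / 2), , ] <- lm[["mesophyll_cell"]]
  area2 <- sa_mes_per_vmes(labeled_volume(lab2, 1)) * n^3
  expect_lt(abs(area2 - n^2) / n^2, 0.02)
})

test_that("surface area per volume scales inversely with voxel size", {
  lm <- leaf_labels()
  n <- 32
  lab <- array(lm[["ias"]], c(n, n, n))
  lab[1:(n / 2), , ] <- lm[["mesophyll_cell"]]
  r1 <- sa_mes_per_vmes(labeled_volume(lab, 1))
  r2 <- sa_mes_per_vmes(labeled_volume(lab, 2))
  expect_equal(r1 / r2, 2, tolerance = 1e-12)
})

test_that("no-interface volumes return 0 area with a warning", {
  expect_warning(a <- sa_mes_per_vmes(solid_mes_volume(0)), "no mesophyll")
  expect_equal(a, 0)
})

test_that("thicknesses recover constructed layer extents", {
  gen <- generate_leaf_volume(leaf_phantom_params(
    shape = c(120L, 32L, 32L), voxel_um = 2,
    thickness_um = c(adaxial_epidermis = 20, palisade = 100, spongy = 80,
                     abaxial_epidermis = 16),
    stomatal_density_mm2 = 0, bse_spacing_um = 0, seed = 1))
  th <- thicknesses(gen$volume)
  expect_equal(unname(th["L_leaf"]), 216, tolerance = 0.01)
  expect_equal(unname(th["L_mes"]), 180, tolerance = 0.01)
  expect_equal(unname(th["L_epi_adaxial"]), 20, tolerance = 0.01)
  expect_equal(unname(th["L_epi_abaxial"]), 16, tolerance = 0.01)
})

test_that("thickness measurement is axis-aligned: a tilted slab reads thicker", {
  lm <- leaf_labels()
  nz <- 80; ny <- 16; nx <- 60
  theta <- 5 * pi / 180
  lab <- array(lm[["background"]], c(nz, ny, nx))
  for (x in 1:nx) {
    off <- round((x - 1) * tan(theta))
    z <- (10 + off):(59 + off)  # 50-voxel axis-aligned extent per column
    lab[z[1:5], , x] <- lm[["epidermis_adaxial"]]
    lab[z[6:45], , x] <- lm[["mesophyll_cell"]]
    lab[z[46:50], , x] <- lm[["epidermis_abaxial"]]
  }
  v <- labeled_volume(lab, 1)
  th <- thicknesses(v)
  # true (normal) thickness is 50*cos(5 deg); the axis-aligned reading is 50
  expect_equal(unname(th["L_leaf"]), 50 * cos(theta) / cos(theta),
               tolerance = 0.02)
})

test_that("porosity depth profile conserves scalar porosity and finds layering", {
  gen <- generate_leaf_volume(leaf_phantom_params(
    shape = c(100L, 48L, 48L), voxel_um = 1,
    thickness_um = c(adaxial_epidermis = 8, palisade = 40, spongy = 40,
                     abaxial_epidermis = 8),
    porosity_palisade = 0.1, porosity_spongy = 0.4,
    palisade_diameter_um = 12, stomatal_density_mm2 = 0,
    bse_spacing_um = 0, spongy_blob_um = 5, seed = 6))
  v <- gen$volume
  prof <- porosity_depth_profile(v, n_bins = 10)
  expect_equal(sum(prof$porosity * prof$n_vox) / sum(prof$n_vox),
               porosity(v), tolerance = 1e-12)
  # adaxial bins lean, abaxial bins porous, step near the layer boundary
  expect_lt(mean(prof$porosity[1:4]), 0.15)
  expect_gt(mean(prof$porosity[7:10]), 0.3)
  expect_error(porosity_depth_profile(v, n_bins = 3), "n_bins")
})

test_that("uniform random mesophyll gives a flat depth profile", {
  v <- solid_mes_volume(0.35, n = 40, seed = 8)
  prof <- porosity_depth_profile(v, n_bins = 8)
  expect_lt(max(abs(prof$porosity - 0.35)), 0.03)
})

test_that("BSE area fraction counts slabs and returns 0 without BSEs", {
  expect_equal(bse_area_fraction(solid_mes_volume(0.2)), 0)
  lm <- leaf_labels()
  lab <- array(lm[["mesophyll_cell"]], c(20, 20, 40))
  lab[, , 1:6] <- lm[["bse"]]  # 15% of 40 columns
  expect_equal(bse_area_fraction(labeled_volume(lab, 1)), 15, tolerance = 0.5)
  # doubling slab width roughly doubles a small fraction
  lab2 <- array(lm[["mesophyll_cell"]], c(20, 20, 40))
  lab2[, , 1:2] <- lm[["bse"]]
  lab3 <- array(lm[["mesophyll_cell"]], c(20, 20, 40))
  lab3[, , 1:4] <- lm[["bse"]]
  f2 <- bse_area_fraction(labeled_volume(lab2, 1))
  f3 <- bse_area_fraction(labeled_volume(lab3, 1))
  expect_equal(f3 / f2, 2, tolerance = 0.05)
})

test_that("paradermal diameter recovers disk diameters and erosion shifts", {
  lm <- leaf_labels()
  mk_disks <- function(r) {
    lab <- array(lm[["ias"]], c(30, 60, 60))
    lab[1:3, , ] <- lm[["epidermis_adaxial"]]
    lab[28:30, , ] <- lm[["epidermis_abaxial"]]
    centers <- expand.grid(cy = c(15, 45), cx = c(15, 45))
    for (i in seq_len(nrow(centers))) {
      yy <- outer((1:60 - centers$cy[i])^2, (1:60 - centers$cx[i])^2, "+") <= r^2
      for (z in 4:27) {
        m <- matrix(lab[z, , ], 60, 60)
        m[yy] <- lm[["mesophyll_cell"]]
        lab[z, , ] <- m
      }
    }
    labeled_volume(lab, 1)
  }
  d8 <- paradermal_palisade_diameter(mk_disks(8), 0.2)
  expect_equal(d8$diameter_um, 16, tolerance = 1.5)
  d6 <- paradermal_palisade_diameter(mk_disks(6), 0.2)
  expect_equal(d8$diameter_um - d6$diameter_um, 4, tolerance = 1.5)
  expect_equal(nrow(paradermal_palisade_diameter(mk_disks(8), numeric(0))), 0)
  expect_warning(paradermal_palisade_diameter(solid_mes_volume(1e-9), 0.5),
                 "no interior components|no mesophyll cells")
})

test_that("traits are invariant under in-plane transposition", {
  gen <- generate_leaf_volume(leaf_phantom_params(
    shape = c(60L, 40L, 48L), voxel_um = 2,
    thickness_um = c(adaxial_epidermis = 10, palisade = 44, spongy = 40,
                     abaxial_epidermis = 10),
    palisade_diameter_um = 16, stomatal_density_mm2 = 100,
    pore_length_um = 8, pore_width_um = 5, bse_spacing_um = 30,
    bse_width_um = 4, vein_diameter_um = 8, spongy_blob_um = 6, seed = 11))
  v <- gen$volume
  vt <- labeled_volume(aperm(v$labels, c(1, 3, 2)), v$voxel_um)
  expect_equal(porosity(vt), porosity(v), tolerance = 1e-14)
  expect_equal(vias_to_vcell(vt), vias_to_vcell(v), tolerance = 1e-14)
  expect_equal(thicknesses(vt), thicknesses(v), tolerance = 1e-12)
  expect_equal(sa_mes_per_vmes(vt), sa_mes_per_vmes(v), tolerance = 1e-9)
})
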