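test_that("geodesic equals straight-line distance in an unobstructed airspace", {
  slab <- make_slab_leaf(pores = cbind(y = 24, x = 24))
  # seed at the pore's inner mouth so every straight line stays in open air
  inner <- cbind(z = slab$abaxial_rows[1] - 1L, y = 24L, x = 24L)
  f <- distance_fields(slab$volume, inner)
  ias_inside <- tissue_mask(slab$volume, "ias")
  ias_inside[slab$abaxial_rows, , ] <- FALSE
  ok <- ias_inside & is.finite(f$L_geo) & f$L_Euc > 0
  expect_lt(max(f$L_geo[ok] / f$L_Euc[ok]) - 1, 0.02)
  # ordering invariants hold everywhere
  expect_true(all(f$L_geo[ok] >= f$L_Euc[ok] - 1e-9))
  expect_true(all(f$L_Euc >= f$L_epi - 1e-9))
})

test_that("a voxel adjacent to the stomate is one pitch away", {
  slab <- make_slab_leaf(pores = cbind(y = 24, x = 24))
  f <- distance_fields(slab$volume, slab$stomata)
  z <- slab$stomata[1, "z"]
  expect_equal(f$L_geo[z - 1, 24, 24], 1)
  expect_equal(f$L_Euc[z - 1, 24, 24], 1)
})

test_that("seed validation rejects missing or buried stomata", {
  slab <- make_slab_leaf()
  expect_error(distance_fields(slab$volume,
                               matrix(integer(0), 0, 3)), "no stomata")
  expect_error(distance_fields(slab$volume, cbind(z = 7, y = 2, x = 2)),
               "not inside the airspace")
})

test_that("production geodesic matches the independent graph oracle exactly", {
  skip_if_not_installed("igraph")
  # wall with a single gap: the path must bend around the opening
  lm <- leaf_labels()
  slab <- make_slab_leaf(nz = 50, ny = 30, nx = 30,
                         pores = cbind(y = 15, x = 15))
  lab <- slab$volume$labels
  lab[25, , ] <- lm[["mesophyll_cell"]]  # full baffle ...
  lab[25, 4, 4] <- lm[["ias"]]           # ... with one gap
  v <- labeled_volume(lab, 1)
  iasm <- tissue_mask(v, "ias")
  seeds <- leafgas:::lin_index(dim(lab), slab$stomata)
  oracle <- igraph_geodesic(iasm, seeds)
  f <- distance_fields(v, slab$stomata, nb_order = 1)
  both <- is.finite(oracle)
  expect_equal(mean(is.finite(f$L_geo)), mean(both))
  rel <- abs(f$L_geo[both] - oracle[both]) / pmax(oracle[both], 1)
  expect_lt(max(rel), 0.02)
  # the default higher-order metric can only shorten paths, never below L_Euc
  f4 <- distance_fields(v, slab$stomata, nb_order = 4)
  ok <- is.finite(f$L_geo)
  expect_true(all(f4$L_geo[ok] <= f$L_geo[ok] + 1e-9))
  expect_true(all(f4$L_geo[ok] >= f$L_Euc[ok] - 1e-9))
})

test_that("tortuosity is 1 in an open slab and grows when baffles are added", {
  slab <- make_slab_leaf(nz = 60, ny = 48, nx = 48,
                         pores = cbind(y = 24, x = 24))
  f <- distance_fields(slab$volume, slab$stomata)
  tau_open <- leaf_tortuosity(f, slab$volume)
  expect_lt(abs(tau_open - 1), 0.02)
  # obstacles never decrease tortuosity
  lm <- leaf_labels()
  lab <- slab$volume$labels
  lab[30, 1:40, ] <- lm[["mesophyll_cell"]]
  v2 <- labeled_volume(lab, 1)
  f2 <- distance_fields(v2, slab$stomata)
  expect_gt(leaf_tortuosity(f2, v2), tau_open)
})

test_that("tortuosity and path lengthening are >= 1 on random phantoms", {
  for (s in 1:6) {
    gen <- generate_leaf_volume(random_phantom(s, shape = c(48L, 40L, 40L)))
    st <- detect_stomata(gen$volume)
    if (nrow(st) == 0) next
    f <- distance_fields(gen$volume, st, nb_order = 2)
    expect_gte(leaf_tortuosity(f, gen$volume), 1)
    expect_gte(leaf_path_lengthening(f, gen$volume), 1)
  }
})

test_that("path lengthening is 1 under full stomatal coverage and grows as stomata thin", {
  ny <- 48; nx <- 48
  all_pores <- as.matrix(expand.grid(y = 1:ny, x = 1:nx))
  slab_full <- make_slab_leaf(ny = ny, nx = nx, pores = all_pores)
  f_full <- distance_fields(slab_full$volume, slab_full$stomata)
  expect_lt(abs(leaf_path_lengthening(f_full, slab_full$volume) - 1), 0.02)

  dense <- as.matrix(expand.grid(y = c(8, 24, 40), x = c(8, 24, 40)))
  sparse <- dense[c(1, 5, 9), ]
  single <- dense[5, , drop = FALSE]
  lams <- vapply(list(dense, sparse, single), function(p) {
    slab <- make_slab_leaf(ny = ny, nx = nx, pores = p)
    leaf_path_lengthening(distance_fields(slab$volume, slab$stomata),
                          slab$volume)
  }, numeric(1))
  expect_true(all(diff(lams) > 0))
  expect_gt(lams[3], 1.1)  # a single stomate forces long lateral paths
})

test_that("airspace conductance matches the hand-computed worked value", {
  # theta 0.3, Dm 1.54e-5 m2/s, Lmes 200 um, tau 1.5, lambda 1.2, 298.15 K,
  # 1 bar: velocity 0.02567 m/s x molar density 40.34 mol/m3 = 1.0354
  expect_equal(g_ias(0.3, 1.5, 1.2, 200e-6), 1.0354, tolerance = 1e-4)
  # obstacle-free limit equals the free-air slab conductance
  free <- 1.54e-5 / (0.5 * 200e-6) * 1e5 / (8.31446261815324 * 298.15)
  expect_equal(g_ias(1, 1, 1, 200e-6), free, tolerance = 1e-12)
  expect_error(g_ias(0, 1.5, 1.2, 200e-6), "positive")
})

test_that("conductance scaling laws hold to machine precision", {
  base <- g_ias(0.3, 1.5, 1.2, 200e-6)
  expect_equal(g_ias(0.6, 1.5, 1.2, 200e-6), 2 * base, tolerance = 1e-14)
  expect_equal(g_ias(0.3, 1.5, 1.2, 400e-6), base / 2, tolerance = 1e-14)
  expect_equal(g_ias(0.3, 3.0, 1.2, 200e-6), base / 2, tolerance = 1e-14)
  expect_equal(g_ias(0.3, 1.5, 2.4, 200e-6), base / 2, tolerance = 1e-14)
})

test_that("gas-phase share of mesophyll resistance is the conductance ratio", {
  expect_equal(gias_contribution(0.22, 1), 0.22)
  expect_equal(gias_contribution(1, 1), 1)
  expect_lt(gias_contribution(0.2, 1e9), 1e-9)
  expect_error(gias_contribution(1.2, 1), "series component")
})

test_that("stomata are auto-detected from abaxial perforations", {
  gen <- generate_leaf_volume(random_phantom(3, shape = c(48L, 40L, 40L)))
  st <- detect_stomata(gen$volume)
  expect_gt(nrow(st), 0)
  # all detected seeds sit in the abaxial half and are airspace voxels
  iasm <- tissue_mask(gen$volume, "ias")
  expect_true(all(iasm[leafgas:::lin_index(dim(gen$volume$labels), st)]))
  dt <- diffusion_traits(gen$volume, nb_order = 2)
  expect_gte(dt$tau_leaf, 1)
  expect_gte(dt$lambda_leaf, 1)
  expect_gt(dt$g_ias, 0)
})
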