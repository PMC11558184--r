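test_that("segmentation recovers the noiseless phantom exactly", {
  sol <- small_solid()
  seg <- small_clot()
  g0 <- render_grayscale(sol, seg, psf_um = 0, noise_sd = 0)
  m <- segment_volume(g0)
  expect_identical(m$grid, sol$grid | seg$clot$grid)
  # a fixed threshold in the fluid/clot valley gives the same mask
  mf <- segment_volume(g0, method = "fixed", threshold = 0.4)
  expect_identical(mf$grid, m$grid)
  # subtraction leaves exactly the simulated clot
  rec <- subtract_mask(m, sol)
  expect_identical(rec$grid, seg$clot$grid)

  flat <- voxel_volume(array(0.5, c(4, 4, 4)), 40)
  expect_error(segment_volume(flat), "flat")
})

test_that("segmentation stays accurate under default rendering noise", {
  sol <- small_solid()
  seg <- small_clot()
  g <- render_grayscale(sol, seg, seed = 42)
  m <- segment_volume(g)
  rec <- subtract_mask(m, sol)
  expect_gte(dice_coefficient(rec, seg$clot), 0.95)
})

test_that("mask subtraction is set difference", {
  clean <- tiny_mask()
  clean$grid[1:2, , ] <- TRUE
  expect_equal(sum(subtract_mask(clean, clean)$grid), 0)

  seg <- clean
  seg$grid[4, 3, 5] <- TRUE
  seg$grid[3, 1, 1] <- TRUE
  out <- subtract_mask(seg, clean)
  expect_equal(sum(out$grid), 2)
  expect_true(out$grid[4, 3, 5] && out$grid[3, 1, 1])
  expect_false(any(out$grid & clean$grid))

  expect_error(
    subtract_mask(seg, tiny_mask(dims = c(2, 2, 2))),
    "shape"
  )
})

test_that("default crop margins reproduce the stated interior extents", {
  vol <- voxel_volume(array(TRUE, c(146, 60, 400)), 50) # 7.3 x 3 x 20 mm
  cr <- crop_volume(vol)
  expect_equal(voxel_extent_mm(cr), c(4.7, 2.2, 19), tolerance = 0.05 / 4.7)
  expect_equal(cr$origin_mm, c(1.3, 0.4, 1.0))

  same <- crop_volume(vol, 0, 0, 0)
  expect_identical(same$grid, vol$grid)
  expect_identical(crop_volume(same, 0, 0, 0)$grid, same$grid)

  expect_error(crop_volume(vol, top_bottom_mm = 2), "exceed")
})

test_that("slice profiles tile, conserve volume, and normalize by void volume", {
  sol <- small_solid()
  seg <- small_clot()
  cropped <- crop_segmentation(seg)

  tiling <- slice_profile(cropped, mode = "tiling")
  expect_equal(sum(tiling$clot_volume_mm3), mask_volume_mm3(cropped$clot))

  five <- slice_profile(cropped)
  expect_equal(nrow(five), 5)
  expect_true(all(five$clot_volume_mm3 <= mask_volume_mm3(cropped$clot)))
  expect_true(all(five$normalized_fraction >= 0 & five$normalized_fraction <= 1))
  # centers at 5/25/50/75/95% of the cropped length, shifted by the 1 mm
  # inlet crop, with end segments clipped inward
  len <- voxel_extent_mm(cropped$clot)[3]
  expect_equal(five$segment_center_mm[3], len / 2 + 1)
  expect_equal(five$segment_center_mm[1], 1 + 1) # clipped to [0, 2]

  # uniform clot: every fluid voxel clotted; tiling segments match the
  # analytic void volume per segment
  full <- crop_volume(voxel_volume(!sol$grid, sol$voxel_um), inlet_mm = 0)
  prof <- slice_profile(full, mode = "tiling", spec = sol$spec)
  vox <- sol$voxel_um / 1000
  expected <- prof$segment_length_mm * 4.7 * 2.2 * 0.5
  expect_equal(prof$clot_volume_mm3, expected, tolerance = 0.03)
  expect_equal(prof$normalized_fraction, rep(1, nrow(prof)), tolerance = 0.04)

  empty <- crop_volume(voxel_volume(array(FALSE, dim(sol$grid)), sol$voxel_um))
  prof0 <- slice_profile(empty, mode = "tiling", spec = sol$spec)
  expect_true(all(prof0$clot_volume_mm3 == 0))

  expect_error(slice_profile(cropped, segment_mm = 50), "exceeds")
})

test_that("normalization divides by the available void volume", {
  spec <- chamber_spec(pd = 0.5)
  expect_equal(normalize_clot_volume(0, spec, 438), 0)
  expect_equal(normalize_clot_volume(21.9, spec, 438), 0.1)
  expect_equal(normalize_clot_volume(219, spec, 438), 1)
  expect_error(normalize_clot_volume(240, spec, 438), "exceeds")
  # linear in the clot volume
  expect_equal(
    normalize_clot_volume(30, spec, 438),
    3 * normalize_clot_volume(10, spec, 438)
  )
})

test_that("probability maps average replicate masks", {
  reps <- lapply(1:6, function(i) {
    m <- tiny_mask()
    if (i <= 3) m$grid[2, 2, 2] <- TRUE
    m$grid[1, 1, i %% 3 + 1] <- TRUE
    m
  })
  pm <- probability_map(reps, label = "demo")
  expect_equal(pm$grid[2, 2, 2], 0.5)
  expect_equal(pm$n_replicates, 6)
  expect_true(all(pm$grid >= 0 & pm$grid <= 1))
  input_fraction <- mean(vapply(reps, function(m) mean(m$grid), 0))
  expect_equal(mean(pm$grid), input_fraction)
  # order invariance
  pm2 <- probability_map(rev(reps))
  expect_identical(pm$grid, pm2$grid)
  # single replicate: the map is that mask
  expect_equal(probability_map(reps[1])$grid, reps[[1]]$grid + 0)

  bad <- tiny_mask(dims = c(5, 3, 5))
  expect_error(probability_map(list(reps[[1]], bad)), "grids differ")
})

test_that("axis projections average and commute with the volume mean", {
  m <- tiny_mask()
  m$grid[2, , 3] <- TRUE # a full rod-axis column
  proj <- project_axis(probability_map(list(m)))
  expect_equal(nrow(proj), 4 * 5)
  col_val <- proj$value[abs(proj$x_mm - 0.15) < 1e-9 & abs(proj$z_mm - 0.25) < 1e-9]
  expect_equal(col_val, 1)
  expect_equal(mean(proj$value), mean(m$grid))

  # single voxel projects to 1/n_slices along the projection axis
  s <- tiny_mask()
  s$grid[1, 2, 4] <- TRUE
  pj <- project_axis(probability_map(list(s)))
  expect_equal(max(pj$value), 1 / dim(s$grid)[2])

  # flow-axis projection of a uniform map is uniform
  u <- voxel_volume(array(0.3, c(3, 3, 3)), 50)
  pf <- project_axis(u, axis = "flow_axis")
  expect_true(all(abs(pf$value - 0.3) < 1e-12))
})

test_that("equivalent-distance slabs measure from the true inlet and tile", {
  sol <- small_solid()
  seg <- crop_segmentation(small_clot())

  # distances are pre-crop: a slab fully inside the cropped region works,
  # one upstream of the crop errors
  one <- clot_at_equivalent_distance(seg, 3, slab_mm = 1)
  expect_equal(one$clot_volume_mm3, sum(one$clot_volume_mm3))
  expect_error(clot_at_equivalent_distance(seg, 0.2), "outside")
  expect_error(clot_at_equivalent_distance(seg, 5.8), "outside")

  # uniform clot: 1 mm slab on the cropped section holds
  # 1 x 4.7 x 2.2 x (1 - PD) mm^3
  full <- crop_volume(voxel_volume(!sol$grid, sol$voxel_um))
  slab <- clot_at_equivalent_distance(full, 3, slab_mm = 1)
  expect_equal(slab$clot_volume_mm3, 1 * 4.7 * 2.2 * 0.5, tolerance = 0.03)

  # contiguous slabs partition the tiling profile
  slabs <- clot_at_equivalent_distance(seg, c(1, 2, 3, 4, 5), slab_mm = 1)
  expect_equal(
    sum(slabs$clot_volume_mm3),
    mask_volume_mm3(seg$clot)
  )

  empty <- crop_volume(voxel_volume(array(FALSE, dim(sol$grid)), sol$voxel_um))
  expect_equal(clot_at_equivalent_distance(empty, 3)$clot_volume_mm3, 0)
})

test_that("dice coefficient behaves", {
  a <- tiny_mask()
  a$grid[1:2, , ] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- tiny_mask()
  b$grid[2:3, , ] <- TRUE
  expect_equal(dice_coefficient(a, b), 0.5)
})
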