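test_that("voxelized chambers hit the requested packing density", {
  sol <- small_solid(voxel_um = 40)
  expect_type(sol$grid, "logical")
  expect_equal(realized_packing_density(sol), 0.5, tolerance = 0.01)
  # sparser lattice, same check
  sol4 <- small_solid(pd = 0.4, voxel_um = 40)
  expect_equal(realized_packing_density(sol4), 0.4, tolerance = 0.01)
  # physical extent matches the spec within one voxel per axis
  expect_equal(voxel_extent_mm(sol), c(7.3, 3, 6), tolerance = 0.04 / 6)
  expect_error(voxelize_chamber(small_spec(), voxel_um = 100), "coarse")
})

test_that("accretion is conservative, disjoint from solid, and monotone in steps", {
  sol <- small_solid()
  cond <- flow_condition(u_cm_min = 20, spec = sol$spec)
  empty <- simulate_clot(sol, cond, clot_sim_params(base_rate = 0, seed = 1))
  expect_equal(sum(empty$clot$grid), 0)

  seg <- small_clot()
  expect_false(any(seg$clot$grid & sol$grid))
  expect_gt(sum(seg$clot$grid), 0)

  # same seed, fewer steps: a prefix of the same growth history
  p3 <- simulate_clot(sol, cond, clot_sim_params(seed = 101, steps = 3))
  p5 <- simulate_clot(sol, cond, clot_sim_params(seed = 101, steps = 5))
  expect_true(all(p5$clot$grid[p3$clot$grid]))
  expect_gte(sum(p5$clot$grid), sum(p3$clot$grid))
})

test_that("fixed seeds give bit-identical volumes", {
  sol <- small_solid()
  cond <- flow_condition(u_cm_min = 20, spec = sol$spec)
  a <- simulate_clot(sol, cond, clot_sim_params(seed = 7))
  b <- simulate_clot(sol, cond, clot_sim_params(seed = 7))
  expect_identical(a$clot$grid, b$clot$grid)
  c <- simulate_clot(sol, cond, clot_sim_params(seed = 8))
  expect_false(identical(a$clot$grid, c$clot$grid))
})

test_that("clot accumulates preferentially toward the outlet", {
  sol <- small_solid(voxel_um = 60)
  cond <- flow_condition(u_cm_min = 20, spec = sol$spec)
  nz <- dim(sol$grid)[3]
  quarter <- function(seg, q) {
    iz <- split(seq_len(nz), cut(seq_len(nz), 4, labels = FALSE))[[q]]
    sum(seg$clot$grid[, , iz])
  }
  q2 <- q4 <- numeric(10)
  for (s in 1:10) {
    seg <- simulate_clot(sol, cond, clot_sim_params(seed = s))
    q2[s] <- quarter(seg, 2) # proximal quarter excluded: inlet capture
    q4[s] <- quarter(seg, 4)
  }
  expect_gt(mean(q4), mean(q2))
})

test_that("packing-density and velocity effect signs are recovered", {
  sols <- list(
    small_solid(pd = 0.4, voxel_um = 60),
    small_solid(pd = 0.6, voxel_um = 60)
  )
  v40 <- v60 <- v16 <- v25 <- numeric(10)
  for (s in 1:10) {
    v40[s] <- mask_volume_mm3(simulate_clot(
      sols[[1]], flow_condition(u_cm_min = 20, spec = sols[[1]]$spec),
      clot_sim_params(seed = s)
    )$clot)
    v60[s] <- mask_volume_mm3(simulate_clot(
      sols[[2]], flow_condition(u_cm_min = 20, spec = sols[[2]]$spec),
      clot_sim_params(seed = s)
    )$clot)
  }
  sol5 <- small_solid(voxel_um = 60)
  for (s in 1:10) {
    v16[s] <- mask_volume_mm3(simulate_clot(
      sol5, flow_condition(u_cm_min = 16, spec = sol5$spec),
      clot_sim_params(seed = s)
    )$clot)
    v25[s] <- mask_volume_mm3(simulate_clot(
      sol5, flow_condition(u_cm_min = 25, spec = sol5$spec),
      clot_sim_params(seed = s)
    )$clot)
  }
  expect_gt(mean(v60), mean(v40))
  expect_gt(mean(v16), mean(v25))
})

test_that("grayscale rendering is exact without noise and bounded with it", {
  sol <- small_solid()
  seg <- small_clot()
  g0 <- render_grayscale(sol, seg, psf_um = 0, noise_sd = 0)
  vals <- sort(unique(as.vector(g0$grid)))
  expect_equal(vals, c(0.2, 0.6, 1.0))
  expect_true(all(g0$grid[seg$clot$grid] == 0.6))
  expect_true(all(g0$grid[sol$grid] == 1.0))

  g <- render_grayscale(sol, seg, seed = 5)
  expect_true(all(g$grid >= 0 & g$grid <= 1))
  g2 <- render_grayscale(sol, seg, seed = 5)
  expect_identical(g$grid, g2$grid)
})

test_that("resistance series follow the porosity-squared occlusion law", {
  spec <- chamber_spec()
  cond <- flow_condition(u_cm_min = 20, spec = spec)
  flat <- simulate_resistance_series(spec, cond, clot_fraction = rep(0, 6))
  expect_equal(flat$resistance, rep(0.365, 6)) # clot-free baseline fixture
  expect_equal(flat$dp_mmhg, rep(0.365 * 4.38, 6))

  # quarter occlusion of a 50% chamber doubles the porosity ratio: R = 4 R0
  s <- simulate_resistance_series(spec, cond,
    clot_fraction = c(0, 0.1, 0.25),
    times_min = c(0, 3, 6)
  )
  expect_equal(s$resistance[3], 4 * 0.365)
  expect_true(all(diff(s$resistance) >= 0))
  expect_equal(s$ln_resistance, log(s$resistance))

  expect_error(
    simulate_resistance_series(spec, cond,
      clot_fraction = c(0, 0.5, 0.2), times_min = c(0, 3, 6)
    ),
    "nondecreasing"
  )
  expect_error(
    simulate_resistance_series(spec, cond,
      clot_fraction = c(0, 0.3, 0.55), times_min = c(0, 3, 6)
    ),
    "occlusion"
  )
})

test_that("cohorts cross donors with conditions, deterministically", {
  conds <- data.frame(pd = c(0.4, 0.6), u_cm_min = 20, path_length_mm = 6)
  des <- cohort_design(conds, donors = 2, seed = 11)
  coh <- generate_cohort(des, clot_sim_params(steps = 5), voxel_um = 60)
  expect_equal(nrow(coh), 4) # full cross
  expect_setequal(coh$donor, c(1, 1, 2, 2))
  expect_true(all(coh$aptt_s >= 20 & coh$aptt_s <= 50))
  expect_true(all(coh$clot_volume_mm3 > 0))

  coh2 <- generate_cohort(des, clot_sim_params(steps = 5), voxel_um = 60)
  expect_identical(coh$clot_volume_mm3, coh2$clot_volume_mm3)
  expect_identical(coh$seed, coh2$seed)

  # no donor effect: multipliers collapse to 1
  des0 <- cohort_design(conds, donors = 2, donor_effect_sd = 0, seed = 11)
  coh0 <- generate_cohort(des0, clot_sim_params(steps = 5), voxel_um = 60)
  expect_true(all(coh0$donor_multiplier == 1))
})
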