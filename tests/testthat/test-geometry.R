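test_that("square-lattice spacing matches the circle-area oracle", {
  # frozen from a brute-force oracle: areal coverage of one circle of
  # diameter 380 um in an s x s cell, counted on a 2000^2 grid
  expect_equal(attr(build_rod_array(small_spec(pd = 0.5)), "spacing_mm"),
    0.4762594,
    tolerance = 1e-6
  )
  expect_equal(attr(build_rod_array(small_spec(pd = 0.4)), "spacing_mm"),
    0.5324742,
    tolerance = 1e-6
  )
  # independent area count at test time (coarser grid, looser tolerance)
  s <- attr(build_rod_array(small_spec(pd = 0.5)), "spacing_mm")
  g <- (seq_len(400) - 0.5) * s / 400
  cover <- mean(outer((g - s / 2)^2, (g - s / 2)^2, `+`) <= 0.19^2)
  expect_equal(cover, 0.5, tolerance = 0.005)
  # packing at the bound: rods touch, spacing equals the diameter
  near_bound <- chamber_spec(pd = pi / 4 - 1e-9, path_length_mm = 4)
  expect_equal(attr(build_rod_array(near_bound), "spacing_mm"), 0.380,
    tolerance = 1e-4
  )
  expect_error(chamber_spec(pd = 0.79), "infeasible")
})

test_that("rods never overlap, on either lattice", {
  for (lat in c("square", "hexagonal")) {
    rods <- build_rod_array(chamber_spec(
      pd = 0.6, path_length_mm = 5,
      lattice = lat
    ))
    d <- as.matrix(stats::dist(cbind(rods$x_mm, rods$z_mm)))
    diag(d) <- Inf
    expect_gte(min(d), 2 * attr(rods, "radius_mm") - 1e-12)
  }
})

test_that("velocity-to-flow conversion uses the superficial convention", {
  spec <- chamber_spec()
  expect_identical(flow_rate_for_velocity(20, spec), 4.38)
  expect_identical(flow_rate_for_velocity(0, spec), 0)
  expect_equal(flow_rate_for_velocity(25, spec), 5.475)
  expect_equal(flow_rate_for_velocity(16, spec), 3.504)
  # consistency check built into flow_condition
  expect_error(
    flow_condition(u_cm_min = 20, q_ml_min = 5, spec = spec),
    "disagree"
  )
  fc <- flow_condition(q_ml_min = 4.38, spec = spec)
  expect_equal(fc$u_cm_min, 20)
})

test_that("interstitial velocity scales by the void fraction", {
  expect_equal(interstitial_velocity(20, 0), 20)
  expect_equal(interstitial_velocity(20, 0.5), 40)
  expect_equal(interstitial_velocity(16, 0.6), 40)
  expect_error(interstitial_velocity(20, 1), "pd")
})

test_that("hydraulic diameter matches d_f (1-PD)/PD and a numeric rod-array estimate", {
  expect_equal(hydraulic_diameter(small_spec(pd = 0.5)), 0.380)
  expect_equal(hydraulic_diameter(small_spec(pd = 0.4)), 0.570)
  expect_equal(hydraulic_diameter(small_spec(pd = 0.6)), 0.2533333,
    tolerance = 1e-6
  )
  # numeric: 4 * void area / wetted perimeter over whole lattice cells
  for (pd in c(0.4, 0.5, 0.6)) {
    spec <- small_spec(pd = pd)
    rods <- build_rod_array(spec)
    s <- attr(rods, "spacing_mm")
    r <- attr(rods, "radius_mm")
    in_window <- rods$x_mm > s & rods$x_mm < s * (1 + floor(spec$width_mm / s) - 2) &
      rods$z_mm > s & rods$z_mm < s * (1 + floor(spec$path_length_mm / s) - 2)
    n <- sum(in_window)
    area <- (floor(spec$width_mm / s) - 2) * (floor(spec$path_length_mm / s) - 2) * s^2
    dh_num <- 4 * (area - n * pi * r^2) / (n * 2 * pi * r)
    expect_equal(dh_num, hydraulic_diameter(spec), tolerance = 0.02)
  }
})

test_that("Reynolds number evaluates the SI formula", {
  expect_equal(reynolds(1.09, 0, 0.38, 3.4), 0)
  # frozen SI substitution: 1090 kg/m^3 * (0.4/60 m/s) * 3.8e-4 m / 3.4e-3 Pa s
  expect_equal(reynolds(1.09, 40, 0.380, 3.4), 0.8121569, tolerance = 1e-6)
  expect_equal(
    reynolds(1.09, 80, 0.380, 3.4),
    2 * reynolds(1.09, 40, 0.380, 3.4)
  )
})

test_that("cumulative surface area matches the closed form and per-rod summation", {
  spec <- chamber_spec()
  expect_equal(cumulative_surface_area(spec, 0), 0)
  expect_equal(cumulative_surface_area(spec, 5.7), 657)
  expect_equal(
    cumulative_surface_area(spec, 8),
    2 * cumulative_surface_area(spec, 4)
  )
  expect_error(cumulative_surface_area(spec, 25), "path length")
  # per-rod oracle: rods with centres in [0, z0] contribute pi * d * H
  # each; the chamber is sized to whole lattice cells so no rod is
  # wall-clipped and the closed form applies without edge corrections
  s_lat <- 0.38 * sqrt(pi / 2)
  spec_c <- chamber_spec(
    pd = 0.5, width_mm = 15 * s_lat, path_length_mm = 21 * s_lat
  )
  rods <- build_rod_array(spec_c)
  z0 <- 12 * s_lat
  n <- sum(rods$z_mm <= z0)
  s_rod <- n * pi * (spec_c$fiber_um / 1000) * spec_c$height_mm
  expect_equal(s_rod, cumulative_surface_area(spec_c, z0), tolerance = 0.01)
})

test_that("equivalent distances: published table and analytic criterion", {
  tab <- equivalent_distance(data.frame(
    u_cm_min = c(16, 20, 25, 20, 20),
    pd = c(0.5, 0.5, 0.5, 0.4, 0.6)
  ))
  expect_equal(tab$distance_mm, c(6.8, 5.7, 4.5, 10.0, 3.2))
  expect_error(
    equivalent_distance(data.frame(u_cm_min = 30, pd = 0.5)),
    "no published"
  )
  # analytic criterion: the reference maps to itself, and distance
  # scales inversely with packing density at fixed velocity
  ana <- equivalent_distance(
    data.frame(u_cm_min = c(20, 20, 20), pd = c(0.5, 0.4, 0.6)),
    criterion = "equal_cumulative_surface"
  )
  expect_equal(ana$distance_mm[1], 5.7)
  expect_equal(ana$distance_mm[2], 5.7 * 0.5 / 0.4)
  expect_equal(ana$distance_mm[3], 5.7 * 0.5 / 0.6)
})

test_that("chamber descriptions round-trip losslessly", {
  spec <- chamber_spec(pd = 0.45, path_length_mm = 37.5, lattice = "hexagonal")
  path <- withr::local_tempfile(fileext = ".json")
  write_chamber_spec(spec, path)
  expect_identical(read_chamber_spec(path), spec)
})
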