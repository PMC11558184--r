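# Shared fixtures, built in code and memoised so expensive phantoms are
# voxelized once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A short chamber that keeps unit tests quick; geometry (width, height,
# rod size, packing) matches the standard design.
small_spec <- function(pd = 0.5, path_length_mm = 6) {
  chamber_spec(pd = pd, path_length_mm = path_length_mm)
}

small_solid <- function(pd = 0.5, path_length_mm = 6, voxel_um = 40) {
  cached(
    sprintf("solid_%g_%g_%g", pd, path_length_mm, voxel_um),
    voxelize_chamber(small_spec(pd, path_length_mm), voxel_um = voxel_um)
  )
}

small_clot <- function(pd = 0.5, path_length_mm = 6, voxel_um = 40,
                       seed = 101, u = 20, steps = 15) {
  cached(
    sprintf("clot_%g_%g_%g_%d_%g_%d", pd, path_length_mm, voxel_um, seed, u, steps),
    {
      sol <- small_solid(pd, path_length_mm, voxel_um)
      cond <- flow_condition(u_cm_min = u, spec = sol$spec)
      simulate_clot(sol, cond, clot_sim_params(seed = seed, steps = steps))
    }
  )
}

# Tiny hand-built binary volume for set-algebra tests.
tiny_mask <- function(fill = FALSE, dims = c(4, 3, 5), voxel_um = 100) {
  voxel_volume(array(fill, dims), voxel_um)
}
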