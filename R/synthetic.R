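#' Accretion simulator parameters
#'
#' Phenomenological parameters of the stochastic surface-accretion clot
#' model. At each step, every fluid voxel touching solid or clot (face
#' adjacency) converts to clot with probability `1 - exp(-lambda)`, where
#'
#' `lambda = base_rate * exp(outlet_bias * z / L) *
#'           (1 + inlet_capture * [z < inlet_window_mm]) *
#'           exp(-gap / gap_scale_mm) * (u_ref / u_i)^velocity_exponent`
#'
#' with `gap` the distance from the voxel's plan position to the surface
#' of the second-nearest rod (fibrin bridges form most readily in narrow
#' inter-fiber gaps), `u_i` the interstitial velocity and
#' `u_ref = 40` cm/min (the interstitial velocity of the 20 cm/min, 50%
#' packing baseline condition).
#'
#' @param base_rate Per-step deposition intensity (dimensionless, >= 0).
#' @param outlet_bias Exponent of the downstream bias; positive values
#'   concentrate clot near the outlet.
#' @param inlet_capture Extra deposition weight over the first
#'   `inlet_window_mm` of the chamber, emulating embolus capture at the
#'   inlet face.
#' @param inlet_window_mm Length of the inlet-capture window, mm.
#' @param gap_scale_mm Bridging length scale, mm; smaller values confine
#'   deposition to tight inter-rod gaps.
#' @param velocity_exponent Exponent of the inverse-velocity dependence.
#' @param steps Number of accretion steps (one per experimental minute at
#'   the default 15).
#' @param seed Optional RNG seed for the run.
#' @return A `clot_sim_params` list.
#' @export
clot_sim_params <- function(base_rate = 0.006, outlet_bias = 2,
                            inlet_capture = 0.5, inlet_window_mm = 1,
                            gap_scale_mm = 0.15, velocity_exponent = 1,
                            steps = 15, seed = NULL) {
  stopifnot(
    base_rate >= 0, inlet_capture >= 0, inlet_window_mm >= 0,
    gap_scale_mm > 0, steps >= 1
  )
  structure(
    list(
      base_rate = base_rate, outlet_bias = outlet_bias,
      inlet_capture = inlet_capture, inlet_window_mm = inlet_window_mm,
      gap_scale_mm = gap_scale_mm, velocity_exponent = velocity_exponent,
      steps = as.integer(steps), seed = seed
    ),
    class = "clot_sim_params"
  )
}

#' Voxelize a chamber into a solid mask
#'
#' Rasterises the rod array (full chamber height) plus the chamber walls
#' onto an isotropic voxel grid. A voxel is solid if its centre falls
#' inside a rod cross-section; rods crossing the chamber boundary are
#' clipped by the grid. Walls occupy `wall_voxels` layers on the x and y
#' faces (none on the inlet/outlet faces).
#'
#' @param spec A [chamber_spec()].
#' @param voxel_um Voxel edge, micrometres; must be at most a quarter of
#'   the fiber diameter.
#' @param wall_voxels Wall thickness in voxels on the x/y faces.
#' @return A binary [voxel_volume()] with the spec attached as `$spec`.
#' @examples
#' voxelize_chamber(chamber_spec(path_length_mm = 2), voxel_um = 50)
#' @export
voxelize_chamber <- function(spec, voxel_um = 20, wall_voxels = 1) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (voxel_um > spec$fiber_um / 4) {
    stop(sprintf(
      "voxel size %g um too coarse: must be <= fiber diameter / 4 = %g um",
      voxel_um, spec$fiber_um / 4
    ), call. = FALSE)
  }
  vox <- voxel_um / 1000 # mm
  nx <- round(spec$width_mm / vox)
  ny <- round(spec$height_mm / vox)
  nz <- round(spec$path_length_mm / vox)
  rods <- build_rod_array(spec)
  r <- attr(rods, "radius_mm")

  xc <- (seq_len(nx) - 0.5) * vox
  zc <- (seq_len(nz) - 0.5) * vox
  plan <- matrix(FALSE, nx, nz)
  for (k in seq_len(nrow(rods))) {
    cx <- rods$x_mm[k]
    cz <- rods$z_mm[k]
    ix <- which(abs(xc - cx) <= r)
    iz <- which(abs(zc - cz) <= r)
    if (!length(ix) || !length(iz)) next
    plan[ix, iz] <- plan[ix, iz] |
      (outer((xc[ix] - cx)^2, (zc[iz] - cz)^2, `+`) <= r^2)
  }

  # replicate the plan across the rod axis y
  grid <- aperm(array(plan, dim = c(nx, nz, ny)), c(1, 3, 2))
  if (wall_voxels > 0) {
    w <- seq_len(wall_voxels)
    grid[c(w, nx + 1 - w), , ] <- TRUE
    grid[, c(w, ny + 1 - w), ] <- TRUE
  }
  vol <- voxel_volume(grid, voxel_um)
  vol$spec <- spec
  vol$wall_voxels <- wall_voxels
  vol
}

#' Realized packing density of a voxelized chamber
#'
#' Measures the solid areal fraction over an interior window spanning a
#' whole number of lattice periods (so partial boundary cells and walls do
#' not bias the estimate). Converges to the spec packing density as the
#' voxel size shrinks.
#'
#' @param solid A chamber mask from [voxelize_chamber()].
#' @return The realized packing-density fraction.
#' @export
realized_packing_density <- function(solid) {
  stopifnot(inherits(solid, "voxel_volume"), !is.null(solid$spec))
  spec <- solid$spec
  s <- attr(build_rod_array(spec), "spacing_mm")
  vox <- solid$voxel_um / 1000
  d <- dim(solid$grid)
  # whole lattice cells fully inside the chamber, one cell in from each side
  kx <- floor(spec$width_mm / s) - 2
  kz <- floor(spec$path_length_mm / s) - 2
  if (kx < 1 || kz < 1) stop("chamber too small to measure interior packing")
  ix <- which((seq_len(d[1]) - 0.5) * vox >= s &
    (seq_len(d[1]) - 0.5) * vox < s * (1 + kx))
  iz <- which((seq_len(d[3]) - 0.5) * vox >= s &
    (seq_len(d[3]) - 0.5) * vox < s * (1 + kz))
  iy <- ceiling(d[2] / 2) # rods are y-invariant; one interior slice suffices
  mean(solid$grid[ix, iy, iz])
}

# Plan-view map of the distance (mm) from each voxel centre to the surface
# of the second-nearest rod: the "gap" that controls fibrin bridging.
gap_map <- function(spec, nx, nz, voxel_um) {
  vox <- voxel_um / 1000
  rods <- build_rod_array(spec)
  r <- attr(rods, "radius_mm")
  s <- attr(rods, "spacing_mm")
  xc <- (seq_len(nx) - 0.5) * vox
  zc <- (seq_len(nz) - 0.5) * vox
  d1 <- matrix(Inf, nx, nz)
  d2 <- matrix(Inf, nx, nz)
  w <- 2.5 * s # beyond this another rod is always nearer than the window rod
  for (k in seq_len(nrow(rods))) {
    cx <- rods$x_mm[k]
    cz <- rods$z_mm[k]
    ix <- which(abs(xc - cx) <= w)
    iz <- which(abs(zc - cz) <= w)
    if (!length(ix) || !length(iz)) next
    dd <- sqrt(outer((xc[ix] - cx)^2, (zc[iz] - cz)^2, `+`))
    old1 <- d1[ix, iz]
    d1[ix, iz] <- pmin(old1, dd)
    d2[ix, iz] <- pmin(d2[ix, iz], pmax(old1, dd))
  }
  pmax(d2 - r, 0)
}

#' Simulate clot accretion in a chamber
#'
#' Iterative stochastic surface accretion: clot nucleates on rod and wall
#' surfaces and grows by converting adjacent fluid voxels, with a
#' deposition intensity that rises toward the outlet, is boosted in a
#' short inlet-capture window, concentrates in narrow inter-rod gaps, and
#' decreases with interstitial velocity (see [clot_sim_params()]). The
#' resulting clot is face-connected to the initial solid by construction
#' and disjoint from it.
#'
#' @param solid Chamber mask from [voxelize_chamber()].
#' @param condition A [flow_condition()].
#' @param params A [clot_sim_params()].
#' @param donor_id,replicate Provenance labels stored on the result.
#' @return A [clot_segmentation()].
#' @examples
#' sol <- voxelize_chamber(chamber_spec(path_length_mm = 2), voxel_um = 60)
#' cond <- flow_condition(u_cm_min = 20)
#' simulate_clot(sol, cond, clot_sim_params(steps = 3, seed = 1))
#' @export
simulate_clot <- function(solid, condition, params = clot_sim_params(),
                          donor_id = NA, replicate = NA) {
  stopifnot(
    inherits(solid, "voxel_volume"), !is.null(solid$spec),
    inherits(condition, "flow_condition"),
    inherits(params, "clot_sim_params")
  )
  spec <- solid$spec
  d <- dim(solid$grid)
  if (!is.null(params$seed)) set.seed(params$seed)

  if (params$base_rate == 0) {
    clot <- voxel_volume(array(FALSE, d), solid$voxel_um, solid$origin_mm)
    return(clot_segmentation(clot, spec, condition,
      donor_id = donor_id,
      replicate = replicate, seed = params$seed, solid = solid
    ))
  }

  vox <- solid$voxel_um / 1000
  zc <- (seq_len(d[3]) - 0.5) * vox
  u_i <- interstitial_velocity(condition$u_cm_min, spec$pd)
  u_ref <- 40 # cm/min: interstitial velocity of the 20 cm/min, 50% baseline
  gap <- gap_map(spec, d[1], d[3], solid$voxel_um)
  lam <- params$base_rate *
    exp(-gap / params$gap_scale_mm) *
    (u_ref / u_i)^params$velocity_exponent
  zfac <- exp(params$outlet_bias * zc / spec$path_length_mm) *
    (1 + params$inlet_capture * (zc < params$inlet_window_mm))
  lam <- sweep(lam, 2, zfac, `*`)
  prob <- 1 - exp(-lam)

  clot_grid <- accrete_cpp(
    as.vector(solid$grid), prob,
    d[1], d[2], d[3], params$steps
  )
  clot <- voxel_volume(array(clot_grid, d), solid$voxel_um, solid$origin_mm)
  clot_segmentation(clot, spec, condition,
    donor_id = donor_id,
    replicate = replicate, seed = params$seed, solid = solid
  )
}

# Separable Gaussian blur along one array axis using a banded sparse
# kernel matrix (rows renormalized at the edges).
blur_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  n <- d[axis]
  k <- max(1L, ceiling(3 * sigma_vox))
  offs <- -k:k
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  idx <- do.call(rbind, lapply(seq_along(offs), function(j) {
    i <- seq_len(n)
    ii <- i + offs[j]
    keep <- ii >= 1 & ii <= n
    cbind(i[keep], ii[keep], w[j])
  }))
  K <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = idx[, 3], dims = c(n, n))
  K <- K / Matrix::rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- as.matrix(K %*% m)
  aperm(array(out, d[perm]), order(perm))
}

#' Render a synthetic grayscale scan
#'
#' Produces a reconstructed-volume stand-in from known solid and clot
#' masks: fluid 0.2, clot 0.6, solid 1.0, convolved with an isotropic
#' Gaussian point-spread function, then corrupted by additive Gaussian
#' noise and clipped to `[0, 1]`.
#'
#' @param solid Chamber mask ([voxelize_chamber()]).
#' @param clot Binary clot volume on the same grid (a [voxel_volume()] or
#'   [clot_segmentation()]).
#' @param psf_um Gaussian PSF standard deviation, micrometres. The
#'   default 5 um matches the instrument being emulated (3 um native
#'   voxels, blur of about two native voxels), and is therefore
#'   sub-voxel at the package's coarser emulation voxel sizes; raise it
#'   only when emulating fine grids.
#' @param noise_sd Additive noise standard deviation (intensity fraction).
#' @param seed Optional RNG seed for the noise.
#' @return A grayscale [voxel_volume()].
#' @export
render_grayscale <- function(solid, clot, psf_um = 5, noise_sd = 0.05,
                             seed = NULL) {
  if (inherits(clot, "clot_segmentation")) clot <- clot$clot
  stopifnot(inherits(solid, "voxel_volume"), inherits(clot, "voxel_volume"))
  if (!identical(dim(solid$grid), dim(clot$grid))) {
    stop("solid and clot grids differ in shape", call. = FALSE)
  }
  if (any(solid$grid & clot$grid)) {
    stop("solid and clot masks must be disjoint", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  img <- array(0.2, dim(solid$grid))
  img[clot$grid] <- 0.6
  img[solid$grid] <- 1
  sigma_vox <- psf_um / solid$voxel_um
  if (sigma_vox > 0) {
    for (ax in 1:3) img <- blur_axis(img, sigma_vox, ax)
  }
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  img <- pmin(pmax(img, 0), 1)
  voxel_volume(array(img, dim(solid$grid)), solid$voxel_um, solid$origin_mm)
}

#' Simulate a resistance time series under progressive occlusion
#'
#' Maps a clot occlusion trajectory to hydraulic resistance with a
#' Kozeny-Carman-style porosity law: with void fraction `1 - PD` and clot
#' occupying a further volume fraction `phi(t)` of the chamber,
#' `R(t) = R0 * ((1 - PD) / (1 - PD - phi(t)))^exponent` (default
#' exponent 2). Pressure drop follows as `dP = R * Q`.
#'
#' @param spec A [chamber_spec()].
#' @param condition A [flow_condition()].
#' @param clot_fraction Occlusion fractions `phi(t)`, one per time point;
#'   must be nondecreasing with `PD + phi < 1`.
#' @param r0 Clot-free baseline resistance, mmHg.min/mL; defaults to the
#'   shipped glycerol-water baseline for the spec's packing density and
#'   path length ([baseline_resistance()]), interpolated for geometries
#'   outside the studied set.
#' @param times_min Measurement times, minutes.
#' @param exponent Porosity-law exponent.
#' @return A `resistance_series` tibble with columns `time_min`,
#'   `clot_fraction`, `q_ml_min`, `dp_mmhg`, `resistance`,
#'   `ln_resistance`, and attribute `baseline_r0`.
#' @examples
#' simulate_resistance_series(
#'   chamber_spec(), flow_condition(u_cm_min = 20),
#'   clot_fraction = seq(0, 0.2, length.out = 6)
#' )
#' @export
simulate_resistance_series <- function(spec, condition, clot_fraction,
                                       r0 = NULL,
                                       times_min = seq(0, 15, by = 3),
                                       exponent = 2) {
  stopifnot(
    inherits(spec, "chamber_spec"), inherits(condition, "flow_condition"),
    length(clot_fraction) == length(times_min)
  )
  if (any(diff(clot_fraction) < 0)) {
    stop("`clot_fraction` must be nondecreasing", call. = FALSE)
  }
  if (any(spec$pd + clot_fraction >= 1)) {
    stop("occlusion: PD + clot fraction must stay below 1", call. = FALSE)
  }
  if (is.null(r0)) r0 <- default_baseline_r0(spec$pd, spec$path_length_mm)
  porosity <- 1 - spec$pd
  res <- r0 * (porosity / (porosity - clot_fraction))^exponent
  out <- tibble::tibble(
    time_min = times_min,
    clot_fraction = clot_fraction,
    q_ml_min = condition$q_ml_min,
    dp_mmhg = res * condition$q_ml_min,
    resistance = res,
    ln_resistance = log(res)
  )
  attr(out, "baseline_r0") <- r0
  class(out) <- c("resistance_series", class(out))
  out
}

#' Describe a donor-paired synthetic cohort
#'
#' Every donor is run on every condition (the paired design of the
#' benchtop protocol). Donor-to-donor variability enters as a single
#' multiplicative factor on the accretion base rate, drawn once per donor
#' and shared across that donor's runs; aPTT covariates are drawn uniform
#' over the inclusion range.
#'
#' @param conditions A data frame with columns `pd`, `u_cm_min` and
#'   optionally `path_length_mm` (default 20), one row per condition.
#' @param donors Number of donors.
#' @param donor_effect_sd Log-scale standard deviation of the donor
#'   multiplier (0 disables donor variability).
#' @param aptt_range aPTT inclusion range, seconds.
#' @param seed Cohort seed; all per-run seeds derive from it.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(conditions, donors = 6, donor_effect_sd = 0.15,
                          aptt_range = c(20, 50), seed = 1) {
  stopifnot(
    is.data.frame(conditions),
    all(c("pd", "u_cm_min") %in% names(conditions)),
    donors >= 1, donor_effect_sd >= 0, length(aptt_range) == 2
  )
  conditions <- tibble::as_tibble(conditions)
  if (!"path_length_mm" %in% names(conditions)) {
    conditions$path_length_mm <- 20
  }
  structure(
    list(
      conditions = conditions, donors = as.integer(donors),
      donor_effect_sd = donor_effect_sd, aptt_range = aptt_range,
      seed = seed
    ),
    class = "cohort_design"
  )
}

#' Generate a donor-paired synthetic cohort
#'
#' Runs the accretion simulator for the full cross of donors and
#' conditions in a [cohort_design()], producing per-run clot
#' segmentations, derived occlusion/resistance series and donor
#' covariates. Chamber masks are voxelized once per distinct chamber and
#' shared across runs; all randomness derives from the design seed.
#'
#' @param design A [cohort_design()].
#' @param params Baseline [clot_sim_params()]; the per-donor multiplier
#'   scales `base_rate`.
#' @param voxel_um Voxel size used for the phantoms.
#' @param keep_volumes Keep the clot segmentations as a list column
#'   (memory permitting); otherwise only summary volumes are returned.
#' @return A tibble with one row per run: donor, condition columns,
#'   covariates, per-run seed, total clot volume (mm^3), clot void
#'   fraction, and list columns `resistance` (a `resistance_series`) and,
#'   if requested, `clot`.
#' @export
generate_cohort <- function(design, params = clot_sim_params(),
                            voxel_um = 50, keep_volumes = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  nd <- design$donors
  conds <- design$conditions
  runs <- tidyr::expand_grid(
    donor = seq_len(nd),
    condition_id = seq_len(nrow(conds))
  )
  donor_mult <- if (design$donor_effect_sd > 0) {
    exp(stats::rnorm(nd, -design$donor_effect_sd^2 / 2, design$donor_effect_sd))
  } else {
    rep(1, nd)
  }
  aptt <- stats::runif(nd, design$aptt_range[1], design$aptt_range[2])
  run_seed <- sample.int(.Machine$integer.max - 1L, nrow(runs))

  solids <- vector("list", nrow(conds))
  results <- purrr::pmap(
    list(runs$donor, runs$condition_id, run_seed),
    function(dn, ci, sd_run) {
      cond_row <- conds[ci, ]
      spec <- chamber_spec(
        pd = cond_row$pd,
        path_length_mm = cond_row$path_length_mm
      )
      if (is.null(solids[[ci]])) {
        solids[[ci]] <<- voxelize_chamber(spec, voxel_um = voxel_um)
      }
      solid <- solids[[ci]]
      cond <- flow_condition(u_cm_min = cond_row$u_cm_min, spec = spec)
      p <- params
      p$base_rate <- params$base_rate * donor_mult[dn]
      p$seed <- sd_run
      seg <- simulate_clot(solid, cond, p, donor_id = dn, replicate = ci)
      void_mm3 <- sum(!solid$grid) * voxel_mm3(solid)
      chamber_mm3 <- prod(voxel_extent_mm(solid))
      v <- mask_volume_mm3(seg$clot)
      phi_final <- v / chamber_mm3 # occlusion as fraction of gross volume
      series <- simulate_resistance_series(
        spec, cond,
        clot_fraction = phi_final * seq(0, 1, length.out = 6)
      )
      list(
        seg = seg, clot_volume_mm3 = v,
        clot_void_fraction = v / void_mm3, resistance = series
      )
    }
  )

  out <- dplyr::bind_cols(
    runs,
    conds[runs$condition_id, ],
    tibble::tibble(
      donor_multiplier = donor_mult[runs$donor],
      aptt_s = aptt[runs$donor],
      seed = run_seed,
      clot_volume_mm3 = purrr::map_dbl(results, "clot_volume_mm3"),
      clot_void_fraction = purrr::map_dbl(results, "clot_void_fraction"),
      resistance = purrr::map(results, "resistance")
    )
  )
  if (keep_volumes) out$clot <- purrr::map(results, "seg")
  out
}
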